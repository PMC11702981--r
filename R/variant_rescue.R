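#' Mutant-allele fraction
#'
#' The fraction of reads supporting the mutant allele at a site. For
#' reporting, [maf_percent()] rounds half-up to the nearest whole percent
#' (so 44/98 = 0.449 reports as 45).
#'
#' @param alt,depth Mutant-supporting and total read counts (vectorized);
#'   `depth` must be positive and `0 <= alt <= depth`.
#' @return Numeric fraction(s) in \[0, 1\].
#' @examples
#' maf(44, 98)          # 0.4489796
#' maf_percent(44, 98)  # 45
#' @export
maf <- function(alt, depth) {
  if (any(depth <= 0)) abort("`depth` must be > 0")
  if (any(alt < 0) || any(alt > depth)) abort("need 0 <= alt <= depth")
  alt / depth
}

#' @rdname maf
#' @export
maf_percent <- function(alt, depth) {
  floor(maf(alt, depth) * 100 + 0.5)   # round half-up
}

#' Re-genotype variant sites from RNA-seq allele counts
#'
#' Applies the depth, allele-fraction and high-quality-read filters to a
#' table of per-site allele counts. A site is `excluded` when fewer than
#' `min_depth` reads map to it; `mutant` when its mutant-allele fraction is
#' at least `maf_cutoff` *and* at least `min_hq_reads` high-quality reads
#' (base and mapping quality > 30) support the mutant allele; `wildtype`
#' otherwise. Both thresholds are inclusive.
#'
#' @param records Tibble/data frame with columns `depth`, `alt`, `hq_alt`
#'   (and any id columns, which are carried through).
#' @param min_depth Minimum mapped reads for a site to be genotyped
#'   (default 10).
#' @param maf_cutoff Minimum mutant-allele fraction (default 0.1).
#' @param min_hq_reads Minimum high-quality mutant reads (default 5).
#' @return The input tibble with `maf` (NA for excluded sites) and `status`
#'   (`"excluded"`, `"wildtype"`, `"mutant"`) appended.
#' @examples
#' recs <- tibble::tibble(depth = c(9, 50, 100, 200),
#'                        alt = c(9, 5, 4, 10),
#'                        hq_alt = c(9, 5, 4, 10))
#' genotype_calls(recs)$status
#' @export
genotype_calls <- function(records, min_depth = 10, maf_cutoff = 0.1,
                           min_hq_reads = 5) {
  records <- as_tibble(records)
  req <- c("depth", "alt", "hq_alt")
  if (!all(req %in% names(records))) {
    abort("records need `depth`, `alt` and `hq_alt` columns")
  }
  with(records, {
    if (any(alt > depth)) abort("malformed counts: alt > depth")
    if (any(hq_alt > alt)) abort("malformed counts: hq_alt > alt")
    if (any(c(depth, alt, hq_alt) < 0)) abort("negative counts")
  })
  excluded <- records$depth < min_depth
  m <- ifelse(excluded, NA_real_, records$alt / records$depth)
  mutant <- !excluded & m >= maf_cutoff & records$hq_alt >= min_hq_reads
  records$maf <- m
  records$status <- ifelse(excluded, "excluded",
                           ifelse(mutant, "mutant", "wildtype"))
  records
}

#' Summarize how many predicted-pRF samples are explained
#'
#' Given the re-genotyping calls for the wild-type tumors predicted as
#' reduced-function, and per-sample MDM2/MDM4 amplification flags, reports
#' the fraction of samples explained by a rescued mutation, by
#' amplification, by either (union; the categories can overlap), and by
#' neither.
#'
#' @param calls Tibble from [genotype_calls()] with a `sample` column (one
#'   row per sample; a sample with any `mutant` site counts as rescued).
#' @param amplified Named logical vector of MDM2/MDM4 amplification flags,
#'   keyed by the same samples.
#' @return One-row tibble: `n`, `n_rescued`, `n_amplified`, `n_either`,
#'   `frac_rescued`, `frac_amplified`, `frac_either`, `frac_neither`.
#' @export
rescue_summary <- function(calls, amplified) {
  if (!all(c("sample", "status") %in% names(calls))) {
    abort("`calls` needs `sample` and `status` columns")
  }
  samples <- unique(calls$sample)
  if (!setequal(samples, names(amplified))) {
    abort("`calls` and `amplified` must be keyed by the same samples")
  }
  rescued_ids <- unique(calls$sample[calls$status == "mutant"])
  amp_ids <- names(amplified)[amplified]
  n <- length(samples)
  n_rescued <- length(rescued_ids)
  n_amp <- length(amp_ids)
  n_either <- length(union(rescued_ids, amp_ids))
  tibble(n = n, n_rescued = n_rescued, n_amplified = n_amp,
         n_either = n_either,
         frac_rescued = n_rescued / n, frac_amplified = n_amp / n,
         frac_either = n_either / n, frac_neither = 1 - n_either / n)
}
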