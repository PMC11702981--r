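#' The four-gene recombination-proficiency signature
#'
#' DNA-repair genes whose joint expression tracks homologous-recombination
#' proficiency and, inversely, sensitivity to platinum-based chemotherapy:
#' RIF1, PARI (gene symbol F2R), RAD51 and Ku80 (gene symbol XRCC5).
#'
#' @return Character vector of the four gene symbols.
#' @export
rps_genes <- function() c("RIF1", "F2R", "RAD51", "XRCC5")

#' Recombination proficiency score (RPS)
#'
#' Chemosensitivity estimate per sample: the negative GSVA enrichment of
#' the four-gene DNA-repair set, computed on the TPM layer. Lower repair
#' proficiency (more negative enrichment of the repair genes) gives a
#' higher predicted platinum sensitivity, hence the sign flip.
#'
#' @param tpm Gene-by-sample TPM matrix (>= 3 samples).
#' @param genes Signature genes (default [rps_genes()]); at least one must
#'   be present in the matrix.
#' @param ... Passed to [gsva_score()].
#' @return Named numeric vector of per-sample RPS values.
#' @export
rps_score <- function(tpm, genes = rps_genes(), ...) {
  present <- intersect(genes, rownames(tpm))
  if (length(present) == 0) {
    abort("none of the RPS signature genes is present in the matrix")
  }
  -gsva_score(tpm, present, ...)
}

#' Radiation sensitivity signature (RSS) scores
#'
#' The published radiation-sensitivity panel splits into genes positively
#' and negatively correlated with radiation sensitivity; each subset is
#' GSVA-scored independently on the TPM layer. Increased sensitivity shows
#' as a higher positive-subset score and a lower negative-subset score.
#'
#' The 51-gene panel itself is not bundled: supply the published membership
#' (e.g. via [read_gmt()]) as two sets.
#'
#' @param tpm Gene-by-sample TPM matrix.
#' @param positive,negative Character vectors of subset gene ids; they must
#'   be disjoint and each must intersect the matrix.
#' @param exclude Optional genes removed from both subsets before scoring
#'   (e.g. genes overlapping the classifier features).
#' @param ... Passed to [gsva_score()].
#' @return Tibble with `sample`, `rss_positive`, `rss_negative`.
#' @export
rss_scores <- function(tpm, positive, negative, exclude = NULL, ...) {
  if (length(intersect(positive, negative)) > 0) {
    abort("a gene appears in both the positive and negative RSS subsets")
  }
  positive <- setdiff(positive, exclude)
  negative <- setdiff(negative, exclude)
  if (length(intersect(positive, rownames(tpm))) == 0 ||
      length(intersect(negative, rownames(tpm))) == 0) {
    abort("an RSS subset has no genes in the matrix after filtering")
  }
  tibble(
    sample = colnames(tpm),
    rss_positive = unname(gsva_score(tpm, positive, ...)),
    rss_negative = unname(gsva_score(tpm, negative, ...))
  )
}

#' Two-group comparison of per-sample scores
#'
#' Two-sided Wilcoxon rank-sum test between two groups of scores, with the
#' exact null distribution when the combined sample is small (<= 20) and
#' tie-free, and the tie-corrected normal approximation otherwise.
#'
#' @param scores Numeric vector of per-sample values.
#' @param groups Vector with exactly two distinct values aligned with
#'   `scores`.
#' @return One-row tibble: the two group labels, sizes, medians, the
#'   p-value and the method used.
#' @export
compare_groups <- function(scores, groups) {
  if (length(scores) != length(groups)) {
    abort("`scores` and `groups` must have the same length")
  }
  keep <- !is.na(scores) & !is.na(groups)
  scores <- scores[keep]
  groups <- as.character(groups[keep])
  lv <- unique(groups)
  if (length(lv) != 2) abort("`groups` must contain exactly two groups")
  xa <- scores[groups == lv[1]]
  xb <- scores[groups == lv[2]]
  if (length(xa) == 0 || length(xb) == 0) abort("empty group")
  n <- length(scores)
  exact <- n <= 20 && !anyDuplicated(scores)
  p <- suppressWarnings(
    wilcox.test(xa, xb, alternative = "two.sided", exact = exact,
                correct = TRUE)$p.value
  )
  tibble(group1 = lv[1], group2 = lv[2],
         n1 = length(xa), n2 = length(xb),
         median1 = median(xa), median2 = median(xb),
         p_value = p,
         method = if (exact) "wilcoxon_exact" else "wilcoxon_normal")
}
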