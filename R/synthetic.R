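#' Simulate a multi-group expression cohort with a latent p53-activity truth
#'
#' Generates a desk-scale RNA-seq cohort with the group structure used
#' throughout the package: adjacent normal tissue (NT), wild-type tumors
#' (WT), missense/in-frame-mutant tumors (MM), and truncating-mutant tumors
#' (TM). Each sample carries a latent p53 activity `a` (1 = normal,
#' 0 = reduced): all NT samples have `a = 1`, all TM samples `a = 0`, and a
#' configurable fraction of WT/MM samples have `a = 0`. Genes fall into
#' three classes: p53-activated targets (down-regulated by a factor
#' `2^-delta` when activity is lost), p53-repressed targets (up-regulated by
#' `2^delta`), and unaffected background genes.
#'
#' Counts are negative-binomial around gene-specific log-normal baselines,
#' scaled by log-normal per-sample library-size factors. The `tpm` and
#' `log2fpkm` layers are derived from the sampled counts (all genes are
#' given a fixed 1-kb length, so FPKM and TPM coincide), which preserves
#' sampling noise in every layer.
#'
#' @param n_nt,n_wt,n_mm,n_tm Sample counts per group.
#' @param n_background Number of unaffected background genes.
#' @param n_activated Number of p53-activated candidate target genes.
#' @param n_repressed Number of p53-repressed candidate target genes.
#' @param delta Log2 effect size of p53-activity loss on target genes.
#' @param phi_wt_rf Fraction of WT samples with latent reduced function.
#' @param phi_mm_rf Fraction of MM samples with latent reduced function.
#' @param dispersion Negative-binomial dispersion (NB size = 1/dispersion).
#' @param libsize_sigma Log-normal sd of per-sample library-size factors.
#' @param baseline_meanlog,baseline_sdlog Log-normal parameters of the
#'   per-gene baseline mean counts.
#' @param cohort Cohort tag recorded in the sample sheet.
#' @param seed Integer seed; identical seeds give bit-identical cohorts.
#'
#' @return A `p53_cohort` object: a list with matrices `counts`, `log2fpkm`
#'   and `tpm` (genes x samples), a `samples` tibble (`sample`, `group`,
#'   `cohort`), and a `truth` list holding the per-gene classes/effects and
#'   the per-sample latent activity.
#' @examples
#' cohort <- simulate_cohort(n_nt = 10, n_wt = 10, n_mm = 5, n_tm = 10,
#'                           n_background = 50, n_activated = 10,
#'                           n_repressed = 5, seed = 1)
#' dim(cohort$counts)
#' dplyr::count(cohort$samples, group)
#' @export
simulate_cohort <- function(n_nt = 60, n_wt = 100, n_mm = 50, n_tm = 60,
                            n_background = 853, n_activated = 116,
                            n_repressed = 31, delta = 1.5,
                            phi_wt_rf = 0.9, phi_mm_rf = 0.99,
                            dispersion = 0.1, libsize_sigma = 0.25,
                            baseline_meanlog = log(100), baseline_sdlog = 1,
                            cohort = "SYNTH", seed = 1) {
  counts_in <- c(n_nt = n_nt, n_wt = n_wt, n_mm = n_mm, n_tm = n_tm,
                 n_background = n_background, n_activated = n_activated,
                 n_repressed = n_repressed)
  if (any(counts_in < 0) || any(counts_in != round(counts_in))) {
    abort("all sample and gene counts must be non-negative integers")
  }
  if (delta < 0) abort("`delta` must be >= 0")
  if (phi_wt_rf < 0 || phi_wt_rf > 1 || phi_mm_rf < 0 || phi_mm_rf > 1) {
    abort("`phi_wt_rf` and `phi_mm_rf` must lie in [0, 1]")
  }
  if (dispersion <= 0) abort("`dispersion` must be > 0")
  if (libsize_sigma < 0) abort("`libsize_sigma` must be >= 0")
  n_genes <- n_background + n_activated + n_repressed
  n_samples <- n_nt + n_wt + n_mm + n_tm
  if (n_genes < 2) abort("need at least 2 genes in total")
  if (n_samples < 4 || n_nt < 1 || n_tm < 1) {
    abort("need >= 4 samples in total with n_nt >= 1 and n_tm >= 1")
  }

  set.seed(child_seed(seed, 1L))

  genes <- c(sprintf("ACT%03d", seq_len(n_activated)),
             sprintf("REP%03d", seq_len(n_repressed)),
             sprintf("BG%04d", seq_len(n_background)))
  gene_class <- rep(c("activated", "repressed", "background"),
                    c(n_activated, n_repressed, n_background))
  baseline <- rlnorm(n_genes, meanlog = baseline_meanlog,
                     sdlog = baseline_sdlog)

  group <- rep(c("NT", "WT", "MM", "TM"), c(n_nt, n_wt, n_mm, n_tm))
  sample_id <- paste0(group, "_",
                      sprintf("%03d", unlist(lapply(c(n_nt, n_wt, n_mm, n_tm),
                                                    seq_len))))
  activity <- integer(n_samples)
  activity[group == "NT"] <- 1L
  activity[group == "TM"] <- 0L
  activity[group == "WT"] <- 1L - rbinom(n_wt, 1L, phi_wt_rf)
  activity[group == "MM"] <- 1L - rbinom(n_mm, 1L, phi_mm_rf)

  # per-gene multiplicative effect in reduced-activity samples
  effect <- rep(1, n_genes)
  effect[gene_class == "activated"] <- 2^(-delta)
  effect[gene_class == "repressed"] <- 2^(delta)

  libfac <- rlnorm(n_samples, 0, libsize_sigma)
  mu <- outer(baseline, libfac)           # genes x samples
  reduced <- activity == 0L
  if (any(reduced)) mu[, reduced] <- mu[, reduced, drop = FALSE] * effect

  counts <- matrix(rnbinom(length(mu), mu = mu, size = 1 / dispersion),
                   nrow = n_genes, dimnames = list(genes, sample_id))
  libsize <- colSums(counts)
  if (any(libsize == 0)) {
    abort("simulated a sample with zero total counts; increase baselines")
  }
  # fixed 1-kb gene lengths make FPKM and TPM numerically identical
  tpm <- sweep(counts, 2, libsize / 1e6, "/")
  log2fpkm <- log2(tpm + 1)

  samples <- tibble(sample = sample_id, group = group, cohort = cohort)
  truth <- list(
    genes = tibble(gene = genes, class = gene_class,
                   baseline = baseline, effect = effect),
    samples = tibble(sample = sample_id, group = group, activity = activity)
  )
  structure(
    list(counts = counts, log2fpkm = log2fpkm, tpm = tpm,
         samples = samples, truth = truth),
    config = list(n_nt = n_nt, n_wt = n_wt, n_mm = n_mm, n_tm = n_tm,
                  n_background = n_background, n_activated = n_activated,
                  n_repressed = n_repressed, delta = delta,
                  phi_wt_rf = phi_wt_rf, phi_mm_rf = phi_mm_rf,
                  dispersion = dispersion, libsize_sigma = libsize_sigma,
                  baseline_meanlog = baseline_meanlog,
                  baseline_sdlog = baseline_sdlog,
                  cohort = cohort, seed = seed),
    class = "p53_cohort"
  )
}

#' @export
print.p53_cohort <- function(x, ...) {
  cfg <- attr(x, "config")
  cat("<p53_cohort> ", nrow(x$counts), " genes x ", ncol(x$counts),
      " samples (", cfg$cohort, ")\n", sep = "")
  print(count(x$samples, .data$group))
  invisible(x)
}

#' Candidate p53-target gene list of a simulated cohort
#'
#' Extracts the activated/repressed candidate genes (the simulated analogue
#' of a literature-derived p53-target list) from a [simulate_cohort()]
#' truth table, optionally together with the background genes.
#'
#' @param cohort A `p53_cohort`.
#' @param include_background Also return background genes (for contamination
#'   checks).
#' @return Tibble with columns `gene` and `class`.
#' @export
candidate_genes <- function(cohort, include_background = FALSE) {
  stopifnot(inherits(cohort, "p53_cohort"))
  out <- cohort$truth$genes[, c("gene", "class")]
  if (!include_background) out <- out[out$class != "background", ]
  as_tibble(out)
}

#' Simulate per-site RNA-seq allele-count records with known genotypes
#'
#' Produces one allele-count record per site: total depth is Poisson around
#' `mean_depth` (truncated at 1), alt reads are binomial at the site's true
#' mutant-allele fraction, and each alt read independently passes the
#' high-quality filter (base and mapping quality > 30) with probability
#' `hq_fraction`.
#'
#' @param n_sites Number of sites (one per synthetic sample).
#' @param mean_depth Mean sequencing depth per site; must be > 0.
#' @param true_maf Per-site true mutant-allele fractions, recycled to
#'   `n_sites`. `NULL` draws them: half the sites are wild-type (0), the
#'   rest uniform on \[0.15, 0.55\].
#' @param hq_fraction Probability an alt read is high-quality; in \[0, 1\].
#' @param seed Integer seed.
#' @return List with `records` (tibble: `sample`, `site`, `depth`, `alt`,
#'   `hq_alt`) and `truth` (tibble: `sample`, `site`, `true_maf`,
#'   `genotype`).
#' @export
simulate_allele_counts <- function(n_sites = 200, mean_depth = 100,
                                   true_maf = NULL, hq_fraction = 0.95,
                                   seed = 1) {
  if (n_sites < 1) abort("`n_sites` must be >= 1")
  if (mean_depth <= 0) abort("`mean_depth` must be > 0")
  if (hq_fraction < 0 || hq_fraction > 1) {
    abort("`hq_fraction` must lie in [0, 1]")
  }
  set.seed(child_seed(seed, 2L))
  if (is.null(true_maf)) {
    wt <- runif(n_sites) < 0.5
    true_maf <- ifelse(wt, 0, runif(n_sites, 0.15, 0.55))
  } else {
    if (any(true_maf < 0 | true_maf > 1)) abort("`true_maf` must lie in [0, 1]")
    true_maf <- rep_len(true_maf, n_sites)
  }
  depth <- pmax(1L, rpois(n_sites, mean_depth))
  alt <- rbinom(n_sites, depth, true_maf)
  hq_alt <- rbinom(n_sites, alt, hq_fraction)
  ids <- sprintf("S%04d", seq_len(n_sites))
  sites <- sprintf("chr17:site%04d", seq_len(n_sites))
  list(
    records = tibble(sample = ids, site = sites, depth = depth,
                     alt = alt, hq_alt = hq_alt),
    truth = tibble(sample = ids, site = sites, true_maf = true_maf,
                   genotype = ifelse(true_maf > 0, "mutant", "wildtype"))
  )
}

#' Simulate PDX radiotherapy survival ratios with a bimodal responder mix
#'
#' Median survival under placebo is log-normal around `placebo_mean` days;
#' the RT/placebo survival ratio is drawn from a two-component normal
#' mixture (a non-responder mode near 1 and a responder mode near 2), and
#' each model additionally carries a latent predicted p53 status (pRF/pN)
#' associated with responder membership at a configurable odds ratio.
#'
#' @param n_models Number of PDX models.
#' @param responder_fraction Fraction of models drawn from the responder
#'   mode.
#' @param mode_nonresponder,mode_responder Mixture mode locations (both must
#'   be > 0).
#' @param spread_nonresponder,spread_responder Mixture mode sds.
#' @param status_or Odds ratio linking pRF status to responder membership.
#' @param p_prf_nonresponder Probability a non-responder model is pRF.
#' @param placebo_mean Mean placebo median-survival in days.
#' @param seed Integer seed.
#' @return List with `models` (tibble: `model`, `rt_median`,
#'   `placebo_median`, `ratio`) and `truth` (tibble: `model`, `responder`,
#'   `status`).
#' @export
simulate_pdx <- function(n_models = 35, responder_fraction = 0.4,
                         mode_nonresponder = 1.0, mode_responder = 2.0,
                         spread_nonresponder = 0.1, spread_responder = 0.3,
                         status_or = 20, p_prf_nonresponder = 0.3,
                         placebo_mean = 40, seed = 1) {
  if (n_models < 1) abort("`n_models` must be >= 1")
  if (responder_fraction < 0 || responder_fraction > 1) {
    abort("`responder_fraction` must lie in [0, 1]")
  }
  if (mode_nonresponder <= 0 || mode_responder <= 0) {
    abort("both mixture modes must be > 0")
  }
  if (status_or <= 0) abort("`status_or` must be > 0")
  set.seed(child_seed(seed, 3L))
  responder <- runif(n_models) < responder_fraction
  mu <- ifelse(responder, mode_responder, mode_nonresponder)
  sigma <- ifelse(responder, spread_responder, spread_nonresponder)
  ratio <- pmax(0.05, rnorm(n_models, mu, sigma))
  odds0 <- p_prf_nonresponder / (1 - p_prf_nonresponder)
  p_prf_responder <- status_or * odds0 / (1 + status_or * odds0)
  p_prf <- ifelse(responder, p_prf_responder, p_prf_nonresponder)
  status <- ifelse(runif(n_models) < p_prf, "pRF", "pN")
  placebo <- rlnorm(n_models, log(placebo_mean), 0.3)
  ids <- sprintf("PDX%03d", seq_len(n_models))
  list(
    models = tibble(model = ids, rt_median = placebo * ratio,
                    placebo_median = placebo, ratio = ratio),
    truth = tibble(model = ids, responder = responder, status = status)
  )
}

# deterministic per-generator child seed from one global seed
child_seed <- function(seed, k) {
  (abs(as.integer(seed)) + 977003L * as.integer(k)) %% 2147483647L
}

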