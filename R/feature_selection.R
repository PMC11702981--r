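#' Filter candidate genes by expression level
#'
#' Keeps candidate p53-target genes whose median TPM across the reference
#' samples strictly exceeds `min_median_tpm`. This mirrors the basal
#' expression screen applied to the literature-derived candidate list
#' before differential expression: genes that are essentially silent in
#' the reference tissue carry no usable signal.
#'
#' @param tpm Gene-by-sample TPM matrix (genes in rows, named).
#' @param candidates Tibble/data frame with columns `gene` and `class`
#'   (`"activated"` or `"repressed"`).
#' @param min_median_tpm Strict lower bound on the per-gene median TPM
#'   (default 1: a gene with median exactly 1 is excluded).
#' @return The `candidates` rows that pass the filter, as a tibble.
#'   Candidates absent from the matrix are dropped with a warning.
#' @examples
#' tpm <- rbind(A = c(0.5, 2, 3), B = c(0, 0, 0))
#' colnames(tpm) <- paste0("s", 1:3)
#' cands <- tibble::tibble(gene = c("A", "B"), class = "activated")
#' filter_expressed(tpm, cands)   # keeps A (median 2), drops B
#' @export
filter_expressed <- function(tpm, candidates, min_median_tpm = 1) {
  candidates <- as_tibble(candidates)
  check_candidates(candidates)
  missing <- setdiff(candidates$gene, rownames(tpm))
  if (length(missing) > 0) {
    warn(paste0(length(missing), " candidate gene(s) absent from the matrix",
                " and skipped: ", paste(head(missing, 5), collapse = ", "),
                if (length(missing) > 5) ", ..."))
    candidates <- candidates[!candidates$gene %in% missing, ]
  }
  if (nrow(candidates) == 0) return(candidates)
  med <- apply(tpm[candidates$gene, , drop = FALSE], 1, median)
  candidates[med > min_median_tpm, ]
}

#' Median-of-ratios size factors
#'
#' Per-sample normalization factors computed as the median across genes of
#' the ratio between a sample's counts and the per-gene geometric mean,
#' using only genes with nonzero counts in every sample.
#'
#' @param counts Gene-by-sample count matrix.
#' @return Named numeric vector of positive size factors, one per sample.
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  if (all(counts == 0)) abort("all-zero count matrix: size factors undefined")
  if (ncol(counts) == 1) {
    return(setNames(1, colnames(counts)))
  }
  log_geo <- rowMeans(log(counts))          # -Inf for genes with any zero
  usable <- is.finite(log_geo)
  if (!any(usable)) {
    # no gene is expressed everywhere: fall back to library-size ratios
    warn("no gene has nonzero counts in all samples; using library-size factors")
    ls <- colSums(counts)
    return(setNames(ls / exp(mean(log(ls))), colnames(counts)))
  }
  sf <- apply(counts[usable, , drop = FALSE], 2, function(cnt) {
    exp(median(log(cnt) - log_geo[usable]))
  })
  setNames(sf, colnames(counts))
}

#' Two-group differential expression on normalized counts
#'
#' Compares two sample groups (canonically NT vs TM) gene by gene:
#' counts are scaled by median-of-ratios size factors computed on the two
#' groups jointly, log2-transformed with a pseudo-count of 1, and tested
#' with Welch's two-sample t-test. P-values are Benjamini-Hochberg adjusted
#' across the tested genes. The log2 fold change is the difference of the
#' group means of normalized counts on the log2 scale (group B relative to
#' group A, so with A = NT and B = TM, "down in TM" is negative).
#'
#' @param counts Gene-by-sample count matrix.
#' @param group_a,group_b Disjoint character vectors of sample names, each
#'   of length >= 2.
#' @param genes Genes to test (default: all rows).
#' @return Tibble with one row per tested gene: `gene`, `mean_a`, `mean_b`
#'   (normalized-count means), `log2fc`, `pvalue`, `padj`, and `flag`
#'   (`"ok"` or `"all_zero_group"` when one group has no counts for the
#'   gene and the fold change rests on the pseudo-count alone).
#' @export
differential_expression <- function(counts, group_a, group_b,
                                    genes = rownames(counts)) {
  counts <- as.matrix(counts)
  if (length(intersect(group_a, group_b)) > 0) {
    abort("`group_a` and `group_b` must be disjoint")
  }
  if (length(group_a) < 2 || length(group_b) < 2) {
    abort("each group needs at least 2 samples")
  }
  miss <- setdiff(c(group_a, group_b), colnames(counts))
  if (length(miss) > 0) {
    abort(paste("samples absent from the matrix:",
                paste(head(miss, 5), collapse = ", ")))
  }
  genes <- intersect(genes, rownames(counts))
  if (length(genes) == 0) abort("no requested gene is present in the matrix")

  sub <- counts[, c(group_a, group_b), drop = FALSE]
  sf <- size_factors(sub)
  norm <- sweep(sub, 2, sf, "/")
  logn <- log2(norm + 1)
  ia <- seq_along(group_a)
  ib <- length(group_a) + seq_along(group_b)

  res <- map(genes, function(g) {
    xa <- logn[g, ia]
    xb <- logn[g, ib]
    mean_a <- mean(norm[g, ia])
    mean_b <- mean(norm[g, ib])
    log2fc <- log2(mean_b + 1) - log2(mean_a + 1)
    p <- welch_p(xa, xb)
    flag <- if (mean_a == 0 || mean_b == 0) "all_zero_group" else "ok"
    tibble(gene = g, mean_a = mean_a, mean_b = mean_b,
           log2fc = log2fc, pvalue = p, flag = flag)
  })
  out <- list_rbind(res)
  out$padj <- p.adjust(out$pvalue, method = "BH")
  out[, c("gene", "mean_a", "mean_b", "log2fc", "pvalue", "padj", "flag")]
}

# Welch two-sample t-test p-value; 1 when both groups are constant and equal,
# 0-distance constant groups that differ get p ~ 0 via the t statistic.
welch_p <- function(xa, xb) {
  va <- var(xa); vb <- var(xb)
  if (va == 0 && vb == 0) {
    return(if (mean(xa) == mean(xb)) 1 else 0)
  }
  na <- length(xa); nb <- length(xb)
  se2 <- va / na + vb / nb
  tstat <- (mean(xa) - mean(xb)) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  2 * pt(-abs(tstat), df)
}

#' Select the down- and up-regulated p53-target gene sets
#'
#' Applies the significance thresholds to a differential-expression table:
#' a gene joins the DR ("down-regulated upon p53 truncation") set when its
#' adjusted p-value is at most `adj_p_max` and its fold change is at most
#' 1/`min_abs_fc`; it joins the UR set when the adjusted p-value passes and
#' the fold change is at least `min_abs_fc`. Both boundaries are inclusive
#' (adjusted p = 0.05 and |fold change| = 2 qualify under the defaults).
#'
#' @param de Tibble from [differential_expression()] (needs `gene`,
#'   `log2fc`, `padj`).
#' @param adj_p_max Adjusted p-value ceiling (default 0.05).
#' @param min_abs_fc Minimum absolute fold change on the linear scale
#'   (default 2, i.e. |log2 fold change| >= 1).
#' @param cohort Cohort tag stored on the result.
#' @return A `p53_geneset_pair`: list with sorted character vectors `dr`
#'   and `ur`, plus `cohort` and `thresholds`.
#' @export
select_gene_sets <- function(de, adj_p_max = 0.05, min_abs_fc = 2,
                             cohort = "cohort") {
  if (adj_p_max <= 0 || min_abs_fc <= 0) abort("thresholds must be positive")
  lfc_min <- log2(min_abs_fc)
  sig <- de$padj <= adj_p_max
  dr <- sort(de$gene[sig & de$log2fc <= -lfc_min])
  ur <- sort(de$gene[sig & de$log2fc >= lfc_min])
  if (length(dr) == 0 || length(ur) == 0) {
    abort(paste0("empty ", if (length(dr) == 0) "DR" else "UR",
                 " set at adj_p_max = ", adj_p_max, ", min_abs_fc = ",
                 min_abs_fc, "; composite scores need both sets. ",
                 "Smallest adjusted p among candidates: ",
                 signif(min(de$padj), 3)))
  }
  new_geneset_pair(dr, ur, cohort,
                   thresholds = list(adj_p_max = adj_p_max,
                                     min_abs_fc = min_abs_fc))
}

new_geneset_pair <- function(dr, ur, cohort = "cohort", thresholds = list()) {
  if (length(intersect(dr, ur)) > 0) {
    abort("DR and UR sets overlap; a gene cannot move both ways")
  }
  structure(list(dr = sort(unique(dr)), ur = sort(unique(ur)),
                 cohort = cohort, thresholds = thresholds),
            class = "p53_geneset_pair")
}

#' Construct a DR/UR gene-set pair directly
#'
#' Bypasses differential expression when the two direction-tagged sets are
#' already known (e.g. read from a GMT file).
#'
#' @param dr,ur Character vectors of gene ids (disjoint).
#' @param cohort Cohort tag.
#' @return A `p53_geneset_pair`.
#' @export
geneset_pair <- function(dr, ur, cohort = "cohort") {
  new_geneset_pair(dr, ur, cohort)
}

#' @export
print.p53_geneset_pair <- function(x, ...) {
  cat("<p53_geneset_pair> cohort ", x$cohort, ": ",
      length(x$dr), " DR / ", length(x$ur), " UR genes\n", sep = "")
  invisible(x)
}

check_candidates <- function(candidates) {
  if (!all(c("gene", "class") %in% names(candidates))) {
    abort("candidates need `gene` and `class` columns")
  }
  if (nrow(candidates) == 0) abort("empty candidate list")
  if (anyDuplicated(candidates$gene)) {
    abort("duplicate gene ids in the candidate list")
  }
  invisible(candidates)
}

#' Run the gene-selection stage end to end
#'
#' Convenience wrapper: expression filter on the TPM layer, NT-vs-TM
#' differential expression on the count layer, and threshold selection.
#'
#' @param cohort A `p53_cohort` (or any list with `counts`, `tpm`,
#'   `samples`).
#' @param candidates Candidate gene tibble (`gene`, `class`).
#' @param nt_samples,tm_samples Sample ids of the two reference groups;
#'   default: taken from the sample sheet.
#' @param adj_p_max,min_abs_fc,min_median_tpm Thresholds, see
#'   [select_gene_sets()] and [filter_expressed()].
#' @return A `p53_geneset_pair` with the DE table attached as attribute
#'   `"de"`.
#' @export
select_p53_genesets <- function(cohort, candidates,
                                nt_samples = NULL, tm_samples = NULL,
                                adj_p_max = 0.05, min_abs_fc = 2,
                                min_median_tpm = 1) {
  nt_samples <- nt_samples %||%
    cohort$samples$sample[cohort$samples$group == "NT"]
  tm_samples <- tm_samples %||%
    cohort$samples$sample[cohort$samples$group == "TM"]
  expressed <- filter_expressed(cohort$tpm, candidates,
                                min_median_tpm = min_median_tpm)
  if (nrow(expressed) == 0) abort("no candidate passes the expression filter")
  de <- differential_expression(cohort$counts, nt_samples, tm_samples,
                                genes = expressed$gene)
  pair <- select_gene_sets(de, adj_p_max = adj_p_max,
                           min_abs_fc = min_abs_fc,
                           cohort = cohort$samples$cohort[1] %||% "cohort")
  attr(pair, "de") <- de
  pair
}
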