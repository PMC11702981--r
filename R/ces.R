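#' Combined Z-score of a gene set
#'
#' Each gene's log2 expression is standardized across samples,
#' `z = (x - mu) / sigma`, and a sample's set score is the sum of its
#' standardized values over the `k` set genes divided by `sqrt(k)`. Under
#' independence this keeps the null variance at 1 regardless of set size.
#'
#' Genes with zero cross-sample variance carry no information and are
#' dropped with a warning; standardization statistics can be restricted to
#' a reference subset of samples (`ref`) so that scores for held-out
#' samples do not leak information from them.
#'
#' @param expr Gene-by-sample numeric matrix (log2 scale expected).
#' @param geneset Character vector of gene ids.
#' @param ref Samples used to estimate per-gene means/sds (default: all).
#' @return Named numeric vector of per-sample scores.
#' @examples
#' m <- matrix(rnorm(40), 4, 10,
#'             dimnames = list(paste0("g", 1:4), paste0("s", 1:10)))
#' combined_zscore(m, c("g1", "g2"))
#' @export
combined_zscore <- function(expr, geneset, ref = colnames(expr)) {
  expr <- as.matrix(expr)
  genes <- resolve_set(expr, geneset)
  mu <- rowMeans(expr[genes, ref, drop = FALSE])
  sigma <- apply(expr[genes, ref, drop = FALSE], 1, sd)
  if (any(sigma == 0)) {
    warn(paste("dropping", sum(sigma == 0),
               "zero-variance gene(s) from the combined Z-score"))
    genes <- genes[sigma > 0]
    mu <- mu[sigma > 0]
    sigma <- sigma[sigma > 0]
  }
  if (length(genes) == 0) abort("no set gene with nonzero variance")
  z <- (expr[genes, , drop = FALSE] - mu) / sigma
  colSums(z) / sqrt(length(genes))
}

#' Single-sample GSEA score of a gene set
#'
#' For each sample, genes are ranked by expression within the sample
#' (average ranks for ties) and traversed in decreasing order. The running
#' sum gains `rank^alpha` (normalized) at in-set genes and loses a uniform
#' step at out-of-set genes; the score is the sum of the running-sum
#' differences over the whole walk. Scores are finally divided by the range
#' (max - min) of scores across the reference samples, so different
#' cohorts live on a comparable scale.
#'
#' @param expr Gene-by-sample numeric matrix.
#' @param geneset Character vector of gene ids (must leave at least one
#'   out-of-set gene).
#' @param alpha Rank weight exponent (default 0.25).
#' @param rescale Divide by the global score range (default TRUE).
#' @param ref Samples defining the rescaling range (default: all).
#' @return Named numeric vector of per-sample scores.
#' @export
ssgsea_score <- function(expr, geneset, alpha = 0.25, rescale = TRUE,
                         ref = colnames(expr)) {
  expr <- as.matrix(expr)
  if (alpha < 0) abort("`alpha` must be >= 0")
  genes <- resolve_set(expr, geneset)
  idx <- match(genes, rownames(expr))
  if (length(idx) >= nrow(expr)) {
    abort("gene set covers the whole matrix: no out-of-set genes")
  }
  scores <- vapply(seq_len(ncol(expr)), function(j) {
    ssgsea_walk(expr[, j], rownames(expr), idx, alpha)
  }, numeric(1))
  names(scores) <- colnames(expr)
  if (rescale) {
    rng <- diff(range(scores[ref]))
    if (rng == 0) {
      warn("degenerate score range; skipping ssGSEA rescaling")
    } else {
      scores <- scores / rng
    }
  }
  scores
}

# integrated weighted KS running sum for one sample
ssgsea_walk <- function(x, gene_ids, set_idx, alpha) {
  n <- length(x)
  r <- rank(x)                                    # average ranks for ties
  ord <- order(-x, gene_ids)                      # walk order, stable by id
  inset <- ord %in% set_idx
  w <- r[ord]^alpha * inset
  step_in <- cumsum(w) / sum(w)
  step_out <- cumsum(!inset) / (n - length(set_idx))
  sum(step_in - step_out)
}

#' GSVA enrichment score of a gene set
#'
#' Per gene, a kernel estimate of the cross-sample cumulative expression
#' distribution is evaluated at each sample (Gaussian kernel with bandwidth
#' sd/4 by default, or the empirical CDF). Per sample, genes are ordered by
#' that statistic, given symmetric rank weights `|position - n/2|`, and a
#' weighted Kolmogorov-Smirnov running sum is accumulated; the score is the
#' sum of the largest positive and largest negative deviations of the walk.
#'
#' @param expr Gene-by-sample numeric matrix; at least 3 samples.
#' @param geneset Character vector of gene ids.
#' @param kernel `"gaussian"` (default) or `"ecdf"`.
#' @param tau Rank-weight exponent of the walk (default 1).
#' @param ref Samples used for the kernel CDF estimate (default: all).
#' @return Named numeric vector of per-sample scores.
#' @export
gsva_score <- function(expr, geneset, kernel = c("gaussian", "ecdf"),
                       tau = 1, ref = colnames(expr)) {
  expr <- as.matrix(expr)
  kernel <- match.arg(kernel)
  if (length(ref) < 3) abort("GSVA needs at least 3 reference samples")
  genes <- resolve_set(expr, geneset)
  z <- gsva_kcdf(expr, ref = ref, kernel = kernel)
  gsva_es(z, match(genes, rownames(expr)), tau = tau)
}

# kernel estimate of each gene's cross-sample cumulative distribution
gsva_kcdf <- function(expr, ref, kernel) {
  z <- matrix(0, nrow(expr), ncol(expr), dimnames = dimnames(expr))
  for (i in seq_len(nrow(expr))) {
    vals <- expr[i, ]
    refv <- expr[i, ref]
    if (kernel == "gaussian") {
      h <- sd(refv) / 4
      z[i, ] <- if (h == 0) 0.5 else
        rowMeans(pnorm(outer(vals, refv, "-") / h))
    } else {
      z[i, ] <- vapply(vals, function(v) mean(refv <= v), numeric(1))
    }
  }
  z
}

# weighted KS statistic per sample from the kcdf matrix
gsva_es <- function(z, set_idx, tau = 1) {
  n <- nrow(z)
  k <- length(set_idx)
  if (k >= n) abort("gene set covers the whole matrix: no out-of-set genes")
  ids <- rownames(z)
  scores <- vapply(seq_len(ncol(z)), function(j) {
    ord <- order(-z[, j], ids)                 # decreasing stat, stable by id
    w <- abs(seq_len(n) - n / 2)^tau
    inset <- ord %in% set_idx
    step_in <- cumsum(w * inset) / sum(w * inset)
    step_out <- cumsum(!inset) / (n - k)
    v <- step_in - step_out
    max(v, 0) + min(v, 0)
  }, numeric(1))
  setNames(scores, colnames(z))
}

#' First-principal-component score over all selected p53-target genes
#'
#' Standardizes each gene across the reference samples, extracts the first
#' principal axis of the reference sample cloud, and projects every sample
#' onto it. The sign is oriented so that the mean score of the NT reference
#' samples exceeds that of the TM reference samples (lost p53 activity then
#' always points the same way regardless of the arbitrary eigenvector
#' sign).
#'
#' @param expr Gene-by-sample numeric matrix.
#' @param geneset Gene ids to use (canonically the union of DR and UR).
#' @param nt_ref,tm_ref Sample ids anchoring the orientation.
#' @param ref Samples used for standardization and the principal axis
#'   (default: all).
#' @return Named numeric vector of per-sample scores.
#' @export
pc1_score <- function(expr, geneset, nt_ref, tm_ref, ref = colnames(expr)) {
  expr <- as.matrix(expr)
  if (ncol(expr) < 2) abort("PC1 needs at least 2 samples")
  genes <- resolve_set(expr, geneset)
  if (length(genes) < 2) abort("PC1 needs at least 2 usable genes")
  if (length(nt_ref) == 0 || length(tm_ref) == 0) {
    abort("both NT and TM orientation references are required")
  }
  mu <- rowMeans(expr[genes, ref, drop = FALSE])
  sigma <- apply(expr[genes, ref, drop = FALSE], 1, sd)
  keep <- sigma > 0
  if (!any(keep)) abort("degenerate input: all genes constant across samples")
  genes <- genes[keep]
  z <- (expr[genes, , drop = FALSE] - mu[keep]) / sigma[keep]
  pc <- prcomp(t(z[, ref, drop = FALSE]), center = FALSE, scale. = FALSE)
  if (pc$sdev[1] == 0) abort("degenerate input: all samples identical")
  scores <- drop(t(z) %*% pc$rotation[, 1])
  if (mean(scores[nt_ref]) < mean(scores[tm_ref])) scores <- -scores
  scores
}

#' Build the seven-score composite expression table
#'
#' Computes, for every sample, the seven composite expression scores used
#' as classifier features: GSVA, ssGSEA and combined Z-score separately for
#' the DR and UR gene sets, plus the PC1 score over the union of both sets.
#' The GSVA kernel estimate and the ssGSEA ranking are shared between the
#' DR and UR sets, so the table costs barely more than a single set.
#'
#' @param expr Gene-by-sample log2-expression matrix.
#' @param pair A `p53_geneset_pair` (fields `dr`, `ur`).
#' @param nt_ref,tm_ref Sample ids orienting the PC1 sign.
#' @param ref Reference samples for all cross-sample statistics
#'   (default: all samples). Pass the training partition during hold-out
#'   validation.
#' @param alpha ssGSEA rank-weight exponent.
#' @param kernel GSVA kernel (`"gaussian"` or `"ecdf"`).
#' @param tau GSVA rank-weight exponent.
#' @return A tibble with columns `sample`, `gsva_dr`, `gsva_ur`,
#'   `ssgsea_dr`, `ssgsea_ur`, `zscore_dr`, `zscore_ur`, `pc1`, in input
#'   sample order.
#' @export
build_ces_table <- function(expr, pair, nt_ref, tm_ref,
                            ref = colnames(expr), alpha = 0.25,
                            kernel = c("gaussian", "ecdf"), tau = 1) {
  expr <- as.matrix(expr)
  kernel <- match.arg(kernel)
  if (!inherits(pair, "p53_geneset_pair")) {
    abort("`pair` must be a p53_geneset_pair (see select_gene_sets())")
  }
  run <- function(label, fn) {
    tryCatch(fn(), error = function(e) {
      abort(paste0("CES column `", label, "` failed: ", conditionMessage(e)))
    })
  }
  z <- run("gsva", function() gsva_kcdf(expr, ref = ref, kernel = kernel))
  dr_idx <- match(resolve_set(expr, pair$dr), rownames(expr))
  ur_idx <- match(resolve_set(expr, pair$ur), rownames(expr))
  out <- tibble(
    sample = colnames(expr),
    gsva_dr = unname(run("gsva_dr", function() gsva_es(z, dr_idx, tau = tau))),
    gsva_ur = unname(run("gsva_ur", function() gsva_es(z, ur_idx, tau = tau))),
    ssgsea_dr = unname(run("ssgsea_dr", function()
      ssgsea_score(expr, pair$dr, alpha = alpha, ref = ref))),
    ssgsea_ur = unname(run("ssgsea_ur", function()
      ssgsea_score(expr, pair$ur, alpha = alpha, ref = ref))),
    zscore_dr = unname(run("zscore_dr", function()
      combined_zscore(expr, pair$dr, ref = ref))),
    zscore_ur = unname(run("zscore_ur", function()
      combined_zscore(expr, pair$ur, ref = ref))),
    pc1 = unname(run("pc1", function()
      pc1_score(expr, c(pair$dr, pair$ur), nt_ref, tm_ref, ref = ref)))
  )
  class(out) <- c("p53_ces", class(out))
  out
}

#' Fixed column order of the seven composite-score features
#'
#' @return Character vector of the seven CES column names.
#' @export
ces_feature_names <- function() {
  c("gsva_dr", "gsva_ur", "ssgsea_dr", "ssgsea_ur",
    "zscore_dr", "zscore_ur", "pc1")
}

resolve_set <- function(expr, geneset) {
  geneset <- unique(geneset)
  if (length(geneset) == 0) abort("empty gene set")
  present <- geneset[geneset %in% rownames(expr)]
  if (length(present) == 0) abort("no set gene is present in the matrix")
  if (length(present) < length(geneset)) {
    warn(paste(length(geneset) - length(present),
               "set gene(s) absent from the matrix and skipped"))
  }
  present
}
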