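# Independent, loop-level oracles for the scoring and testing primitives.
# These are deliberately written as literal enumerations of the published
# definitions, separate from the vectorized package implementations.

# integrated weighted KS running sum for a single sample, step by step
oracle_ssgsea_unscaled <- function(x, ids, set, alpha) {
  n <- length(x)
  rk <- rank(x)
  ord <- order(-x, ids)
  in_set <- ids[ord] %in% set
  denom_in <- sum(rk[ord][in_set]^alpha)
  n_out <- n - sum(in_set)
  p_in <- 0
  p_out <- 0
  total <- 0
  for (i in seq_len(n)) {
    if (in_set[i]) {
      p_in <- p_in + rk[ord[i]]^alpha / denom_in
    } else {
      p_out <- p_out + 1 / n_out
    }
    total <- total + (p_in - p_out)
  }
  total
}

# GSVA with the empirical-CDF kernel, enumerated per gene and sample
oracle_gsva_ecdf <- function(mat, set, tau = 1) {
  n <- nrow(mat)
  z <- mat
  for (i in seq_len(n)) {
    for (j in seq_len(ncol(mat))) {
      z[i, j] <- sum(mat[i, ] <= mat[i, j]) / ncol(mat)
    }
  }
  ids <- rownames(mat)
  out <- numeric(ncol(mat))
  for (j in seq_len(ncol(mat))) {
    ord <- order(-z[, j], ids)
    in_set <- ids[ord] %in% set
    w <- abs(seq_len(n) - n / 2)^tau
    denom_in <- sum(w[in_set])
    n_out <- n - sum(in_set)
    p_in <- 0
    p_out <- 0
    best_pos <- 0
    best_neg <- 0
    for (i in seq_len(n)) {
      if (in_set[i]) p_in <- p_in + w[i] / denom_in
      else p_out <- p_out + 1 / n_out
      v <- p_in - p_out
      if (v > best_pos) best_pos <- v
      if (v < best_neg) best_neg <- v
    }
    out[j] <- best_pos + best_neg
  }
  setNames(out, colnames(mat))
}

# AUROC as explicit pairwise concordance with half-credit ties
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + (p > q) + 0.5 * (p == q)
    }
  }
  total / (length(pos) * length(neg))
}

# two-sided Fisher p by exhaustive enumeration of tables with fixed margins,
# using log-factorials rather than dhyper
oracle_fisher_p <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d <- tab[2, 2]
  r1 <- a + b; r2 <- c_ + d; c1 <- a + c_; c2 <- b + d; n <- sum(tab)
  lp <- function(x) {
    lgamma(r1 + 1) + lgamma(r2 + 1) + lgamma(c1 + 1) + lgamma(c2 + 1) -
      lgamma(n + 1) - lgamma(x + 1) - lgamma(r1 - x + 1) -
      lgamma(c1 - x + 1) - lgamma(d - a + x + 1)
  }
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- exp(vapply(support, lp, numeric(1)))
  sum(probs[probs <= exp(lp(a)) * (1 + 1e-7)])
}
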