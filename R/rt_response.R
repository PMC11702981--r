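#' RT-to-placebo median-survival ratio
#'
#' @param rt_median,placebo_median Median survival in days under
#'   radiotherapy and placebo; both must be positive (vectorized).
#' @return `rt_median / placebo_median`.
#' @examples
#' survival_ratio(60.8, 40)  # 1.52
#' @export
survival_ratio <- function(rt_median, placebo_median) {
  if (any(rt_median <= 0) || any(placebo_median <= 0)) {
    abort("survival medians must be > 0")
  }
  rt_median / placebo_median
}

#' Locate the responder cutoff on the survival-ratio density
#'
#' Fits a Gaussian kernel density (Silverman's rule-of-thumb bandwidth) to
#' the survival ratios and returns the changing point: the location of the
#' deepest density minimum between the two largest modes. When the density
#' is unimodal, the ratios are too few (< 5), or degenerate, the published
#' default cutoff is returned with a warning instead of an error.
#'
#' @param ratios Numeric survival ratios.
#' @param fallback Cutoff used when no valley exists (default 1.52).
#' @return The cutoff value.
#' @export
find_cutoff <- function(ratios, fallback = 1.52) {
  ratios <- ratios[is.finite(ratios)]
  if (length(ratios) < 5 || diff(range(ratios)) == 0) {
    warn("too few or degenerate ratios; falling back to the default cutoff")
    return(fallback)
  }
  d <- density(ratios, bw = "nrd0")
  y <- d$y
  n <- length(y)
  peaks <- which(y > c(-Inf, y[-n]) & y >= c(y[-1], -Inf))
  peaks <- peaks[y[peaks] >= 0.1 * max(y)]   # ignore tail-noise bumps
  if (length(peaks) < 2) {
    warn("unimodal ratio density; falling back to the default cutoff")
    return(fallback)
  }
  top2 <- sort(peaks[order(y[peaks], decreasing = TRUE)][1:2])
  between <- seq(top2[1], top2[2])
  valley <- between[which.min(y[between])]
  # a shoulder on one mode is not a changing point: demand a real dip
  if (y[valley] > 0.5 * min(y[top2])) {
    warn(paste("no pronounced valley between ratio modes;",
               "falling back to the default cutoff"))
    return(fallback)
  }
  d$x[valley]
}

#' Classify radiotherapy responders from survival ratios
#'
#' A model is responsive when its RT/placebo median-survival ratio meets or
#' exceeds the cutoff (inclusive: a ratio of exactly 1.52 is responsive
#' under the default).
#'
#' @param ratios Finite numeric survival ratios.
#' @param cutoff Responder threshold (default 1.52).
#' @return Logical vector of responder flags.
#' @export
classify_responders <- function(ratios, cutoff = 1.52) {
  if (any(!is.finite(ratios))) abort("ratios must be finite")
  ratios >= cutoff
}

#' Exact association between two binary labelings
#'
#' Fisher's exact test on the 2x2 table of (e.g.) responder flags against
#' predicted p53 statuses: the two-sided p-value sums, over all tables with
#' the observed margins, the hypergeometric probabilities no larger than
#' that of the observed table (probability ordering). The sample
#' (cross-product) odds ratio is reported alongside.
#'
#' @param x Logical/binary vector, or a 2x2 count matrix (then `y` is
#'   ignored).
#' @param y Logical/binary vector aligned with `x`.
#' @return One-row tibble with `odds_ratio` and `p_value` (a degenerate
#'   margin gives p = 1 with a warning).
#' @examples
#' fisher_association(matrix(c(9, 2, 1, 8), 2))
#' @export
fisher_association <- function(x, y = NULL) {
  if (is.matrix(x)) {
    if (!all(dim(x) == 2)) abort("matrix input must be 2x2")
    tab <- x
  } else {
    if (is.null(y) || length(x) != length(y)) {
      abort("need two aligned binary vectors or a 2x2 matrix")
    }
    tab <- table(factor(as.logical(x), levels = c(TRUE, FALSE)),
                 factor(as.logical(y), levels = c(TRUE, FALSE)))
    tab <- unclass(tab)
  }
  if (any(tab < 0) || sum(tab) == 0) abort("invalid contingency table")
  a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d <- tab[2, 2]
  or <- (a * d) / (b * c_)   # may be Inf/NaN for zero cells
  r1 <- a + b; c1 <- a + c_; n <- sum(tab)
  if (r1 == 0 || r1 == n || c1 == 0 || c1 == n) {
    warn("degenerate margin; association undefined, reporting p = 1")
    return(tibble(odds_ratio = or, p_value = 1))
  }
  support <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- dhyper(support, c1, n - c1, r1)
  p_obs <- dhyper(a, c1, n - c1, r1)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  tibble(odds_ratio = or, p_value = min(1, p))
}
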