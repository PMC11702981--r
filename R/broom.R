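#' Tidy a trained classifier into its decision-rule terms
#'
#' @param x A `p53_classifier`.
#' @param ... Unused.
#' @return Tibble with one row per feature weight plus the bias term:
#'   `term`, `estimate`, `center`, `scale` (NA for the bias).
#' @exportS3Method generics::tidy
tidy.p53_classifier <- function(x, ...) {
  bind_rows(
    tibble(term = names(x$weights), estimate = unname(x$weights),
           center = unname(x$center), scale = unname(x$scale)),
    tibble(term = "(bias)", estimate = x$bias,
           center = NA_real_, scale = NA_real_)
  )
}

#' One-row summary of a trained classifier
#'
#' @param x A `p53_classifier`.
#' @param ... Unused.
#' @return Tibble with `cost`, `cv_accuracy` (at the chosen cost),
#'   `n_features`, `n_train`, `seed`.
#' @exportS3Method generics::glance
glance.p53_classifier <- function(x, ...) {
  tibble(cost = x$cost,
         cv_accuracy = x$cv$cv_accuracy[x$cv$cost == x$cost][1],
         n_features = length(x$weights),
         n_train = length(x$training_samples),
         seed = x$seed)
}

#' Per-repeat metrics of a hold-out validation
#'
#' @param x A `p53_validation`.
#' @param ... Unused.
#' @return The per-repeat metrics tibble (confusion counts, recall,
#'   precision, accuracy, F1, AUROC).
#' @exportS3Method generics::tidy
tidy.p53_validation <- function(x, ...) x$metrics

#' Mean metrics across hold-out repeats
#'
#' @param x A `p53_validation`.
#' @param ... Unused.
#' @return One-row tibble of metric means plus the repeat count.
#' @exportS3Method generics::glance
glance.p53_validation <- function(x, ...) {
  m <- x$metrics
  tibble(repeats = nrow(m),
         mean_recall = mean(m$recall), mean_precision = mean(m$precision),
         mean_accuracy = mean(m$accuracy), mean_f1 = mean(m$f1),
         mean_auroc = mean(m$auroc))
}

#' Tidy a DR/UR gene-set pair into a long table
#'
#' @param x A `p53_geneset_pair`.
#' @param ... Unused.
#' @return Tibble with `gene`, `direction` (`"DR"`/`"UR"`) and `cohort`.
#' @exportS3Method generics::tidy
tidy.p53_geneset_pair <- function(x, ...) {
  tibble(gene = c(x$dr, x$ur),
         direction = rep(c("DR", "UR"), c(length(x$dr), length(x$ur))),
         cohort = x$cohort)
}
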