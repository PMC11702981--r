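#' Train the linear maximum-margin classifier on CES features
#'
#' Fits a linear-kernel support vector machine on the seven composite
#' expression scores of the NT (coded 0, normal p53) and TM (coded 1,
#' reduced p53) reference groups. Features are standardized with
#' training-set statistics; the cost parameter `C` is chosen by stratified
#' k-fold cross-validated grid search (ties favor the smallest `C`). With a
#' linear kernel the RBF width parameter is inert, so only `C` is searched.
#'
#' @param features A CES tibble from [build_ces_table()] (column `sample`
#'   plus the seven scores), restricted to the training samples.
#' @param labels Numeric/integer vector of 0 (NT/normal) and 1
#'   (TM/reduced), aligned with `features` rows.
#' @param c_grid Candidate cost values.
#' @param n_folds Cross-validation folds for the grid search.
#' @param seed Integer seed controlling fold assignment.
#' @return A `p53_classifier`: weights over the seven features, bias,
#'   chosen cost, standardization center/scale, grid-search table, seed and
#'   training sample ids. Decision values are positive for predicted
#'   reduced function.
#' @export
train_p53_classifier <- function(features, labels,
                                 c_grid = c(0.01, 0.1, 1, 10, 100),
                                 n_folds = 5, seed = 1) {
  x <- ces_matrix(features)
  labels <- as.integer(labels)
  if (length(labels) != nrow(x)) abort("labels must align with feature rows")
  if (!all(labels %in% c(0L, 1L))) abort("labels must be coded 0/1")
  if (length(unique(labels)) < 2) abort("both classes must be present")
  if (nrow(x) < 4) abort("need at least 4 training samples")

  center <- colMeans(x)
  scale_ <- apply(x, 2, sd)
  scale_[scale_ == 0] <- 1
  xs <- scale(x, center = center, scale = scale_)

  folds <- stratified_folds(labels, n_folds, seed)
  cv <- map(c_grid, function(cost) {
    acc <- map_dbl(seq_len(max(folds)), function(f) {
      tr <- folds != f
      if (length(unique(labels[tr])) < 2) return(NA_real_)
      fit <- e1071::svm(xs[tr, , drop = FALSE], factor(labels[tr]),
                        kernel = "linear", cost = cost, scale = FALSE)
      mean(predict(fit, xs[!tr, , drop = FALSE]) == labels[!tr])
    })
    tibble(cost = cost, cv_accuracy = mean(acc, na.rm = TRUE))
  })
  cv <- list_rbind(cv)
  best <- cv$cost[which.max(cv$cv_accuracy)]   # first max -> smallest C

  fit <- e1071::svm(xs, factor(labels), kernel = "linear", cost = best,
                    scale = FALSE)
  w <- drop(t(fit$coefs) %*% fit$SV)
  b <- -fit$rho
  d <- drop(xs %*% w) + b
  if (mean(d[labels == 1]) < mean(d[labels == 0])) {   # positive = reduced
    w <- -w
    b <- -b
  }
  structure(
    list(weights = setNames(w, ces_feature_names()), bias = b, cost = best,
         center = center, scale = scale_, c_grid = c_grid, cv = cv,
         seed = seed, training_samples = features$sample %||% rownames(x)),
    class = "p53_classifier"
  )
}

#' @export
print.p53_classifier <- function(x, ...) {
  cat("<p53_classifier> linear kernel, C =", x$cost, "\n")
  cat("  trained on", length(x$training_samples), "samples\n")
  invisible(x)
}

#' Predict p53 functional status for new samples
#'
#' Applies a trained classifier to CES features (canonically the WT and MM
#' tumors excluded from training). A sample is labeled `pRF` (predicted
#' reduced function) when its signed decision value is positive under the
#' 1 = reduced coding, `pN` otherwise.
#'
#' @param object A `p53_classifier`.
#' @param features CES tibble (or matrix with the seven feature columns).
#' @param groups Optional original group per sample (e.g. WT/MM), recycled
#'   into the output.
#' @param ... Unused.
#' @return Tibble with `sample`, `group`, `decision` and `label`
#'   (`"pRF"`/`"pN"`); empty input yields an empty tibble.
#' @export
predict.p53_classifier <- function(object, features, groups = NULL, ...) {
  if (is.null(features) ||
      (is.data.frame(features) && nrow(features) == 0)) {
    return(tibble(sample = character(), group = character(),
                  decision = numeric(), label = character()))
  }
  x <- ces_matrix(features)
  d <- drop(scale(x, object$center, object$scale) %*% object$weights) +
    object$bias
  tibble(
    sample = if (is.data.frame(features) && "sample" %in% names(features))
      features$sample else rownames(x) %||% as.character(seq_len(nrow(x))),
    group = if (is.null(groups)) NA_character_ else rep_len(groups, nrow(x)),
    decision = unname(d),
    label = unname(ifelse(d > 0, "pRF", "pN"))
  )
}

#' Performance metrics from a confusion matrix
#'
#' Recall = TP/(TP+FN), precision = TP/(TP+FP), accuracy =
#' (TP+TN)/(TP+TN+FP+FN), and F1 = the harmonic mean of recall and
#' precision. Ratios with a zero denominator are reported as `NaN` with a
#' warning rather than silently coerced to 0.
#'
#' @param tp,fp,tn,fn Non-negative confusion counts.
#' @return One-row tibble with `tp`, `fp`, `tn`, `fn`, `recall`,
#'   `precision`, `accuracy`, `f1`.
#' @examples
#' compute_metrics(tp = 3, fp = 1, tn = 5, fn = 1)
#' @export
compute_metrics <- function(tp, fp, tn, fn) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("confusion counts must be non-negative integers")
  }
  total <- tp + fp + tn + fn
  if (total == 0) abort("no evaluated samples")
  safe_ratio <- function(num, den, what) {
    if (den == 0) {
      warn(paste(what, "undefined (zero denominator); reporting NaN"))
      return(NaN)
    }
    num / den
  }
  recall <- safe_ratio(tp, tp + fn, "recall")
  precision <- safe_ratio(tp, tp + fp, "precision")
  f1 <- if (is.nan(recall) || is.nan(precision) || recall + precision == 0) {
    warn("F1 undefined; reporting NaN")
    NaN
  } else {
    2 * recall * precision / (recall + precision)
  }
  tibble(tp = tp, fp = fp, tn = tn, fn = fn,
         recall = recall, precision = precision,
         accuracy = (tp + tn) / total, f1 = f1)
}

#' Area under the ROC curve
#'
#' Computed as the probability that a randomly chosen positive sample
#' outscores a randomly chosen negative one, with ties counted as 1/2
#' (the Mann-Whitney formulation, via average ranks).
#'
#' @param scores Numeric decision values or probabilities.
#' @param labels 0/1 (or logical) labels; both classes must be present.
#' @return AUROC in \[0, 1\].
#' @examples
#' roc_auc(c(0.9, 0.7, 0.8, 0.6), c(1, 1, 0, 0))  # 0.75
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels)) abort("scores/labels length mismatch")
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) abort("both classes must be present")
  r <- rank(scores)
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Repeated hold-out validation of the full training workflow
#'
#' Per repeat: the NT and TM samples are split, stratified by class, into a
#' training partition (`split`, default 75%) and a held-out test partition.
#' Gene-set selection (differential expression), all cross-sample CES
#' statistics, feature standardization and the classifier fit are derived
#' from the training partition only; the confusion matrix, the four
#' metrics, and the AUROC are computed on the held-out partition. Feature
#' genes are re-selected inside every repeat, so the reported performance
#' covers the whole selection-plus-classification procedure, not just the
#' final fit.
#'
#' @param cohort A `p53_cohort` (needs `counts`, `tpm`, `log2fpkm`,
#'   `samples`).
#' @param candidates Candidate gene tibble (`gene`, `class`).
#' @param split Training fraction.
#' @param repeats Number of repeats (default 10).
#' @param seed Integer seed.
#' @param labels_override Optional named 0/1 vector replacing the
#'   group-derived labels (used for permutation nulls).
#' @param adj_p_max,min_abs_fc Gene-selection thresholds.
#' @param c_grid Cost grid for the classifier.
#' @return A `p53_validation`: per-repeat metrics tibble, per-repeat
#'   selected gene sets, and the configuration.
#' @export
holdout_validate <- function(cohort, candidates, split = 0.75, repeats = 10,
                             seed = 1, labels_override = NULL,
                             adj_p_max = 0.05, min_abs_fc = 2,
                             c_grid = c(0.01, 0.1, 1, 10, 100)) {
  samp <- cohort$samples
  nt <- samp$sample[samp$group == "NT"]
  tm <- samp$sample[samp$group == "TM"]
  if (length(nt) < 8 || length(tm) < 8) {
    abort("hold-out validation needs >= 8 NT and >= 8 TM samples")
  }
  all_ids <- c(nt, tm)
  labels <- setNames(rep(c(0L, 1L), c(length(nt), length(tm))), all_ids)
  if (!is.null(labels_override)) {
    labels <- labels_override[all_ids]
    if (anyNA(labels)) abort("labels_override must cover all NT/TM samples")
  }

  reps <- map(seq_len(repeats), function(r) {
    set.seed(child_seed(seed, 100L + r))
    test_ids <- c(sample(nt, max(1, round((1 - split) * length(nt)))),
                  sample(tm, max(1, round((1 - split) * length(tm)))))
    train_ids <- setdiff(all_ids, test_ids)
    if (length(unique(labels[train_ids])) < 2 ||
        length(unique(labels[test_ids])) < 2) {
      abort("split left a partition with a single class; adjust sizes")
    }
    train_nt <- intersect(train_ids, nt)
    train_tm <- intersect(train_ids, tm)

    expressed <- suppressWarnings(
      filter_expressed(cohort$tpm[, train_ids, drop = FALSE], candidates))
    de <- differential_expression(cohort$counts, train_nt, train_tm,
                                  genes = expressed$gene)
    pair <- select_gene_sets(de, adj_p_max = adj_p_max,
                             min_abs_fc = min_abs_fc,
                             cohort = samp$cohort[1])

    expr <- cohort$log2fpkm[, all_ids, drop = FALSE]
    ces <- build_ces_table(expr, pair, nt_ref = train_nt,
                           tm_ref = train_tm, ref = train_ids)
    ces_train <- ces[match(train_ids, ces$sample), ]
    ces_test <- ces[match(test_ids, ces$sample), ]

    model <- train_p53_classifier(ces_train, labels[train_ids],
                                  c_grid = c_grid,
                                  seed = child_seed(seed, 200L + r))
    pred <- predict(model, ces_test)
    truth <- labels[test_ids]
    pred_pos <- pred$label == "pRF"
    metrics <- suppressWarnings(compute_metrics(
      tp = sum(pred_pos & truth == 1L),
      fp = sum(pred_pos & truth == 0L),
      tn = sum(!pred_pos & truth == 0L),
      fn = sum(!pred_pos & truth == 1L)
    ))
    metrics$auroc <- roc_auc(pred$decision, truth)
    metrics$repeat_id <- r
    list(metrics = metrics, pair = pair)
  })

  metrics <- list_rbind(map(reps, "metrics"))
  metrics <- metrics[, c("repeat_id", setdiff(names(metrics), "repeat_id"))]
  structure(
    list(metrics = metrics,
         gene_sets = map(reps, "pair"),
         config = list(split = split, repeats = repeats, seed = seed,
                       adj_p_max = adj_p_max, min_abs_fc = min_abs_fc,
                       c_grid = c_grid)),
    class = "p53_validation"
  )
}

#' @export
print.p53_validation <- function(x, ...) {
  cat("<p53_validation>", nrow(x$metrics), "repeats\n")
  means <- colMeans(x$metrics[, c("recall", "precision", "accuracy",
                                  "f1", "auroc")])
  print(round(means, 4))
  invisible(x)
}

#' Unsupervised two-group fallback prediction
#'
#' When too few NT/TM samples exist to train a classifier (e.g. xenograft
#' cohorts), samples are split into two groups by Ward-linkage hierarchical
#' clustering on the standardized CES features. The cluster whose centroid
#' lies nearer the TM reference centroid is labeled `pRF`, the other `pN`.
#'
#' @param features CES tibble (column `sample` plus the seven scores).
#' @param nt_ref,tm_ref Non-empty sample-id vectors anchoring the two
#'   clusters; must be present in `features`.
#' @return Tibble with `sample`, `cluster` and `label`.
#' @export
cluster_predict <- function(features, nt_ref, tm_ref) {
  if (length(nt_ref) == 0 || length(tm_ref) == 0) {
    abort("both NT and TM reference anchors are required")
  }
  x <- ces_matrix(features)
  ids <- features$sample
  if (nrow(x) < 4) abort("clustering needs at least 4 samples")
  if (!all(c(nt_ref, tm_ref) %in% ids)) {
    abort("reference samples must be present in `features`")
  }
  scale_ <- apply(x, 2, sd)
  if (all(scale_ == 0)) abort("degenerate input: all samples identical")
  scale_[scale_ == 0] <- 1
  xs <- scale(x, center = TRUE, scale = scale_)
  rownames(xs) <- ids
  cl <- cutree(hclust(dist(xs), method = "ward.D2"), k = 2)

  centroid <- function(rows) colMeans(xs[rows, , drop = FALSE])
  c1 <- centroid(ids[cl == 1])
  c2 <- centroid(ids[cl == 2])
  nt_c <- centroid(intersect(ids, nt_ref))
  tm_c <- centroid(intersect(ids, tm_ref))
  d2 <- function(a, b) sum((a - b)^2)
  # cluster closer to the TM anchor carries the reduced-function label
  cl1_prf <- (d2(c1, tm_c) - d2(c1, nt_c)) < (d2(c2, tm_c) - d2(c2, nt_c))
  label <- ifelse((cl == 1) == cl1_prf, "pRF", "pN")
  tibble(sample = ids, cluster = unname(cl), label = unname(label))
}

# stratified fold ids, balanced within each class
stratified_folds <- function(labels, n_folds, seed) {
  set.seed(child_seed(seed, 999L))
  folds <- integer(length(labels))
  for (lv in unique(labels)) {
    idx <- which(labels == lv)
    folds[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
  }
  folds
}

# accept a CES tibble or a bare matrix with the seven feature columns
ces_matrix <- function(features) {
  needed <- ces_feature_names()
  if (is.matrix(features)) {
    if (!all(needed %in% colnames(features))) {
      abort("feature matrix lacks the seven CES columns")
    }
    return(features[, needed, drop = FALSE])
  }
  if (!all(needed %in% names(features))) {
    abort(paste("missing CES feature column(s):",
                paste(setdiff(needed, names(features)), collapse = ", ")))
  }
  m <- as.matrix(features[, needed])
  rownames(m) <- features$sample %||% NULL
  m
}
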