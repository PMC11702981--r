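test_that("confusion metrics follow their definitions", {
  m <- compute_metrics(tp = 3, fp = 1, tn = 5, fn = 1)
  expect_equal(m$precision, 0.75)
  expect_equal(m$recall, 0.75)
  expect_equal(m$accuracy, 0.80)
  expect_equal(m$f1, 0.75)

  perfect <- compute_metrics(tp = 4, fp = 0, tn = 6, fn = 0)
  expect_true(all(unlist(perfect[, c("recall", "precision",
                                     "accuracy", "f1")]) == 1))

  w <- capture_warnings(bad <- compute_metrics(tp = 0, fp = 3, tn = 2,
                                               fn = 0))
  expect_length(w, 2)   # recall and F1 are each flagged as undefined
  expect_match(w, "undefined", all = TRUE)
  expect_equal(bad$precision, 0)
  expect_true(is.nan(bad$f1))
  expect_error(compute_metrics(-1, 0, 1, 0), "non-negative")
})

test_that("AUROC equals pairwise concordance with half-credit ties", {
  expect_equal(roc_auc(c(0.9, 0.7, 0.8, 0.6), c(1, 1, 0, 0)), 0.75)
  expect_equal(roc_auc(c(5, 4, 2, 1), c(1, 1, 0, 0)), 1)
  expect_equal(roc_auc(rep(3, 6), c(1, 1, 1, 0, 0, 0)), 0.5)
  expect_error(roc_auc(1:3, c(1, 1, 1)), "both classes")

  set.seed(13)
  for (i in 1:25) {
    n <- sample(4:12, 1)
    labels <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    scores <- sample(seq_len(6), n, replace = TRUE) / 2  # forces ties
    expect_equal(roc_auc(scores, labels), oracle_auc(scores, labels))
  }
})

test_that("training is deterministic, separable and grid-constrained", {
  sc <- small_ces(seed = 1)
  feats <- sc$ces[match(c(sc$nt, sc$tm), sc$ces$sample), ]
  labels <- rep(c(0L, 1L), c(length(sc$nt), length(sc$tm)))
  model <- train_p53_classifier(feats, labels, seed = 3)
  model2 <- train_p53_classifier(feats, labels, seed = 3)
  expect_identical(model$weights, model2$weights)
  expect_true(model$cost %in% model$c_grid)

  fitted <- predict(model, feats)
  expect_equal(mean((fitted$label == "pRF") == (labels == 1L)), 1)
  # an exact copy of an NT training sample stays predicted-normal
  expect_identical(predict(model, feats[1, ])$label, "pN")

  expect_error(train_p53_classifier(feats, rep(0L, nrow(feats))),
               "both classes")
  expect_error(train_p53_classifier(feats[, -2], labels), "missing CES")
})

test_that("flipping the label coding flips decisions but not metrics", {
  sc <- small_ces(seed = 1)
  feats <- sc$ces[match(c(sc$nt, sc$tm), sc$ces$sample), ]
  labels <- rep(c(0L, 1L), c(length(sc$nt), length(sc$tm)))
  m1 <- train_p53_classifier(feats, labels, seed = 5)
  m2 <- train_p53_classifier(feats, 1L - labels, seed = 5)
  d1 <- predict(m1, feats)$decision
  d2 <- predict(m2, feats)$decision
  expect_equal(d1, -d2, tolerance = 1e-8)
  expect_equal(roc_auc(d1, labels), roc_auc(d2, 1 - labels))
})

test_that("prediction handles empty input and labels by decision sign", {
  sc <- small_ces(seed = 1)
  feats <- sc$ces[match(c(sc$nt, sc$tm), sc$ces$sample), ]
  labels <- rep(c(0L, 1L), c(length(sc$nt), length(sc$tm)))
  model <- train_p53_classifier(feats, labels, seed = 1)
  empty <- predict(model, sc$ces[0, ])
  expect_equal(nrow(empty), 0)
  pred <- predict(model, sc$ces)
  expect_identical(pred$label, ifelse(pred$decision > 0, "pRF", "pN"))
})

test_that("hold-out validation reports the configured repeats and learns", {
  co <- small_cohort(seed = 1)
  v <- holdout_validate(co, candidate_genes(co), repeats = 3, seed = 2)
  expect_equal(nrow(tidy(v)), 3)
  expect_true(all(tidy(v)$tp + tidy(v)$fp + tidy(v)$tn + tidy(v)$fn ==
                    round(0.25 * 15) * 2))
  expect_gte(glance(v)$mean_auroc, 0.95)
  expect_length(v$gene_sets, 3)
  expect_error(holdout_validate(simulate_cohort(n_nt = 4, n_wt = 0,
                                                n_mm = 0, n_tm = 4,
                                                n_background = 30,
                                                n_activated = 5,
                                                n_repressed = 3, seed = 1),
                                candidate_genes(co)),
               ">= 8")
})

test_that("more separation never hurts hold-out AUROC", {
  aurocs <- vapply(c(0.5, 1.0, 1.5), function(delta) {
    co <- simulate_cohort(n_nt = 16, n_wt = 0, n_mm = 0, n_tm = 16,
                          n_background = 100, n_activated = 20,
                          n_repressed = 8, delta = delta, seed = 9)
    # a relaxed fold-change floor keeps both sets non-empty at delta = 0.5
    v <- holdout_validate(co, candidate_genes(co), repeats = 3, seed = 9,
                          min_abs_fc = 1.2)
    glance(v)$mean_auroc
  }, numeric(1))
  expect_true(all(diff(aurocs) >= -1e-9))
})

test_that("cluster fallback recovers the latent classes and is order-stable", {
  sc <- small_ces(seed = 1)
  cl <- cluster_predict(sc$ces, nt_ref = sc$nt, tm_ref = sc$tm)
  truth <- setNames(sc$cohort$truth$samples$activity,
                    sc$cohort$truth$samples$sample)
  expect_gte(mean((cl$label == "pRF") == (truth[cl$sample] == 0)), 0.95)

  perm <- sample(nrow(sc$ces))
  cl2 <- cluster_predict(sc$ces[perm, ], nt_ref = sc$nt, tm_ref = sc$tm)
  expect_identical(cl$label[match(cl2$sample, cl$sample)], cl2$label)

  expect_error(cluster_predict(sc$ces, nt_ref = sc$nt, tm_ref = character(0)),
               "both NT and TM")
})
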