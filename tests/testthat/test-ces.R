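test_that("combined Z-score equals the per-gene standardization summed over sqrt(k)", {
  m <- rand_expr(6, 9, seed = 3)
  set <- c("g01", "g02", "g04", "g06")
  # manual transcription of the definition
  z <- t(apply(m[set, ], 1, function(x) (x - mean(x)) / sd(x)))
  expected <- colSums(z) / sqrt(length(set))
  expect_equal(combined_zscore(m, set), expected, tolerance = 1e-12)

  # k = 1 reduces to the single gene's z-score
  expect_equal(combined_zscore(m, "g03"),
               (m["g03", ] - mean(m["g03", ])) / sd(m["g03", ]),
               tolerance = 1e-12)
})

test_that("a sample sitting at the per-gene means scores zero", {
  base <- rand_expr(5, 4, seed = 4)
  centered <- cbind(base, s_mean = rowMeans(base))
  # the appended column equals the mean of all five columns by construction
  expect_equal(unname(combined_zscore(centered, rownames(base))["s_mean"]),
               0, tolerance = 1e-12)
})

test_that("zero-variance genes are dropped from the Z-score with a warning", {
  m <- rand_expr(4, 6, seed = 5)
  m["g02", ] <- 7
  expect_warning(z <- combined_zscore(m, c("g01", "g02")), "zero-variance")
  expect_equal(z, combined_zscore(m, "g01"))
  expect_error(suppressWarnings(combined_zscore(m, "g02")), "nonzero variance")
})

test_that("ssGSEA matches the enumerated running-sum oracle", {
  fix <- read_expression(fixture_path("ssgsea_oracle_6x2.tsv"),
                         layer = "log2fpkm")
  set <- c("g2", "g4")
  got <- ssgsea_score(fix, set, alpha = 0.25, rescale = FALSE)
  want <- vapply(seq_len(ncol(fix)), function(j)
    oracle_ssgsea_unscaled(fix[, j], rownames(fix), set, 0.25), numeric(1))
  expect_equal(unname(got), want, tolerance = 1e-9)

  # randomized small fixtures, several set sizes and alphas
  for (seed in 1:5) {
    m <- rand_expr(10, 4, seed = seed)
    set <- sample(rownames(m), 3)
    for (alpha in c(0, 0.25, 1)) {
      got <- ssgsea_score(m, set, alpha = alpha, rescale = FALSE)
      want <- vapply(seq_len(ncol(m)), function(j)
        oracle_ssgsea_unscaled(m[, j], rownames(m), set, alpha), numeric(1))
      expect_equal(unname(got), want, tolerance = 1e-9)
    }
  }
})

test_that("ssGSEA is maximal for the top-expressed set and rank-invariant", {
  m <- rand_expr(8, 3, seed = 9)
  top2 <- rownames(m)[order(-m[, 1])][1:2]
  best <- ssgsea_score(m, top2, alpha = 0, rescale = FALSE)[1]
  combos <- utils::combn(rownames(m), 2)
  for (i in seq_len(ncol(combos))) {
    expect_lte(ssgsea_score(m, combos[, i], alpha = 0, rescale = FALSE)[1],
               best + 1e-12)
  }

  # strictly increasing transform of one sample leaves its score unchanged
  m2 <- m
  m2[, 2] <- exp(m2[, 2] / 3)
  set <- c("g01", "g05", "g07")
  expect_equal(ssgsea_score(m, set, rescale = FALSE)[2],
               ssgsea_score(m2, set, rescale = FALSE)[2],
               tolerance = 1e-12)
})

test_that("GSVA matches the enumerated ecdf-kernel oracle", {
  fix <- read_expression(fixture_path("gsva_oracle_8x4.tsv"),
                         layer = "log2fpkm")
  set <- c("g2", "g5", "g8")
  expect_equal(gsva_score(fix, set, kernel = "ecdf"),
               oracle_gsva_ecdf(fix, set), tolerance = 1e-9)

  for (seed in 1:5) {
    m <- rand_expr(9, 5, seed = 20 + seed)
    set <- sample(rownames(m), 4)
    expect_equal(gsva_score(m, set, kernel = "ecdf"),
                 oracle_gsva_ecdf(m, set), tolerance = 1e-9)
  }
})

test_that("GSVA respects symmetry and its input contract", {
  m <- rand_expr(8, 4, seed = 31)
  m2 <- cbind(m, dup = m[, 2])
  s <- gsva_score(m2, c("g01", "g04"))
  expect_equal(unname(s["dup"]), unname(s[2]), tolerance = 1e-12)

  expect_error(gsva_score(m[, 1:2], "g01"), "at least 3")
  expect_error(gsva_score(m, rownames(m)), "out-of-set")
})

test_that("PC1 matches a closed-form eigen decomposition and is oriented", {
  m <- rand_expr(3, 5, seed = 41)
  z <- t(apply(m, 1, function(x) (x - mean(x)) / sd(x)))
  ev <- eigen(z %*% t(z))$vectors[, 1]       # principal axis of 3x3 problem
  want <- drop(t(z) %*% ev)
  got <- pc1_score(m, rownames(m), nt_ref = "s01", tm_ref = "s02")
  # equal up to the orientation sign
  expect_equal(abs(unname(got)), abs(unname(want)), tolerance = 1e-9)
  expect_gt(mean(got["s01"]), mean(got["s02"]))

  # swapping the anchor roles flips the sign deterministically
  flipped <- pc1_score(m, rownames(m), nt_ref = "s02", tm_ref = "s01")
  expect_equal(unname(got), -unname(flipped), tolerance = 1e-12)
})

test_that("PC1 separates two constructed clusters perfectly", {
  set.seed(6)
  shift <- c(rep(0, 5), rep(4, 5))
  m <- sapply(shift, function(s) rnorm(6, mean = 5 + s, sd = 0.3))
  dimnames(m) <- list(paste0("g", 1:6), paste0("s", 1:10))
  sc <- pc1_score(m, rownames(m), nt_ref = paste0("s", 1:5),
                  tm_ref = paste0("s", 6:10))
  expect_equal(roc_auc(sc, shift == 0), 1)   # NT-oriented: cluster 1 high
  expect_error(pc1_score(matrix(1, 3, 4,
                                dimnames = list(letters[1:3], LETTERS[1:4])),
                         letters[1:3], "A", "B"),
               "constant|identical")
})

test_that("the CES table carries exactly the seven scores in input order", {
  sc <- small_ces(seed = 1)
  ces <- sc$ces
  expect_identical(names(ces), c("sample", ces_feature_names()))
  expect_identical(ces$sample, colnames(sc$cohort$log2fpkm))
  expect_false(anyNA(ces))
  expect_equal(ces$zscore_dr,
               unname(combined_zscore(sc$cohort$log2fpkm, sc$pair$dr)),
               tolerance = 1e-12)
  expect_equal(ces$ssgsea_ur,
               unname(ssgsea_score(sc$cohort$log2fpkm, sc$pair$ur)),
               tolerance = 1e-12)
})

test_that("DR and UR scores anti-correlate and order the groups", {
  sc <- small_ces(seed = 1)
  ces <- sc$ces
  expect_lte(cor(ces$zscore_dr, ces$zscore_ur), -0.9)
  expect_lte(cor(ces$gsva_dr, ces$gsva_ur), -0.9)
  con <- cor(as.matrix(ces[, c("gsva_dr", "ssgsea_dr", "zscore_dr")]))
  expect_true(all(con[upper.tri(con)] >= 0.8))
  grp <- setNames(sc$cohort$samples$group, sc$cohort$samples$sample)
  means <- tapply(ces$zscore_dr, grp[ces$sample], mean)
  expect_gt(means["NT"], means["WT"])
  expect_gt(means["WT"], means["TM"])
})
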