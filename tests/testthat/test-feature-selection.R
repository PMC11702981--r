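test_that("the expression filter applies a strict median-TPM cutoff", {
  tpm <- rbind(zero = c(0, 0, 0),
               at_one = c(1, 1, 1),
               above = c(0.5, 2, 3))
  colnames(tpm) <- paste0("s", 1:3)
  cands <- tibble::tibble(gene = rownames(tpm), class = "activated")
  kept <- filter_expressed(tpm, cands)
  expect_identical(kept$gene, "above")   # median 2 passes; median 1 does not
  expect_warning(
    filter_expressed(tpm, tibble::tibble(gene = c("above", "ghost"),
                                         class = "activated")),
    "absent")
})

test_that("size factors follow the median-of-ratios definition", {
  a <- c(10, 20, 30, 40, 50)
  m <- cbind(s1 = a, s2 = 2 * a)
  rownames(m) <- paste0("g", 1:5)
  sf <- size_factors(m)
  expect_equal(unname(sf["s2"] / sf["s1"]), 2)
  # the geometric-mean reference makes the factors multiply to 1 here
  expect_equal(unname(prod(sf)), 1, tolerance = 1e-12)

  expect_equal(unname(size_factors(m[, 1, drop = FALSE])), 1)
  expect_equal(sort(size_factors(m[c(3, 1, 5, 2, 4), ])), sort(sf))
  expect_error(size_factors(matrix(0, 3, 2)), "all-zero")
})

test_that("size factors agree with the DESeq2 reference implementation", {
  set.seed(11)
  m <- matrix(rpois(200, 60) + 1, 20, 10,
              dimnames = list(paste0("g", 1:20), paste0("s", 1:10)))
  expect_equal(unname(size_factors(m)),
               unname(DESeq2::estimateSizeFactorsForMatrix(m)),
               tolerance = 1e-10)
})

test_that("differential expression enforces its input contract", {
  m <- rand_expr(5, 8)
  m[] <- abs(round(m))
  expect_error(differential_expression(m, c("s01", "s02"), c("s02", "s03")),
               "disjoint")
  expect_error(differential_expression(m, "s01", c("s02", "s03")),
               "at least 2")
})

test_that("a gene absent from one group still yields a finite fold change", {
  set.seed(2)
  m <- matrix(rpois(6 * 10, 50), 6, 10,
              dimnames = list(paste0("g", 1:6), paste0("s", 1:10)))
  m[1, 6:10] <- 0
  de <- differential_expression(m, paste0("s", 1:5), paste0("s", 6:10))
  expect_true(is.finite(de$log2fc[de$gene == "g1"]))
  expect_lt(de$log2fc[de$gene == "g1"], 0)
  expect_identical(de$flag[de$gene == "g1"], "all_zero_group")
  # BH monotonicity: adjusted p non-decreasing along raw-p order
  o <- order(de$pvalue)
  expect_true(all(diff(de$padj[o]) >= -1e-15))
})

test_that("gene-set selection applies inclusive significance boundaries", {
  de <- tibble::tibble(
    gene = c("down", "up_exact", "insig", "weak"),
    log2fc = c(-1.2, 1.0, -3, 0.5),
    padj = c(0.04, 0.04, 0.2, 0.01)
  )
  pair <- select_gene_sets(de)
  expect_identical(pair$dr, "down")
  expect_identical(pair$ur, "up_exact")   # |FC| = 2 exactly qualifies
  expect_length(intersect(pair$dr, pair$ur), 0)

  de_nodr <- tibble::tibble(gene = "up", log2fc = 2, padj = 0.01)
  expect_error(select_gene_sets(de_nodr), "empty DR")
  expect_error(geneset_pair(c("a", "b"), c("b", "c")), "overlap")
})

test_that("selection recovers the simulated truth with little contamination", {
  co <- small_cohort(seed = 1)
  pair <- select_p53_genesets(co, candidate_genes(co,
                                                  include_background = TRUE))
  tr <- co$truth$genes
  act <- tr$gene[tr$class == "activated"]
  rep_ <- tr$gene[tr$class == "repressed"]
  bg <- tr$gene[tr$class == "background"]
  expect_gte(mean(act %in% pair$dr), 0.9)
  expect_gte(mean(rep_ %in% pair$ur), 0.9)
  expect_lte(mean(bg %in% c(pair$dr, pair$ur)), 0.05)
})
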