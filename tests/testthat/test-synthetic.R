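test_that("cohort dimensions, labels and determinism match the configuration", {
  co <- default_cohort(seed = 1)
  expect_equal(dim(co$counts), c(1000, 270))
  expect_equal(dim(co$log2fpkm), c(1000, 270))
  expect_equal(dim(co$tpm), c(1000, 270))
  tab <- table(co$samples$group)
  expect_equal(unname(tab[c("NT", "WT", "MM", "TM")]),
               as.vector(c(60, 100, 50, 60)), ignore_attr = TRUE)
  expect_identical(colnames(co$counts), co$samples$sample)

  co2 <- simulate_cohort(seed = 1)
  expect_identical(co$counts, co2$counts)
  expect_identical(co$truth, co2$truth)
  co3 <- simulate_cohort(seed = 2)
  expect_false(identical(co$counts, co3$counts))
})

test_that("latent activity follows the group contract", {
  co <- default_cohort(seed = 1)
  tr <- co$truth$samples
  expect_true(all(tr$activity[tr$group == "NT"] == 1))
  expect_true(all(tr$activity[tr$group == "TM"] == 0))
  # binomial sampling around phi_wt_rf = 0.9 at n = 100
  expect_gt(mean(tr$activity[tr$group == "WT"] == 0), 0.78)
  expect_lt(mean(tr$activity[tr$group == "WT"] == 0), 0.98)
})

test_that("the simulated effect size is recovered on the log2 scale", {
  co <- default_cohort(seed = 1)
  act <- co$truth$genes$gene[co$truth$genes$class == "activated"]
  rep_ <- co$truth$genes$gene[co$truth$genes$class == "repressed"]
  nt <- co$samples$sample[co$samples$group == "NT"]
  tm <- co$samples$sample[co$samples$group == "TM"]
  d_act <- mean(co$log2fpkm[act, tm]) - mean(co$log2fpkm[act, nt])
  expect_lt(abs(d_act - (-1.5)), 0.1)
  d_rep <- mean(co$log2fpkm[rep_, tm]) - mean(co$log2fpkm[rep_, nt])
  expect_lt(abs(d_rep - 1.5), 0.15)
})

test_that("every activated gene drops in TM at positive delta", {
  for (seed in 1:3) {
    co <- simulate_cohort(n_nt = 30, n_wt = 0, n_mm = 0, n_tm = 30,
                          n_background = 40, n_activated = 15,
                          n_repressed = 6, seed = seed)
    act <- co$truth$genes$gene[co$truth$genes$class == "activated"]
    nt <- co$samples$sample[co$samples$group == "NT"]
    tm <- co$samples$sample[co$samples$group == "TM"]
    diff_ <- rowMeans(co$log2fpkm[act, tm]) - rowMeans(co$log2fpkm[act, nt])
    expect_true(all(diff_ < 0))
  }
})

test_that("invalid cohort configurations are rejected", {
  expect_error(simulate_cohort(n_nt = -1), "non-negative")
  expect_error(simulate_cohort(delta = -0.5), "delta")
  expect_error(simulate_cohort(phi_wt_rf = 1.2), "phi")
  expect_error(simulate_cohort(dispersion = 0), "dispersion")
  expect_error(simulate_cohort(n_nt = 0), "n_nt")
})

test_that("allele-count simulation respects the binomial model", {
  sim <- simulate_allele_counts(n_sites = 50, true_maf = 0, seed = 3)
  expect_true(all(sim$records$alt == 0))
  expect_true(all(sim$truth$genotype == "wildtype"))

  sim1 <- simulate_allele_counts(n_sites = 100, seed = 5)
  sim2 <- simulate_allele_counts(n_sites = 100, seed = 5)
  expect_identical(sim1, sim2)
  expect_true(all(sim1$records$hq_alt <= sim1$records$alt))
  expect_true(all(sim1$records$alt <= sim1$records$depth))

  sim3 <- simulate_allele_counts(n_sites = 1000, mean_depth = 100,
                                 true_maf = 0.45, seed = 7)
  frac <- with(sim3$records, mean(alt / depth))
  expect_lt(abs(frac - 0.45), 0.02)
})

test_that("PDX simulation produces the configured bimodal structure", {
  sim0 <- simulate_pdx(n_models = 40, responder_fraction = 0, seed = 2)
  expect_true(all(!sim0$truth$responder))
  expect_true(all(sim0$models$ratio < 1.52))

  sim <- simulate_pdx(n_models = 35, seed = 4)
  expect_equal(nrow(sim$models), 35)
  expect_identical(sim, simulate_pdx(n_models = 35, seed = 4))
  expect_equal(sim$models$ratio,
               sim$models$rt_median / sim$models$placebo_median)

  simb <- simulate_pdx(n_models = 200, responder_fraction = 0.5,
                       spread_responder = 0.1, seed = 6)
  flags <- classify_responders(simb$models$ratio, cutoff = 1.52)
  expect_gte(mean(flags == simb$truth$responder), 0.95)
})
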