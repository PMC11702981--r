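# Shared small fixtures, built in code. The default-size cohort and its
# derived objects are cached because several files reuse them.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, build) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, build(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

default_cohort <- function(seed = 1) {
  cached(paste0("cohort", seed), function() simulate_cohort(seed = seed))
}

# a light cohort for unit tests: enough samples for stable statistics,
# small enough that scoring is instant
small_cohort <- function(seed = 1, delta = 1.5) {
  cached(paste0("small", seed, "_", delta), function() {
    simulate_cohort(n_nt = 15, n_wt = 20, n_mm = 10, n_tm = 15,
                    n_background = 120, n_activated = 20, n_repressed = 8,
                    delta = delta, seed = seed)
  })
}

small_ces <- function(seed = 1) {
  cached(paste0("small_ces", seed), function() {
    co <- small_cohort(seed)
    pair <- select_p53_genesets(co, candidate_genes(co))
    nt <- co$samples$sample[co$samples$group == "NT"]
    tm <- co$samples$sample[co$samples$group == "TM"]
    list(cohort = co, pair = pair, nt = nt, tm = tm,
         ces = build_ces_table(co$log2fpkm, pair, nt_ref = nt, tm_ref = tm))
  })
}

# deterministic random expression matrix with named dimensions
rand_expr <- function(n_genes, n_samples, seed = 1) {
  set.seed(seed)
  matrix(rnorm(n_genes * n_samples, mean = 5, sd = 2), n_genes,
         dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                         sprintf("s%02d", seq_len(n_samples))))
}
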