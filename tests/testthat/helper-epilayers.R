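# Shared fixtures: simulated cohorts and one fitted model, built once per
# test run and cached. Sizes are chosen so the correlation-threshold filters
# behave as they do at cohort scale while keeping the suite fast.

.cache <- new.env(parent = emptyenv())

cache_get <- function(key, builder) {
  if (!exists(key, envir = .cache)) assign(key, builder(), envir = .cache)
  get(key, envir = .cache)
}

# mid-size cohort: large enough that |r| > 0.25 prunes null loci
mid_config <- function(...) {
  sim_config(n_tumors = 300L, n_normals = 40L, n_er_neg = 80L,
             n_genes = 500L, n_immune_genes = 40L, n_caf_genes = 40L,
             n_fragments = 800L, n_enhancers = 80L,
             n_cis_pairs = 20L, n_distal_pairs = 10L,
             gene_spacing = 2e5, rng_seed = 42L, ...)
}

mid_cohort <- function() cache_get("mid_cohort", function() simulate_cohort(mid_config()))

mid_fit <- function() cache_get("mid_fit", function() {
  coh <- mid_cohort()
  epilayer_fit(coh$meth, coh$expr, coh$metadata, group = "ER+")
})

# tiny cohort for structural/smoke tests
tiny_config <- function(...) {
  sim_config(n_tumors = 120L, n_normals = 25L, n_genes = 250L,
             n_immune_genes = 30L, n_caf_genes = 30L,
             n_fragments = 400L, n_enhancers = 40L,
             n_cis_pairs = 10L, n_distal_pairs = 5L,
             gene_spacing = 1e5, rng_seed = 7L, ...)
}

tiny_cohort <- function() cache_get("tiny_cohort", function() simulate_cohort(tiny_config()))

er_pos_truth <- function(coh) {
  tr <- coh$truth$samples
  tr[tr$group == "ER+", , drop = FALSE]
}

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

# adjusted Rand index (brute force from the pair-counting definition)
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  nij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  n2 <- choose(sum(tab), 2)
  exp_ <- ai * bj / n2
  (nij - exp_) / ((ai + bj) / 2 - exp_)
}

# brute-force pairwise-complete Pearson between rows of x and y
slow_pairwise_cor <- function(x, y) {
  r <- matrix(NA_real_, nrow(x), nrow(y))
  for (i in seq_len(nrow(x))) for (j in seq_len(nrow(y))) {
    ok <- !is.na(x[i, ]) & !is.na(y[j, ])
    if (sum(ok) > 1 && stats::sd(x[i, ok]) > 0 && stats::sd(y[j, ok]) > 0)
      r[i, j] <- stats::cor(x[i, ok], y[j, ok])
  }
  r
}

# brute-force Gini-Simpson by enumerating individual reads
slow_epipoly <- function(counts) {
  reads <- rep(seq_along(counts), counts)
  n <- length(reads)
  same <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) if (reads[i] == reads[j]) same <- same + 1
  1 - same / n^2
}

# full-size reference cohort (the default simulator conditions) and its fit;
# built once, used by the acceptance suite
full_cohort <- function() cache_get("full_cohort", function() simulate_cohort(sim_config()))

full_fit <- function() cache_get("full_fit", function() {
  coh <- full_cohort()
  t0 <- Sys.time()
  fit <- epilayer_fit(coh$meth, coh$expr, coh$metadata, group = "ER+")
  attr(fit, "elapsed_s") <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  fit
})
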