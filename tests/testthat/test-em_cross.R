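make_paired <- function(ev, mv) {
  samples <- sprintf("s%02d", seq_len(ncol(ev)))
  colnames(ev) <- colnames(mv) <- samples
  genes <- data.frame(gene = sprintf("g%d", seq_len(nrow(ev))), chrom = "chr1",
                      tss = seq_len(nrow(ev)) * 1000L, strand = "+")
  loci <- locus_table("chr1", seq_len(nrow(mv)) * 2000L,
                      seq_len(nrow(mv)) * 2000L + 550L,
                      strand = "+", locus_class = "promoter")
  list(expr = expr_matrix(ev, genes), meth = meth_matrix(mv, loci))
}

test_that("cross-correlation matches a brute-force Pearson oracle with missing data", {
  set.seed(10)
  n <- 60
  ev <- matrix(rnorm(5 * n, 8), 5, n)
  mv <- matrix(runif(5 * n, 0.2, 0.8), 5, n)
  mv[sample(length(mv), 40)] <- NA
  d <- make_paired(ev, mv)
  cc <- build_cross_correlation(d$expr, d$meth, params = epilayer_params(
    min_corr_samples = 10L, corr_floor = 0))
  oracle <- slow_pairwise_cor(ev, mv)
  dimnames(oracle) <- list(d$expr$genes$gene, d$meth$loci$locus_id)
  expect_equal(cc$r, oracle[rownames(cc$r), colnames(cc$r)], tolerance = 1e-12)
  # support counts are the pairwise non-missing sample counts
  i <- rownames(cc$r)[1]; j <- colnames(cc$r)[1]
  expect_equal(unname(cc$n_support[i, j]),
               sum(!is.na(mv[match(j, d$meth$loci$locus_id), ])))
})

test_that("perfect anticorrelation, zero variance and mean bounds behave as specified", {
  set.seed(11)
  n <- 60
  m1 <- runif(n, 0.3, 0.7)
  ev <- rbind(-m1 + 9, rnorm(n, 8))
  mv <- rbind(m1, rep(0.5, n), runif(n, 0, 0.05), runif(n, 0.95, 1))
  d <- make_paired(ev, mv)
  p <- epilayer_params(min_corr_samples = 10L)
  cc <- build_cross_correlation(d$expr, d$meth, params = p)
  expect_equal(unname(cc$r["g1", "chr1:2000-2550"]), -1, tolerance = 1e-12)
  # the constant locus and the out-of-bounds loci are gone
  expect_false(any(c("chr1:4000-4550", "chr1:6000-6550", "chr1:8000-8550")
                   %in% colnames(cc$r)))
  # too few shared samples is an error
  expect_error(build_cross_correlation(d$expr, d$meth,
                                       params = epilayer_params(min_corr_samples = 100L)),
               "shared samples")
})

test_that("cross-correlation is invariant to affine rescaling of expression", {
  coh <- tiny_cohort()
  p <- epilayer_params()
  cc1 <- build_cross_correlation(coh$expr, coh$meth, coh$metadata, "ER+", p)
  ev2 <- coh$expr$values * 3.7 - 12
  cc2 <- build_cross_correlation(expr_matrix(ev2, coh$expr$genes),
                                 coh$meth, coh$metadata, "ER+", p)
  expect_equal(cc1$r, cc2$r, tolerance = 1e-9)
})

test_that("Ward clustering recovers planted blocks and is deterministic", {
  set.seed(12)
  base <- matrix(rnorm(3 * 40), 3, 40)
  ev <- base[rep(1:3, each = 10), ] + matrix(rnorm(30 * 40, 0, 0.05), 30, 40)
  rownames(ev) <- sprintf("g%02d", 1:30)
  cc <- structure(list(r = ev, params = epilayer_params()), class = "cross_corr")
  cl <- cluster_cross_correlation(cc, n_clusters = 3)
  expect_gt(adjusted_rand(cl$row_clusters, rep(1:3, each = 10)), 0.95)
  cl2 <- cluster_cross_correlation(cc, n_clusters = 3)
  expect_identical(cl$row_clusters, cl2$row_clusters)
  # two exact blocks are perfectly recovered
  ex <- rbind(matrix(1:5, 4, 5, byrow = TRUE), matrix(c(9, 1, 4, 2, 7), 4, 5, byrow = TRUE))
  rownames(ex) <- letters[1:8]
  cce <- structure(list(r = ex, params = epilayer_params()), class = "cross_corr")
  cle <- cluster_cross_correlation(cce, n_clusters = 2)
  expect_equal(adjusted_rand(cle$row_clusters, rep(1:2, each = 4)), 1)
  # more clusters than rows degrades gracefully with a warning (rows and cols)
  expect_warning(expect_warning(
    clw <- cluster_cross_correlation(cce, n_clusters = 30), "reducing"))
  expect_equal(length(unique(clw$row_clusters)), 8L)
})

test_that("anchor plurality identifies TME modules; degenerate anchors error", {
  rc <- c(CD3D = 1L, CD3E = 1L, CD8A = 2L, CAV1 = 3L, FAP = 3L, g1 = 1L, g2 = 3L)
  cc <- structure(list(r = matrix(0, 7, 2, dimnames = list(names(rc), NULL)),
                       row_clusters = rc, params = epilayer_params()),
                  class = "cross_corr")
  tm <- identify_tme_modules(cc)
  expect_setequal(tm$immune_genes, c("CD3D", "CD3E", "g1"))
  expect_setequal(tm$caf_genes, c("CAV1", "FAP", "g2"))
  expect_length(intersect(tm$immune_genes, tm$caf_genes), 0)
  # anchors absent from the matrix
  expect_error(identify_tme_modules(cc, anchors = list(immune = "NOPE", caf = "CAV1")),
               "anchor")
  # split without plurality demands an override, which then works
  rc2 <- rc; rc2[c("CD3D", "CD3E")] <- c(1L, 2L); rc2["CD8A"] <- 4L
  cc2 <- cc; cc2$row_clusters <- rc2
  expect_error(identify_tme_modules(cc2, anchors = list(immune = c("CD3D", "CD3E"),
                                                        caf = "CAV1")),
               "override")
  tm2 <- identify_tme_modules(cc2, anchors = list(immune = c("CD3D", "CD3E"), caf = "CAV1"),
                              override = list(immune = 1L))
  expect_true("CD3D" %in% tm2$immune_genes)
})

test_that("module recovery on the simulated cohort finds the planted gene sets", {
  coh <- mid_cohort()
  fit <- mid_fit()
  expect_gt(jaccard(fit$tme$immune_genes, coh$truth$immune_genes), 0.7)
  expect_gt(jaccard(fit$tme$caf_genes, coh$truth$caf_genes), 0.7)
  # TME modules contain no planted cis genes
  expect_length(intersect(c(fit$tme$immune_genes, fit$tme$caf_genes),
                          coh$truth$cis_pairs$gene), 0)
})

test_that("signature scores are set means and track the planted fractions", {
  ev <- rbind(a = c(1, 2, 3), b = c(1, 2, 3), c = c(5, 5, 5))
  colnames(ev) <- c("s1", "s2", "s3")
  expect_equal(unname(compute_signature(ev, "c")), c(5, 5, 5))
  expect_equal(unname(compute_signature(ev, c("a", "b"))), c(1, 2, 3))
  expect_error(compute_signature(ev, "zz"), "present")
  coh <- mid_cohort()
  tr <- er_pos_truth(coh)
  sig <- compute_signature(coh$expr$values[, tr$sample], coh$truth$immune_genes)
  expect_gt(stats::cor(sig, tr$f_imm), 0.9)
})
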