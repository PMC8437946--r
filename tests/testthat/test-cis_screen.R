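screen_fixture <- function(n_genes, n_samples, planted = integer(0), rho = 0.7,
                           seed = 1, positive = FALSE) {
  # promoters with independent variation; planted genes anti-coupled (or
  # coupled, when positive) to their own promoter
  set.seed(seed)
  samples <- sprintf("s%03d", seq_len(n_samples))
  mv <- matrix(runif(n_genes * n_samples, 0.2, 0.8), n_genes, n_samples,
               dimnames = list(NULL, samples))
  ev <- matrix(rnorm(n_genes * n_samples, 8), n_genes, n_samples,
               dimnames = list(NULL, samples))
  sgn <- if (positive) 1 else -1
  for (g in planted) {
    z <- as.numeric(scale(mv[g, ]))
    ev[g, ] <- 8 + sgn * (rho * z + sqrt(1 - rho^2) * rnorm(n_samples))
  }
  genes <- data.frame(gene = sprintf("g%04d", seq_len(n_genes)), chrom = "chr1",
                      tss = seq_len(n_genes) * 10000L, strand = "+")
  loci <- locus_table("chr1", seq_len(n_genes) * 10000L - 500L,
                      seq_len(n_genes) * 10000L + 50L,
                      strand = "+", locus_class = "promoter",
                      locus_id = paste0("P_", genes$gene))
  list(expr = expr_matrix(ev, genes), meth = meth_matrix(mv, loci),
       pairing = data.frame(gene = genes$gene, locus_id = loci$locus_id))
}

test_that("the empirical FDR is k/m and hit lists respect the rank cutoffs", {
  d <- screen_fixture(300, 100, planted = 1:30, rho = 0.9)
  cs <- promoter_cis_screen(d$expr, d$meth, d$pairing)
  ft <- cs$fdr_table[cs$fdr_table$direction == "negative", ]
  expect_equal(ft$fdr, ft$k / ft$m)
  expect_true(all(diff(ft$m) > 0))
  res <- cs$results[cs$results$direction == "negative", ]
  # fdr at each gene's own rank agrees with the table
  for (i in which(!is.na(res$rank))[1:10]) {
    m_at <- sum(res$rank <= res$rank[i], na.rm = TRUE)
    expect_equal(res$fdr_at_rank[i], res$rank[i] / m_at)
  }
  # strongly planted pairs are recovered at rank 1
  hits <- cis_hits(cs, 0.05)
  expect_gte(mean(sprintf("g%04d", 1:30) %in% hits), 0.8)
  r1 <- cis_hits(cs, rank1 = TRUE)
  expect_true(all(r1 %in% res$gene[res$rank == 1]))
})

test_that("rank arithmetic matches the k/m definition on a constructed example", {
  # six of 600 genes carry a perfect anti-correlation: their diagonal rank is
  # 1 and the FDR at k = 6 is about 6/m with m counting diagonal ranks <= 6
  d <- screen_fixture(600, 60, planted = 1:6, rho = 0.999)
  cs <- promoter_cis_screen(d$expr, d$meth, d$pairing)
  ft <- cs$fdr_table[cs$fdr_table$direction == "negative", ]
  neg_rank <- cs$results$rank[cs$results$direction == "negative"]
  kk <- max(ft$k[ft$k <= 6])
  expect_equal(ft$fdr[ft$k == kk], kk / sum(neg_rank <= kk, na.rm = TRUE))
  expect_gte(sum(neg_rank <= 6, na.rm = TRUE), 6)
})

test_that("the positive pass catches induction-type coupling", {
  d <- screen_fixture(250, 80, planted = 1:25, rho = 0.9, positive = TRUE)
  cs <- promoter_cis_screen(d$expr, d$meth, d$pairing)
  neg_hits <- cis_hits(cs, 0.05, "negative")
  pos_hits <- cis_hits(cs, 0.05, "positive")
  expect_gte(mean(sprintf("g%04d", 1:25) %in% pos_hits), 0.8)
  expect_lt(length(neg_hits), 3)
})

test_that("the screen excludes module genes, low-support cells and unresolved genes", {
  d <- screen_fixture(60, 80, planted = 1:5, rho = 0.9)
  cs <- promoter_cis_screen(d$expr, d$meth, d$pairing,
                            exclude_genes = c("g0001", "g0002"))
  expect_false(any(c("g0001", "g0002") %in% cs$results$gene))
  # support below 50 paired samples removes the cell
  mv <- d$meth$values
  mv["P_g0003", 1:60] <- NA
  d2 <- d; d2$meth <- meth_matrix(mv, d$meth$loci)
  cs2 <- promoter_cis_screen(d2$expr, d2$meth, d$pairing)
  expect_true(is.na(cs2$results$rank[cs2$results$gene == "g0003" &
                                       cs2$results$direction == "negative"]))
  expect_error(promoter_cis_screen(d$expr, d$meth,
                                   data.frame(gene = c("g0001", "g0002"),
                                              locus_id = c("P_g0001", "P_g0001"))),
               "one-to-one")
})

test_that("under the global null the screen stays calibrated", {
  reps <- 10
  rank1 <- numeric(reps); disc <- numeric(reps)
  for (i in seq_len(reps)) {
    d <- screen_fixture(300, 80, seed = 100 + i)
    cs <- promoter_cis_screen(d$expr, d$meth, d$pairing,
                              directions = "negative")
    res <- cs$results
    rank1[i] <- sum(res$rank == 1, na.rm = TRUE)
    disc[i] <- length(cis_hits(cs, 0.05))
  }
  # expected count of rank-1 diagonals is about 1 per replicate
  expect_lt(abs(mean(rank1) - 1), 3 * sqrt(1 / reps))
  # essentially nothing is declared at nominal FDR 0.05
  expect_lte(mean(disc), 2)
})

test_that("the screen is invariant under per-profile affine transforms", {
  d <- screen_fixture(80, 70, planted = 1:5, rho = 0.8)
  cs1 <- promoter_cis_screen(d$expr, d$meth, d$pairing, directions = "negative")
  ev2 <- d$expr$values * 2.5 + 3
  cs2 <- promoter_cis_screen(expr_matrix(ev2, d$expr$genes), d$meth, d$pairing,
                             directions = "negative")
  expect_equal(cs1$results$rank, cs2$results$rank)
  expect_equal(cs1$results$r_cis, cs2$results$r_cis, tolerance = 1e-9)
})

test_that("distal pairing uses the 500 kb same-chromosome rule with shuffle FDR", {
  coh <- mid_cohort()
  tr <- er_pos_truth(coh)
  pw <- coh$meth$loci[coh$meth$loci$locus_class == "promoter", ]
  ds <- distal_cis_screen(coh$expr, coh$meth, pw, samples = tr$sample,
                          n_shuffles = 2, seed = 9)
  # the planted enhancer-gene pairs are recovered as pairings
  planted <- coh$truth$distal_pairs
  got <- ds$results[match(planted$locus_id, ds$results$locus_id), ]
  expect_gte(mean(got$paired & got$gene == planted$gene, na.rm = TRUE), 0.8)
  expect_true(all(got$distance[got$paired] <= 500000))
  # FDR is the ratio of mean shuffled to real pairing counts
  expect_equal(ds$fdr, mean(ds$shuffled_counts) / ds$n_paired)
  expect_error(distal_cis_screen(coh$expr, coh$meth, pw, n_shuffles = 0), "n_shuffles")
  # cross-chromosome best genes are never paired
  other <- ds$results[!is.na(ds$results$gene), ]
  gt <- coh$expr$genes
  for (i in head(which(!other$paired & !is.na(other$distance)), 5))
    expect_gt(other$distance[i], 500000)
})

test_that("loci within 2 kb of promoters are excluded from the distal screen", {
  coh <- tiny_cohort()
  pw <- coh$meth$loci[coh$meth$loci$locus_class == "promoter", ]
  ds <- distal_cis_screen(coh$expr, coh$meth, pw, n_shuffles = 1, seed = 2)
  kept <- coh$meth$loci[match(ds$results$locus_id, coh$meth$loci$locus_id), ]
  gr <- GenomicRanges::GRanges(kept$chrom, IRanges::IRanges(kept$start + 1, kept$end))
  pg <- GenomicRanges::GRanges(pw$chrom, IRanges::IRanges(pw$start + 1, pw$end))
  d <- as.data.frame(GenomicRanges::distanceToNearest(gr, pg))
  expect_true(all(d$distance > 2000))
})

test_that("epiconvergence comparisons behave under null and planted differences", {
  set.seed(40)
  bg <- runif(400, 0.3, 0.9)
  bg_m <- runif(400)
  # identical distributions: no stratum strongly significant
  rep_null <- epiconvergence_report(bg[1:200], bg_m[1:200], bg[201:400], bg_m[201:400])
  expect_true(mean(rep_null$p) > 0.2)
  # concentrated (lower) epi-polymorphism in cis loci in low-methylation strata
  cis_e <- runif(200, 0.05, 0.45)
  rep_alt <- epiconvergence_report(cis_e, bg_m[1:200], bg, bg_m)
  expect_true(any(rep_alt$p < 0.01))
})
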