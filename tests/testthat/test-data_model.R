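test_that("promoter windows are 500 bp upstream / 50 bp downstream, strand-aware", {
  p <- make_promoter_window(10000, "+")
  expect_equal(c(p$start, p$end), c(9500, 10050))
  m <- make_promoter_window(10000, "-")
  expect_equal(c(m$start, m$end), c(9950, 10500))
  clip <- make_promoter_window(100, "+")
  expect_equal(c(clip$start, clip$end), c(0, 150))
  expect_error(make_promoter_window(100, "*"), "strand")
  # plus/minus windows are mirror images around the TSS, width always 550
  for (tss in c(1000L, 54321L, 99999L)) {
    a <- make_promoter_window(tss, "+")
    b <- make_promoter_window(tss, "-")
    expect_equal(a$end - a$start, 550L)
    expect_equal(b$end - b$start, 550L)
    expect_equal(tss - a$start, b$end - tss)
  }
})

test_that("alternative promoters resolve to minimal normal methylation, 5'-most on ties", {
  cands <- locus_table("chr1", c(100L, 900L), c(650L, 1450L),
                       strand = "+", locus_class = "promoter")
  nm <- rbind(c(0.05, 0.05), c(0.40, 0.40))
  expect_equal(resolve_promoter("g", cands, nm)$locus_id, cands$locus_id[1])
  # single candidate is the identity
  expect_equal(resolve_promoter("g", cands[2, ], nm[2, , drop = FALSE])$locus_id,
               cands$locus_id[2])
  # exhaustive 2-candidate oracle: lower mean wins, ties go 5'-most
  means <- c(0.10, 0.25, 0.10)
  grid <- expand.grid(i = 1:3, j = 1:3)
  for (k in seq_len(nrow(grid))) {
    i <- grid$i[k]; j <- grid$j[k]
    if (i == j) next
    cc <- locus_table("chr1", c(100L, 900L)[order(c(1, 2))], c(650L, 1450L),
                      strand = "+", locus_class = "promoter")
    picked <- resolve_promoter("g", cc, cbind(c(means[i], means[j])))
    want <- if (means[i] < means[j]) 1L else if (means[j] < means[i]) 2L else 1L
    expect_equal(picked$locus_id, cc$locus_id[want])
  }
  expect_warning(out <- resolve_promoter("g", cands, cbind(c(NA, NA))), "unresolved")
  expect_null(out)
})

test_that("locus aggregation pools reads and is permutation invariant", {
  expect_equal(aggregate_methylation(c(3, 7), c(10, 10)), 0.5)
  expect_equal(aggregate_methylation(c(10, 10), c(10, 10)), 1.0)
  expect_true(is.na(aggregate_methylation(numeric(0), numeric(0))))
  expect_true(is.na(aggregate_methylation(c(NA, NA), c(NA, 0))))
  set.seed(1)
  m <- rbinom(20, 30, 0.4); t <- rep(30, 20)
  o <- sample(20)
  expect_equal(aggregate_methylation(m, t), aggregate_methylation(m[o], t[o]))
  v <- aggregate_methylation(m, t)
  expect_true(v >= 0 && v <= 1)
  # unweighted mode averages per-CpG fractions instead of pooling reads
  expect_equal(aggregate_methylation(c(1, 9), c(10, 90), weighted = FALSE),
               mean(c(0.1, 0.1)))
  expect_equal(aggregate_methylation(c(1, 9), c(10, 10), weighted = FALSE), 0.5)
})

test_that("fragments overlapping promoters or exons are excluded", {
  prom <- make_promoter_window(10000, "+")
  frags <- locus_table("chr1", c(9000L, 9600L, 20000L), c(9400L, 9900L, 20300L))
  kept <- exclude_overlapping_fragments(frags, prom)
  expect_equal(kept$locus_id, frags$locus_id[c(1, 3)])
  exons <- data.frame(chrom = "chr1", start = 20100L, end = 20200L)
  kept2 <- exclude_overlapping_fragments(frags, prom, exons)
  expect_equal(kept2$locus_id, frags$locus_id[1])
})

test_that("enhancer calling takes the top 3% of coverage away from promoters, homogenized to 200 bp", {
  set.seed(2)
  n <- 100
  cov <- data.frame(chrom = "chr1", start = seq(0, by = 10000, length.out = n),
                    end = seq(1000, by = 10000, length.out = n),
                    coverage = sample(n))
  prom <- make_promoter_window(5e6, "+")
  enh <- call_enhancers(cov, prom)
  # brute-force quantile oracle; the promoter sits far away so nothing is
  # excluded by distance here
  thr <- quantile(cov$coverage, 0.97)
  top <- cov[cov$coverage >= thr, ]
  expect_equal(nrow(enh), nrow(top))
  expect_true(all(enh$end - enh$start == 200L))
  mid <- (top$start + top$end) %/% 2L
  expect_true(all(enh$start %in% (mid - 100L)))
  # interval 1.5 kb from a promoter is excluded
  near <- data.frame(chrom = "chr1", start = prom$end + 1500L,
                     end = prom$end + 1600L, coverage = 1e9)
  out <- call_enhancers(rbind(cov, near), prom)
  expect_false(any(out$start == (near$start + near$end) %/% 2 - 100))
  # all-equal coverage: ties at the threshold are retained, so all survive
  flat <- cov; flat$coverage <- 5
  expect_equal(nrow(call_enhancers(flat, prom[0, ])), n)
  expect_equal(nrow(call_enhancers(flat[0, ], prom)), 0L)
})

test_that("time-of-replication binning uses median and 20/60 percentile splits", {
  b <- bin_time_of_replication(1:10)
  expect_equal(b$bin2[3], "late")
  expect_equal(b$bin2[8], "early")
  # value exactly at the median counts as late
  b5 <- bin_time_of_replication(1:5)
  expect_equal(b5$bin2[3], "late")
  b100 <- bin_time_of_replication(1:100)
  expect_equal(b100$bin3[50], "intermediate")
  expect_equal(b100$bin3[10], "late")
  expect_equal(b100$bin3[90], "early")
  allna <- bin_time_of_replication(c(NA_real_, NA_real_))
  expect_true(all(is.na(allna$bin2)) && all(is.na(allna$bin3)))
})

test_that("matrix containers validate their invariants", {
  expect_error(locus_table("chr1", 100, 100), "start")
  expect_error(locus_table("chr1", c(0, 0), c(10, 10), locus_id = c("a", "a")), "unique")
  loci <- locus_table("chr1", c(0L, 500L), c(300L, 900L))
  v <- matrix(c(0.2, 0.8, NA, 0.5), 2, dimnames = list(NULL, c("s1", "s2")))
  mm <- meth_matrix(v, loci)
  expect_s3_class(mm, "meth_matrix")
  expect_error(meth_matrix(v * 2, loci), "\\[0,1\\]")
  expect_error(meth_matrix(v[, c(1, 1)], loci))
  expect_error(sample_metadata(c("a", "b"), c("ER+", "weird")), "group")
})

test_that("write/read round-trips methylation and expression matrices bit-exactly", {
  coh <- tiny_cohort()
  tmp <- tempfile(fileext = ".tsv")
  write_meth_matrix(coh$meth, tmp, header = c("tool x", "seed: 1"))
  back <- read_meth_matrix(tmp)
  expect_identical(back$values, coh$meth$values)
  expect_equal(back$loci$start, coh$meth$loci$start)
  # gzip-transparent
  tmpgz <- tempfile(fileext = ".tsv.gz")
  con <- gzfile(tmpgz, "w"); writeLines(readLines(tmp), con); close(con)
  expect_identical(read_meth_matrix(tmpgz)$values, coh$meth$values)
  te <- tempfile(fileext = ".tsv")
  write_expr_matrix(coh$expr, te)
  expect_identical(read_expr_matrix(te)$values, coh$expr$values)
  # 1-based input converts to 0-based half-open
  df <- utils::read.delim(tmp, comment.char = "#", check.names = FALSE)
  df$start <- df$start + 1L
  t1 <- tempfile(fileext = ".tsv")
  utils::write.table(df, t1, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(read_meth_matrix(t1, one_based = TRUE)$loci$start,
               coh$meth$loci$start)
})

test_that("active promoters require log expression above 7 in at least one sample", {
  genes <- data.frame(gene = c("a", "b"), chrom = "chr1", tss = c(0L, 10L),
                      strand = "+")
  ev <- rbind(c(6, 6.9), c(6, 7.1))
  colnames(ev) <- c("s1", "s2")
  em <- expr_matrix(ev, genes)
  expect_equal(unname(active_promoters(em)), c(FALSE, TRUE))
})
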