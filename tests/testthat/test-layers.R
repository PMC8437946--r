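test_that("layer inference recovers planted clock/MG/ML loci and latents", {
  coh <- mid_cohort()
  fit <- mid_fit()
  lt <- coh$truth$loci
  planted <- lt[lt$layer %in% c("clock", "MG", "ML"), ]
  got <- fit$layers$loci
  lab <- got$layer[match(planted$locus_id, got$locus_id)]
  acc <- mean(tolower(planted$layer) == ifelse(is.na(lab), "none", lab))
  expect_gt(acc, 0.85)
  tr <- er_pos_truth(coh)
  sc <- fit$layers$scores[tr$sample, ]
  # loss layers anti-correlate with their latents (documented sign convention)
  expect_gt(abs(stats::cor(sc[, "clock"], tr$c_s)), 0.85)
  expect_gt(abs(stats::cor(sc[, "mg"], tr$g_s)), 0.75)
  expect_gt(abs(stats::cor(sc[, "ml"], tr$l_s)), 0.85)
  expect_lt(stats::cor(sc[, "clock"], tr$c_s), 0)
  expect_gt(stats::cor(sc[, "mg"], tr$g_s), 0)
  # labeling evidence: normals are most methylated at clock loci, least at MG
  lev <- fit$layers$labeling
  expect_equal(lev$layer[which.max(lev$normal_raw_mean)], "clock")
  expect_equal(lev$layer[which.min(lev$normal_raw_mean)], "mg")
})

test_that("layer fits are deterministic and blockwise correlation is block-size invariant", {
  coh <- mid_cohort()
  fit <- mid_fit()
  f2 <- fit_layers(fit$norm, coh$meth, coh$metadata, fit$params)
  expect_identical(fit$layers$loci, f2$loci)
  expect_identical(fit$layers$scores, f2$scores)
  set.seed(30)
  x <- matrix(rnorm(40 * 25), 40, 25,
              dimnames = list(sprintf("l%02d", 1:40), NULL))
  x[sample(length(x), 50)] <- NA
  c1 <- epilayers:::cor_blockwise(x, block = 7L)
  c2 <- epilayers:::cor_blockwise(x, block = 4000L)
  expect_equal(c1, c2, tolerance = 1e-12)
})

test_that("scores project onto other groups when layer loci are covered", {
  coh <- mid_cohort()
  fit <- mid_fit()
  # projecting onto the training matrix reproduces the scores
  pr <- project_scores(fit$layers, fit$norm)
  expect_equal(pr[, "clock"], fit$layers$scores[, "clock"], tolerance = 1e-12)
  # a matrix missing all MG loci yields a missing MG score
  keep <- setdiff(rownames(fit$norm$values),
                  fit$layers$loci$locus_id[fit$layers$loci$layer == "mg"])
  norm_sub <- fit$norm
  norm_sub$values <- norm_sub$values[keep, ]
  expect_warning(pr2 <- project_scores(fit$layers, norm_sub), "mg")
  expect_true(all(is.na(pr2[, "mg"])))
  expect_false(any(is.na(pr2[, "clock"])))
  # an ER- group sharing the latent model projects faithfully
  tr <- coh$truth$samples
  er <- tr[tr$group == "ER-", ]
  pr3 <- predict(fit,
                 meth_matrix(coh$meth$values[, er$sample], coh$meth$loci),
                 expr_matrix(coh$expr$values[, er$sample], coh$expr$genes),
                 K = 15)
  expect_gt(abs(stats::cor(pr3$Clock, er$c_s)), 0.85)
  expect_gt(abs(stats::cor(pr3$ML, er$l_s)), 0.85)
})

test_that("score table and fit methods expose the five scores", {
  fit <- mid_fit()
  st <- signature_table(fit, mid_cohort()$metadata)
  expect_named(st, c("sample", "group", "grade", "Immune", "CAF", "Clock", "MG", "ML"))
  expect_equal(nrow(st), length(fit$norm$samples))
  cf <- coef(fit)
  expect_equal(dim(cf), c(length(fit$norm$samples), 5L))
  expect_output(print(fit), "epilayer_fit")
  expect_output(print(summary(fit)), "deconvolution")
  expect_identical(residuals(fit), fit$norm$values)
})

test_that("layer annotation reports TOR lateness, KS statistics and enhancer linkage", {
  coh <- mid_cohort()
  fit <- mid_fit()
  ann <- annotate_layer(fit$layers, coh$meth, fit$norm, coh$metadata,
                        gene_tab = coh$expr$genes)
  # the clock layer is late-replication enriched
  late_clock <- ann$tor$composition$fraction[
    ann$tor$composition$layer == "clock" & ann$tor$composition$bin == "late"]
  expect_gt(late_clock, ann$tor$background_late)
  ks_clock <- ann$tor$ks[ann$tor$ks$layer == "clock", ]
  expect_lt(ks_clock$p, 0.01)
  # self-comparison of a background sample gives a near-zero KS statistic
  set.seed(31)
  v <- rnorm(500)
  ks0 <- suppressWarnings(stats::ks.test(v, v))
  expect_lt(unname(ks0$statistic), 1e-12)
  expect_true(is.data.frame(ann$enhancers))
  expect_true(all(ann$enhancers$linked_fraction >= 0 | is.na(ann$enhancers$linked_fraction)))
})

test_that("a single planted layer still yields three clusters, two of them noise", {
  cfg <- mid_config(frac_clock = 0, frac_ml = 0, frac_tme = 0.05,
                    n_cis_pairs = 0, n_distal_pairs = 0, rng_seed = 33L)
  coh <- simulate_cohort(cfg)
  fit <- epilayer_fit(coh$meth, coh$expr, coh$metadata, group = "ER+")
  cl <- fit$layers$clusters
  expect_equal(length(unique(cl)), 3L)
  lt <- coh$truth$loci
  mg_planted <- lt$locus_id[lt$layer == "MG"]
  main <- names(which.max(table(cl[names(cl) %in% mg_planted])))
  C <- epilayers:::cor_blockwise(fit$norm$values[names(cl), , drop = FALSE])
  for (k in setdiff(unique(cl), as.integer(main))) {
    mem <- names(cl)[cl == k]
    if (length(mem) < 2) next
    sub <- C[mem, mem]
    expect_lt(mean(abs(sub[upper.tri(sub)]), na.rm = TRUE), 0.2)
  }
})

test_that("scores are invariant to duplicating a layer's locus rows", {
  fit <- mid_fit()
  norm <- fit$norm
  mg <- fit$layers$loci$locus_id[fit$layers$loci$layer == "mg"]
  dup <- norm
  extra <- norm$values[mg, , drop = FALSE]
  rownames(extra) <- paste0(mg, "_dup")
  dup$values <- rbind(norm$values, extra)
  model2 <- fit$layers
  model2$loci <- rbind(model2$loci,
                       data.frame(locus_id = paste0(mg, "_dup"), layer = "mg",
                                  cor = NA_real_))
  pr <- project_scores(model2, dup)
  expect_equal(pr[, "mg"], fit$layers$scores[, "mg"], tolerance = 1e-12)
})
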