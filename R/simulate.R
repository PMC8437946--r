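# Synthetic cohorts with the statistical structure the deconvolution assumes:
# bulk methylation as a cell-type mixture (tumor / immune / fibroblast), three
# tumor-intrinsic latent layers (replication-timing-graded loss clock, CpG
# island gain, partial-methylation loss), planted cis-coupled promoter-gene
# and enhancer-gene pairs, and read-level epialleles. Ground truth is returned
# alongside so recovery is testable.

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Simulation configuration
#'
#' Defaults define the reference synthetic cohort: 500 ER+ tumors and 60
#' normals; 2000 genes plus 60-gene immune and fibroblast (CAF) expression
#' modules; 3000 restriction fragments and 300 enhancers; per-sample immune
#' and CAF fractions Beta(2,8); uniform (0,1) clock/gain/loss latents in
#' tumors (zero in normals); 5% of loci per layer; 50 cis-coupled
#' promoter-gene pairs at coupling 0.6 and 30 distal enhancer-gene pairs;
#' heteroscedastic measurement noise (binomial read-sampling variance at
#' depth 60 plus a flat 0.02 technical floor) and 5% missing calls.
#'
#' @param ... named overrides of any default.
#' @return list of class "sim_config".
#' @export
sim_config <- function(...) {
  cfg <- list(
    n_tumors = 500L, n_er_neg = 0L, n_normals = 60L,
    n_genes = 2000L, n_immune_genes = 60L, n_caf_genes = 60L,
    n_fragments = 3000L, n_enhancers = 300L,
    frac_clock = 0.05, frac_mg = 0.05, frac_ml = 0.05, frac_tme = 0.05,
    n_cis_pairs = 50L, rho_cis = 0.6,
    n_distal_pairs = 30L, rho_distal = 0.6,
    distal_dist_range = c(10000L, 400000L),
    imm_beta = c(2, 8), caf_beta = c(2, 8),
    latent_dist = "uniform",        # or "beta"
    latent_beta = c(2, 2),
    clock_max_loading = 0.6,
    mg_loading = c(0.4, 0.8), ml_loading = c(0.3, 0.6),
    read_depth = 60L, sigma_meth = 0.02, sigma_expr = 0.5,
    sigma_module_expr = 0.3, module_expr_gain = 4,
    frac_trans_genes = 0.10, trans_coef = 0.8, trans_weak_sd = 0.25,
    tme_expr_sd = 1.0,
    n_variable_promoters = 200L, promoter_jitter_sd = 0.15,
    missing_rate = 0.05,
    n_mutations = 20L, mutation_rate = 0.15,
    n_chrom = 10L, gene_spacing = 1e6,
    rng_seed = 1L
  )
  ov <- list(...)
  if (length(ov)) {
    bad <- setdiff(names(ov), names(cfg))
    if (length(bad)) stop("unknown sim_config field(s): ", paste(bad, collapse = ", "))
    cfg[names(ov)] <- ov
  }
  class(cfg) <- "sim_config"
  cfg
}

draw_latent <- function(n, cfg) {
  if (cfg$latent_dist == "uniform") stats::runif(n)
  else stats::rbeta(n, cfg$latent_beta[1], cfg$latent_beta[2])
}

# bimodal beta-mixture locus baseline, clamped away from the boundaries so
# measurement noise rarely clips
baseline_mix <- function(n, w = c(hypo = 0.35, hemi = 0.25, hyper = 0.40)) {
  comp <- sample(names(w), n, replace = TRUE, prob = w)
  v <- numeric(n)
  v[comp == "hypo"] <- stats::rbeta(sum(comp == "hypo"), 1, 12)
  v[comp == "hemi"] <- stats::rbeta(sum(comp == "hemi"), 5, 5)
  v[comp == "hyper"] <- stats::rbeta(sum(comp == "hyper"), 12, 1)
  pmin(pmax(v, 0.08), 0.92)
}

#' Simulate a bulk methylome cohort with ground truth
#'
#' Observed methylation is the mixture
#' (1 - f_imm - f_caf) * tumor + f_imm * immune + f_caf * caf + noise,
#' clipped to [0,1]. The tumor compartment carries the three latent layers:
#' clock loci lose methylation proportionally to the sample clock latent and
#' a loading equal to the locus's normalized replication-timing lateness rank;
#' gain (MG) loci start near zero and gain with the gain latent; loss (ML)
#' loci start partially methylated and lose with the loss latent. Immune /
#' CAF module genes' expression increases with the respective fraction;
#' planted cis genes' expression is anti-coupled to their own promoter's
#' observed methylation at the configured coupling strength.
#'
#' @param cfg a \code{\link{sim_config}}.
#' @return list with \code{meth} (\code{\link{meth_matrix}}), \code{expr}
#'   (\code{\link{expr_matrix}}), \code{metadata}
#'   (\code{\link{sample_metadata}} plus a \code{mutations} attribute) and
#'   \code{truth} (per-sample fractions/latents, per-locus layer labels,
#'   planted pairs, module gene sets).
#' @export
simulate_cohort <- function(cfg = sim_config()) {
  with_seed(cfg$rng_seed, simulate_cohort_impl(cfg))
}

simulate_cohort_impl <- function(cfg) {
  ## ---- samples ----
  n_t <- cfg$n_tumors; n_e <- cfg$n_er_neg; n_n <- cfg$n_normals
  n_s <- n_t + n_e + n_n
  samples <- c(sprintf("T%04d", seq_len(n_t)),
               if (n_e > 0) sprintf("E%04d", seq_len(n_e)),
               sprintf("N%04d", seq_len(n_n)))
  group <- c(rep("ER+", n_t), rep("ER-", n_e), rep("normal", n_n))
  is_tumor <- group != "normal"

  f_imm <- stats::rbeta(n_s, cfg$imm_beta[1], cfg$imm_beta[2])
  f_caf <- stats::rbeta(n_s, cfg$caf_beta[1], cfg$caf_beta[2])
  tot <- f_imm + f_caf
  over <- tot > 0.95
  f_imm[over] <- f_imm[over] / tot[over] * 0.95
  f_caf[over] <- f_caf[over] / tot[over] * 0.95

  c_s <- ifelse(is_tumor, draw_latent(n_s, cfg), 0)
  g_s <- ifelse(is_tumor, draw_latent(n_s, cfg), 0)
  l_s <- ifelse(is_tumor, draw_latent(n_s, cfg), 0)

  ## ---- genes and genome layout ----
  genes_plain <- sprintf("G%04d", seq_len(cfg$n_genes))
  imm_anchor <- c("CD3D", "CD3E", "CD8A", "CTLA4", "PDCD1")
  caf_anchor <- c("CAV1", "FAP", "VIM")
  genes_imm <- c(imm_anchor, sprintf("IMM%03d", seq_len(max(0, cfg$n_immune_genes - length(imm_anchor)))))
  genes_caf <- c(caf_anchor, sprintf("CAF%03d", seq_len(max(0, cfg$n_caf_genes - length(caf_anchor)))))
  genes <- c(genes_plain, genes_imm, genes_caf)
  n_g <- length(genes)
  chrom <- sprintf("chr%d", (seq_len(n_g) - 1L) %% cfg$n_chrom + 1L)
  idx_on_chrom <- (seq_len(n_g) - 1L) %/% cfg$n_chrom
  tss <- as.integer(idx_on_chrom * cfg$gene_spacing + 5e5)
  strand <- rep(c("+", "-"), length.out = n_g)
  gene_tab <- data.frame(gene = genes, chrom = chrom, tss = tss,
                         strand = strand, stringsAsFactors = FALSE)

  ## ---- loci ----
  prom <- make_promoter_window(gene_tab$tss, gene_tab$strand,
                               chrom = gene_tab$chrom)
  prom$locus_id <- paste0("P_", gene_tab$gene)
  chrom_span <- (max(idx_on_chrom) + 1) * cfg$gene_spacing + 1e6

  frag_chrom <- sprintf("chr%d", sample.int(cfg$n_chrom, cfg$n_fragments, replace = TRUE))
  frag_start <- as.integer(floor(stats::runif(cfg$n_fragments, 0, chrom_span - 500)))
  frags <- locus_table(frag_chrom, frag_start, frag_start + 300L,
                       locus_class = "fragment",
                       locus_id = sprintf("F%05d", seq_len(cfg$n_fragments)))

  # distal planted enhancers near their target gene's TSS; the rest random
  distal_genes <- character(0)
  enh_chrom <- sprintf("chr%d", sample.int(cfg$n_chrom, cfg$n_enhancers, replace = TRUE))
  enh_start <- as.integer(floor(stats::runif(cfg$n_enhancers, 0, chrom_span - 500)))
  nd <- min(cfg$n_distal_pairs, cfg$n_enhancers)
  if (nd > 0) {
    # avoid genes used for other plants; chosen later in order
    distal_genes <- genes_plain[seq(cfg$n_cis_pairs + 1L,
                                    cfg$n_cis_pairs + nd)]
    gi <- match(distal_genes, gene_tab$gene)
    off <- sample(c(-1, 1), nd, TRUE) *
      as.integer(floor(stats::runif(nd, cfg$distal_dist_range[1],
                                    cfg$distal_dist_range[2])))
    enh_chrom[seq_len(nd)] <- gene_tab$chrom[gi]
    enh_start[seq_len(nd)] <- pmax(as.integer(gene_tab$tss[gi] + off), 3000L)
  }
  enhs <- locus_table(enh_chrom, enh_start, enh_start + 200L,
                      locus_class = "enhancer",
                      locus_id = sprintf("E%04d", seq_len(cfg$n_enhancers)))

  loci <- rbind(prom, frags, enhs)
  n_l <- nrow(loci)
  loci$tor_value <- stats::runif(n_l, 0, 100)  # larger = earlier replication
  loci$cpg_content <- ifelse(loci$locus_class == "promoter",
                             stats::rbeta(n_l, 6, 40),
                             stats::rbeta(n_l, 2, 60))

  ## ---- layer / TME labels ----
  layer <- rep("neutral", n_l)
  names(layer) <- loci$locus_id
  layer[paste0("P_", genes_imm)] <- "TME-immune"
  layer[paste0("P_", genes_caf)] <- "TME-caf"
  frag_ids <- frags$locus_id
  n_tme_frag <- round(cfg$frac_tme * cfg$n_fragments)
  pick <- sample(frag_ids, 2 * n_tme_frag)
  layer[pick[seq_len(n_tme_frag)]] <- "TME-immune"
  layer[pick[n_tme_frag + seq_len(n_tme_frag)]] <- "TME-caf"

  lateness <- 1 - (rank(loci$tor_value) - 0.5) / n_l  # 1 = latest replicating
  names(lateness) <- loci$locus_id
  free_frag <- frag_ids[layer[frag_ids] == "neutral"]
  n_clock <- round(cfg$frac_clock * n_l)
  clock_ids <- sample(free_frag, min(n_clock, length(free_frag)),
                      prob = lateness[free_frag]^2)
  layer[clock_ids] <- "clock"

  cis_genes <- genes_plain[seq_len(cfg$n_cis_pairs)]
  reserved_prom <- paste0("P_", c(cis_genes, distal_genes), recycle0 = TRUE)
  free_pe <- setdiff(c(prom$locus_id, enhs$locus_id),
                     c(names(layer)[layer != "neutral"], reserved_prom,
                       if (nd > 0) enhs$locus_id[seq_len(nd)]))
  n_mg <- round(cfg$frac_mg * n_l)
  mg_ids <- sample(free_pe, min(n_mg, length(free_pe)))
  layer[mg_ids] <- "MG"
  free_frag2 <- frag_ids[layer[frag_ids] == "neutral"]
  n_ml <- round(cfg$frac_ml * n_l)
  ml_ids <- sample(free_frag2, min(n_ml, length(free_frag2)))
  layer[ml_ids] <- "ML"

  ## ---- cell-type methylation profiles ----
  base <- baseline_mix(n_l)
  names(base) <- loci$locus_id
  base[layer == "clock"] <- pmin(pmax(stats::rbeta(sum(layer == "clock"), 12, 3), 0.6), 0.92)
  base[layer == "MG"] <- 0.08
  base[layer == "ML"] <- pmin(pmax(stats::rbeta(sum(layer == "ML"), 6, 4), 0.35), 0.85)
  base[layer %in% c("TME-immune", "TME-caf")] <- 0.85

  imm_prof <- caf_prof <- base
  imm_prof[layer == "TME-immune"] <- 0.08
  caf_prof[layer == "TME-caf"] <- 0.08
  # immune/CAF compartments do not carry the tumor-intrinsic latents

  loading <- numeric(n_l)
  names(loading) <- loci$locus_id
  loading[layer == "clock"] <- cfg$clock_max_loading * lateness[layer == "clock"]
  loading[layer == "MG"] <- stats::runif(sum(layer == "MG"), cfg$mg_loading[1], cfg$mg_loading[2])
  loading[layer == "ML"] <- stats::runif(sum(layer == "ML"), cfg$ml_loading[1], cfg$ml_loading[2])

  ## ---- tumor-compartment matrix ----
  tum <- matrix(base, n_l, n_s)
  dimnames(tum) <- list(loci$locus_id, samples)
  ic <- layer == "clock"; im <- layer == "MG"; il <- layer == "ML"
  tum[ic, ] <- tum[ic, ] - outer(loading[ic], c_s)
  tum[im, ] <- tum[im, ] + outer(loading[im], g_s)
  tum[il, ] <- tum[il, ] - outer(loading[il], l_s)

  # tumor-intrinsic per-sample variability at planted cis/distal promoters,
  # planted enhancers and a matched set of uncoupled decoy promoters
  var_prom <- paste0("P_", sample(setdiff(genes_plain, c(cis_genes, distal_genes)),
                                  min(cfg$n_variable_promoters,
                                      cfg$n_genes - cfg$n_cis_pairs - length(distal_genes))),
                    recycle0 = TRUE)
  jitter_ids <- c(paste0("P_", cis_genes, recycle0 = TRUE),
                  paste0("P_", distal_genes, recycle0 = TRUE),
                  if (length(distal_genes)) enhs$locus_id[seq_along(distal_genes)],
                  var_prom)
  ji <- match(jitter_ids, loci$locus_id)
  base[ji] <- pmin(pmax(base[ji], 0.25), 0.75)  # room to vary both ways
  tum[ji, ] <- matrix(base[ji], length(ji), n_s) +
    matrix(stats::rnorm(length(ji) * n_s, 0, cfg$promoter_jitter_sd), length(ji), n_s)
  tum <- pmin(pmax(tum, 0), 1)

  ## ---- mixture + measurement noise ----
  # noise is heteroscedastic: binomial read-sampling variance m(1-m)/depth at
  # the locus's mixed methylation level, plus a small flat technical floor
  w_t <- 1 - f_imm - f_caf
  obs <- sweep(tum, 2, w_t, "*") +
    outer(imm_prof, f_imm) + outer(caf_prof, f_caf)
  m0 <- pmin(pmax(obs, 0), 1)
  noise_sd <- sqrt(m0 * (1 - m0) / cfg$read_depth + cfg$sigma_meth^2)
  obs <- obs + matrix(stats::rnorm(n_l * n_s), n_l, n_s) * noise_sd
  clipped <- mean(obs < 0 | obs > 1)
  obs <- pmin(pmax(obs, 0), 1)

  ## ---- expression ----
  mu_g <- stats::rnorm(n_g, 8, 1)
  ev <- matrix(mu_g, n_g, n_s) +
    matrix(stats::rnorm(n_g * n_s, 0, cfg$sigma_expr), n_g, n_s)
  dimnames(ev) <- list(genes, samples)
  ev[genes_imm, ] <- 6 + cfg$module_expr_gain * matrix(f_imm, length(genes_imm), n_s, byrow = TRUE) +
    matrix(stats::rnorm(length(genes_imm) * n_s, 0, cfg$sigma_module_expr), length(genes_imm), n_s)
  ev[genes_caf, ] <- 6 + cfg$module_expr_gain * matrix(f_caf, length(genes_caf), n_s, byrow = TRUE) +
    matrix(stats::rnorm(length(genes_caf) * n_s, 0, cfg$sigma_module_expr), length(genes_caf), n_s)

  # trans structure: every background gene couples weakly to one tumor
  # latent (pervasive proliferation/instability expression programs), and a
  # designated subset couples strongly
  lat <- rbind(c_s, g_s, l_s)
  trans_pool <- setdiff(genes_plain, c(cis_genes, distal_genes))
  if (cfg$tme_expr_sd > 0) {
    # bulk expression is itself a cell-type mixture: most genes differ
    # between tumor and stromal compartments, so their measured expression
    # drifts with the infiltrating fractions
    d_imm <- stats::rnorm(length(trans_pool), 0, cfg$tme_expr_sd)
    d_caf <- stats::rnorm(length(trans_pool), 0, cfg$tme_expr_sd)
    ev[trans_pool, ] <- ev[trans_pool, ] + outer(d_imm, f_imm) + outer(d_caf, f_caf)
  }
  if (cfg$trans_weak_sd > 0) {
    wl <- sample.int(3L, length(trans_pool), replace = TRUE)
    wc <- stats::rnorm(length(trans_pool), 0, cfg$trans_weak_sd)
    ev[trans_pool, ] <- ev[trans_pool, ] +
      wc * (lat[wl, , drop = FALSE] - 0.5)
  }
  n_trans <- round(cfg$frac_trans_genes * cfg$n_genes)
  trans_genes <- if (n_trans > 0) sample(trans_pool, min(n_trans, length(trans_pool))) else character(0)
  for (i in seq_along(trans_genes)) {
    which_lat <- (i - 1L) %% 3L + 1L
    ev[trans_genes[i], ] <- mu_g[match(trans_genes[i], genes)] +
      cfg$trans_coef * (lat[which_lat, ] - 0.5) +
      stats::rnorm(n_s, 0, cfg$sigma_expr)
  }

  couple <- function(gene, locus_id, rho) {
    m <- obs[locus_id, ]
    z <- as.numeric(scale(m))
    e <- -(rho * z + sqrt(1 - rho^2) * stats::rnorm(n_s))
    mu_g[match(gene, genes)] + e
  }
  for (g in cis_genes) ev[g, ] <- couple(g, paste0("P_", g), cfg$rho_cis)
  for (i in seq_along(distal_genes))
    ev[distal_genes[i], ] <- couple(distal_genes[i], enhs$locus_id[i], cfg$rho_distal)

  ## ---- missing data ----
  if (cfg$missing_rate > 0) {
    holes <- matrix(stats::runif(n_l * n_s) < cfg$missing_rate, n_l, n_s)
    obs[holes] <- NA_real_
  }

  ## ---- metadata / mutations ----
  meta <- sample_metadata(samples, group,
                          grade = ifelse(is_tumor, sample(1:3, n_s, TRUE), NA),
                          CIN = ifelse(is_tumor, stats::runif(n_s, 0, 0.8), NA))
  mut <- NULL
  if (cfg$n_mutations > 0) {
    mut <- matrix(stats::rbinom(cfg$n_mutations * n_s, 1, cfg$mutation_rate),
                  cfg$n_mutations, n_s,
                  dimnames = list(sprintf("MUT%02d", seq_len(cfg$n_mutations)), samples))
    mut[, !is_tumor] <- 0L
  }

  truth <- list(
    samples = data.frame(sample = samples, group = group,
                         f_imm = f_imm, f_caf = f_caf,
                         c_s = c_s, g_s = g_s, l_s = l_s,
                         stringsAsFactors = FALSE),
    loci = data.frame(locus_id = loci$locus_id, layer = unname(layer),
                      loading = unname(loading), stringsAsFactors = FALSE),
    cis_pairs = data.frame(gene = cis_genes,
                           locus_id = paste0("P_", cis_genes, recycle0 = TRUE),
                           rho = rep(cfg$rho_cis, length(cis_genes)),
                           stringsAsFactors = FALSE),
    distal_pairs = if (length(distal_genes))
      data.frame(gene = distal_genes,
                 locus_id = enhs$locus_id[seq_along(distal_genes)],
                 rho = rep(cfg$rho_distal, length(distal_genes)),
                 stringsAsFactors = FALSE)
      else NULL,
    immune_genes = genes_imm, caf_genes = genes_caf,
    trans_genes = trans_genes,
    clip_fraction = clipped
  )

  list(meth = meth_matrix(obs, loci), expr = expr_matrix(ev, gene_tab),
       metadata = meta, mutations = mut, truth = truth, config = cfg)
}

## ---- read-level epiallele simulation --------------------------------------

#' Simulate read-level methylation patterns for one fragment
#'
#' Draws reads from a multinomial over 5-CpG epialleles for a fragment with
#' \code{n_cpgs} CpGs (the epiallele pattern lives on 5 designated CpGs;
#' additional CpGs carry independent random calls). Per-CpG dropout jitters
#' coverage so downstream most-covered-CpG selection is exercised. Fragments
#' with fewer than 5 CpGs are emitted but flagged, to test downstream
#' filtering.
#'
#' @param fragment_id id string.
#' @param depth number of reads to draw (>= 1).
#' @param epiallele_distribution named probability vector over 5-character
#'   binary pattern strings (e.g. "01011"); need not be normalized.
#' @param n_cpgs number of CpGs on the fragment (default 5).
#' @param positions CpG genomic positions (default 1..n_cpgs spaced 10 bp).
#' @param dropout per-CpG probability that a read misses the CpG; scalar or
#'   length n_cpgs.
#' @param seed optional RNG seed.
#' @return list of class "read_set": \code{reads} (reads x CpGs 0/1 matrix
#'   with NA where dropped), \code{positions}, \code{fragment_id},
#'   \code{flagged} (TRUE when n_cpgs < 5).
#' @export
simulate_read_patterns <- function(fragment_id, depth, epiallele_distribution,
                                   n_cpgs = 5L, positions = NULL,
                                   dropout = 0, seed = NULL) {
  stopifnot(depth >= 1)
  run <- function() {
    if (is.null(positions)) positions <- seq_len(n_cpgs) * 10L
    stopifnot(length(positions) == n_cpgs)
    pat <- names(epiallele_distribution)
    if (is.null(pat) || any(nchar(pat) != 5L))
      stop("epiallele_distribution must be named by 5-character patterns")
    p <- epiallele_distribution / sum(epiallele_distribution)
    draw <- sample(pat, depth, replace = TRUE, prob = p)
    k <- min(5L, n_cpgs)
    bits <- t(vapply(strsplit(draw, ""), function(ch) as.integer(ch),
                     integer(5)))
    reads <- matrix(NA_integer_, depth, n_cpgs)
    reads[, seq_len(k)] <- bits[, seq_len(k), drop = FALSE]
    if (n_cpgs > 5L)
      reads[, 6:n_cpgs] <- matrix(stats::rbinom(depth * (n_cpgs - 5L), 1, 0.5),
                                  depth, n_cpgs - 5L)
    dropout <- rep_len(dropout, n_cpgs)
    for (j in seq_len(n_cpgs))
      if (dropout[j] > 0)
        reads[stats::runif(depth) < dropout[j], j] <- NA_integer_
    structure(list(fragment_id = fragment_id, positions = positions,
                   reads = reads, flagged = n_cpgs < 5L),
              class = "read_set")
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Simulate a copy-number dosage cohort
#'
#' Generates per-gene promoter methylation, expression and copy-number states
#' for a mixture of "compensated" genes (methylation rises with copy-number
#' gain while expression stays flat) and "pure dosage" genes (expression
#' scales with copy number while methylation stays flat), for testing the
#' dosage-compensation classifier.
#'
#' @param n_genes total genes (half compensated, half dosage).
#' @param n_samples samples.
#' @param meth_shift methylation increase per gained copy for compensated genes.
#' @param expr_log2_per_copy expression log2 shift on 3N for dosage genes.
#' @param seed RNG seed.
#' @return list: meth, expr (genes x samples matrices), cn (states 1-4),
#'   truth (character vector "compensated"/"dosage").
#' @export
simulate_dosage_cohort <- function(n_genes = 200L, n_samples = 300L,
                                   meth_shift = 0.2, expr_log2_per_copy = log2(1.5),
                                   seed = 1L) {
  with_seed(seed, {
    gene <- sprintf("DG%04d", seq_len(n_genes))
    truth <- rep(c("compensated", "dosage"), length.out = n_genes)
    cn <- matrix(sample(c(1L, 2L, 3L), n_genes * n_samples, TRUE,
                        prob = c(0.2, 0.5, 0.3)), n_genes, n_samples,
                 dimnames = list(gene, sprintf("S%03d", seq_len(n_samples))))
    base_m <- stats::runif(n_genes, 0.3, 0.6)
    meth <- matrix(base_m, n_genes, n_samples) +
      matrix(stats::rnorm(n_genes * n_samples, 0, 0.05), n_genes, n_samples)
    expr <- matrix(stats::rnorm(n_genes * n_samples, 8, 0.3), n_genes, n_samples)
    comp <- truth == "compensated"
    meth[comp, ] <- meth[comp, ] + meth_shift * (cn[comp, ] - 2L)
    expr[!comp, ] <- expr[!comp, ] + expr_log2_per_copy * (cn[!comp, ] - 2L)
    meth <- pmin(pmax(meth, 0), 1)
    dimnames(meth) <- dimnames(expr) <- dimnames(cn)
    list(meth = meth, expr = expr, cn = cn, truth = stats::setNames(truth, gene))
  })
}
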