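# End-to-end orchestration. One configuration drives all stages (simulate ->
# crosscor -> normalize -> layers -> cis -> epipoly -> integrate); each stage
# reads the previous stage's TSV outputs from the run directory and writes
# its own, so reruns under the same config and seed are byte-identical.

# small multiply-add rolling hash over the serialized config (stays exact in
# doubles; no external digest dependency)
config_hash <- function(x) {
  raw <- serialize(x, NULL, ascii = TRUE)
  h <- 5381
  for (b in as.integer(raw)) h <- (h * 33 + b) %% 4294967296
  sprintf("%08x", as.integer(h %% 2147483648))
}

#' Pipeline run configuration
#'
#' @param outdir output directory (created if needed).
#' @param seed master seed; stage seeds are derived deterministically.
#' @param stages stages to run, in order, out of simulate, crosscor,
#'   normalize, layers, cis, epipoly, integrate.
#' @param group group the model is fitted on (default "ER+").
#' @param sim \code{\link{sim_config}} overrides (list) for the simulate
#'   stage.
#' @param params \code{\link{epilayer_params}} overrides (list).
#' @param inputs optional named list of input paths (meth, expr, metadata,
#'   mutations) used instead of the simulate stage.
#' @param n_shuffles permutations for the distal screen stage.
#' @param n_pattern_fragments fragments simulated for the epipoly stage.
#' @return list of class "run_config".
#' @export
run_config <- function(outdir, seed = 1L,
                       stages = c("simulate", "crosscor", "normalize",
                                  "layers", "cis", "epipoly", "integrate"),
                       group = "ER+", sim = list(), params = list(),
                       inputs = NULL, n_shuffles = 3L,
                       n_pattern_fragments = 40L) {
  structure(list(outdir = outdir, seed = as.integer(seed), stages = stages,
                 group = group, sim = sim, params = params, inputs = inputs,
                 n_shuffles = n_shuffles,
                 n_pattern_fragments = n_pattern_fragments),
            class = "run_config")
}

#' Run the pipeline
#'
#' Executes the enabled stages in order. Every output table carries a header
#' with the package version, a hash of the configuration, and the seed. A
#' stage whose upstream outputs are missing stops with an error naming the
#' missing stage. The configuration itself is serialized to
#' \code{config.dcf} in the run directory.
#'
#' @param config a \code{\link{run_config}}.
#' @return the output directory, invisibly; a JSON-like per-stage summary is
#'   written to \code{run_summary.json} and a log to \code{run.log}.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$outdir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config[setdiff(names(config), "outdir")])
  hdr <- run_header(seed = config$seed, config_hash = hash)
  pth <- function(f) file.path(out, f)
  params <- do.call(epilayer_params, config$params)
  logf <- file(pth("run.log"), "w")
  on.exit(close(logf))
  summary_rows <- list()
  note <- function(stage, msg, ...) {
    line <- sprintf("[%s] %s", stage, sprintf(msg, ...))
    writeLines(line, logf)
    message(line)
  }
  need <- function(f, produced_by) {
    if (!file.exists(pth(f)))
      stop(sprintf("missing %s: enable the '%s' stage (or provide inputs)",
                   f, produced_by))
    pth(f)
  }
  stage_on <- function(s) s %in% config$stages

  writeLines(paste(capture_dcf(config[setdiff(names(config), "outdir")]),
                   collapse = "\n"), pth("config.dcf"))

  if (stage_on("simulate")) {
    sim <- do.call(sim_config, c(config$sim,
                                 list(rng_seed = config$seed)[!("rng_seed" %in% names(config$sim))]))
    coh <- simulate_cohort(sim)
    write_meth_matrix(coh$meth, pth("meth.tsv"), hdr)
    write_expr_matrix(coh$expr, pth("expr.tsv"), hdr)
    write_tsv_with_header(as.data.frame(coh$metadata), pth("metadata.tsv"), hdr)
    if (!is.null(coh$mutations))
      write_tsv_with_header(cbind(data.frame(feature = rownames(coh$mutations)),
                                  as.data.frame(coh$mutations, check.names = FALSE)),
                            pth("mutations.tsv"), hdr)
    write_tsv_with_header(coh$truth$samples, pth("ground_truth_samples.tsv"), hdr)
    write_tsv_with_header(coh$truth$loci, pth("ground_truth_loci.tsv"), hdr)
    write_tsv_with_header(coh$truth$cis_pairs, pth("ground_truth_cis_pairs.tsv"), hdr)
    # read-level patterns for a subset of fragments, varying concentration
    frag_ids <- coh$meth$loci$locus_id[coh$meth$loci$locus_class == "fragment"]
    nf <- min(config$n_pattern_fragments, length(frag_ids))
    pats <- all_patterns()
    sets <- with_seed(config$seed + 7L, lapply(seq_len(nf), function(i) {
      conc <- stats::runif(1)  # 0 = uniform epialleles, 1 = concentrated
      w <- stats::rexp(32)^(1 + 6 * conc)
      rs <- simulate_read_patterns(frag_ids[i], depth = sample(10:120, 1),
                                   epiallele_distribution = stats::setNames(w, pats),
                                   n_cpgs = 7L, dropout = 0.1)
      homogenize_fragment(rs)
    }))
    write_pattern_sets(sets, pth("patterns.tsv"))
    note("simulate", "%d loci x %d samples, %d genes, %d pattern fragments",
         nrow(coh$meth$values), ncol(coh$meth$values), nrow(coh$expr$values), nf)
    summary_rows$simulate <- list(n_loci = nrow(coh$meth$values),
                                  n_samples = ncol(coh$meth$values))
  }

  load_inputs <- function() {
    ip <- config$inputs
    list(meth = read_meth_matrix(if (!is.null(ip$meth)) ip$meth else need("meth.tsv", "simulate")),
         expr = read_expr_matrix(if (!is.null(ip$expr)) ip$expr else need("expr.tsv", "simulate")),
         metadata = read_tsv_skip_header(if (!is.null(ip$metadata)) ip$metadata else need("metadata.tsv", "simulate")))
  }

  if (stage_on("crosscor")) {
    d <- load_inputs()
    cc <- build_cross_correlation(d$expr, d$meth, d$metadata, config$group, params)
    cc <- cluster_cross_correlation(cc)
    tme <- identify_tme_modules(cc)
    samp <- intersect(cc$samples, samples_in_group(d$metadata, config$group))
    sig <- data.frame(sample = samp,
                      immune_expr = compute_signature(d$expr$values[, samp, drop = FALSE], tme$immune_genes),
                      caf_expr = compute_signature(d$expr$values[, samp, drop = FALSE], tme$caf_genes))
    write_tsv_with_header(data.frame(gene = names(cc$row_clusters),
                                     cluster = as.integer(cc$row_clusters)),
                          pth("crosscor_gene_clusters.tsv"), hdr)
    write_tsv_with_header(data.frame(locus_id = names(cc$col_clusters),
                                     cluster = as.integer(cc$col_clusters)),
                          pth("crosscor_locus_clusters.tsv"), hdr)
    write_tsv_with_header(data.frame(gene = tme$immune_genes), pth("module_immune.tsv"), hdr)
    write_tsv_with_header(data.frame(gene = tme$caf_genes), pth("module_caf.tsv"), hdr)
    write_tsv_with_header(sig, pth("signatures.tsv"), hdr)
    note("crosscor", "%d genes x %d loci; immune module %d, caf module %d",
         length(cc$genes), length(cc$loci),
         length(tme$immune_genes), length(tme$caf_genes))
    summary_rows$crosscor <- list(n_genes = length(cc$genes), n_loci = length(cc$loci))
  }

  if (stage_on("normalize")) {
    d <- load_inputs()
    sig <- read_tsv_skip_header(need("signatures.tsv", "crosscor"))
    imm <- stats::setNames(sig$immune_expr, sig$sample)
    caf <- stats::setNames(sig$caf_expr, sig$sample)
    K <- if (identical(config$group, "ER+")) params$knn_K else params$knn_K_small
    norm <- knn_normalize(d$meth, imm, caf, K = K,
                          zscore_axes = params$knn_zscore_axes,
                          min_frac_neighbors = params$knn_min_frac_neighbors)
    df <- cbind(norm$loci[c("locus_id", "chrom", "start", "end", "strand",
                            "locus_class", "cpg_content", "tor_value")],
                as.data.frame(norm$values, check.names = FALSE))
    write_tsv_with_header(df, pth("normalized_meth.tsv"), hdr)
    write_tsv_with_header(cbind(data.frame(sample = rownames(norm$neighbors)),
                                as.data.frame(norm$neighbors)),
                          pth("neighbors.tsv"), hdr)
    note("normalize", "%d loci x %d samples, K = %d", nrow(norm$values),
         ncol(norm$values), K)
    summary_rows$normalize <- list(K = K, n_samples = ncol(norm$values))
  }

  if (stage_on("layers")) {
    d <- load_inputs()
    norm <- read_normalized(need("normalized_meth.tsv", "normalize"))
    sig <- read_tsv_skip_header(need("signatures.tsv", "crosscor"))
    fitl <- fit_layers(norm, d$meth, d$metadata, params, seed = config$seed)
    imm_ms <- tme_methylation_score(d$meth, stats::setNames(sig$immune_expr, sig$sample), params)
    caf_ms <- tme_methylation_score(d$meth, stats::setNames(sig$caf_expr, sig$sample), params)
    st <- data.frame(sample = rownames(fitl$scores),
                     Immune = imm_ms[rownames(fitl$scores)],
                     CAF = caf_ms[rownames(fitl$scores)],
                     Clock = fitl$scores[, "clock"],
                     MG = fitl$scores[, "mg"], ML = fitl$scores[, "ml"])
    write_tsv_with_header(fitl$loci, pth("layer_loci.tsv"), hdr)
    write_tsv_with_header(st, pth("signature_table.tsv"), hdr)
    note("layers", "clock/mg/ml loci: %s",
         paste(as.integer(table(fitl$loci$layer)[c("clock", "mg", "ml")]), collapse = "/"))
    summary_rows$layers <- list(n_loci = nrow(fitl$loci))
  }

  if (stage_on("cis")) {
    d <- load_inputs()
    imm <- read_tsv_skip_header(need("module_immune.tsv", "crosscor"))$gene
    caf <- read_tsv_skip_header(need("module_caf.tsv", "crosscor"))$gene
    samp <- d$metadata$sample[d$metadata$group %in% config$group]
    pairing <- data.frame(gene = d$expr$genes$gene,
                          locus_id = paste0("P_", d$expr$genes$gene))
    pairing <- pairing[pairing$locus_id %in% rownames(d$meth$values), ]
    cs <- promoter_cis_screen(d$expr, d$meth, pairing,
                              exclude_genes = c(imm, caf), samples = samp,
                              params = params)
    write_tsv_with_header(cs$results, pth("cis_promoter.tsv"), hdr)
    write_tsv_with_header(cs$fdr_table, pth("cis_fdr_table.tsv"), hdr)
    prom_windows <- d$meth$loci[d$meth$loci$locus_class == "promoter", ]
    ds <- distal_cis_screen(d$expr, d$meth, prom_windows, samples = samp,
                            n_shuffles = config$n_shuffles,
                            seed = config$seed + 11L, params = params)
    write_tsv_with_header(ds$results, pth("distal_pairs.tsv"), hdr)
    note("cis", "%d promoter hits at FDR<=0.05; %d distal paired (FDR %.2f)",
         length(cis_hits(cs, 0.05)), ds$n_paired, ds$fdr)
    summary_rows$cis <- list(promoter_hits = length(cis_hits(cs, 0.05)),
                             distal_paired = ds$n_paired)
  }

  if (stage_on("epipoly")) {
    sets <- read_pattern_sets(need("patterns.tsv", "simulate"))
    rows <- do.call(rbind, lapply(seq_along(sets), function(i) {
      ps <- downsample_patterns(sets[[i]], depth = params$epipoly_depth,
                                seed = config$seed + 13L + i)
      data.frame(fragment_id = ps$fragment_id, n_reads_in = sets[[i]]$n_reads,
                 covered = isTRUE(ps$covered),
                 epipoly = if (isTRUE(ps$covered))
                   epipolymorphism(ps, params$epipoly_depth) else NA_real_,
                 avg_meth = ps$avg_meth, stringsAsFactors = FALSE)
    }))
    write_tsv_with_header(rows, pth("epipoly.tsv"), hdr)
    note("epipoly", "%d fragments, %d covered", nrow(rows), sum(rows$covered))
    summary_rows$epipoly <- list(n_fragments = nrow(rows))
  }

  if (stage_on("integrate")) {
    st <- read_tsv_skip_header(need("signature_table.tsv", "layers"))
    mut_path <- if (!is.null(config$inputs$mutations)) config$inputs$mutations
      else need("mutations.tsv", "simulate")
    mt <- read_tsv_skip_header(mut_path)
    features <- as.matrix(mt[, -1, drop = FALSE])
    rownames(features) <- mt[[1]]
    scores <- as.matrix(st[c("Immune", "CAF", "Clock", "MG", "ML")])
    rownames(scores) <- st$sample
    assoc <- associate_scores(scores, features,
                              min_group_size = params$min_group_size,
                              n_strata = params$n_mut_strata)
    write_tsv_with_header(assoc$associations, pth("associations.tsv"), hdr)
    if (!is.null(assoc$strata))
      write_tsv_with_header(assoc$strata, pth("association_strata.tsv"), hdr)
    note("integrate", "%d association tests", nrow(assoc$associations))
    summary_rows$integrate <- list(n_tests = nrow(assoc$associations))
  }

  writeLines(to_json_summary(summary_rows), pth("run_summary.json"))
  invisible(out)
}

read_normalized <- function(path) {
  df <- read_tsv_skip_header(path)
  ann <- c("locus_id", "chrom", "start", "end", "strand", "locus_class",
           "cpg_content", "tor_value")
  samp <- setdiff(names(df), ann)
  loci <- locus_table(df$chrom, df$start, df$end, strand = df$strand,
                      locus_class = df$locus_class,
                      cpg_content = df$cpg_content, tor_value = df$tor_value,
                      locus_id = df$locus_id)
  v <- as.matrix(df[samp])
  rownames(v) <- loci$locus_id
  structure(list(values = v, loci = loci, samples = samp,
                 neighbors = NULL, K = NA_integer_),
            class = "normalized_meth")
}

capture_dcf <- function(config) {
  flat <- lapply(config, function(v)
    if (is.list(v)) paste(deparse(v), collapse = " ") else paste(v, collapse = ","))
  sprintf("%s: %s", names(flat), unlist(flat))
}

to_json_summary <- function(rows) {
  ent <- vapply(names(rows), function(nm) {
    kv <- vapply(names(rows[[nm]]), function(k)
      sprintf('"%s": %s', k, format(rows[[nm]][[k]])), character(1))
    sprintf('  "%s": {%s}', nm, paste(kv, collapse = ", "))
  }, character(1))
  c("{", paste(ent, collapse = ",\n"), "}")
}
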