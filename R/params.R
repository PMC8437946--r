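#' Analysis parameters
#'
#' Returns the full set of tunable constants used across the pipeline, with
#' the defaults used throughout: promoter windows of 500 bp upstream / 50 bp
#' downstream of the TSS, mean-methylation bounds of [0.1, 0.9] for loci
#' entering cross-correlation, a correlation floor of 0.25 for row/column
#' retention, a -0.3 threshold for TME methylation scores, K = 30 nearest
#' neighbors for ER+ cohorts (15 for ER- and normals), 30 cross-correlation
#' clusters, 3 methylation layers fitted on up to 50,000 sampled loci, a
#' minimum of 50 paired samples per correlation, a 500 kb window for distal
#' element pairing, 5-CpG epialleles downsampled to depth 30, enhancers called
#' at the top 3% of H3K4me1 coverage at least 2 kb from promoters and
#' homogenized to 200 bp, and time-of-replication bins at the 20th/60th
#' percentiles.
#'
#' @param ... named overrides for any default (e.g. \code{knn_K = 15}).
#' @return A named list of parameters with class \code{"epilayer_params"}.
#' @examples
#' p <- epilayer_params(knn_K = 15)
#' p$promoter_upstream
#' @export
epilayer_params <- function(...) {
  p <- list(
    promoter_upstream = 500L,
    promoter_downstream = 50L,
    active_promoter_expr_threshold = 7,
    meth_mean_bounds = c(0.1, 0.9),
    corr_floor = 0.25,
    tme_corr_threshold = -0.3,
    knn_K = 30L,
    knn_K_small = 15L,
    knn_zscore_axes = TRUE,
    knn_min_frac_neighbors = 0.5,
    n_cross_clusters = 30L,
    n_layer_clusters = 3L,
    layer_sample_size = 50000L,
    layer_link_threshold = c(
      enhancer = 0.25, trans = 0.3, mg_ml = 0.5, clock = 0.6
    ),
    layer_eligibility = "normalized",  # or "raw"
    min_corr_samples = 50L,
    distal_window = 500000L,
    epipoly_ncpg = 5L,
    epipoly_depth = 30L,
    enhancer_top_quantile = 0.03,
    enhancer_promoter_exclusion = 2000L,
    enhancer_width = 200L,
    tor_bins = c(late = 0.20, intermediate = 0.60),
    n_mut_strata = 5L,
    min_cn_stratum = 10L,
    min_group_size = 20L,
    rng_seed = 1L
  )
  ov <- list(...)
  if (length(ov)) {
    bad <- setdiff(names(ov), names(p))
    if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    p[names(ov)] <- ov
  }
  class(p) <- "epilayer_params"
  p
}

#' @export
print.epilayer_params <- function(x, ...) {
  cat("epilayer analysis parameters:\n")
  for (nm in names(x)) {
    v <- x[[nm]]
    cat(sprintf("  %-32s %s\n", nm, paste(format(v), collapse = ", ")))
  }
  invisible(x)
}
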