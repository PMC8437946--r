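# The core deconvolution as one fitted model: cross-correlation -> TME
# modules -> signatures -> K-nn normalization -> layer inference, returning a
# classed object with the usual accessor methods.

#' Fit the layered methylome deconvolution model
#'
#' Runs the full deconvolution on one sample group: (A) cross-correlates log
#' expression with raw promoter methylation, (B) clusters the matrix and
#' identifies the immune and CAF gene modules from anchor markers, (C)
#' computes per-sample immune/CAF expression signatures and finds each
#' tumor's K nearest neighbors in the 2D signature plane, (D) subtracts each
#' tumor's neighborhood-mean methylation, then fits the three global
#' methylation layers (loss clock, gain MG, loss ML) on the normalized matrix
#' and computes all five per-sample scores.
#'
#' @param meth a \code{\link{meth_matrix}} (all groups; promoters and
#'   non-promoters).
#' @param expr an \code{\link{expr_matrix}}.
#' @param metadata \code{\link{sample_metadata}}.
#' @param group the group to fit on (default "ER+").
#' @param params see \code{\link{epilayer_params}}.
#' @param anchors anchor marker lists, see \code{\link{identify_tme_modules}}.
#' @param K neighborhood size; defaults to \code{params$knn_K} for ER+ and
#'   \code{params$knn_K_small} otherwise.
#' @param seed RNG seed (locus subsampling in the layer fit).
#' @return object of class "epilayer_fit" with components \code{cross_corr},
#'   \code{tme} (modules), \code{signatures} (expression signatures),
#'   \code{tme_meth_scores}, \code{norm} (normalized methylation),
#'   \code{layers} (\code{"layer_model"}), \code{group}, \code{params}.
#'   Methods: \code{print}, \code{summary}, \code{coef} (five scores),
#'   \code{predict} (project onto new samples), \code{residuals} (the
#'   normalized matrix), \code{plot}.
#' @export
epilayer_fit <- function(meth, expr, metadata, group = "ER+",
                         params = epilayer_params(),
                         anchors = list(
                           immune = c("CD3D", "CD3E", "CD8A", "CTLA4", "PDCD1"),
                           caf = c("CAV1", "FAP", "VIM")),
                         K = NULL, seed = params$rng_seed) {
  if (is.null(K)) K <- if (identical(group, "ER+")) params$knn_K else params$knn_K_small
  cc <- build_cross_correlation(expr, meth, metadata, group, params)
  cc <- cluster_cross_correlation(cc)
  tme <- identify_tme_modules(cc, anchors)
  samp <- intersect(cc$samples, samples_in_group(metadata, group))
  ev <- expr$values[, samp, drop = FALSE]
  sig_imm <- compute_signature(ev, tme$immune_genes)
  sig_caf <- compute_signature(ev, tme$caf_genes)
  norm <- knn_normalize(meth, sig_imm, sig_caf, K = K,
                        zscore_axes = params$knn_zscore_axes,
                        min_frac_neighbors = params$knn_min_frac_neighbors)
  ms_imm <- tme_methylation_score(meth, sig_imm, params)
  ms_caf <- tme_methylation_score(meth, sig_caf, params)
  layers <- fit_layers(norm, meth, metadata, params, seed)
  structure(list(cross_corr = cc, tme = tme,
                 signatures = cbind(immune = sig_imm, caf = sig_caf),
                 tme_meth_scores = cbind(immune = ms_imm[samp], caf = ms_caf[samp]),
                 tme_meth_loci = list(immune = attr(ms_imm, "loci"),
                                      caf = attr(ms_caf, "loci")),
                 norm = norm, layers = layers,
                 group = group, K = K, params = params,
                 call = match.call()),
            class = "epilayer_fit")
}

#' Per-sample score table of a fit
#'
#' The five methylation scores per sample: Immune and CAF (raw methylation of
#' TME-correlated promoters) and Clock, MG, ML (mean normalized methylation
#' over the layer loci; the loss layers fall as loss accumulates).
#'
#' @param fit an \code{"epilayer_fit"}.
#' @param metadata optional \code{\link{sample_metadata}} to join.
#' @return data.frame(sample, [group, grade,] Immune, CAF, Clock, MG, ML).
#' @export
signature_table <- function(fit, metadata = NULL) {
  sc <- fit$layers$scores
  df <- data.frame(sample = rownames(sc),
                   Immune = fit$tme_meth_scores[rownames(sc), "immune"],
                   CAF = fit$tme_meth_scores[rownames(sc), "caf"],
                   Clock = sc[, "clock"], MG = sc[, "mg"], ML = sc[, "ml"],
                   stringsAsFactors = FALSE)
  if (!is.null(metadata))
    df <- merge(metadata[c("sample", "group", "grade")], df,
                by = "sample", sort = FALSE)
  rownames(df) <- NULL
  df
}

#' @export
coef.epilayer_fit <- function(object, ...) {
  st <- signature_table(object)
  m <- as.matrix(st[c("Immune", "CAF", "Clock", "MG", "ML")])
  rownames(m) <- st$sample
  m
}

#' @export
residuals.epilayer_fit <- function(object, ...) object$norm$values

#' @export
print.epilayer_fit <- function(x, ...) {
  cat(sprintf("epilayer_fit (%s, %d samples, K = %d)\n",
              x$group, length(x$norm$samples), x$K))
  print(x$tme)
  print(x$layers)
  invisible(x)
}

#' @export
summary.epilayer_fit <- function(object, ...) {
  sc <- coef(object)
  structure(list(group = object$group, n_samples = nrow(sc),
                 K = object$K,
                 n_genes = length(object$cross_corr$genes),
                 n_loci = length(object$cross_corr$loci),
                 module_sizes = c(immune = length(object$tme$immune_genes),
                                  caf = length(object$tme$caf_genes)),
                 layer_sizes = table(object$layers$loci$layer),
                 score_summary = apply(sc, 2, stats::quantile,
                                       c(0, 0.25, 0.5, 0.75, 1), na.rm = TRUE)),
            class = "summary.epilayer_fit")
}

#' @export
print.summary.epilayer_fit <- function(x, ...) {
  cat(sprintf("Layered methylome deconvolution: %s group, %d samples (K = %d)\n",
              x$group, x$n_samples, x$K))
  cat(sprintf("Cross-correlation matrix: %d genes x %d promoter loci\n",
              x$n_genes, x$n_loci))
  cat(sprintf("TME modules: %d immune genes, %d CAF genes\n",
              x$module_sizes["immune"], x$module_sizes["caf"]))
  cat("Layer loci: ", paste(sprintf("%s=%d", names(x$layer_sizes),
                                    as.integer(x$layer_sizes)), collapse = ", "), "\n")
  cat("Score quantiles:\n")
  print(round(x$score_summary, 3))
  invisible(x)
}

#' Project a fit onto new samples
#'
#' Computes immune/CAF signatures for the new samples with the fitted module
#' genes, K-nn-normalizes their methylation within the new group, and
#' projects the fitted layer locus sets; Immune/CAF methylation scores reuse
#' the fitted promoter sets.
#'
#' @param object an \code{"epilayer_fit"}.
#' @param meth,expr new-group data (shared loci/genes with the fit).
#' @param K neighborhood size for the new group (default
#'   \code{params$knn_K_small}).
#' @param ... unused.
#' @return data.frame like \code{\link{signature_table}} for the new samples.
#' @export
predict.epilayer_fit <- function(object, meth, expr, K = NULL, ...) {
  p <- object$params
  if (is.null(K)) K <- p$knn_K_small
  samp <- intersect(expr$samples, meth$samples)
  ev <- expr$values[, samp, drop = FALSE]
  sig_imm <- compute_signature(ev, object$tme$immune_genes)
  sig_caf <- compute_signature(ev, object$tme$caf_genes)
  norm <- knn_normalize(meth, sig_imm, sig_caf, K = K,
                        zscore_axes = p$knn_zscore_axes,
                        min_frac_neighbors = p$knn_min_frac_neighbors)
  sc <- project_scores(object$layers, norm)
  imm_loci <- intersect(object$tme_meth_loci$immune, rownames(meth$values))
  caf_loci <- intersect(object$tme_meth_loci$caf, rownames(meth$values))
  prom <- meth$values[, samp, drop = FALSE]
  score_from <- function(set)
    if (length(set)) colMeans(prom[set, , drop = FALSE], na.rm = TRUE)
    else rep(NA_real_, length(samp))
  data.frame(sample = samp,
             Immune = score_from(imm_loci), CAF = score_from(caf_loci),
             Clock = sc[samp, "clock"], MG = sc[samp, "mg"],
             ML = sc[samp, "ml"], stringsAsFactors = FALSE, row.names = NULL)
}

#' @export
plot.epilayer_fit <- function(x, ...) {
  graphics::pairs(coef(x), pch = 20, col = grDevices::grey(0.3, 0.5),
                  main = sprintf("Methylation scores (%s)", x$group), ...)
  invisible(x)
}
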