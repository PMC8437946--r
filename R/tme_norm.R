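# K-nearest-neighbor normalization of bulk methylation in the 2D space of
# immune / CAF expression signatures: each tumor's raw methylation, minus the
# mean methylation of the K tumors most similar to it in TME composition,
# leaves the tumor-intrinsic signal.

#' K-nn normalization of methylation in signature space
#'
#' Neighbors of each sample are found by Euclidean distance in the 2D
#' (immune signature, CAF signature) plane, excluding the sample itself
#' (K = 30 for ER+ cohorts; 15 for the smaller ER- and normal groups). The
#' normalized value is raw methylation minus the mean over the K neighbors'
#' non-missing values at the locus; cells where fewer than K/2 neighbors are
#' non-missing are set missing. By default both signature axes are z-scored
#' before computing distances so neither dominates; \code{zscore_axes = FALSE}
#' uses the raw axes.
#'
#' @param meth a \code{\link{meth_matrix}} (samples must include all score names).
#' @param immune_score,caf_score named per-sample signature vectors
#'   (\code{\link{compute_signature}}); their names define the samples to
#'   normalize.
#' @param K neighborhood size; must be < number of samples.
#' @param zscore_axes z-score the two axes before distances (default TRUE).
#' @param min_frac_neighbors minimum fraction of non-missing neighbors per
#'   cell (default 0.5).
#' @return list of class "normalized_meth": \code{values} (loci x samples,
#'   in [-1, 1], NA allowed), \code{loci}, \code{samples}, \code{neighbors}
#'   (samples x K matrix of neighbor ids), \code{K}.
#' @export
knn_normalize <- function(meth, immune_score, caf_score,
                          K = epilayer_params()$knn_K,
                          zscore_axes = TRUE, min_frac_neighbors = 0.5) {
  samp <- names(immune_score)
  stopifnot(!is.null(samp), identical(samp, names(caf_score)))
  samp <- intersect(samp, meth$samples)
  n <- length(samp)
  if (K >= n) stop(sprintf("K = %d must be smaller than the %d samples", K, n))
  ax <- cbind(imm = immune_score[samp], caf = caf_score[samp])
  if (zscore_axes) ax <- scale(ax)
  d <- as.matrix(stats::dist(ax))
  nbr <- matrix(NA_integer_, n, K, dimnames = list(samp, NULL))
  for (i in seq_len(n)) {
    # stable tie-break on sample index so duplicated coordinates are handled
    ord <- order(d[i, ], seq_len(n))
    ord <- ord[ord != i]
    nbr[i, ] <- ord[seq_len(K)]
  }
  v <- meth$values[, samp, drop = FALSE]
  out <- matrix(NA_real_, nrow(v), n, dimnames = dimnames(v))
  min_nb <- ceiling(K * min_frac_neighbors)
  for (i in seq_len(n)) {
    nb <- v[, nbr[i, ], drop = FALSE]
    cnt <- rowSums(!is.na(nb))
    mu <- rowMeans(nb, na.rm = TRUE)
    res <- v[, i] - mu
    res[cnt < min_nb] <- NA_real_
    out[, i] <- res
  }
  nbr_ids <- matrix(samp[nbr], n, K, dimnames = list(samp, NULL))
  structure(list(values = out, loci = meth$loci, samples = samp,
                 neighbors = nbr_ids, K = K),
            class = "normalized_meth")
}

#' @export
print.normalized_meth <- function(x, ...) {
  cat(sprintf("normalized_meth: %d loci x %d samples (K = %d neighbors)\n",
              nrow(x$values), ncol(x$values), x$K))
  invisible(x)
}

#' TME methylation scores
#'
#' The immune (or CAF) methylation score of a sample is the mean raw
#' methylation over all promoters whose methylation profile is negatively
#' correlated (below -0.3) with the immune (or CAF) expression signature.
#' Because the qualifying promoters are unmethylated in the infiltrating
#' cells, the score falls as the infiltrating fraction rises.
#'
#' @param meth a \code{\link{meth_matrix}} (promoter loci are used).
#' @param signature named per-sample signature vector.
#' @param params see \code{\link{epilayer_params}} (\code{tme_corr_threshold}).
#' @return named numeric per-sample score, with attribute "loci" giving the
#'   qualifying promoters; all-NA with a warning when no promoter qualifies.
#' @export
tme_methylation_score <- function(meth, signature, params = epilayer_params()) {
  samp <- intersect(names(signature), meth$samples)
  v <- meth$values[meth$loci$locus_class == "promoter", samp, drop = FALSE]
  r <- suppressWarnings(stats::cor(t(v), signature[samp],
                                   use = "pairwise.complete.obs"))[, 1]
  qual <- !is.na(r) & r < params$tme_corr_threshold
  if (!any(qual)) {
    warning("no promoter correlated below the threshold; score undefined")
    return(structure(stats::setNames(rep(NA_real_, length(samp)), samp),
                     loci = character(0)))
  }
  s <- colMeans(v[qual, , drop = FALSE], na.rm = TRUE)
  structure(s, loci = rownames(v)[qual])
}
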