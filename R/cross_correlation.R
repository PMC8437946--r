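# Expression x promoter-methylation cross-correlation: the unsupervised
# backbone for identifying tumor-microenvironment (immune / CAF) expression
# modules whose cell fractions contaminate bulk methylation.

# Pairwise-complete Pearson r between rows of two matrices, with support
# counts; cells with fewer than min_n paired observations are set missing.
# Computed from cross-products of the NA-masked matrices (exact: Pearson over
# each pairwise-complete subset, identical to use = "pairwise.complete.obs"
# but BLAS-speed). Rows are centered by their overall mean first, which
# leaves every pairwise correlation unchanged and improves precision.
pairwise_cor <- function(x, y, min_n = 0L) {
  prep <- function(m) {
    m <- m - rowMeans(m, na.rm = TRUE)
    tm <- t(m)
    M <- !is.na(tm)
    tm[!M] <- 0
    list(v = tm, v2 = tm^2, m = M * 1)
  }
  a <- prep(x); b <- prep(y)
  n <- crossprod(a$m, b$m)
  sx <- crossprod(a$v, b$m); sy <- crossprod(a$m, b$v)
  sxx <- crossprod(a$v2, b$m); syy <- crossprod(a$m, b$v2)
  sxy <- crossprod(a$v, b$v)
  with_n <- n > 1
  cv <- sxy - sx * sy / ifelse(with_n, n, 1)
  vx <- sxx - sx^2 / ifelse(with_n, n, 1)
  vy <- syy - sy^2 / ifelse(with_n, n, 1)
  den <- sqrt(pmax(vx, 0) * pmax(vy, 0))
  r <- cv / den
  tol <- 1e-12
  r[!with_n | vx < tol | vy < tol] <- NA_real_
  r <- pmin(pmax(r, -1), 1)
  dimnames(r) <- list(rownames(x), rownames(y))
  r[n < min_n] <- NA_real_
  list(r = r, n = n)
}

#' Cross-correlate expression with promoter methylation
#'
#' Computes pairwise-complete Pearson correlation between log-expression
#' profiles (rows) and raw promoter-methylation profiles (columns) over the
#' samples of one group. Loci with mean methylation below 0.1 or above 0.9
#' are excluded first; correlations supported by fewer than 50 paired samples
#' are set missing; rows and columns are retained only if they carry at least
#' one correlation above 0.25 or below -0.25.
#'
#' @param expr an \code{\link{expr_matrix}}.
#' @param meth a \code{\link{meth_matrix}}; only loci of class "promoter" are
#'   used unless \code{promoters_only = FALSE}.
#' @param metadata \code{\link{sample_metadata}}, used with \code{group} to
#'   select samples; \code{group = NULL} uses all shared samples.
#' @param group "ER+", "ER-" or "normal" (or NULL).
#' @param params see \code{\link{epilayer_params}}.
#' @param promoters_only restrict methylation columns to promoter loci.
#' @return list of class "cross_corr": \code{r} (genes x loci), \code{n_support},
#'   \code{genes}, \code{loci}, \code{samples}; cluster labels are added by
#'   \code{\link{cluster_cross_correlation}}.
#' @export
build_cross_correlation <- function(expr, meth, metadata = NULL, group = NULL,
                                    params = epilayer_params(),
                                    promoters_only = TRUE) {
  samp <- intersect(expr$samples, meth$samples)
  if (!is.null(metadata)) samp <- intersect(samp, samples_in_group(metadata, group))
  if (length(samp) < params$min_corr_samples)
    stop(sprintf("only %d shared samples; need at least %d",
                 length(samp), params$min_corr_samples))
  mv <- meth$values[, samp, drop = FALSE]
  if (promoters_only) mv <- mv[meth$loci$locus_class == "promoter", , drop = FALSE]
  mm <- rowMeans(mv, na.rm = TRUE)
  keep <- !is.na(mm) & mm >= params$meth_mean_bounds[1] & mm <= params$meth_mean_bounds[2]
  mv <- mv[keep, , drop = FALSE]
  ev <- expr$values[, samp, drop = FALSE]

  pc <- pairwise_cor(ev, mv, min_n = params$min_corr_samples)
  r <- pc$r
  hit <- abs(r) > params$corr_floor
  hit[is.na(hit)] <- FALSE
  rows <- rowSums(hit) > 0
  cols <- colSums(hit) > 0
  structure(list(r = r[rows, cols, drop = FALSE],
                 n_support = pc$n[rows, cols, drop = FALSE],
                 genes = rownames(r)[rows], loci = colnames(r)[cols],
                 samples = samp, params = params,
                 row_clusters = NULL, col_clusters = NULL),
            class = "cross_corr")
}

#' @export
print.cross_corr <- function(x, ...) {
  cat(sprintf("cross_corr: %d genes x %d promoter loci over %d samples\n",
              length(x$genes), length(x$loci), length(x$samples)))
  if (!is.null(x$row_clusters))
    cat(sprintf("  clustered: %d gene clusters, %d locus clusters\n",
                length(unique(x$row_clusters)), length(unique(x$col_clusters))))
  invisible(x)
}

# Ward (ward.D2) clustering of the rows of a matrix on Euclidean distances,
# missing entries imputed as 0 correlation; cluster ids are relabeled in
# dendrogram order so runs on identical input are identical.
ward_cluster_rows <- function(m, k) {
  m[is.na(m)] <- 0
  if (nrow(m) < k) {
    warning(sprintf("only %d rows; reducing clusters from %d", nrow(m), k))
    k <- nrow(m)
  }
  hc <- stats::hclust(stats::dist(m), method = "ward.D2")
  lab <- stats::cutree(hc, k = k)
  first <- lab[hc$order]
  map <- stats::setNames(seq_along(unique(first)), unique(first))
  stats::setNames(as.integer(map[as.character(lab)]), names(lab))
}

#' Cluster the cross-correlation matrix
#'
#' Rows (genes) and columns (loci) are clustered independently with
#' hierarchical clustering (Euclidean distance, Ward "ward.D2" linkage) and
#' the tree is cut at \code{n_clusters} (30 by default). Missing correlations
#' are imputed as 0 before clustering. Cluster ids follow dendrogram order,
#' so the labeling is deterministic.
#'
#' @param cc a \code{"cross_corr"} from \code{\link{build_cross_correlation}}.
#' @param n_clusters number of clusters for rows and columns.
#' @return the \code{cross_corr} with \code{row_clusters} / \code{col_clusters}
#'   filled in.
#' @export
cluster_cross_correlation <- function(cc, n_clusters = cc$params$n_cross_clusters) {
  cc$row_clusters <- ward_cluster_rows(cc$r, n_clusters)
  cc$col_clusters <- ward_cluster_rows(t(cc$r), n_clusters)
  cc
}

#' Identify immune and CAF gene modules from the clustered cross-correlation
#'
#' Each anchor set (canonical immune T-cell markers and canonical fibroblast
#' markers by default) votes for the gene cluster containing the plurality of
#' its members; that cluster's genes become the module. The assignment is
#' semi-supervised: \code{override} can force cluster ids.
#'
#' @param cc clustered \code{"cross_corr"}.
#' @param anchors list with character vectors \code{immune} and \code{caf}.
#' @param override optional list(immune =, caf =) of cluster ids.
#' @return list of class "tme_modules": \code{immune_genes}, \code{caf_genes},
#'   \code{anchor_evidence} (data.frame anchor/set/cluster).
#' @export
identify_tme_modules <- function(cc,
                                 anchors = list(
                                   immune = c("CD3D", "CD3E", "CD8A", "CTLA4", "PDCD1"),
                                   caf = c("CAV1", "FAP", "VIM")),
                                 override = NULL) {
  if (is.null(cc$row_clusters)) stop("cluster_cross_correlation() must run first")
  pick <- function(set, nm) {
    if (!is.null(override[[nm]])) return(as.integer(override[[nm]]))
    present <- intersect(set, names(cc$row_clusters))
    if (length(present) == 0)
      stop(sprintf("no %s anchor genes present in the clustered matrix", nm))
    tab <- sort(table(cc$row_clusters[present]), decreasing = TRUE)
    if (length(tab) > 1 && tab[1] == tab[2])
      stop(sprintf("%s anchors split without a plurality; pass override=", nm))
    as.integer(names(tab)[1])
  }
  ci <- pick(anchors$immune, "immune")
  cf <- pick(anchors$caf, "caf")
  if (ci == cf)
    stop("immune and CAF anchors map to the same cluster; pass override=")
  ev <- do.call(rbind, lapply(c("immune", "caf"), function(nm) {
    present <- intersect(anchors[[nm]], names(cc$row_clusters))
    if (!length(present)) return(NULL)
    data.frame(anchor = present, set = nm,
               cluster = as.integer(cc$row_clusters[present]))
  }))
  structure(list(immune_genes = names(cc$row_clusters)[cc$row_clusters == ci],
                 caf_genes = names(cc$row_clusters)[cc$row_clusters == cf],
                 immune_cluster = ci, caf_cluster = cf,
                 anchor_evidence = ev),
            class = "tme_modules")
}

#' @export
print.tme_modules <- function(x, ...) {
  cat(sprintf("tme_modules: immune cluster %d (%d genes), CAF cluster %d (%d genes)\n",
              x$immune_cluster, length(x$immune_genes),
              x$caf_cluster, length(x$caf_genes)))
  invisible(x)
}

#' Per-sample signature score of a gene set
#'
#' Mean log expression of the set's genes per sample.
#'
#' @param expr an \code{\link{expr_matrix}} (or plain genes x samples matrix).
#' @param gene_set character vector of genes; at least one must be present.
#' @return named numeric vector over samples.
#' @export
compute_signature <- function(expr, gene_set) {
  v <- if (inherits(expr, "expr_matrix")) expr$values else expr
  present <- intersect(gene_set, rownames(v))
  if (length(present) == 0) stop("no gene of the set is present")
  colMeans(v[present, , drop = FALSE], na.rm = TRUE)
}
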