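# Rank-based screen for in-cis expression-methylation regulation. Trans
# effects (TME composition, global layers) correlate many loci with many
# genes; a promoter whose methylation ranks first among all promoters for its
# own gene's expression is unlikely to be explained by them. Significance is
# an empirical FDR: assuming independence, the FDR for diagonal rank <= k is
# k/m, with m the number of genes whose own promoter attains rank <= k.

#' Promoter cis-regulation screen
#'
#' Builds the square promoters x genes Pearson correlation matrix (pairwise
#' complete; cells under 50 paired samples removed), ranks each gene's
#' correlations over all promoters (ascending; rank 1 = strongest negative
#' correlation; ties broken by promoter id), and evaluates the rank of the
#' gene's own promoter with the empirical FDR(k) = k/m. A mirrored descending
#' pass screens positive (induction) correlations; both passes are returned,
#' labeled by sign.
#'
#' @param expr an \code{\link{expr_matrix}}.
#' @param meth a \code{\link{meth_matrix}} of promoter methylation.
#' @param pairing data.frame(gene, locus_id) mapping each screened gene to
#'   its resolved promoter locus; must be one-to-one.
#' @param exclude_genes genes to drop (immune / CAF module genes).
#' @param samples optional sample subset (e.g. one ER group).
#' @param params see \code{\link{epilayer_params}}.
#' @param directions which passes to run ("negative", "positive").
#' @return object of class "cis_screen": \code{results} data.frame(gene,
#'   locus_id, direction, r_cis, rank, n_support, fdr_at_rank), \code{fdr_table}
#'   (direction, k, m, fdr), \code{n_genes}.
#' @export
promoter_cis_screen <- function(expr, meth, pairing, exclude_genes = NULL,
                                samples = NULL, params = epilayer_params(),
                                directions = c("negative", "positive")) {
  pairing <- pairing[!pairing$gene %in% exclude_genes, , drop = FALSE]
  pairing <- pairing[pairing$gene %in% rownames(expr$values) &
                       pairing$locus_id %in% rownames(meth$values), , drop = FALSE]
  if (anyDuplicated(pairing$gene) || anyDuplicated(pairing$locus_id))
    stop("pairing must map genes and promoters one-to-one")
  if (nrow(pairing) == 0) stop("no screenable gene-promoter pairs")
  samp <- intersect(expr$samples, meth$samples)
  if (!is.null(samples)) samp <- intersect(samp, samples)

  ev <- expr$values[pairing$gene, samp, drop = FALSE]
  mv <- meth$values[pairing$locus_id, samp, drop = FALSE]
  pc <- pairwise_cor(mv, ev, min_n = params$min_corr_samples)  # promoters x genes
  r <- pc$r
  if (all(is.na(diag(r)))) stop("no gene has an observed cis correlation")

  one_pass <- function(direction) {
    n_gene <- ncol(r)
    diag_rank <- rep(NA_integer_, n_gene)
    for (j in seq_len(n_gene)) {
      col <- r[, j]
      obs <- which(!is.na(col))
      if (!(j %in% obs)) next
      v <- if (direction == "negative") col[obs] else -col[obs]
      o <- order(v, rownames(r)[obs])
      diag_rank[j] <- match(j, obs[o])
    }
    ok <- !is.na(diag_rank)
    m_of <- function(k) sum(diag_rank[ok] <= k)
    ks <- sort(unique(diag_rank[ok]))
    fdr_table <- data.frame(direction = direction, k = ks,
                            m = vapply(ks, m_of, integer(1)))
    fdr_table$fdr <- fdr_table$k / fdr_table$m
    res <- data.frame(gene = pairing$gene, locus_id = pairing$locus_id,
                      direction = direction,
                      r_cis = diag(r), rank = diag_rank,
                      n_support = diag(pc$n),
                      stringsAsFactors = FALSE)
    res$fdr_at_rank <- res$rank / vapply(res$rank, function(k)
      if (is.na(k)) NA_integer_ else m_of(k), integer(1))
    list(res = res, fdr_table = fdr_table)
  }

  passes <- lapply(directions, one_pass)
  structure(list(results = do.call(rbind, lapply(passes, `[[`, "res")),
                 fdr_table = do.call(rbind, lapply(passes, `[[`, "fdr_table")),
                 n_genes = nrow(pairing), samples = samp, params = params),
            class = "cis_screen")
}

#' Genes passing an FDR threshold in the promoter cis screen
#'
#' Finds the largest rank cutoff k with k/m <= \code{fdr}; genes whose own
#' promoter attains rank <= k are returned. \code{rank1 = TRUE} instead
#' returns genes whose own promoter is rank 1.
#'
#' @param screen a \code{"cis_screen"}.
#' @param fdr FDR ceiling (e.g. 0.05, 0.01, 0.005).
#' @param direction "negative" (repression) or "positive" (induction).
#' @param rank1 return only rank-1 hits.
#' @return character vector of genes (possibly empty).
#' @export
cis_hits <- function(screen, fdr = 0.05, direction = "negative", rank1 = FALSE) {
  res <- screen$results[screen$results$direction == direction, ]
  if (rank1) return(res$gene[!is.na(res$rank) & res$rank == 1L])
  ft <- screen$fdr_table[screen$fdr_table$direction == direction, ]
  ok <- ft$k[ft$fdr <= fdr]
  if (!length(ok)) return(character(0))
  kstar <- max(ok)
  res$gene[!is.na(res$rank) & res$rank <= kstar]
}

#' @export
print.cis_screen <- function(x, ...) {
  cat(sprintf("cis_screen: %d genes over %d samples\n",
              x$n_genes, length(x$samples)))
  for (d in unique(x$results$direction))
    cat(sprintf("  %s pass: %d hits at FDR<=0.05, %d at rank 1\n", d,
                length(cis_hits(x, 0.05, d)),
                length(cis_hits(x, direction = d, rank1 = TRUE))))
  invisible(x)
}

#' Distal element / gene pairing screen
#'
#' For each non-promoter locus (at least 2 kb from any promoter window when
#' windows are supplied), finds the gene with the maximal absolute expression
#' correlation; the locus is "paired" when that gene's TSS lies within 500 kb
#' on the same chromosome (midpoint-to-TSS distance; strand ignored). Sample
#' labels of the expression matrix are permuted \code{n_shuffles} times to
#' estimate the chance pairing rate; the pairing FDR is the ratio of mean
#' shuffled to real pairing counts.
#'
#' @param expr an \code{\link{expr_matrix}} with gene TSS coordinates.
#' @param meth a \code{\link{meth_matrix}} of non-promoter loci.
#' @param promoter_windows optional locus table; loci within 2 kb are dropped.
#' @param samples optional sample subset.
#' @param n_shuffles number of label permutations (>= 1).
#' @param seed RNG seed for the permutations.
#' @param params see \code{\link{epilayer_params}}.
#' @return object of class "distal_screen": \code{results} data.frame(locus_id,
#'   gene, r, distance, paired), \code{n_paired}, \code{shuffled_counts},
#'   \code{fdr}, \code{distance_summary} (fractions within 50 kb and
#'   50-500 kb among paired loci).
#' @export
distal_cis_screen <- function(expr, meth, promoter_windows = NULL,
                              samples = NULL, n_shuffles = 10L, seed = 1L,
                              params = epilayer_params()) {
  if (n_shuffles < 1) stop("n_shuffles must be at least 1")
  loci <- meth$loci[meth$loci$locus_class != "promoter", , drop = FALSE]
  if (!is.null(promoter_windows) && nrow(promoter_windows)) {
    gr <- loci_granges(loci)
    d <- as.data.frame(GenomicRanges::distanceToNearest(
      gr, loci_granges(promoter_windows), ignore.strand = TRUE))
    dist <- rep(Inf, nrow(loci)); dist[d$queryHits] <- d$distance
    loci <- loci[dist > params$enhancer_promoter_exclusion, , drop = FALSE]
  }
  if (nrow(loci) == 0) stop("no non-promoter loci to screen")
  samp <- intersect(expr$samples, meth$samples)
  if (!is.null(samples)) samp <- intersect(samp, samples)
  mv <- meth$values[loci$locus_id, samp, drop = FALSE]
  ev <- expr$values[, samp, drop = FALSE]
  gt <- expr$genes
  mid <- (loci$start + loci$end) / 2

  pair_count <- function(r) {
    best <- integer(nrow(r))
    for (i in seq_len(nrow(r))) {
      v <- abs(r[i, ])
      if (all(is.na(v))) { best[i] <- NA_integer_; next }
      o <- order(-v, colnames(r), na.last = TRUE)
      best[i] <- o[1]
    }
    bi <- best
    gene <- ifelse(is.na(bi), NA_character_, gt$gene[bi])
    dist <- ifelse(is.na(bi) | gt$chrom[bi] != loci$chrom,
                   NA_real_, abs(gt$tss[bi] - mid))
    paired <- !is.na(dist) & dist <= params$distal_window
    r_best <- r[cbind(seq_len(nrow(r)), ifelse(is.na(bi), 1L, bi))]
    r_best[is.na(bi)] <- NA_real_
    list(gene = gene, dist = dist, paired = paired, r_best = r_best)
  }

  real <- pair_count(pairwise_cor(mv, ev, min_n = params$min_corr_samples)$r)
  shuf_counts <- with_seed(seed, vapply(seq_len(n_shuffles), function(i) {
    perm <- sample(ncol(ev))
    ev_s <- ev[, perm, drop = FALSE]
    colnames(ev_s) <- colnames(ev)
    sum(pair_count(pairwise_cor(mv, ev_s, min_n = params$min_corr_samples)$r)$paired)
  }, numeric(1)))

  n_paired <- sum(real$paired)
  fdr <- if (n_paired > 0) mean(shuf_counts) / n_paired else NA_real_
  ds <- if (n_paired > 0) {
    dd <- real$dist[real$paired]
    c(within_50kb = mean(dd <= 50000), kb50_to_500 = mean(dd > 50000))
  } else c(within_50kb = NA_real_, kb50_to_500 = NA_real_)

  structure(list(results = data.frame(locus_id = loci$locus_id,
                                      gene = real$gene, r = real$r_best,
                                      distance = real$dist,
                                      paired = real$paired,
                                      stringsAsFactors = FALSE),
                 n_paired = n_paired, shuffled_counts = shuf_counts,
                 fdr = fdr, distance_summary = ds, samples = samp),
            class = "distal_screen")
}

#' @export
print.distal_screen <- function(x, ...) {
  cat(sprintf("distal_screen: %d loci, %d paired (shuffled mean %.1f, FDR %.3f)\n",
              nrow(x$results), x$n_paired, mean(x$shuffled_counts), x$fdr))
  invisible(x)
}

#' Epi-polymorphism of cis candidates versus background
#'
#' Compares epi-polymorphism of cis-candidate loci against background loci
#' within average-methylation strata (candidate epialleles are expected to be
#' more concentrated, i.e. less polymorphic). One-sided Wilcoxon rank-sum
#' (candidates lower) per stratum.
#'
#' @param cis_epipoly,cis_avg_meth epi-polymorphism and average methylation of
#'   cis-candidate fragments.
#' @param bg_epipoly,bg_avg_meth the same for background fragments.
#' @param strata_breaks stratum bounds on average methylation.
#' @return data.frame(stratum, n_cis, n_bg, statistic, p); empty strata are
#'   skipped.
#' @export
epiconvergence_report <- function(cis_epipoly, cis_avg_meth,
                                  bg_epipoly, bg_avg_meth,
                                  strata_breaks = c(0, 0.2, 0.5, 0.8, 1)) {
  cs <- cut(cis_avg_meth, strata_breaks, include.lowest = TRUE)
  bs <- cut(bg_avg_meth, strata_breaks, include.lowest = TRUE)
  do.call(rbind, lapply(levels(cs), function(sband) {
    a <- cis_epipoly[!is.na(cs) & cs == sband]
    b <- bg_epipoly[!is.na(bs) & bs == sband]
    if (length(a) == 0 || length(b) == 0) return(NULL)
    wt <- suppressWarnings(stats::wilcox.test(a, b, alternative = "less"))
    data.frame(stratum = sband, n_cis = length(a), n_bg = length(b),
               statistic = unname(wt$statistic), p = wt$p.value)
  }))
}
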