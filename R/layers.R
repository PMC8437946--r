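# Global methylation layers: after TME normalization, the dominant
# correlation structure among loci decomposes into three layers — a
# replication-timing-graded methylation-loss clock and two
# epigenomic-instability layers (gain at normally unmethylated loci, loss at
# partially methylated loci). Per-sample layer scores are mean normalized
# methylation over each layer's loci.

# locus x locus Pearson correlation computed in column blocks to bound the
# working-memory of any one crossprod; result is independent of block size.
cor_blockwise <- function(x, block = 2000L) {
  n <- nrow(x)
  out <- matrix(NA_real_, n, n, dimnames = list(rownames(x), rownames(x)))
  idx <- split(seq_len(n), ceiling(seq_len(n) / block))
  for (jj in idx) {
    out[, jj] <- pairwise_cor(x, x[jj, , drop = FALSE])$r
  }
  out
}

#' Fit the clock / MG / ML methylation layers
#'
#' Samples up to 50,000 eligible normalized methylation signatures (promoters
#' and non-promoters), computes their locus-locus correlation matrix, removes
#' loci without at least one absolute correlation above 0.25, clusters the
#' matrix (Euclidean distance, Ward "ward.D2") into three clusters, and
#' labels them: the cluster whose loci are most methylated in normal samples
#' (raw values) is the loss clock, the least methylated is the gain layer
#' (MG), the intermediate one the loss layer (ML). When replication-timing
#' values are present the clock labeling is cross-checked for late-replication
#' enrichment (a warning is raised if absent). Per-sample scores are the mean
#' normalized methylation over each layer's loci; loss layers therefore
#' anti-correlate with the underlying loss process.
#'
#' Eligibility default follows normalized values (|mean normalized
#' methylation| < 0.1); \code{eligibility = "raw"} instead requires raw mean
#' methylation < 0.1.
#'
#' @param norm a \code{"normalized_meth"} from \code{\link{knn_normalize}}
#'   (ER+ tumors in the reference analysis).
#' @param raw the matching raw \code{\link{meth_matrix}} (used for labeling).
#' @param metadata \code{\link{sample_metadata}}; normal samples in \code{raw}
#'   drive the labeling. Absent normals trigger a warning and a tumor-mean
#'   fallback.
#' @param params see \code{\link{epilayer_params}}.
#' @param seed RNG seed for the locus subsample.
#' @return object of class "layer_model": \code{loci} (data.frame locus_id /
#'   layer / cor: correlation of the locus with its layer score),
#'   \code{scores} (samples x clock/mg/ml), \code{layer_sets} (thresholded
#'   locus sets: cor > 0.6 for clock, > 0.5 for MG/ML), \code{labeling}
#'   (evidence table), \code{sampled} ids.
#' @export
fit_layers <- function(norm, raw, metadata, params = epilayer_params(),
                       seed = params$rng_seed) {
  thr <- params$meth_mean_bounds[1]   # 0.1 on either scale
  if (params$layer_eligibility == "raw") {
    rm_ <- rowMeans(raw$values[rownames(norm$values), norm$samples, drop = FALSE],
                    na.rm = TRUE)
    elig <- !is.na(rm_) & rm_ < thr
  } else {
    nm <- rowMeans(norm$values, na.rm = TRUE)
    elig <- !is.na(nm) & abs(nm) < thr
  }
  ids <- rownames(norm$values)[elig]
  if (length(ids) > params$layer_sample_size)
    ids <- with_seed(seed, sample(ids, params$layer_sample_size))
  ids <- ids[order(match(ids, rownames(norm$values)))]
  x <- norm$values[ids, , drop = FALSE]

  C <- cor_blockwise(x)
  diag(C) <- NA_real_
  has_partner <- apply(C, 1, function(v) any(abs(v) > params$corr_floor, na.rm = TRUE))
  keep <- ids[has_partner]
  if (length(keep) < params$n_layer_clusters)
    stop("too few correlated loci to form the layer clusters")
  C <- C[keep, keep, drop = FALSE]
  diag(C) <- 1

  cl <- ward_cluster_rows(C, params$n_layer_clusters)

  # label clusters by raw methylation level in normals
  normals <- intersect(samples_in_group(metadata, "normal"), raw$samples)
  ref_samples <- normals
  if (length(normals) == 0) {
    warning("no normal samples; labeling layers by tumor raw methylation")
    ref_samples <- norm$samples
  }
  rawv <- raw$values[keep, ref_samples, drop = FALSE]
  lev <- vapply(sort(unique(cl)), function(k)
    mean(rawv[cl == k, , drop = FALSE], na.rm = TRUE), numeric(1))
  ord <- order(lev)  # low -> MG, mid -> ML, high -> clock
  lab <- character(length(lev))
  lab[ord[1]] <- "mg"
  lab[ord[length(ord)]] <- "clock"
  if (length(ord) > 2) lab[ord[seq(2, length(ord) - 1)]] <- "ml"
  layer <- lab[cl]
  names(layer) <- keep

  # TOR cross-check: clock loci should be late-replicating-enriched
  tor <- raw$loci$tor_value[match(keep, raw$loci$locus_id)]
  tor_note <- NA_real_
  if (any(!is.na(tor))) {
    ck <- layer == "clock"
    if (sum(ck) > 1 && sum(!ck) > 1 &&
        any(!is.na(tor[ck])) && any(!is.na(tor[!ck]))) {
      tor_note <- stats::median(tor[ck], na.rm = TRUE) -
        stats::median(tor[!ck], na.rm = TRUE)
      if (tor_note > 0)
        warning("clock cluster is not late-replication enriched; check labeling")
    }
  }

  score_of <- function(set) colMeans(x[set, , drop = FALSE], na.rm = TRUE)
  scores <- sapply(c("clock", "ml", "mg"), function(L)
    score_of(keep[layer == L]))
  scores <- scores[, c("clock", "mg", "ml"), drop = FALSE]

  locus_cor <- vapply(seq_along(keep), function(i)
    suppressWarnings(stats::cor(x[keep[i], ], scores[, layer[i]],
                                use = "pairwise.complete.obs")), numeric(1))
  loci_df <- data.frame(locus_id = keep, layer = unname(layer),
                        cor = locus_cor, stringsAsFactors = FALSE)
  thr_set <- params$layer_link_threshold
  layer_sets <- list(
    clock = loci_df$locus_id[loci_df$layer == "clock" & !is.na(loci_df$cor) &
                               loci_df$cor > thr_set[["clock"]]],
    mg = loci_df$locus_id[loci_df$layer == "mg" & !is.na(loci_df$cor) &
                            loci_df$cor > thr_set[["mg_ml"]]],
    ml = loci_df$locus_id[loci_df$layer == "ml" & !is.na(loci_df$cor) &
                            loci_df$cor > thr_set[["mg_ml"]]])

  structure(list(loci = loci_df, scores = scores, layer_sets = layer_sets,
                 sampled = ids, clusters = cl,
                 labeling = data.frame(cluster = sort(unique(cl)),
                                       normal_raw_mean = lev, layer = lab),
                 tor_median_shift = tor_note,
                 params = params, samples = norm$samples),
            class = "layer_model")
}

#' @export
print.layer_model <- function(x, ...) {
  tab <- table(x$loci$layer)
  cat(sprintf("layer_model: %d correlated loci over %d samples\n",
              nrow(x$loci), length(x$samples)))
  for (L in c("clock", "mg", "ml"))
    cat(sprintf("  %-5s %4d loci (%d above link threshold)\n",
                L, if (L %in% names(tab)) tab[[L]] else 0L,
                length(x$layer_sets[[L]])))
  invisible(x)
}

#' Project layer scores onto another sample group
#'
#' Scores (mean normalized methylation over the layer's loci) are computed on
#' a second group's normalized matrix; a layer's score is reported only when
#' at least half of its loci are covered there.
#'
#' @param model a \code{"layer_model"}.
#' @param norm_other a \code{"normalized_meth"} for the other group.
#' @param min_coverage minimum fraction of layer loci present (default 0.5).
#' @return samples x (clock, mg, ml) matrix (all-NA column when coverage is
#'   insufficient).
#' @export
project_scores <- function(model, norm_other, min_coverage = 0.5) {
  out <- sapply(c("clock", "mg", "ml"), function(L) {
    set <- model$loci$locus_id[model$loci$layer == L]
    present <- intersect(set, rownames(norm_other$values))
    if (length(present) < min_coverage * length(set)) {
      warning(sprintf("layer %s: only %d/%d loci covered; score missing",
                      L, length(present), length(set)))
      return(rep(NA_real_, ncol(norm_other$values)))
    }
    colMeans(norm_other$values[present, , drop = FALSE], na.rm = TRUE)
  })
  rownames(out) <- norm_other$samples
  out
}

#' Annotate the fitted layers
#'
#' For each layer: time-of-replication three-bin composition and a two-sample
#' KS test of TOR values against the non-layer background; KS tests of CpG
#' content and TSS distance against background; and, per normal-methylation
#' stratum, the fraction of enhancer loci whose normalized methylation
#' correlates above 0.25 with the layer score.
#'
#' @param model a \code{"layer_model"}.
#' @param meth raw \code{\link{meth_matrix}} carrying locus annotation
#'   (tor_value, cpg_content) and enhancer loci.
#' @param norm the \code{"normalized_meth"} the model was fitted on (for
#'   enhancer linkage correlations).
#' @param metadata \code{\link{sample_metadata}} (normals define the
#'   normal-methylation strata of enhancers).
#' @param gene_tab optional data.frame(gene, chrom, tss) for TSS distances.
#' @param normal_meth_breaks strata bounds on normal enhancer methylation.
#' @param params see \code{\link{epilayer_params}}.
#' @return list of class "layer_annotation": \code{tor} (per-layer bin
#'   composition + KS), \code{cpg}, \code{tss_distance}, \code{enhancers}
#'   (layer x stratum linked fraction). Sections with missing annotation are
#'   skipped (NULL).
#' @export
annotate_layer <- function(model, meth, norm, metadata = NULL,
                           gene_tab = NULL,
                           normal_meth_breaks = c(0, 0.2, 0.6, 1),
                           params = epilayer_params()) {
  ann <- meth$loci[match(model$loci$locus_id, meth$loci$locus_id), ]
  layer <- model$loci$layer
  out <- list()

  ks_by_layer <- function(v) {
    do.call(rbind, lapply(c("clock", "mg", "ml"), function(L) {
      a <- v[layer == L]; b <- v[layer != L]
      a <- a[!is.na(a)]; b <- b[!is.na(b)]
      if (length(a) < 2 || length(b) < 2) return(NULL)
      ks <- suppressWarnings(stats::ks.test(a, b))
      data.frame(layer = L, n = length(a), statistic = unname(ks$statistic),
                 p = ks$p.value)
    }))
  }

  if (any(!is.na(ann$tor_value))) {
    bins <- bin_time_of_replication(meth$loci$tor_value, params)
    comp <- do.call(rbind, lapply(c("clock", "mg", "ml"), function(L) {
      b <- bins$bin3[match(model$loci$locus_id[layer == L], meth$loci$locus_id)]
      tab <- table(factor(b, levels = c("late", "intermediate", "early")))
      data.frame(layer = L, bin = names(tab),
                 fraction = as.numeric(tab) / max(sum(tab), 1))
    }))
    out$tor <- list(composition = comp,
                    background_late = mean(bins$bin3 == "late", na.rm = TRUE),
                    ks = ks_by_layer(ann$tor_value))
  }
  if (any(!is.na(ann$cpg_content))) out$cpg <- ks_by_layer(ann$cpg_content)

  if (!is.null(gene_tab)) {
    mid <- (ann$start + ann$end) / 2
    tssd <- vapply(seq_len(nrow(ann)), function(i) {
      on_chr <- gene_tab$tss[gene_tab$chrom == ann$chrom[i]]
      if (!length(on_chr)) return(NA_real_)
      min(abs(on_chr - mid[i]))
    }, numeric(1))
    out$tss_distance <- ks_by_layer(tssd)
  }

  enh_ids <- meth$loci$locus_id[meth$loci$locus_class == "enhancer"]
  enh_ids <- intersect(enh_ids, rownames(norm$values))
  if (length(enh_ids)) {
    normals <- if (!is.null(metadata))
      intersect(samples_in_group(metadata, "normal"), meth$samples) else character(0)
    nm <- if (length(normals))
      rowMeans(meth$values[enh_ids, normals, drop = FALSE], na.rm = TRUE)
    else rowMeans(meth$values[enh_ids, , drop = FALSE], na.rm = TRUE)
    stratum <- cut(nm, normal_meth_breaks, include.lowest = TRUE)
    r <- suppressWarnings(stats::cor(t(norm$values[enh_ids, , drop = FALSE]),
                                     model$scores, use = "pairwise.complete.obs"))
    linked <- !is.na(r) & r > params$layer_link_threshold[["enhancer"]]
    out$enhancers <- do.call(rbind, lapply(colnames(model$scores), function(L) {
      data.frame(layer = L, stratum = levels(stratum),
                 n = as.integer(table(stratum)),
                 linked_fraction = vapply(levels(stratum), function(sband) {
                   i <- !is.na(stratum) & stratum == sband
                   if (!any(i)) return(NA_real_)
                   mean(linked[i, L])
                 }, numeric(1)))
    }))
  }
  structure(out, class = "layer_annotation")
}
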