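# Integration of the methylation scores with genetic features: mutation and
# copy-number association (Wilcoxon / Spearman with BH correction and
# quintile stratification), copy-number dosage-compensation calls (KS tests
# per CN contrast), and mutant-allele tumor heterogeneity (MATH).

#' Associate epigenomic scores with genetic features
#'
#' Binary features (mutation flags, CNA gain/loss flags) are tested per score
#' with a two-sided Wilcoxon rank-sum of the score in carriers versus
#' non-carriers; continuous features (CIN, MATH) with Spearman correlation.
#' q-values are Benjamini-Hochberg over all feature x score tests. For
#' visualization, samples are also grouped into five sample-count-balanced
#' score quintiles and the feature frequency per stratum is reported.
#'
#' @param scores samples x scores numeric matrix (e.g. the score columns of
#'   \code{\link{signature_table}}).
#' @param features features x samples matrix (binary 0/1 or continuous).
#' @param min_group_size minimum samples per compared group for binary
#'   features (default 20); smaller or degenerate features are skipped.
#' @param n_strata number of score quantile strata (default 5).
#' @return list of class "score_associations": \code{associations}
#'   data.frame(feature, score, type, statistic, estimate, p, q),
#'   \code{strata} data.frame(feature, score, stratum, n, frequency).
#' @export
associate_scores <- function(scores, features, min_group_size = 20L,
                             n_strata = 5L) {
  scores <- as.matrix(scores)
  features <- as.matrix(features)
  samp <- intersect(rownames(scores), colnames(features))
  if (length(samp) == 0) stop("no shared samples between scores and features")
  scores <- scores[samp, , drop = FALSE]
  features <- features[, samp, drop = FALSE]

  rows <- list(); strat <- list()
  for (f in rownames(features)) {
    fv <- features[f, ]
    vals <- unique(fv[!is.na(fv)])
    if (length(vals) < 2) next  # degenerate feature
    binary <- length(vals) == 2 && all(vals %in% c(0, 1))
    for (s in colnames(scores)) {
      sv <- scores[, s]
      ok <- !is.na(fv) & !is.na(sv)
      if (binary) {
        n1 <- sum(fv[ok] == 1); n0 <- sum(fv[ok] == 0)
        if (min(n1, n0) < min_group_size) next
        wt <- suppressWarnings(stats::wilcox.test(sv[ok & fv == 1],
                                                  sv[ok & fv == 0]))
        est <- stats::median(sv[ok & fv == 1]) - stats::median(sv[ok & fv == 0])
        rows[[length(rows) + 1L]] <- data.frame(
          feature = f, score = s, type = "binary",
          statistic = unname(wt$statistic), estimate = est, p = wt$p.value)
        q <- cut(rank(sv[ok], ties.method = "first"),
                 breaks = n_strata, labels = FALSE)
        strat[[length(strat) + 1L]] <- data.frame(
          feature = f, score = s, stratum = seq_len(n_strata),
          n = as.integer(table(factor(q, levels = seq_len(n_strata)))),
          frequency = vapply(seq_len(n_strata), function(b)
            mean(fv[ok][q == b]), numeric(1)))
      } else {
        if (sum(ok) < 2 * min_group_size) next
        ct <- suppressWarnings(stats::cor.test(fv[ok], sv[ok],
                                               method = "spearman"))
        rows[[length(rows) + 1L]] <- data.frame(
          feature = f, score = s, type = "continuous",
          statistic = unname(ct$statistic), estimate = unname(ct$estimate),
          p = ct$p.value)
      }
    }
  }
  if (!length(rows)) stop("no testable feature/score pair")
  assoc <- do.call(rbind, rows)
  assoc$q <- stats::p.adjust(assoc$p, method = "BH")
  structure(list(associations = assoc,
                 strata = if (length(strat)) do.call(rbind, strat) else NULL),
            class = "score_associations")
}

#' @export
print.score_associations <- function(x, ...) {
  a <- x$associations
  cat(sprintf("score_associations: %d tests, %d with q < 0.05\n",
              nrow(a), sum(a$q < 0.05)))
  invisible(x)
}

#' Copy-number dosage-compensation analysis
#'
#' For each gene and each copy-number contrast against the diploid state
#' (1N vs 2N, 3N vs 2N, 4N vs 2N) with at least \code{min_stratum} samples in
#' both strata, promoter methylation and expression are compared between the
#' strata with two-sample Kolmogorov-Smirnov tests. A gene-contrast is called
#' compensated when methylation shifts in the compensating direction (up on
#' gain, down on loss) at BH q < 0.05 while the expression difference is not
#' significant at 0.05 (i.e. expression does not scale with copy number). The
#' X chromosome and autosomes share this code path; X differs only by
#' annotation.
#'
#' @param meth genes x samples promoter-methylation matrix.
#' @param expr genes x samples log-expression matrix.
#' @param cn_states genes x samples integer copy-number states (1-4).
#' @param min_stratum minimum samples per CN stratum (default 10).
#' @return data.frame of class "dosage_result": gene, contrast, n_alt, n_ref,
#'   meth_shift, meth_stat, meth_p, meth_q, expr_shift, expr_p, expr_scaling,
#'   compensated.
#' @export
dosage_compensation <- function(meth, expr, cn_states, min_stratum = 10L) {
  genes <- intersect(intersect(rownames(meth), rownames(expr)),
                     rownames(cn_states))
  samp <- intersect(intersect(colnames(meth), colnames(expr)),
                    colnames(cn_states))
  rows <- list()
  for (g in genes) {
    cn <- cn_states[g, samp]
    mv <- meth[g, samp]; ev <- expr[g, samp]
    ref <- !is.na(cn) & cn == 2L
    for (alt_cn in c(1L, 3L, 4L)) {
      alt <- !is.na(cn) & cn == alt_cn
      if (sum(alt & !is.na(mv)) < min_stratum ||
          sum(ref & !is.na(mv)) < min_stratum) next
      ksm <- suppressWarnings(stats::ks.test(mv[alt], mv[ref]))
      kse <- suppressWarnings(stats::ks.test(ev[alt], ev[ref]))
      rows[[length(rows) + 1L]] <- data.frame(
        gene = g, contrast = sprintf("%dN_vs_2N", alt_cn),
        n_alt = sum(alt), n_ref = sum(ref),
        meth_shift = mean(mv[alt], na.rm = TRUE) - mean(mv[ref], na.rm = TRUE),
        meth_stat = unname(ksm$statistic), meth_p = ksm$p.value,
        expr_shift = mean(ev[alt], na.rm = TRUE) - mean(ev[ref], na.rm = TRUE),
        expr_p = kse$p.value, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    out <- data.frame(gene = character(0), contrast = character(0))
    class(out) <- c("dosage_result", "data.frame")
    return(out)
  }
  out <- do.call(rbind, rows)
  out$meth_q <- stats::p.adjust(out$meth_p, method = "BH")
  gain <- grepl("^[34]N", out$contrast)
  compensating_dir <- ifelse(gain, out$meth_shift > 0, out$meth_shift < 0)
  out$expr_scaling <- out$expr_p < 0.05 &
    ifelse(gain, out$expr_shift > 0, out$expr_shift < 0)
  out$compensated <- compensating_dir & out$meth_q < 0.05 & out$expr_p >= 0.05
  class(out) <- c("dosage_result", "data.frame")
  out
}

#' Mutant-allele tumor heterogeneity (MATH) score
#'
#' 100 times the median absolute deviation (with the 1.4826 consistency
#' constant) of the tumor's mutation variant-allele frequencies, divided by
#' their median. Higher values indicate greater genetic intra-tumor
#' heterogeneity. Requires at least two VAFs in (0, 1].
#'
#' @param vafs numeric variant-allele frequencies; NAs dropped.
#' @return numeric score, or NA when fewer than two usable VAFs.
#' @examples
#' math_score(c(0.2, 0.3, 0.4))  # 49.42
#' @export
math_score <- function(vafs) {
  v <- vafs[!is.na(vafs)]
  v <- v[v > 0 & v <= 1]
  if (length(v) < 2) return(NA_real_)
  100 * stats::mad(v) / stats::median(v)
}
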