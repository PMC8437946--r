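#' Construct a locus table
#'
#' Loci are genomic intervals carrying methylation measurements. Coordinates
#' are 0-based half-open throughout the package (BED convention); 1-based
#' inputs must be converted on read (see \code{\link{read_meth_matrix}}).
#'
#' @param chrom chromosome names.
#' @param start,end 0-based half-open interval bounds; \code{start < end}.
#' @param strand "+", "-" or "*" (unknown).
#' @param locus_class one of "promoter", "fragment", "enhancer".
#' @param cpg_content fraction of dinucleotides that are CpG, in [0,1]; NA ok.
#' @param tor_value replication-timing signal (arbitrary units; larger =
#'   earlier-replicating); NA ok.
#' @param locus_id unique id; defaults to "chrom:start-end".
#' @return data.frame with one row per locus.
#' @export
locus_table <- function(chrom, start, end, strand = "*",
                        locus_class = "fragment",
                        cpg_content = NA_real_, tor_value = NA_real_,
                        locus_id = NULL) {
  start <- as.integer(start); end <- as.integer(end)
  n <- length(start)
  strand <- rep_len(strand, n)
  locus_class <- rep_len(locus_class, n)
  cpg_content <- rep_len(cpg_content, n)
  tor_value <- rep_len(tor_value, n)
  if (any(start >= end)) stop("locus start must be < end (0-based half-open)")
  if (!all(locus_class %in% c("promoter", "fragment", "enhancer")))
    stop("locus_class must be promoter, fragment or enhancer")
  if (any(!is.na(cpg_content) & (cpg_content < 0 | cpg_content > 1)))
    stop("cpg_content must lie in [0,1]")
  if (is.null(locus_id)) locus_id <- sprintf("%s:%d-%d", chrom, start, end)
  if (anyDuplicated(locus_id)) stop("locus ids must be unique")
  data.frame(locus_id = locus_id, chrom = as.character(chrom),
             start = start, end = end, strand = strand,
             locus_class = locus_class, cpg_content = cpg_content,
             tor_value = tor_value, stringsAsFactors = FALSE)
}

loci_granges <- function(loci) {
  GenomicRanges::GRanges(
    seqnames = loci$chrom,
    ranges = IRanges::IRanges(start = loci$start + 1L, end = loci$end),
    strand = ifelse(loci$strand %in% c("+", "-"), loci$strand, "*")
  )
}

#' Construct a methylation matrix
#'
#' @param values numeric matrix, loci x samples, entries in [0,1] or NA.
#' @param loci locus table (\code{\link{locus_table}}) matching the rows.
#' @param coverage optional read-count matrix of the same shape.
#' @return list with class \code{"meth_matrix"}: \code{$loci}, \code{$samples},
#'   \code{$values}, \code{$coverage}.
#' @export
meth_matrix <- function(values, loci, coverage = NULL) {
  values <- as.matrix(values)
  if (nrow(values) != nrow(loci)) stop("values rows must match loci rows")
  if (is.null(colnames(values))) stop("values must carry sample names")
  if (anyDuplicated(colnames(values))) stop("sample ids must be unique")
  v <- values[!is.na(values)]
  if (length(v) && (min(v) < 0 || max(v) > 1))
    stop("methylation values must lie in [0,1]")
  rownames(values) <- loci$locus_id
  if (!is.null(coverage)) {
    coverage <- as.matrix(coverage)
    stopifnot(all(dim(coverage) == dim(values)))
    dimnames(coverage) <- dimnames(values)
  }
  structure(list(loci = loci, samples = colnames(values),
                 values = values, coverage = coverage),
            class = "meth_matrix")
}

#' Construct an expression matrix
#'
#' @param values numeric matrix, genes x samples, log-scale expression.
#' @param genes data.frame with columns \code{gene}, \code{chrom}, \code{tss}
#'   (0-based position), \code{strand}.
#' @return list with class \code{"expr_matrix"}.
#' @export
expr_matrix <- function(values, genes) {
  values <- as.matrix(values)
  if (nrow(values) != nrow(genes)) stop("values rows must match genes rows")
  if (anyDuplicated(genes$gene)) stop("gene ids must be unique")
  if (is.null(colnames(values))) stop("values must carry sample names")
  if (anyDuplicated(colnames(values))) stop("sample ids must be unique")
  rownames(values) <- genes$gene
  structure(list(genes = genes, samples = colnames(values), values = values),
            class = "expr_matrix")
}

#' @export
print.meth_matrix <- function(x, ...) {
  cat(sprintf("meth_matrix: %d loci x %d samples (%s)\n",
              nrow(x$values), ncol(x$values),
              paste(sprintf("%d %s", table(x$loci$locus_class),
                            names(table(x$loci$locus_class))), collapse = ", ")))
  invisible(x)
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d genes x %d samples (log scale)\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Sample metadata table
#'
#' @param sample sample ids (unique).
#' @param group one of "ER+", "ER-", "normal" per sample.
#' @param grade optional ordinal tumor grade.
#' @param CIN optional fraction of the genome affected by copy-number
#'   aberrations, in [0,1].
#' @return data.frame with class c("sample_metadata","data.frame").
#' @export
sample_metadata <- function(sample, group, grade = NA, CIN = NA_real_) {
  if (anyDuplicated(sample)) stop("sample ids must be unique")
  if (!all(group %in% c("ER+", "ER-", "normal")))
    stop('group must be one of "ER+", "ER-", "normal"')
  if (any(!is.na(CIN) & (CIN < 0 | CIN > 1))) stop("CIN must lie in [0,1]")
  structure(data.frame(sample = sample, group = group, grade = grade,
                       CIN = CIN, stringsAsFactors = FALSE),
            class = c("sample_metadata", "data.frame"))
}

samples_in_group <- function(metadata, group) {
  if (is.null(group)) return(metadata$sample)
  metadata$sample[metadata$group %in% group]
}

## ---- promoter windows and resolution -------------------------------------

#' Promoter window around a TSS
#'
#' The promoter is 500 bp upstream and 50 bp downstream of the TSS,
#' strand-aware, clipped at the chromosome start: plus strand gives
#' [tss-500, tss+50), minus strand [tss-50, tss+500).
#'
#' @param tss_position 0-based TSS coordinate(s).
#' @param strand "+" or "-" (vectorized); unknown strand is an error.
#' @param chrom chromosome name(s).
#' @param params see \code{\link{epilayer_params}}.
#' @return locus table of class "promoter" windows.
#' @export
make_promoter_window <- function(tss_position, strand, chrom = "chr1",
                                 params = epilayer_params()) {
  if (any(!strand %in% c("+", "-")))
    stop("promoter windows require a known strand")
  up <- params$promoter_upstream; dn <- params$promoter_downstream
  start <- ifelse(strand == "+", tss_position - up, tss_position - dn)
  end <- ifelse(strand == "+", tss_position + dn, tss_position + up)
  start <- pmax(start, 0L)
  locus_table(chrom = rep_len(chrom, length(start)), start = start, end = end,
              strand = strand, locus_class = "promoter")
}

#' Resolve alternative promoters for a gene
#'
#' When a gene has several annotated promoters, the one with the minimal
#' average methylation over normal samples is used; ties are broken by the
#' 5'-most genomic coordinate (smallest start, then smallest end, then id) so
#' the choice is deterministic.
#'
#' @param gene gene id (informational).
#' @param candidate_promoters locus table of candidate promoter windows.
#' @param normal_methylation numeric matrix, candidates x normal samples
#'   (rows aligned with \code{candidate_promoters}).
#' @return one-row locus table (the chosen promoter), or NULL with a warning
#'   when no candidate is covered in normals (gene is unresolved and excluded
#'   downstream).
#' @export
resolve_promoter <- function(gene, candidate_promoters, normal_methylation) {
  normal_methylation <- as.matrix(normal_methylation)
  stopifnot(nrow(normal_methylation) == nrow(candidate_promoters))
  m <- rowMeans(normal_methylation, na.rm = TRUE)
  m[is.nan(m)] <- NA_real_
  if (all(is.na(m))) {
    warning(sprintf("gene %s: no candidate promoter covered in normals; unresolved", gene))
    return(NULL)
  }
  ord <- order(m, candidate_promoters$start, candidate_promoters$end,
               candidate_promoters$locus_id, na.last = TRUE)
  candidate_promoters[ord[1L], , drop = FALSE]
}

## ---- aggregation ----------------------------------------------------------

#' Aggregate per-CpG calls into a locus methylation fraction
#'
#' Default is the read-pooled ratio sum(methylated)/sum(total) over all CpGs
#' in the locus (coverage-weighted); \code{weighted = FALSE} switches to the
#' unweighted mean of per-CpG fractions.
#'
#' @param meth_calls methylated read counts per CpG.
#' @param total_calls total read counts per CpG.
#' @param weighted pool reads (default) or average per-CpG fractions.
#' @return methylation fraction in [0,1], or NA when no CpG is covered.
#' @export
aggregate_methylation <- function(meth_calls, total_calls, weighted = TRUE) {
  stopifnot(length(meth_calls) == length(total_calls))
  keep <- !is.na(meth_calls) & !is.na(total_calls) & total_calls > 0
  if (!any(keep)) return(NA_real_)
  if (weighted) {
    sum(meth_calls[keep]) / sum(total_calls[keep])
  } else {
    mean(meth_calls[keep] / total_calls[keep])
  }
}

#' Drop restriction fragments overlapping promoters or exons
#'
#' Non-promoter methylation is averaged per MspI restriction fragment;
#' fragments with any overlap to a promoter window (or, when provided, an
#' exon) are excluded before aggregation.
#'
#' @param fragments locus table of fragments.
#' @param promoter_windows locus table of promoter windows.
#' @param exons optional locus-like data.frame (chrom/start/end).
#' @return the retained subset of \code{fragments}.
#' @export
exclude_overlapping_fragments <- function(fragments, promoter_windows,
                                          exons = NULL) {
  gr <- loci_granges(fragments)
  drop <- rep(FALSE, nrow(fragments))
  if (nrow(promoter_windows) > 0) {
    hits <- GenomicRanges::findOverlaps(gr, loci_granges(promoter_windows),
                                        ignore.strand = TRUE)
    drop[unique(S4Vectors_queryHits(hits))] <- TRUE
  }
  if (!is.null(exons) && nrow(exons) > 0) {
    egr <- GenomicRanges::GRanges(exons$chrom,
             IRanges::IRanges(exons$start + 1L, exons$end))
    hits <- GenomicRanges::findOverlaps(gr, egr, ignore.strand = TRUE)
    drop[unique(S4Vectors_queryHits(hits))] <- TRUE
  }
  fragments[!drop, , drop = FALSE]
}

# queryHits without importing S4Vectors directly
S4Vectors_queryHits <- function(hits) {
  as.data.frame(hits)$queryHits
}

## ---- enhancer calling -----------------------------------------------------

#' Call putative enhancers from H3K4me1 coverage
#'
#' Intervals at the top 3% of the coverage distribution (ties at the
#' threshold retained), excluding intervals within 2 kb of any promoter
#' window, homogenized to 200 bp by centering (100 bp each side of the
#' interval midpoint).
#'
#' @param h3k4me1_coverage data.frame with chrom, start, end, coverage.
#' @param promoter_windows locus table of promoter windows.
#' @param params see \code{\link{epilayer_params}}.
#' @return locus table of enhancers (possibly empty).
#' @export
call_enhancers <- function(h3k4me1_coverage, promoter_windows,
                           params = epilayer_params()) {
  cov <- h3k4me1_coverage
  if (is.null(cov) || nrow(cov) == 0)
    return(locus_table(character(0), integer(0), integer(0))[0, ])
  thr <- stats::quantile(cov$coverage, 1 - params$enhancer_top_quantile,
                         names = FALSE, type = 7)
  top <- cov[cov$coverage >= thr, , drop = FALSE]
  if (nrow(top) == 0) return(locus_table(character(0), integer(0), integer(0))[0, ])
  gr <- GenomicRanges::GRanges(top$chrom,
          IRanges::IRanges(top$start + 1L, top$end))
  if (nrow(promoter_windows) > 0) {
    pgr <- loci_granges(promoter_windows)
    d <- GenomicRanges::distanceToNearest(gr, pgr, ignore.strand = TRUE)
    dist <- rep(Inf, nrow(top))
    dd <- as.data.frame(d)
    dist[dd$queryHits] <- dd$distance
    top <- top[dist > params$enhancer_promoter_exclusion, , drop = FALSE]
  }
  if (nrow(top) == 0) return(locus_table(character(0), integer(0), integer(0))[0, ])
  half <- params$enhancer_width %/% 2L
  mid <- (top$start + top$end) %/% 2L
  locus_table(chrom = top$chrom, start = pmax(mid - half, 0L),
              end = pmax(mid - half, 0L) + params$enhancer_width,
              locus_class = "enhancer")
}

## ---- time of replication --------------------------------------------------

#' Bin loci by time of replication
#'
#' Two labelings of the replication-timing signal (larger value = earlier):
#' a median split ("late"/"early"; values at the median count as late) and a
#' three-way split at the 20th and 60th percentiles ("late" at or below the
#' 20th, "intermediate" up to the 60th, "early" above).
#'
#' @param tor_values numeric replication-timing signal per locus; NA allowed.
#' @param params see \code{\link{epilayer_params}}.
#' @return data.frame with columns \code{bin2} and \code{bin3} (character,
#'   NA where tor is missing). All-missing input gives all-NA bins.
#' @export
bin_time_of_replication <- function(tor_values, params = epilayer_params()) {
  bin2 <- bin3 <- rep(NA_character_, length(tor_values))
  ok <- !is.na(tor_values)
  if (any(ok)) {
    med <- stats::median(tor_values[ok])
    bin2[ok] <- ifelse(tor_values[ok] <= med, "late", "early")
    q <- stats::quantile(tor_values[ok], params$tor_bins, names = FALSE)
    bin3[ok] <- ifelse(tor_values[ok] <= q[1], "late",
                       ifelse(tor_values[ok] <= q[2], "intermediate", "early"))
  }
  data.frame(bin2 = bin2, bin3 = bin3, stringsAsFactors = FALSE)
}

#' Flag active promoters
#'
#' A promoter is active when its gene's log expression exceeds the threshold
#' (default 7) in at least one sample. Used for coverage reporting only, not
#' as a global gate.
#'
#' @param expr an \code{\link{expr_matrix}}.
#' @param params see \code{\link{epilayer_params}}.
#' @return named logical vector over genes.
#' @export
active_promoters <- function(expr, params = epilayer_params()) {
  apply(expr$values, 1, function(v)
    any(!is.na(v) & v > params$active_promoter_expr_threshold))
}
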