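# TSV input/output. All tables are gzip-transparent (R connections), the
# missing-value token is "NA", and numeric values are written with "%.17g"
# so write-then-read round-trips bit-exactly. Lines starting with "#" are
# run headers (tool version, config hash, seed) and are skipped on read.

fmt_num <- function(x) {
  out <- ifelse(is.na(x), "NA", sprintf("%.17g", x))
  out
}

write_tsv_with_header <- function(df, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  is_num <- vapply(df, is.numeric, logical(1)) &
    !vapply(df, is.integer, logical(1))
  df[is_num] <- lapply(df[is_num], fmt_num)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

read_tsv_skip_header <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                    check.names = FALSE, na.strings = "NA")
}

run_header <- function(seed = NULL, config_hash = NULL) {
  h <- sprintf("epilayers %s", as.character(utils::packageVersion("epilayers")))
  if (!is.null(config_hash)) h <- c(h, sprintf("config_hash: %s", config_hash))
  if (!is.null(seed)) h <- c(h, sprintf("seed: %d", as.integer(seed)))
  h
}

#' Write / read a methylation matrix as TSV
#'
#' Columns: locus_id, chrom, start, end, strand, locus_class, cpg_content,
#' tor_value, then one column per sample. Coordinates on disk are 0-based
#' half-open (BED-style).
#'
#' @param x a \code{\link{meth_matrix}}.
#' @param path file path (".gz" suffix is handled transparently).
#' @param header optional character vector of run-header lines.
#' @return the path (write) / a \code{meth_matrix} (read).
#' @export
write_meth_matrix <- function(x, path, header = NULL) {
  df <- cbind(x$loci[c("locus_id", "chrom", "start", "end", "strand",
                       "locus_class", "cpg_content", "tor_value")],
              as.data.frame(x$values, check.names = FALSE))
  write_tsv_with_header(df, path, header)
}

#' @rdname write_meth_matrix
#' @param one_based set TRUE when the input TSV uses 1-based inclusive
#'   coordinates; they are converted to 0-based half-open on read.
#' @export
read_meth_matrix <- function(path, one_based = FALSE) {
  df <- read_tsv_skip_header(path)
  ann <- intersect(c("locus_id", "chrom", "start", "end", "strand",
                     "locus_class", "cpg_content", "tor_value"), names(df))
  samp <- setdiff(names(df), ann)
  start <- df$start - if (one_based) 1L else 0L
  loci <- locus_table(df$chrom, start, df$end,
                      strand = if ("strand" %in% ann) df$strand else "*",
                      locus_class = if ("locus_class" %in% ann) df$locus_class else "fragment",
                      cpg_content = if ("cpg_content" %in% ann) df$cpg_content else NA_real_,
                      tor_value = if ("tor_value" %in% ann) df$tor_value else NA_real_,
                      locus_id = if ("locus_id" %in% ann) df$locus_id else NULL)
  vals <- as.matrix(df[samp])
  meth_matrix(vals, loci)
}

#' Write / read an expression matrix as TSV
#'
#' Columns: gene, chrom, tss, strand, then one column per sample
#' (log-scale expression).
#'
#' @inheritParams write_meth_matrix
#' @param x an \code{\link{expr_matrix}}.
#' @export
write_expr_matrix <- function(x, path, header = NULL) {
  df <- cbind(x$genes[c("gene", "chrom", "tss", "strand")],
              as.data.frame(x$values, check.names = FALSE))
  write_tsv_with_header(df, path, header)
}

#' @rdname write_expr_matrix
#' @export
read_expr_matrix <- function(path) {
  df <- read_tsv_skip_header(path)
  ann <- c("gene", "chrom", "tss", "strand")
  samp <- setdiff(names(df), ann)
  expr_matrix(as.matrix(df[samp]), df[ann])
}

#' Read a bedGraph track (chrom, start, end, value; 0-based half-open)
#' @param path file path.
#' @param value_name name for the fourth column.
#' @return data.frame chrom/start/end/<value_name>.
#' @export
read_bedgraph <- function(path, value_name = "value") {
  df <- utils::read.delim(path, header = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE)[, 1:4]
  names(df) <- c("chrom", "start", "end", value_name)
  df
}

#' Read a BED file into a locus table
#' @param path file path.
#' @param locus_class class assigned to the intervals.
#' @return locus table.
#' @export
read_bed <- function(path, locus_class = "fragment") {
  df <- utils::read.delim(path, header = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE)
  strand <- if (ncol(df) >= 6) df[[6]] else "*"
  locus_table(df[[1]], df[[2]], df[[3]], strand = strand,
              locus_class = locus_class)
}
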