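# Read-level epiallele analysis. Reads are grouped per MspI restriction
# fragment, projected onto the fragment's 5 most covered CpGs to give
# homogenized 5-mer epialleles (32 possible patterns), downsampled to a fixed
# depth of 30 reads, and summarized by the Gini-Simpson diversity of the
# epiallele frequencies (epi-polymorphism; 0 = perfectly homogeneous).

all_patterns <- function() {
  g <- expand.grid(rep(list(0:1), 5))[, 5:1]
  apply(g, 1, paste, collapse = "")
}

#' Homogenize a fragment's reads to 5-CpG epialleles
#'
#' Selects the fragment's 5 most covered CpGs (coverage ties broken by
#' genomic position, leftmost first), drops reads that fail to cover all
#' five, and counts the surviving reads' 5-bit methylation patterns (bits in
#' genomic order).
#'
#' @param reads reads x CpGs matrix of 0/1 calls, NA where a read does not
#'   cover a CpG (or a "read_set" from \code{\link{simulate_read_patterns}}).
#' @param positions CpG genomic positions (columns of \code{reads}).
#' @param fragment_id id carried through.
#' @return list of class "pattern_set": \code{counts} (named by 5-character
#'   patterns), \code{positions} (the 5 selected, sorted), \code{n_reads},
#'   \code{downsampled = FALSE}; or NULL when the fragment has fewer than 5
#'   CpGs (excluded).
#' @export
homogenize_fragment <- function(reads, positions = NULL, fragment_id = NULL) {
  if (inherits(reads, "read_set")) {
    positions <- reads$positions
    fragment_id <- reads$fragment_id
    reads <- reads$reads
  }
  reads <- as.matrix(reads)
  if (is.null(positions)) positions <- seq_len(ncol(reads))
  stopifnot(length(positions) == ncol(reads))
  if (ncol(reads) < 5L) return(NULL)
  coverage <- colSums(!is.na(reads))
  sel <- order(-coverage, positions)[1:5]
  sel <- sel[order(positions[sel])]
  sub <- reads[, sel, drop = FALSE]
  full <- rowSums(is.na(sub)) == 0L
  sub <- sub[full, , drop = FALSE]
  key <- apply(sub, 1, paste, collapse = "")
  counts <- table(factor(key, levels = all_patterns()))
  counts <- counts[counts > 0]
  structure(list(fragment_id = fragment_id,
                 positions = positions[sel],
                 counts = stats::setNames(as.integer(counts), names(counts)),
                 n_reads = sum(counts), downsampled = FALSE,
                 avg_meth = NA_real_),
            class = "pattern_set")
}

#' Downsample a pattern set to fixed depth
#'
#' Uniform sampling without replacement (the default; \code{replace = TRUE}
#' switches to with-replacement) of \code{depth} reads from the homogenized
#' multiset. Fragments with fewer than \code{depth} reads are marked
#' uncovered. Average methylation is recomputed from the downsampled reads.
#'
#' @param ps a \code{"pattern_set"}.
#' @param depth target read count (default 30).
#' @param seed optional RNG seed.
#' @param replace sample with replacement.
#' @return the pattern set with \code{counts} downsampled,
#'   \code{downsampled = TRUE} and \code{avg_meth} set; or, when under depth,
#'   the input with \code{covered = FALSE}.
#' @export
downsample_patterns <- function(ps, depth = 30L, seed = NULL, replace = FALSE) {
  stopifnot(inherits(ps, "pattern_set"))
  if (ps$n_reads < depth && !replace) {
    ps$covered <- FALSE
    return(ps)
  }
  run <- function() {
    pool <- rep(names(ps$counts), ps$counts)
    keep <- sample(pool, depth, replace = replace)
    tab <- table(keep)
    ps$counts <- stats::setNames(as.integer(tab), names(tab))
    ps$n_reads <- depth
    ps$downsampled <- TRUE
    ps$covered <- TRUE
    bits <- vapply(strsplit(names(ps$counts), ""),
                   function(ch) sum(as.integer(ch)), numeric(1))
    ps$avg_meth <- sum(bits * ps$counts) / (5 * depth)
    ps
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Epi-polymorphism of a downsampled pattern set
#'
#' Gini-Simpson diversity 1 - sum(p_i^2) of the epiallele frequencies at
#' fixed depth; 0 when all reads share one pattern, at most 1 - 1/depth.
#'
#' @param pattern_counts named integer vector of pattern counts (or a
#'   \code{"pattern_set"}); counts must sum to \code{depth}.
#' @param depth expected total (default 30); a different sum is an error
#'   (downsampling must run first).
#' @return numeric value in [0, 1 - 1/depth].
#' @export
epipolymorphism <- function(pattern_counts, depth = 30L) {
  if (inherits(pattern_counts, "pattern_set"))
    pattern_counts <- pattern_counts$counts
  total <- sum(pattern_counts)
  if (total != depth)
    stop(sprintf("pattern counts sum to %d, expected %d (downsample first)",
                 total, depth))
  p <- pattern_counts / depth
  1 - sum(p^2)
}

#' Write / read pattern sets as TSV
#'
#' Wide format: fragment_id, positions (comma-separated), then 32 count
#' columns named by the 5-bit patterns.
#'
#' @param pattern_sets list of \code{"pattern_set"} objects.
#' @param path file path.
#' @export
write_pattern_sets <- function(pattern_sets, path) {
  pats <- all_patterns()
  rows <- lapply(pattern_sets, function(ps) {
    cnt <- stats::setNames(rep(0L, 32L), pats)
    cnt[names(ps$counts)] <- ps$counts
    cbind(data.frame(fragment_id = ps$fragment_id,
                     positions = paste(ps$positions, collapse = ","),
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(cnt), check.names = FALSE))
  })
  write_tsv_with_header(do.call(rbind, rows), path)
}

#' @rdname write_pattern_sets
#' @export
read_pattern_sets <- function(path) {
  df <- read_tsv_skip_header(path)
  pats <- intersect(all_patterns(), names(df))
  lapply(seq_len(nrow(df)), function(i) {
    cnt <- as.integer(df[i, pats])
    names(cnt) <- pats
    cnt <- cnt[cnt > 0]
    structure(list(fragment_id = df$fragment_id[i],
                   positions = as.integer(strsplit(df$positions[i], ",")[[1]]),
                   counts = cnt, n_reads = sum(cnt),
                   downsampled = FALSE, avg_meth = NA_real_),
              class = "pattern_set")
  })
}
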