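#' Write and read marker-by-individual matrices as TSV
#'
#' On-disk layout: one row per marker with `id`, `chrom`, `pos` followed by
#' one column per individual.
#'
#' @param values Marker x individual matrix (genotypes or LRR).
#' @param markers Marker data frame (`id`, `chrom`, `pos`).
#' @param file Path.
#' @return `read_marker_matrix_tsv` returns `list(markers, values)`.
#' @export
write_marker_matrix_tsv <- function(values, markers, file) {
  stopifnot(nrow(values) == nrow(markers))
  df <- cbind(markers[, c("id", "chrom", "pos")], as.data.frame(values))
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname write_marker_matrix_tsv
#' @export
read_marker_matrix_tsv <- function(file) {
  df <- read.delim(file, stringsAsFactors = FALSE, check.names = FALSE)
  markers <- df[, c("id", "chrom", "pos")]
  values <- as.matrix(df[, setdiff(names(df), c("id", "chrom", "pos")),
                         drop = FALSE])
  rownames(values) <- markers$id
  list(markers = markers, values = values)
}

#' BED-family readers and writers
#'
#' In-memory intervals are 1-based inclusive; BED, BEDPE and bedGraph files
#' are 0-based half-open. The shift happens here and nowhere else, so a
#' read-write round trip is exact.
#'
#' @param df Data frame with `chrom`, `start`, `end` (1-based inclusive) and
#'   optionally further columns, written in order.
#' @param file Path.
#' @return Readers return 1-based inclusive data frames.
#' @export
write_bed <- function(df, file) {
  out <- df
  out$start <- out$start - 1L
  write.table(out, file, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(file)
}

#' @rdname write_bed
#' @param col_names Names assigned to the columns beyond the first three.
#' @export
read_bed <- function(file, col_names = NULL) {
  df <- read.delim(file, header = FALSE, stringsAsFactors = FALSE)
  names(df)[1:3] <- c("chrom", "start", "end")
  if (!is.null(col_names)) {
    names(df)[seq(4, 3 + length(col_names))] <- col_names
  }
  df$start <- df$start + 1L
  df
}

#' @rdname write_bed
#' @param pairs An `fm_matepair_set`.
#' @export
write_bedpe <- function(pairs, file) {
  n <- nrow(pairs)
  out <- data.frame(
    chrom1 = pairs$chrom, start1 = pairs$start1 - 1L, end1 = pairs$end1,
    chrom2 = pairs$chrom, start2 = pairs$start2 - 1L, end2 = pairs$end2,
    name = sprintf("pair%07d", seq_len(n)), score = 0L,
    strand1 = pairs$strand1, strand2 = pairs$strand2
  )
  write.table(out, file, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(file)
}

#' @rdname write_bed
#' @export
read_bedpe <- function(file) {
  df <- read.delim(file, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 10) stop("malformed BEDPE: fewer than 10 columns")
  pairs <- data.frame(
    chrom = df[[1]],
    start1 = df[[2]] + 1L, end1 = df[[3]], strand1 = df[[9]],
    start2 = df[[5]] + 1L, end2 = df[[6]], strand2 = df[[10]],
    stringsAsFactors = FALSE
  )
  pairs$distance <- abs(pairs$start1 - pairs$start2)
  structure(pairs, class = c("fm_matepair_set", "data.frame"),
            locus = c(min(pairs$start1, pairs$start2),
                      max(pairs$end1, pairs$end2)))
}

#' @rdname write_bed
#' @param track A data frame with `start`, `end` and a value column.
#' @param value Name of the value column to write.
#' @param chrom Chromosome name for the track lines.
#' @export
write_bedgraph <- function(track, file, value = "norm", chrom = "chr20") {
  out <- data.frame(chrom = chrom, start = track$start - 1L, end = track$end,
                    value = track[[value]])
  write.table(out, file, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(file)
}

#' FASTA output for reference and allele sequences
#'
#' @param sequences Named character vector of DNA strings.
#' @param file Path.
#' @export
write_fasta <- function(sequences, file) {
  x <- Biostrings::DNAStringSet(sequences)
  Biostrings::writeXStringSet(x, file)
  invisible(file)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(file) {
  x <- Biostrings::readDNAStringSet(file)
  stats::setNames(as.character(x), names(x))
}

#' Serialize and restore a truth record
#'
#' Truth records (planted breakpoints, copy numbers, PSV markers, fold
#' changes) are plain JSON; a write-read round trip restores an equal object.
#'
#' @param truth A truth list.
#' @param file Path.
#' @export
write_truth_json <- function(truth, file) {
  jsonlite::write_json(truth, file, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(file)
}

#' @rdname write_truth_json
#' @export
read_truth_json <- function(file) {
  jsonlite::read_json(file, simplifyVector = TRUE)
}
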