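#' dermadup: discovery of an inverted-duplication structural variant
#'
#' End-to-end, synthetic-data-driven reimplementation of the analyses used to
#' discover and characterize a dominant dermal-hyperpigmentation allele formed
#' by the inverted duplication and joining of two genomic regions: SNP-array
#' Log R ratio copy-number scanning, pooled mate-pair structural-variant
#' detection, rearrangement enumeration from junction evidence, and
#' delta-delta-Ct qPCR quantification.
#'
#' @useDynLib dermadup, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif median sd lm coef t.test aov qt var ks.test
#' @importFrom utils read.delim write.table head tail
#' @keywords internal
"_PACKAGE"

# Run code under a private RNG stream without disturbing the caller's
# .Random.seed. All generators in the package route randomness through this.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

#' Genomic interval arithmetic (1-based inclusive)
#'
#' The pipeline's reporting currency is the 1-based inclusive interval used in
#' the source genome assembly. `interval_length()` is `end - start + 1`;
#' `interval_gap()` is the number of bases strictly between two intervals;
#' `bp_to_kb()` rounds to the nearest whole kilobase, the convention used when
#' quoting region sizes.
#'
#' @param start,end Interval bounds, 1-based inclusive.
#' @param end_a End of the left interval; `start_b` start of the right one.
#' @param start_b See `end_a`.
#' @param bp A length in base pairs.
#' @return An integer-valued numeric.
#' @examples
#' interval_length(10518217, 11000943)     # 482727 bp
#' bp_to_kb(interval_length(10518217, 11000943))  # 483
#' @export
interval_length <- function(start, end) {
  stopifnot(all(end >= start))
  end - start + 1
}

#' @rdname interval_length
#' @export
interval_gap <- function(end_a, start_b) {
  stopifnot(all(start_b > end_a))
  start_b - end_a - 1
}

#' @rdname interval_length
#' @export
bp_to_kb <- function(bp) {
  round(bp / 1000)
}

#' Convert between 1-based inclusive and 0-based half-open coordinates
#'
#' Reports and in-memory objects use 1-based inclusive coordinates; the BED
#' family of on-disk formats (BED, BEDPE, bedGraph) uses 0-based half-open.
#' The conversion is applied at exactly one layer: these two functions.
#'
#' @param df A data frame with `start` and `end` columns.
#' @return The data frame with coordinates shifted to the other convention.
#' @export
to_bed_coords <- function(df) {
  df$start <- df$start - 1L
  df
}

#' @rdname to_bed_coords
#' @export
from_bed_coords <- function(df) {
  df$start <- df$start + 1L
  df
}

# Reverse complement for plain character DNA (A/C/G/T, upper case).
revcomp <- function(x) {
  chartr("ACGT", "TGCA", vapply(x, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE))
}

comp_base <- function(x) chartr("ACGT", "TGCA", x)

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

substr_at <- function(seq, start, len) substr(seq, start, start + len - 1)

`substr_at<-` <- function(seq, start, value) {
  substr(seq, start, start + nchar(value) - 1) <- value
  seq
}
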