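#' Circular binary segmentation parameters
#'
#' Defaults follow the segmentation settings used with array Log R ratio data
#' in this analysis: 10,000 permutations, change-point acceptance at
#' alpha = 0.01, random-number seed 12345678.
#'
#' @param n_permutations Permutations per change-point test (>= 100).
#' @param alpha Significance level for accepting a change-point.
#' @param rng_seed Seed for the permutation stream.
#' @param min_markers_per_segment Minimum markers in an accepted arc and in
#'   its complement (small edge remnants can still arise at segment borders).
#' @return A list of class `fm_cbs_params`.
#' @export
cbs_params <- function(n_permutations = 10000, alpha = 0.01,
                       rng_seed = 12345678, min_markers_per_segment = 3) {
  stopifnot(alpha > 0, alpha < 1, n_permutations >= 100,
            min_markers_per_segment >= 1)
  structure(list(n_permutations = n_permutations, alpha = alpha,
                 rng_seed = rng_seed,
                 min_markers_per_segment = min_markers_per_segment),
            class = "fm_cbs_params")
}

#' Segment one individual's Log R ratio by circular binary segmentation
#'
#' Recursively finds, within each current segment, the circular arc whose mean
#' most differs from the rest of the segment (standardized mean difference),
#' accepts the split when a within-segment permutation test gives
#' `p <= alpha`, and recurses into the resulting pieces. Deterministic for a
#' fixed `rng_seed`.
#'
#' @param lrr Numeric vector of Log R ratios (no missing values; drop them
#'   upstream).
#' @param positions Increasing marker positions, same length.
#' @param params An `fm_cbs_params`.
#' @return A data frame of segments: `start`/`end` (first and last marker
#'   positions), `n_markers`, `mean_lrr`, and `p_value` of the permutation
#'   test whose acceptance created the segment's boundaries (`NA` for an
#'   unsplit input).
#' @export
cbs_segment <- function(lrr, positions, params = cbs_params()) {
  stopifnot(length(lrr) == length(positions), !anyNA(lrr),
            inherits(params, "fm_cbs_params"))
  if (is.unsorted(positions, strictly = TRUE)) {
    stop("positions must be strictly increasing")
  }
  n <- length(lrr)
  seg_row <- function(lo, hi, p) {
    data.frame(start = positions[lo], end = positions[hi],
               n_markers = hi - lo + 1L,
               mean_lrr = mean(lrr[lo:hi]), p_value = p)
  }
  if (n < 2) {
    return(seg_row(1, max(n, 1), NA_real_))
  }
  min_w <- params$min_markers_per_segment
  recurse <- function(lo, hi, p_in) {
    m <- hi - lo + 1
    if (m < 2 * min_w) return(seg_row(lo, hi, p_in))
    x <- lrr[lo:hi]
    arc <- cbs_max_arc(x, min_w)
    if (arc$i < 0 || arc$stat <= 0) return(seg_row(lo, hi, p_in))
    perm <- cbs_perm_pvalue(x, arc$stat, min_w,
                            params$n_permutations, params$alpha)
    if (perm$p > params$alpha) return(seg_row(lo, hi, p_in))
    cuts <- unique(c(arc$i, arc$j))           # local boundaries after these
    cuts <- cuts[cuts > 0 & cuts < m]
    if (length(cuts) == 0) return(seg_row(lo, hi, p_in))
    bounds <- c(0, cuts, m)
    out <- NULL
    for (k in seq_len(length(bounds) - 1)) {
      out <- rbind(out, recurse(lo + bounds[k], lo + bounds[k + 1] - 1, perm$p))
    }
    out
  }
  res <- with_seed(params$rng_seed, recurse(1, n, NA_real_))
  rownames(res) <- NULL
  res
}
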