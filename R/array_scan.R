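#' Group-wise Log R ratio differencing
#'
#' Subtracts the per-marker average Log R ratio of the wild-type group from
#' that of the carrier group, the contrast that sharpens duplication
#' boundaries beyond what per-individual segmentation achieves. Means are
#' unweighted; missing values are dropped marker-wise.
#'
#' @param lrr_fm,lrr_wt Marker x individual LRR matrices for the two groups
#'   (same markers, same order), or a single `fm_array_cohort` in `lrr_fm`
#'   with ids supplied via `fm_ids`/`wt_ids`.
#' @param markers Marker data frame (`id`, `pos`); taken from the cohort when
#'   one is supplied.
#' @param fm_ids,wt_ids Column ids used when `lrr_fm` is a cohort.
#' @param threshold Delta level above which a marker counts as elevated
#'   (exceedance is strict: a delta equal to the threshold is below it).
#' @param min_run Minimum run length of elevated markers for a region call.
#' @return An object of class `fm_delta_track`: a data frame (`id`, `pos`,
#'   `delta`) plus the threshold and run parameters.
#' @export
groupwise_delta <- function(lrr_fm, lrr_wt = NULL, markers = NULL,
                            fm_ids = NULL, wt_ids = NULL,
                            threshold = 0.1, min_run = 5) {
  if (inherits(lrr_fm, "fm_array_cohort")) {
    cohort <- lrr_fm
    if (is.null(fm_ids)) fm_ids <- cohort_ids(cohort, "FM")
    if (is.null(wt_ids)) wt_ids <- cohort_ids(cohort, "WT")
    markers <- cohort$markers
    lrr_fm <- cohort$lrr[, fm_ids, drop = FALSE]
    lrr_wt <- cohort$lrr[, wt_ids, drop = FALSE]
  }
  stopifnot(is.matrix(lrr_fm), is.matrix(lrr_wt), threshold > 0, min_run >= 1)
  if (nrow(lrr_fm) != nrow(lrr_wt) ||
      !identical(rownames(lrr_fm), rownames(lrr_wt))) {
    stop("marker sets of the two groups do not match")
  }
  if (ncol(lrr_fm) == 0 || ncol(lrr_wt) == 0) stop("both groups must be non-empty")
  delta <- rowMeans(lrr_fm, na.rm = TRUE) - rowMeans(lrr_wt, na.rm = TRUE)
  if (is.null(markers)) {
    ids <- rownames(lrr_fm)
    if (is.null(ids)) ids <- sprintf("m%05d", seq_along(delta))
    markers <- data.frame(id = ids, pos = seq_along(delta))
  }
  structure(
    list(track = data.frame(id = markers$id, pos = markers$pos,
                            delta = unname(delta), stringsAsFactors = FALSE),
         threshold = threshold, min_run = min_run),
    class = "fm_delta_track"
  )
}

#' @export
print.fm_delta_track <- function(x, ...) {
  cat("Group-wise LRR delta track:", nrow(x$track), "markers; threshold",
      x$threshold, "; min run", x$min_run, "\n")
  invisible(x)
}

#' Call elevated regions from a delta track
#'
#' A region is a maximal run of at least `min_run` consecutive markers with
#' delta strictly above the threshold; qualifying runs separated by fewer than
#' `min_run` below-threshold markers are merged into one region. Each boundary
#' is estimated as the midpoint between the outermost in-run marker and its
#' nearest out-of-run neighbour (the marker position itself at track edges),
#' which halves the worst-case error relative to quoting the outermost marker.
#'
#' @param track An `fm_delta_track`.
#' @param threshold,min_run Override the track's parameters.
#' @return A data frame with one row per region: `start`/`end` (outermost
#'   elevated markers), `boundary_lo`/`boundary_hi` (midpoint estimates),
#'   `n_markers`, `mean_delta`, `method`. Zero rows when nothing is elevated.
#' @export
call_elevated_regions <- function(track, threshold = track$threshold,
                                  min_run = track$min_run) {
  stopifnot(inherits(track, "fm_delta_track"))
  tr <- track$track
  above <- tr$delta > threshold
  empty <- data.frame(start = numeric(0), end = numeric(0),
                      boundary_lo = numeric(0), boundary_hi = numeric(0),
                      n_markers = integer(0), mean_delta = numeric(0),
                      method = character(0), stringsAsFactors = FALSE)
  if (!any(above)) return(empty)
  r <- rle(above)
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1
  keep <- r$values & r$lengths >= min_run
  if (!any(keep)) return(empty)
  runs <- data.frame(from = run_start[keep], to = run_end[keep])
  # merge qualifying runs separated by short below-threshold stretches
  merged <- runs[1, , drop = FALSE]
  if (nrow(runs) > 1) {
    for (k in 2:nrow(runs)) {
      gap <- runs$from[k] - merged$to[nrow(merged)] - 1
      if (gap < min_run) {
        merged$to[nrow(merged)] <- runs$to[k]
      } else {
        merged <- rbind(merged, runs[k, ])
      }
    }
  }
  out <- lapply(seq_len(nrow(merged)), function(k) {
    i0 <- merged$from[k]; i1 <- merged$to[k]
    lo <- if (i0 == 1) tr$pos[1] else round((tr$pos[i0 - 1] + tr$pos[i0]) / 2)
    hi <- if (i1 == nrow(tr)) tr$pos[nrow(tr)] else
      round((tr$pos[i1] + tr$pos[i1 + 1]) / 2)
    data.frame(start = tr$pos[i0], end = tr$pos[i1],
               boundary_lo = lo, boundary_hi = hi,
               n_markers = i1 - i0 + 1L,
               mean_delta = mean(tr$delta[i0:i1]),
               method = "midpoint", stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Scan for markers with fixed heterozygosity in carriers
#'
#' Returns the markers at which every carrier is called heterozygous -- the
#' signature of collapsed paralogous sequence variants inside a duplication --
#' and classifies each by its wild-type allele distribution.
#'
#' @param gt Genotype matrix (`"AA"`/`"AB"`/`"BB"`/`NA`) or an
#'   `fm_array_cohort`.
#' @param fm_ids,wt_ids Column ids of carriers and wild types; defaults come
#'   from the cohort (all carriers, including heterozygotes).
#' @param markers Marker data frame; taken from the cohort when supplied.
#' @param region Optional two-vector restricting the scan.
#' @param strict_missing When `TRUE` (default) a missing call in any carrier
#'   disqualifies the marker; when `FALSE`, missing calls are ignored.
#' @return Data frame `id`, `pos`, `class` (`"fixed_reference"` or
#'   `"segregating"` in wild types).
#' @export
fixed_het_scan <- function(gt, fm_ids = NULL, wt_ids = NULL, markers = NULL,
                           region = NULL, strict_missing = TRUE) {
  if (inherits(gt, "fm_array_cohort")) {
    cohort <- gt
    if (is.null(fm_ids)) fm_ids <- cohort$samples$id[cohort$samples$group != "WT"]
    if (is.null(wt_ids)) wt_ids <- cohort_ids(cohort, "WT")
    markers <- cohort$markers
    gt <- cohort$genotypes
  }
  if (length(fm_ids) == 0) stop("carrier group is empty")
  g_fm <- gt[, fm_ids, drop = FALSE]
  g_wt <- gt[, wt_ids, drop = FALSE]
  if (is.null(markers)) {
    markers <- data.frame(id = rownames(gt), pos = seq_len(nrow(gt)))
  }
  ok <- seq_len(nrow(gt))
  if (!is.null(region)) ok <- ok[markers$pos >= region[1] & markers$pos <= region[2]]
  hit <- vapply(ok, function(m) {
    calls <- g_fm[m, ]
    if (strict_missing && anyNA(calls)) return(FALSE)
    calls <- calls[!is.na(calls)]
    length(calls) > 0 && all(calls == "AB")
  }, logical(1))
  sel <- ok[hit]
  cls <- vapply(sel, function(m) {
    wt <- g_wt[m, ]
    wt <- wt[!is.na(wt)]
    if (length(wt) > 0 && all(wt == "AA")) "fixed_reference" else "segregating"
  }, character(1))
  data.frame(id = markers$id[sel], pos = markers$pos[sel], class = cls,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Shared-haplotype interval around the fixed-heterozygosity block
#'
#' Identity-by-descent analogue: finds the maximal run of consecutive markers
#' at which all listed carriers have identical (non-missing) genotype vectors,
#' containing the fixed-heterozygosity block. Carriers recombinant in a flank
#' shrink the interval to the shared core.
#'
#' @param gt Genotype matrix or an `fm_array_cohort`.
#' @param fm_ids Ids of (typically homozygous) carriers; at least two.
#' @param markers Marker data frame; from the cohort when supplied.
#' @return List with `interval` (first/last marker positions), `marker_ids`,
#'   and `n_markers`.
#' @export
shared_haplotype_interval <- function(gt, fm_ids = NULL, markers = NULL) {
  if (inherits(gt, "fm_array_cohort")) {
    cohort <- gt
    if (is.null(fm_ids)) fm_ids <- cohort_ids(cohort, "FM")
    markers <- cohort$markers
    gt <- cohort$genotypes
  }
  if (length(fm_ids) < 2) stop("need at least two carriers")
  g <- gt[, fm_ids, drop = FALSE]
  identical_m <- apply(g, 1, function(x) !anyNA(x) && length(unique(x)) == 1)
  fixed_het <- apply(g, 1, function(x) !anyNA(x) && all(x == "AB"))
  if (!any(fixed_het)) stop("no fixed-heterozygosity block found")
  anchor <- which(fixed_het)[ceiling(sum(fixed_het) / 2)]
  lo <- anchor
  while (lo > 1 && identical_m[lo - 1]) lo <- lo - 1
  hi <- anchor
  while (hi < length(identical_m) && identical_m[hi + 1]) hi <- hi + 1
  if (is.null(markers)) {
    markers <- data.frame(id = rownames(gt), pos = seq_len(nrow(gt)))
  }
  list(interval = c(start = markers$pos[lo], end = markers$pos[hi]),
       marker_ids = markers$id[lo:hi],
       n_markers = hi - lo + 1L)
}
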