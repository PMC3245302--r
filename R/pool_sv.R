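#' Windowed read depth
#'
#' Counts mapped reads per fixed-width window over the locus; each read
#' increments the window containing its leftmost base. Normalized depth is
#' reads per window per million mapped reads of the library (the library total
#' attached to the pair set, or the locus total when none is attached).
#'
#' @param pairs An `fm_matepair_set` (both reads of each pair are counted).
#' @param window_size Window width, bp (default 1 kb).
#' @param locus Two-vector of locus bounds; defaults to the pair set's.
#' @return An object of class `fm_depth_track`: data frame `start`, `end`,
#'   `count`, `norm`, plus `window_size` and `library_total` attributes.
#' @export
window_depth <- function(pairs, window_size = 1000, locus = attr(pairs, "locus")) {
  if (window_size <= 0) stop("window_size must be positive")
  starts <- c(pairs$start1, pairs$start2)
  locus_len <- locus[2] - locus[1] + 1
  n_win <- ceiling(locus_len / window_size)
  idx <- (starts - locus[1]) %/% window_size + 1
  idx <- idx[idx >= 1 & idx <= n_win]
  counts <- tabulate(idx, nbins = n_win)
  lib <- attr(pairs, "library_total")
  if (is.null(lib)) lib <- sum(counts)
  win_start <- locus[1] + (seq_len(n_win) - 1) * window_size
  structure(
    data.frame(start = win_start,
               end = pmin(win_start + window_size - 1, locus[2]),
               count = counts,
               norm = counts / lib * 1e6),
    class = c("fm_depth_track", "data.frame"),
    window_size = window_size, library_total = lib
  )
}

#' Per-window log2 depth fold change between two libraries
#'
#' Each track is first normalized to its own library total (reads per million
#' mapped); a half-read pseudocount is added to each window's count before
#' normalization, guarding empty windows without biasing windows of ordinary
#' depth. Swapping the two tracks negates the result exactly.
#'
#' @param track_a,track_b `fm_depth_track`s over identical windows
#'   (case first: the ratio is a over b).
#' @param pseudocount Added to each window's read count.
#' @return Data frame `start`, `end`, `log2fc`.
#' @export
log2_fold_change <- function(track_a, track_b, pseudocount = 0.5) {
  if (!identical(track_a$start, track_b$start)) {
    stop("windowing mismatch between the two tracks")
  }
  lib_a <- attr(track_a, "library_total")
  lib_b <- attr(track_b, "library_total")
  a <- (track_a$count + pseudocount) / lib_a * 1e6
  b <- (track_b$count + pseudocount) / lib_b * 1e6
  data.frame(start = track_a$start, end = track_a$end, log2fc = log2(a / b))
}

#' Parameters of the discordant mate-pair candidate-SV rule
#'
#' A window is a candidate when at least `min_discordant_fraction` of its
#' pairs have mapping distances exceeding `sd_multiplier` standard deviations
#' above the library mean, the supporting subset being those within
#' `median_band` bp of the discordant pairs' median distance.
#'
#' @param min_discordant_fraction Minimum fraction of discordant pairs.
#' @param sd_multiplier Distance threshold in SDs above the library mean.
#' @param median_band Half-width (bp) of the band around the discordant
#'   median within which supporting pairs must lie.
#' @param min_pairs_per_window Windows with fewer pairs are skipped (guards
#'   the fraction against tiny denominators).
#' @param window_size Window width, bp.
#' @return A list of class `fm_sv_params`.
#' @export
sv_params <- function(min_discordant_fraction = 0.20, sd_multiplier = 6,
                      median_band = 1500, min_pairs_per_window = 10,
                      window_size = 1000) {
  stopifnot(min_discordant_fraction > 0, sd_multiplier > 0, median_band > 0,
            min_pairs_per_window > 0, window_size > 0)
  structure(list(min_discordant_fraction = min_discordant_fraction,
                 sd_multiplier = sd_multiplier, median_band = median_band,
                 min_pairs_per_window = min_pairs_per_window,
                 window_size = window_size),
            class = "fm_sv_params")
}

#' Candidate structural variants from discordant mate pairs
#'
#' Assigns each pair once, to the window of its leftmost read, and applies the
#' discordant-fraction rule window by window. The partner window is placed at
#' the median far-read position of the supporting pairs; the inversion flag is
#' raised when a strict majority of supporting pairs have their two reads on
#' different strands.
#'
#' @param pairs An `fm_matepair_set`.
#' @param params An `fm_sv_params`.
#' @param chrom_stats Optional `c(mean, sd)` of mapping distances; computed
#'   from all pairs of the library when `NULL`.
#' @param locus Locus bounds; defaults to the pair set's.
#' @return Data frame with one row per candidate window: `start`, `end`,
#'   `partner_start`, `partner_end`, `n_support`, `discordant_fraction`,
#'   `median_distance`, `inversion`. Zero rows when nothing qualifies.
#' @export
candidate_sv_windows <- function(pairs, params = sv_params(),
                                 chrom_stats = NULL,
                                 locus = attr(pairs, "locus")) {
  stopifnot(inherits(params, "fm_sv_params"))
  if (is.null(chrom_stats)) {
    chrom_stats <- c(mean = mean(pairs$distance), sd = sd(pairs$distance))
  }
  cutoff <- chrom_stats[[1]] + params$sd_multiplier * chrom_stats[[2]]
  left <- pmin(pairs$start1, pairs$start2)
  far <- pmax(pairs$start1, pairs$start2)
  win <- (left - locus[1]) %/% params$window_size
  groups <- split(seq_len(nrow(pairs)), win)
  rows <- lapply(groups, function(ii) {
    if (length(ii) < params$min_pairs_per_window) return(NULL)
    disc <- pairs$distance[ii] > cutoff
    frac <- mean(disc)
    if (frac < params$min_discordant_fraction) return(NULL)
    di <- ii[disc]
    med <- median(pairs$distance[di])
    keep <- di[abs(pairs$distance[di] - med) <= params$median_band]
    if (length(keep) == 0) return(NULL)
    w0 <- locus[1] + win[ii[1]] * params$window_size
    partner_mid <- median(far[keep])
    p0 <- locus[1] +
      ((partner_mid - locus[1]) %/% params$window_size) * params$window_size
    strand_disc <- pairs$strand1[keep] != pairs$strand2[keep]
    data.frame(start = w0, end = w0 + params$window_size - 1,
               partner_start = p0, partner_end = p0 + params$window_size - 1,
               n_support = length(keep),
               discordant_fraction = frac,
               median_distance = median(pairs$distance[keep]),
               inversion = sum(strand_disc) * 2 > length(keep),
               stringsAsFactors = FALSE)
  })
  rows <- Filter(Negate(is.null), rows)
  if (length(rows) == 0) {
    return(data.frame(start = numeric(0), end = numeric(0),
                      partner_start = numeric(0), partner_end = numeric(0),
                      n_support = integer(0), discordant_fraction = numeric(0),
                      median_distance = numeric(0), inversion = logical(0)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$start), ]
}

#' Depth-gain regions from a log2 fold-change track
#'
#' Reporting rule for duplicated regions: at least `min_windows` consecutive
#' windows at or above `min_log2fc` (a 2x guide line corresponds to 1.0; the
#' default 0.8 leaves headroom for sampling noise).
#'
#' @param fc A data frame from [log2_fold_change()].
#' @param min_windows Minimum run length of elevated windows.
#' @param min_log2fc Log2 fold-change threshold.
#' @return Data frame `start`, `end`, `n_windows`, `mean_log2fc`.
#' @export
call_depth_gain_regions <- function(fc, min_windows = 20, min_log2fc = 0.8) {
  above <- fc$log2fc >= min_log2fc
  r <- rle(above)
  to <- cumsum(r$lengths)
  from <- to - r$lengths + 1
  keep <- r$values & r$lengths >= min_windows
  if (!any(keep)) {
    return(data.frame(start = numeric(0), end = numeric(0),
                      n_windows = integer(0), mean_log2fc = numeric(0)))
  }
  data.frame(start = fc$start[from[keep]], end = fc$end[to[keep]],
             n_windows = r$lengths[keep],
             mean_log2fc = mapply(function(a, b) mean(fc$log2fc[a:b]),
                                  from[keep], to[keep]))
}

#' Refine a junction breakpoint and its microhomology from sequence
#'
#' Given a fragment spanning a rearrangement junction (e.g. a sequenced PCR
#' product), anchors the fragment's two ends on the reference (either strand),
#' extends each anchor to its maximal exact match, and reports the junction:
#' the overlap of the two matched stretches on the fragment is the
#' microhomology; a gap between them is inserted sequence. Exact and
#' deterministic.
#'
#' @param fragment DNA string containing the junction.
#' @param ref An `fm_reference`.
#' @param anchor_len Exact-match seed length required at each fragment end.
#' @return An object of class `fm_junction_call`: per-side strand, matched
#'   reference interval and breakpoint coordinate (chromosome frame),
#'   `microhomology_len`, `microhomology_seq`, `inserted_seq`.
#' @export
refine_junction <- function(fragment, ref, anchor_len = 30) {
  stopifnot(inherits(ref, "fm_reference"), nchar(fragment) >= 2 * anchor_len)
  refseq <- ref$sequence
  n_ref <- nchar(refseq)
  frag <- strsplit(fragment, "", fixed = TRUE)[[1]]
  refv <- strsplit(refseq, "", fixed = TRUE)[[1]]
  n_frag <- length(frag)

  locate <- function(pattern) {
    p <- regexpr(pattern, refseq, fixed = TRUE)[1]
    if (p > 0) return(list(strand = "+", q = p))
    p <- regexpr(revcomp(pattern), refseq, fixed = TRUE)[1]
    if (p > 0) {
      # + coordinate matching the pattern's FIRST base
      return(list(strand = "-", q = p + nchar(pattern) - 1))
    }
    NULL
  }
  # maximal match of the fragment prefix, anchored at its first anchor_len bases
  prefix <- locate(substr(fragment, 1, anchor_len))
  if (is.null(prefix)) stop("5' side of fragment unmappable at anchor length")
  a_len <- anchor_len
  repeat {
    t <- a_len + 1
    if (t > n_frag) break
    rp <- if (prefix$strand == "+") prefix$q + t - 1 else prefix$q - t + 1
    if (rp < 1 || rp > n_ref) break
    base <- if (prefix$strand == "+") refv[rp] else comp_base(refv[rp])
    if (base != frag[t]) break
    a_len <- t
  }
  # maximal match of the fragment suffix, anchored at its last anchor_len bases
  suffix <- locate(substr(fragment, n_frag - anchor_len + 1, n_frag))
  if (is.null(suffix)) stop("3' side of fragment unmappable at anchor length")
  # q above maps the anchor's first base (fragment position n_frag-anchor_len+1)
  b_start <- n_frag - anchor_len + 1
  repeat {
    t <- b_start - 1
    if (t < 1) break
    off <- t - (n_frag - anchor_len + 1)        # negative offset from anchor
    rp <- if (suffix$strand == "+") suffix$q + off else suffix$q - off
    if (rp < 1 || rp > n_ref) break
    base <- if (suffix$strand == "+") refv[rp] else comp_base(refv[rp])
    if (base != frag[t]) break
    b_start <- t
  }
  mh_len <- max(0L, a_len - b_start + 1L)
  mh_seq <- if (mh_len > 0) substr(fragment, b_start, a_len) else ""
  inserted <- if (a_len + 1 <= b_start - 1) {
    substr(fragment, a_len + 1, b_start - 1)
  } else {
    ""
  }
  chrom_pos <- function(i) ref$locus[1] + i - 1
  side_pos <- function(side, frag_pos, anchor_pos) {
    off <- frag_pos - anchor_pos
    rp <- if (side$strand == "+") side$q + off else side$q - off
    chrom_pos(rp)
  }
  structure(list(
    chrom = ref$chrom,
    side_a = list(strand = prefix$strand,
                  breakpoint = side_pos(prefix, a_len, 1)),
    side_b = list(strand = suffix$strand,
                  breakpoint = side_pos(suffix, b_start, n_frag - anchor_len + 1)),
    microhomology_len = mh_len,
    microhomology_seq = mh_seq,
    inserted_seq = inserted
  ), class = "fm_junction_call")
}

#' @export
print.fm_junction_call <- function(x, ...) {
  cat("Junction call on", x$chrom, "\n")
  cat(sprintf("  side A: %s strand, breakpoint %s\n", x$side_a$strand,
              format(x$side_a$breakpoint, big.mark = ",")))
  cat(sprintf("  side B: %s strand, breakpoint %s\n", x$side_b$strand,
              format(x$side_b$breakpoint, big.mark = ",")))
  cat("  microhomology:", x$microhomology_len, "bp",
      if (x$microhomology_len > 0) paste0("(", x$microhomology_seq, ")") else "",
      "\n")
  if (nzchar(x$inserted_seq)) cat("  inserted:", x$inserted_seq, "\n")
  invisible(x)
}
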