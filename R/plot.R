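#' Plot a group-wise delta track
#'
#' Scatter of per-marker group-mean LRR differences with the threshold guides
#' and any called regions shaded.
#'
#' @param track An `fm_delta_track`.
#' @param regions Optional region table from [call_elevated_regions()].
#' @param ... Passed to [graphics::plot()].
#' @export
plot_delta_track <- function(track, regions = NULL, ...) {
  tr <- track$track
  graphics::plot(tr$pos / 1e6, tr$delta, pch = 16, cex = 0.4,
                 xlab = "position (Mb)", ylab = "mean LRR difference (FM - WT)",
                 ...)
  graphics::abline(h = c(-track$threshold, track$threshold),
                   col = "red", lty = 3)
  if (!is.null(regions) && nrow(regions) > 0) {
    for (k in seq_len(nrow(regions))) {
      graphics::rect(regions$boundary_lo[k] / 1e6, graphics::par("usr")[3],
                     regions$boundary_hi[k] / 1e6, graphics::par("usr")[4],
                     col = grDevices::adjustcolor("steelblue", 0.2),
                     border = NA)
    }
  }
  invisible(track)
}

#' Plot a windowed log2 fold-change track
#'
#' @param fc Data frame from [log2_fold_change()].
#' @param guide Horizontal guide line (1 = two-fold).
#' @param ... Passed to [graphics::plot()].
#' @export
plot_log2fc <- function(fc, guide = 1, ...) {
  graphics::plot(fc$start / 1e6, fc$log2fc, type = "h", col = "grey40",
                 xlab = "position (Mb)", ylab = "log2 fold change", ...)
  graphics::abline(h = guide, col = "red", lty = 3)
  invisible(fc)
}
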