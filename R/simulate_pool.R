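#' Specification of a pooled mate-pair sequencing library
#'
#' Large-insert (mate-pair) library over the locus: ~2.5 kb inserts, short
#' reads, ~30x per-copy depth. `genome_size` sets the genome-wide mapped-read
#' total implied by the target depth; it only matters for per-million
#' normalization (the locus is a small fraction of a real genome, so library
#' totals are effectively equal between pools).
#'
#' @param mean_insert,insert_sd Insert-size distribution, bp.
#' @param read_length Read length, bp.
#' @param target_depth Per-copy fold coverage of the template.
#' @param genome_size Genome size (bp) implied when reporting the library's
#'   total mapped reads.
#' @param seed Integer seed.
#' @return A list of class `fm_pool_spec`.
#' @export
pool_spec <- function(mean_insert = 2500, insert_sd = 300, read_length = 50,
                      target_depth = 30, genome_size = 1.05e9, seed = 1) {
  stopifnot(target_depth > 0, insert_sd >= 0, read_length > 0)
  if (mean_insert <= 2 * read_length) {
    stop("mean insert must exceed twice the read length")
  }
  structure(list(mean_insert = mean_insert, insert_sd = insert_sd,
                 read_length = read_length, target_depth = target_depth,
                 genome_size = genome_size, seed = seed),
            class = "fm_pool_spec")
}

#' Simulate a pooled mate-pair library mapped back to the reference
#'
#' Draws pairs uniformly along the template (the wild-type reference or a
#' rearranged allele), then reports each read's mapping in reference
#' coordinates directly -- no alignment step is simulated. A read falling
#' across a template junction has no contiguous reference image and is
#' dropped as unmappable; pairs whose two reads land in differently oriented
#' or distant template pieces acquire the aberrant implied distance and/or
#' strand pattern that the structural-variant scan looks for.
#'
#' @param template An `fm_reference` or `fm_allele`.
#' @param spec An `fm_pool_spec`.
#' @return An object of class `fm_matepair_set`: a data frame with one row per
#'   mapped pair (`start1`/`end1`/`strand1`, `start2`/`end2`/`strand2` in
#'   reference chromosome coordinates, and `distance`, the absolute difference
#'   of the two leftmost coordinates), with the library total, locus bounds
#'   and the spec attached as attributes.
#' @export
simulate_matepair_pool <- function(template, spec = pool_spec()) {
  stopifnot(inherits(spec, "fm_pool_spec"))
  pieces <- template$pieces
  len <- max(pieces$t_end)
  rl <- spec$read_length
  n_pairs <- round(spec$target_depth * len / (2 * rl))
  sim <- with_seed(spec$seed, {
    ins <- round(rnorm(n_pairs, spec$mean_insert, spec$insert_sd))
    ins <- pmin(pmax(ins, 2 * rl), len)
    s <- 1 + floor(runif(n_pairs) * (len - ins + 1))
    list(t1 = s, t2 = s + ins - rl)
  })
  map_read <- function(ts) {
    fi <- findInterval(ts, pieces$t_start)
    ok <- ts + rl - 1 <= pieces$t_end[fi]
    fwd <- pieces$sign[fi] == "+"
    start <- ifelse(fwd,
                    pieces$ref_start[fi] + (ts - pieces$t_start[fi]),
                    pieces$ref_start[fi] + (pieces$t_end[fi] - (ts + rl - 1)))
    list(start = start, strand = ifelse(fwd, "+", "-"), ok = ok)
  }
  r1 <- map_read(sim$t1)
  r2 <- map_read(sim$t2)
  keep <- r1$ok & r2$ok
  pairs <- data.frame(
    chrom = template$chrom,
    start1 = r1$start[keep], end1 = r1$start[keep] + rl - 1,
    strand1 = r1$strand[keep],
    start2 = r2$start[keep], end2 = r2$start[keep] + rl - 1,
    strand2 = r2$strand[keep],
    stringsAsFactors = FALSE
  )
  pairs$distance <- abs(pairs$start1 - pairs$start2)
  locus <- c(min(pieces$ref_start), max(pieces$ref_end))
  structure(pairs,
            class = c("fm_matepair_set", "data.frame"),
            library_total = round(spec$genome_size * spec$target_depth / rl),
            n_pairs_simulated = n_pairs,
            locus = locus,
            spec = spec)
}

#' @export
print.fm_matepair_set <- function(x, ...) {
  spec <- attr(x, "spec")
  cat("Mate-pair set:", nrow(x), "mapped pairs (of",
      attr(x, "n_pairs_simulated"), "simulated),",
      spec$target_depth, "x,", spec$mean_insert, "bp inserts\n")
  invisible(x)
}
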