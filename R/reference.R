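#' Build the synthetic reference model of the pigmentation locus
#'
#' Constructs a standalone random DNA sequence for a ~1.7 Mb locus, reported in
#' the chromosome frame of the source assembly so that published coordinates
#' are directly usable. The locus is tiled, in order and without gaps, by five
#' blocks: left flank `L`, first duplicated region `D1`, inter-duplication
#' single-copy region `S`, second duplicated region `D2`, and right flank `R`.
#' Bases flanking the two future junction points are adjusted so that the
#' mutant allele built from this reference carries an exactly known
#' microhomology at each junction (default: none at the 5' junction, a single
#' shared C at the 3' junction).
#'
#' @param chrom Chromosome name used in all coordinate output.
#' @param locus Two-vector, 1-based inclusive bounds of the simulated locus.
#' @param d1,d2 Two-vectors: bounds of the two duplicated regions.
#' @param overlap_5p,overlap_3p Microhomology lengths (bp) planted at the
#'   junction of the 5' ends and of the 3' ends of the duplicated regions.
#' @param seed Integer seed; the sequence is a deterministic function of it.
#' @return An object of class `fm_reference`: chromosome, locus and block
#'   coordinates, the locus sequence, the planted junction overlaps, and a
#'   piece table describing the wild-type template (used by the read
#'   simulator).
#' @examples
#' ref <- build_reference(seed = 20)
#' interval_length(ref$blocks$D1[1], ref$blocks$D1[2])  # 128939
#' @export
build_reference <- function(chrom = "chr20",
                            locus = c(10218000, 11935000),
                            d1 = c(10717294, 10846232),
                            d2 = c(11262904, 11435256),
                            overlap_5p = 0,
                            overlap_3p = 1,
                            seed = 20) {
  stopifnot(length(locus) == 2, length(d1) == 2, length(d2) == 2,
            overlap_5p >= 0, overlap_3p >= 0)
  ok <- locus[1] < d1[1] && d1[1] <= d1[2] && d1[2] < d2[1] &&
    d2[1] <= d2[2] && d2[2] < locus[2]
  if (!ok) {
    stop("block coordinates must be ordered and strictly inside the locus")
  }
  blocks <- list(
    L  = c(locus[1], d1[1] - 1),
    D1 = d1,
    S  = c(d1[2] + 1, d2[1] - 1),
    D2 = d2,
    R  = c(d2[2] + 1, locus[2])
  )
  len <- interval_length(locus[1], locus[2])
  seq <- with_seed(seed, random_dna(len))
  idx <- function(pos) pos - locus[1] + 1
  seq <- plant_junction_overlaps(seq, idx(d1[1]), idx(d1[2]),
                                 idx(d2[1]), idx(d2[2]),
                                 overlap_5p, overlap_3p)
  pieces <- data.frame(
    block = names(blocks),
    sign = "+",
    ref_start = vapply(blocks, `[`, numeric(1), 1),
    ref_end = vapply(blocks, `[`, numeric(1), 2),
    stringsAsFactors = FALSE
  )
  pieces$t_start <- idx(pieces$ref_start)
  pieces$t_end <- idx(pieces$ref_end)
  rownames(pieces) <- NULL
  structure(
    list(chrom = chrom, locus = locus, blocks = blocks, sequence = seq,
         overlap_5p = overlap_5p, overlap_3p = overlap_3p, seed = seed,
         pieces = pieces),
    class = "fm_reference"
  )
}

#' @export
print.fm_reference <- function(x, ...) {
  cat("Synthetic reference locus (", x$chrom, ":",
      format(x$locus[1], big.mark = ","), "-",
      format(x$locus[2], big.mark = ","), ", ",
      format(nchar(x$sequence), big.mark = ","), " bp)\n", sep = "")
  for (b in names(x$blocks)) {
    cat(sprintf("  %-2s %s-%s (%s bp)\n", b,
                format(x$blocks[[b]][1], big.mark = ","),
                format(x$blocks[[b]][2], big.mark = ","),
                format(interval_length(x$blocks[[b]][1], x$blocks[[b]][2]),
                       big.mark = ",")))
  }
  cat("  planted junction microhomology: 5' =", x$overlap_5p,
      "bp, 3' =", x$overlap_3p, "bp\n")
  invisible(x)
}

# Force exact microhomology lengths at the two future junction points by
# editing single bases of the sequence (template-frame indices).
#
# 3' junction (D1 3' end joined to D2 3' end, fragment = D1-forward then
# rc(D2)): the last k3 bases of D1 must equal, base for base, the complement
# of D2's last k3 bases read inward, and the first base beyond the overlap on
# each side must break the match. The junction-proximal shared base is forced
# to C. The 5' junction (fragment = rc(D2) then D1-forward) is handled
# symmetrically with k5 bases.
plant_junction_overlaps <- function(seq, d1s, d1e, d2s, d2e, k5, k3) {
  mutate_away <- function(seq, i, avoid) {
    cur <- substr_at(seq, i, 1)
    repl <- setdiff(c("A", "C", "G", "T"), c(cur, avoid))[1]
    substr_at(seq, i) <- repl
    seq
  }
  ## 3' junction
  if (k3 >= 1) {
    substr_at(seq, d2e - k3 + 1) <- "G"  # complement = shared C at the junction
  }
  for (t in seq_len(k3) - 1) {
    substr_at(seq, d1e - t) <- comp_base(substr_at(seq, d2e - k3 + 1 + t, 1))
  }
  # stop the D1-side match right after the junction
  if (substr_at(seq, d1e + 1, 1) == comp_base(substr_at(seq, d2e - k3, 1))) {
    seq <- mutate_away(seq, d1e + 1, comp_base(substr_at(seq, d2e - k3, 1)))
  }
  # stop the D2-side match right before the overlap
  if (substr_at(seq, d1e - k3, 1) == comp_base(substr_at(seq, d2e + 1, 1))) {
    seq <- mutate_away(seq, d1e - k3, comp_base(substr_at(seq, d2e + 1, 1)))
  }
  ## 5' junction
  for (t in seq_len(k5) - 1) {
    substr_at(seq, d2s + t) <- comp_base(substr_at(seq, d1s + k5 - 1 - t, 1))
  }
  if (comp_base(substr_at(seq, d2s + k5, 1)) == substr_at(seq, d1s - 1, 1)) {
    seq <- mutate_away(seq, d2s + k5,
                       comp_base(substr_at(seq, d1s - 1, 1)))
  }
  if (substr_at(seq, d1s + k5, 1) == comp_base(substr_at(seq, d2s - 1, 1))) {
    seq <- mutate_away(seq, d2s - 1,
                       comp_base(substr_at(seq, d1s + k5, 1)))
  }
  seq
}

#' Signed-block composition of the candidate locus architectures
#'
#' The wild-type locus and the three mutant architectures consistent with the
#' junction evidence. `FM_1` carries the single-copy region inverted between
#' the junctions; `FM_2` places an inverted copy of the second duplicated
#' region between two direct copies of the first; `FM_3` appends the
#' inverted-joined copies after an intact wild-type run.
#'
#' @param scenario `"N"`, `"FM_1"`, `"FM_2"` or `"FM_3"`.
#' @return Character vector of signed internal-block tokens.
#' @export
scenario_blocks <- function(scenario) {
  switch(scenario,
    N    = c("+D1", "+S", "+D2"),
    FM_1 = c("+D1", "-D2", "-S", "-D1", "+D2"),
    FM_2 = c("+D1", "-D2", "+D1", "+S", "+D2"),
    FM_3 = c("+D1", "+S", "+D2", "-D1", "+D2"),
    stop("unknown scenario: ", scenario)
  )
}

signed_block_name <- function(token) substring(token, 2)
signed_block_sign <- function(token) substring(token, 1, 1)

# entry/exit end labels of a signed block in reference orientation
block_entry_end <- function(token) {
  b <- signed_block_name(token)
  if (b %in% c("L", "R")) return(b)
  paste0(b, if (signed_block_sign(token) == "+") ".5" else ".3")
}
block_exit_end <- function(token) {
  b <- signed_block_name(token)
  if (b %in% c("L", "R")) return(b)
  paste0(b, if (signed_block_sign(token) == "+") ".3" else ".5")
}

adjacency_key <- function(end_a, end_b) paste(sort(c(end_a, end_b)), collapse = "|")

novel_junction_type <- function(key) {
  if (key == adjacency_key("D1.5", "D2.5")) return("5p")
  if (key == adjacency_key("D1.3", "D2.3")) return("3p")
  NA_character_
}

#' Build a mutant (or wild-type) allele sequence from the reference
#'
#' Linearizes one of the candidate locus architectures into an explicit
#' template sequence. At each junction of the 5' ends of the two duplicated
#' regions, `overlap_5p` leading bases of the downstream piece are collapsed
#' into the junction (microhomology); likewise `overlap_3p` at each 3'-end
#' junction. With both overlaps zero the mutant allele length is exactly the
#' wild-type length plus the lengths of the two duplicated regions.
#'
#' @param ref An `fm_reference`.
#' @param scenario One of `"N"`, `"FM_1"`, `"FM_2"` (default; the architecture
#'   supported by recombinant analysis), `"FM_3"`.
#' @param overlap_5p,overlap_3p Microhomology collapsed at the novel junctions;
#'   defaults are the values planted in the reference.
#' @return An object of class `fm_allele`: scenario, signed block arrangement,
#'   template sequence, a piece table mapping template to reference
#'   coordinates, junction records, and a truth fragment (junction breakpoints,
#'   per-block copy numbers, overlaps).
#' @export
build_fm_allele <- function(ref, scenario = "FM_2",
                            overlap_5p = ref$overlap_5p,
                            overlap_3p = ref$overlap_3p) {
  stopifnot(inherits(ref, "fm_reference"))
  internal <- scenario_blocks(scenario)
  tokens <- c("+L", internal, "+R")
  idx <- function(pos) pos - ref$locus[1] + 1

  pieces <- NULL
  junctions <- list()
  t_cursor <- 0
  chunks <- character(length(tokens))
  for (i in seq_along(tokens)) {
    tok <- tokens[i]
    b <- signed_block_name(tok)
    sgn <- signed_block_sign(tok)
    span <- ref$blocks[[b]]
    piece_seq <- substr(ref$sequence, idx(span[1]), idx(span[2]))
    if (sgn == "-") piece_seq <- revcomp(piece_seq)
    drop <- 0
    if (i > 1) {
      key <- adjacency_key(block_exit_end(tokens[i - 1]), block_entry_end(tok))
      jt <- novel_junction_type(key)
      if (!is.na(jt)) {
        drop <- if (jt == "5p") overlap_5p else overlap_3p
        junctions[[length(junctions) + 1]] <- list(
          type = jt,
          template_pos = t_cursor,  # last base of the upstream piece
          overlap = drop,
          breakpoint_d1 = if (jt == "5p") ref$blocks$D1[1] else ref$blocks$D1[2],
          breakpoint_d2 = if (jt == "5p") ref$blocks$D2[1] else ref$blocks$D2[2]
        )
      }
    }
    if (drop > 0) piece_seq <- substring(piece_seq, drop + 1)
    ref_start <- span[1]
    ref_end <- span[2]
    if (drop > 0) {
      if (sgn == "+") ref_start <- ref_start + drop else ref_end <- ref_end - drop
    }
    pieces <- rbind(pieces, data.frame(
      block = b, sign = sgn, ref_start = ref_start, ref_end = ref_end,
      t_start = t_cursor + 1, t_end = t_cursor + nchar(piece_seq),
      stringsAsFactors = FALSE
    ))
    chunks[i] <- piece_seq
    t_cursor <- t_cursor + nchar(piece_seq)
  }
  sequence <- paste(chunks, collapse = "")

  counts <- table(factor(signed_block_name(internal), levels = c("D1", "S", "D2")))
  truth <- list(
    scenario = scenario,
    breakpoints = c(
      d1_start = ref$blocks$D1[1], d1_end = ref$blocks$D1[2],
      d2_start = ref$blocks$D2[1], d2_end = ref$blocks$D2[2]
    ),
    copy_number_per_allele = as.list(counts),
    junction_overlaps = list(`5p` = overlap_5p, `3p` = overlap_3p)
  )
  structure(
    list(scenario = scenario, arrangement = internal, chrom = ref$chrom,
         sequence = sequence, pieces = pieces, junctions = junctions,
         overlap_5p = overlap_5p, overlap_3p = overlap_3p, truth = truth),
    class = "fm_allele"
  )
}

#' @export
print.fm_allele <- function(x, ...) {
  cat("Synthetic allele", x$scenario, ":",
      paste(c("L", x$arrangement, "R"), collapse = " "), "\n")
  cat("  template length:", format(nchar(x$sequence), big.mark = ","), "bp;",
      length(x$junctions), "novel junction(s)\n")
  invisible(x)
}

#' Extract the template sequence around a novel junction
#'
#' Returns a fragment of the allele template centered on one of the two novel
#' junctions, emulating the sequenced PCR product spanning the breakpoint.
#'
#' @param allele An `fm_allele`.
#' @param which `"5p"` or `"3p"`.
#' @param flank Bases kept on each side of the junction point.
#' @return A character scalar of length `2 * flank` (clipped at template ends).
#' @export
junction_fragment <- function(allele, which = c("5p", "3p"), flank = 400) {
  which <- match.arg(which)
  hit <- Filter(function(j) j$type == which, allele$junctions)
  if (length(hit) == 0) stop("allele has no ", which, " junction")
  pos <- hit[[1]]$template_pos
  start <- max(1, pos - flank + 1)
  end <- min(nchar(allele$sequence), pos + flank)
  substr(allele$sequence, start, end)
}
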