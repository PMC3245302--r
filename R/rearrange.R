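#' Adjacency evidence sets for arrangement enumeration
#'
#' An adjacency is an orientation-aware, unordered pair of block ends
#' (`"D1.5"`, `"D1.3"`, ..., plus the flank tokens `"L"` and `"R"`).
#' `fm_adjacency_evidence()` is the junction-PCR evidence for the mutant
#' locus: all four wild-type boundary adjacencies are retained, and the only
#' novel junctions are 5'-to-5' and 3'-to-3' between the two duplicated
#' regions. `wt_adjacency_evidence()` is the wild-type boundary set alone.
#'
#' @return Character vector of adjacency keys (each `"end1|end2"`, ends
#'   sorted), with multiplicity.
#' @export
fm_adjacency_evidence <- function() {
  c(adjacency_key("L", "D1.5"),
    adjacency_key("D1.3", "S.5"),
    adjacency_key("S.3", "D2.5"),
    adjacency_key("D2.3", "R"),
    adjacency_key("D1.5", "D2.5"),
    adjacency_key("D1.3", "D2.3"))
}

#' @rdname fm_adjacency_evidence
#' @export
wt_adjacency_evidence <- function() {
  c(adjacency_key("L", "D1.5"),
    adjacency_key("D1.3", "S.5"),
    adjacency_key("S.3", "D2.5"),
    adjacency_key("D2.3", "R"))
}

# adjacency multiset of a signed internal-block sequence, flanks included
arrangement_adjacencies <- function(tokens) {
  full <- c("+L", tokens, "+R")
  vapply(seq_len(length(full) - 1), function(i) {
    adjacency_key(block_exit_end(full[i]), block_entry_end(full[i + 1]))
  }, character(1))
}

arrangement_copy_numbers <- function(tokens) {
  tab <- table(factor(signed_block_name(tokens), levels = c("D1", "S", "D2")))
  stats::setNames(as.integer(tab), names(tab))
}

has_novel_junction <- function(tokens) {
  novel <- c(adjacency_key("D1.5", "D2.5"), adjacency_key("D1.3", "D2.3"))
  any(arrangement_adjacencies(tokens) %in% novel)
}

#' Serialize a signed block arrangement
#'
#' @param tokens Signed block tokens, e.g. `c("+D1", "-D2", "+D1", "+S", "+D2")`.
#' @return A string like `"L +D1 -D2 +D1 +S +D2 R"`.
#' @export
arrangement_string <- function(tokens) {
  paste(c("L", tokens, "R"), collapse = " ")
}

revcomp_arrangement <- function(tokens) {
  flipped <- ifelse(substring(tokens, 1, 1) == "+",
                    paste0("-", substring(tokens, 2)),
                    paste0("+", substring(tokens, 2)))
  rev(flipped)
}

canonical_arrangement <- function(tokens) {
  a <- paste(tokens, collapse = " ")
  b <- paste(revcomp_arrangement(tokens), collapse = " ")
  if (a <= b) a else b
}

#' Enumerate all locus architectures consistent with adjacency evidence
#'
#' Exhaustive path enumeration from the left flank to the right flank through
#' the given block copies, consuming each adjacency of the evidence multiset
#' exactly once. Arrangements identical up to reverse complement of the whole
#' locus are de-duplicated. Under the mutant evidence (four wild-type
#' boundaries plus the two inverted junctions) and copies D1 x 2, S x 1,
#' D2 x 2, exactly three architectures exist.
#'
#' @param copies Named integer vector of internal-block copy numbers.
#' @param evidence Adjacency-key multiset; see [fm_adjacency_evidence()].
#' @return List of arrangements, each a character vector of signed block
#'   tokens (empty list when the evidence is infeasible).
#' @export
enumerate_arrangements <- function(copies = c(D1 = 2, S = 1, D2 = 2),
                                   evidence = fm_adjacency_evidence()) {
  n_internal <- sum(copies)
  if (length(evidence) != n_internal + 1) {
    stop("evidence multiset must hold exactly ", n_internal + 1, " adjacencies")
  }
  results <- list()
  dfs <- function(exposed, remaining_copies, remaining_ev, path) {
    for (u in unique(remaining_ev)) {
      ends <- strsplit(u, "|", fixed = TRUE)[[1]]
      # the adjacency can be entered from either of its two ends
      others <- c(if (ends[1] == exposed) ends[2],
                  if (ends[2] == exposed) ends[1])
      for (other in unique(others)) {
        ev2 <- remaining_ev[-match(u, remaining_ev)]
        if (other == "R") {
          if (length(ev2) == 0 && all(remaining_copies == 0)) {
            results[[length(results) + 1]] <<- path
          }
          next
        }
        if (other == "L") next
        parts <- strsplit(other, ".", fixed = TRUE)[[1]]
        b <- parts[1]; e <- parts[2]
        if (is.na(remaining_copies[b]) || remaining_copies[b] <= 0) next
        tok <- paste0(if (e == "5") "+" else "-", b)
        rc2 <- remaining_copies
        rc2[b] <- rc2[b] - 1
        dfs(block_exit_end(tok), rc2, ev2, c(path, tok))
      }
    }
  }
  dfs("L", copies, evidence, character(0))
  if (length(results) == 0) return(list())
  keys <- vapply(results, canonical_arrangement, character(1))
  results[!duplicated(keys)]
}

#' Label an arrangement by its defining structural property
#'
#' `FM_1`: the single-copy region sits inverted between the junctions (a
#' crossover pairing it with a wild-type chromosome is inversion-heterozygous,
#' hence dicentric/acentric loss). `FM_2`: an inverted copy of the second
#' duplicated region lies between two direct copies of the first. `FM_3`: the
#' wild-type run is intact and the inverted-joined copies follow it. `"N"` is
#' the wild-type single-copy arrangement.
#'
#' @param tokens Signed block tokens.
#' @return One of `"N"`, `"FM_1"`, `"FM_2"`, `"FM_3"`, or `NA`.
#' @export
classify_arrangement <- function(tokens) {
  key <- canonical_arrangement(tokens)
  for (sc in c("N", "FM_1", "FM_2", "FM_3")) {
    if (key == canonical_arrangement(scenario_blocks(sc))) return(sc)
  }
  NA_character_
}

#' Synthetic diagnostic primer set
#'
#' Outward-facing primers at the boundaries of the two duplicated regions,
#' with offsets placed so that the diagnostic products have the package's
#' reference sizes: assay A gives a 379 bp wild-type product across the first
#' duplication's 5' boundary and a 280 bp product across the 5'-to-5' mutant
#' junction; assay B gives 302 bp across the second duplication's 3' boundary
#' and 159 bp across the 3'-to-3' mutant junction. Primer sequences are not
#' modelled; placement is purely coordinate-based.
#'
#' @return Data frame: `name`, `block`, `end`, `offset`, `orientation`,
#'   `max_size`, `assay`.
#' @export
fm_diagnostic_primers <- function() {
  data.frame(
    name = c("232", "234", "200", "201", "202", "197"),
    block = c("L", "D1", "D2", "D2", "R", "D1"),
    end = c("3p", "5p", "5p", "3p", "5p", "3p"),
    offset = c(229, 150, 130, 100, 202, 59),
    orientation = "outward",
    max_size = 1000,
    assay = c("A", "A", "A", "B", "B", "B"),
    stringsAsFactors = FALSE
  )
}

#' In-silico PCR over a linearized arrangement
#'
#' Places every primer on every instance of its host block in the linearized
#' arrangement (block lengths from the reference; junction microhomology of a
#' few bases is ignored for sizing) and emits a product for every pair of
#' sites that face each other within the maximum amplicon size.
#'
#' @param tokens Signed internal-block tokens of the arrangement.
#' @param primers Primer table as from [fm_diagnostic_primers()].
#' @param ref An `fm_reference` supplying block lengths.
#' @return Data frame `primer_fwd`, `primer_rev`, `size` (bp), de-duplicated;
#'   zero rows when nothing amplifies.
#' @export
insilico_pcr <- function(tokens, primers = fm_diagnostic_primers(), ref) {
  stopifnot(inherits(ref, "fm_reference"))
  block_len <- vapply(ref$blocks, function(b) interval_length(b[1], b[2]),
                      numeric(1))
  full <- c("+L", tokens, "+R")
  lens <- block_len[signed_block_name(full)]
  ends <- cumsum(lens)
  starts <- ends - lens + 1
  if (any(primers$offset < 0)) stop("primer offsets must be non-negative")
  sites <- NULL
  for (p in seq_len(nrow(primers))) {
    pr <- primers[p, ]
    for (i in which(signed_block_name(full) == pr$block)) {
      sgn <- signed_block_sign(full[i])
      st <- starts[i]; en <- ends[i]
      if (pr$offset > lens[i]) stop("primer offset exceeds block length")
      at_left <- (pr$end == "5p") == (sgn == "+")
      if (at_left) {
        c_pos <- st + pr$offset - 1
        facing <- "L"
      } else {
        c_pos <- en - pr$offset + 1
        facing <- "R"
      }
      if (pr$orientation == "inward") facing <- if (facing == "L") "R" else "L"
      sites <- rbind(sites, data.frame(name = pr$name, pos = c_pos,
                                       facing = facing, max_size = pr$max_size,
                                       stringsAsFactors = FALSE))
    }
  }
  out <- NULL
  fwd <- sites[sites$facing == "R", , drop = FALSE]
  rev <- sites[sites$facing == "L", , drop = FALSE]
  for (i in seq_len(nrow(fwd))) {
    for (j in seq_len(nrow(rev))) {
      size <- rev$pos[j] - fwd$pos[i] + 1
      if (size >= 1 && size <= min(fwd$max_size[i], rev$max_size[j])) {
        out <- rbind(out, data.frame(primer_fwd = fwd$name[i],
                                     primer_rev = rev$name[j],
                                     size = size, stringsAsFactors = FALSE))
      }
    }
  }
  if (is.null(out)) {
    return(data.frame(primer_fwd = character(0), primer_rev = character(0),
                      size = numeric(0)))
  }
  out <- unique(out)
  rownames(out) <- NULL
  out[order(out$size), ]
}

#' Products of a single crossover between two chromosomes
#'
#' Models one crossover inside a shared block (by default the single-copy
#' region between the duplications). When the paired copies have opposite
#' orientations the exchange is inversion-heterozygous and yields
#' dicentric/acentric products: chromosomal loss. Otherwise the two reciprocal
#' products are returned with their block copy numbers, novel-junction
#' presence and marker provenance.
#'
#' @param arr_a,arr_b Signed-token arrangements of the two parents.
#' @param block Block within which the crossover occurs.
#' @return An object of class `fm_crossover`: `loss` flag; when viable,
#'   `products` (list of two token vectors, `a_left_b_right` first),
#'   `copy_numbers`, and `novel_junction` per product.
#' @export
crossover_products <- function(arr_a, arr_b, block = "S") {
  ia <- which(signed_block_name(arr_a) == block)[1]
  ib <- which(signed_block_name(arr_b) == block)[1]
  if (is.na(ia) || is.na(ib)) stop("block ", block, " absent from a parent")
  if (signed_block_sign(arr_a[ia]) != signed_block_sign(arr_b[ib])) {
    return(structure(list(loss = TRUE, block = block, products = NULL),
                     class = "fm_crossover"))
  }
  tail_b <- if (ib < length(arr_b)) arr_b[(ib + 1):length(arr_b)] else character(0)
  tail_a <- if (ia < length(arr_a)) arr_a[(ia + 1):length(arr_a)] else character(0)
  p1 <- c(arr_a[seq_len(ia)], tail_b)   # A left of the crossover, B right
  p2 <- c(arr_b[seq_len(ib)], tail_a)
  structure(list(
    loss = FALSE, block = block,
    products = list(a_left_b_right = p1, b_left_a_right = p2),
    copy_numbers = list(a_left_b_right = arrangement_copy_numbers(p1),
                        b_left_a_right = arrangement_copy_numbers(p2)),
    novel_junction = c(a_left_b_right = has_novel_junction(p1),
                       b_left_a_right = has_novel_junction(p2))
  ), class = "fm_crossover")
}

#' @export
print.fm_crossover <- function(x, ...) {
  if (x$loss) {
    cat("Crossover in", x$block,
        ": inversion-heterozygous pairing -> chromosomal loss\n")
  } else {
    cat("Crossover in", x$block, ": two viable products\n")
    for (nm in names(x$products)) {
      cat(" ", nm, ":", arrangement_string(x$products[[nm]]),
          if (x$novel_junction[[nm]]) "(carries novel junction)" else "", "\n")
    }
  }
  invisible(x)
}

#' Filter candidate arrangements by a recombinant observation
#'
#' Encodes the recombinant-offspring argument: an individual inheriting the
#' left part of a wild-type chromosome and the right part of a mutant
#' chromosome, via a crossover in the single-copy region. The dominant mutant
#' phenotype follows the rule "affected iff the chromosome carries either
#' novel junction". An arrangement survives when such a crossover is viable
#' and its wild-type-left product matches the observed phenotype/copy state.
#'
#' @param arrangements List of signed-token arrangements.
#' @param observation List: `recombinant` (was such an individual observed?),
#'   `phenotype` of the recombinant product -- `"wild_type"` requires no novel
#'   junction and single-copy state of both duplicated regions; `"any"` only
#'   requires viability.
#' @param block Crossover block.
#' @return The surviving subset of `arrangements`.
#' @export
consistent_scenarios <- function(arrangements,
                                 observation = list(recombinant = TRUE,
                                                    phenotype = "wild_type"),
                                 block = "S") {
  if (length(arrangements) == 0) stop("empty arrangement list")
  if (!isTRUE(observation$recombinant)) return(arrangements)
  wt <- scenario_blocks("N")
  keep <- vapply(arrangements, function(arr) {
    out <- crossover_products(wt, arr, block)
    if (out$loss) return(FALSE)
    prod <- out$products$a_left_b_right
    if (identical(observation$phenotype, "wild_type")) {
      cn <- arrangement_copy_numbers(prod)
      !has_novel_junction(prod) && cn[["D1"]] == 1 && cn[["D2"]] == 1
    } else {
      TRUE
    }
  }, logical(1))
  arrangements[keep]
}
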