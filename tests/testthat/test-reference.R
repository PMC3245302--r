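test_that("default block coordinates reproduce the published interval sizes", {
  ref <- default_ref()
  expect_equal(interval_length(ref$blocks$D1[1], ref$blocks$D1[2]), 128939)
  expect_equal(interval_length(ref$blocks$D2[1], ref$blocks$D2[2]), 172353)
  expect_equal(interval_gap(ref$blocks$D1[2], ref$blocks$D2[1]), 416671)
  expect_equal(bp_to_kb(interval_gap(ref$blocks$D1[2], ref$blocks$D2[1])), 417)
})

test_that("blocks tile the locus in order without gaps or overlaps", {
  ref <- default_ref()
  b <- do.call(rbind, ref$blocks)
  expect_equal(unname(b[1, 1]), ref$locus[1])
  expect_equal(unname(b[nrow(b), 2]), ref$locus[2])
  expect_true(all(b[-1, 1] == b[-nrow(b), 2] + 1))
  expect_equal(sum(b[, 2] - b[, 1] + 1), nchar(ref$sequence))
})

test_that("reference sequence is deterministic in the seed", {
  a <- tiny_ref(seed = 11)
  b <- tiny_ref(seed = 11)
  c <- tiny_ref(seed = 12)
  expect_identical(a$sequence, b$sequence)
  expect_false(identical(a$sequence, c$sequence))
})

test_that("misordered or overlapping blocks are rejected", {
  expect_error(build_reference(locus = c(1, 1000), d1 = c(500, 600),
                               d2 = c(550, 700)), "ordered")
  expect_error(build_reference(locus = c(1, 1000), d1 = c(700, 800),
                               d2 = c(100, 200)), "ordered")
})

test_that("allele length bookkeeping matches the planted overlaps", {
  ref <- default_ref()
  wt_len <- nchar(ref$sequence)
  d1 <- interval_length(ref$blocks$D1[1], ref$blocks$D1[2])
  d2 <- interval_length(ref$blocks$D2[1], ref$blocks$D2[2])
  al0 <- build_fm_allele(ref, "FM_2", overlap_3p = 0)
  expect_equal(nchar(al0$sequence), wt_len + d1 + d2)
  al1 <- build_fm_allele(ref, "FM_2", overlap_3p = 1)
  expect_equal(nchar(al1$sequence), wt_len + d1 + d2 - 1)
  expect_error(build_fm_allele(ref, "FM_9"), "unknown scenario")
})

test_that("all four wild-type boundary 60-mers survive in the mutant allele", {
  ref <- default_ref()
  al <- default_allele()
  idx <- function(p) p - ref$locus[1] + 1
  boundaries <- c(ref$blocks$D1[1], ref$blocks$D1[2],
                  ref$blocks$D2[1], ref$blocks$D2[2])
  for (b in boundaries) {
    kmer <- substr(ref$sequence, idx(b) - 29, idx(b) + 30)
    expect_true(grepl(kmer, al$sequence, fixed = TRUE))
  }
})

test_that("mutant allele conserves block copy numbers as exact substrings", {
  ref <- tiny_ref(overlap_3p = 0)   # zero overlap keeps every copy intact
  idx <- function(p) p - ref$locus[1] + 1
  block_seq <- function(b) substr(ref$sequence, idx(ref$blocks[[b]][1]),
                                  idx(ref$blocks[[b]][2]))
  count_occ <- function(pat, s) {
    sum(gregexpr(pat, s, fixed = TRUE)[[1]] > 0)
  }
  for (sc in c("FM_2", "FM_3")) {
    al <- build_fm_allele(ref, sc, overlap_3p = 0)
    for (b in c("D1", "D2")) {
      fwd <- count_occ(block_seq(b), al$sequence)
      rev <- count_occ(dermadup:::revcomp(block_seq(b)), al$sequence)
      expect_equal(fwd + rev, 2, info = paste(sc, b))
    }
    expect_equal(count_occ(block_seq("S"), al$sequence) +
                   count_occ(dermadup:::revcomp(block_seq("S")), al$sequence),
                 1, info = sc)
  }
})

test_that("the FM_2 arrangement places an inverted D2 between two direct D1 copies", {
  al <- default_allele()
  expect_identical(al$arrangement, c("+D1", "-D2", "+D1", "+S", "+D2"))
  expect_equal(length(al$junctions), 2)
  types <- vapply(al$junctions, `[[`, character(1), "type")
  expect_setequal(types, c("5p", "3p"))
})
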