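test_that("window depth counts reads by leftmost base and conserves totals", {
  pairs <- data.frame(chrom = "toy",
                      start1 = c(1005, 1010, 1500), end1 = c(1054, 1059, 1549),
                      strand1 = "+",
                      start2 = c(1020, 1030, 1600), end2 = c(1069, 1079, 1649),
                      strand2 = "+")
  pairs$distance <- abs(pairs$start1 - pairs$start2)
  dt <- window_depth(pairs, window_size = 1000, locus = c(1001, 3000))
  expect_equal(dt$count, c(6, 0))
  expect_equal(sum(dt$count), 6)
  # with no library total attached, per-million normalization sums to 1e6
  expect_equal(sum(dt$norm), 1e6)
  # empty set: all-zero track
  dt0 <- window_depth(pairs[0, ], window_size = 1000, locus = c(1001, 3000))
  expect_equal(dt0$count, c(0, 0))
  expect_error(window_depth(pairs, window_size = 0), "positive")
})

test_that("uniform coverage gives the expected windowed depth with low dispersion", {
  wt <- simulate_matepair_pool(default_ref(), pool_spec(seed = 202))
  dt <- window_depth(wt)
  interior <- dt$count[50:(nrow(dt) - 50)]   # clip edge effects
  expect_equal(mean(interior), 30 * 1000 / 50, tolerance = 0.05)
  expect_lt(sd(interior) / mean(interior), 0.1)
})

test_that("log2 fold change is zero for identical tracks and antisymmetric", {
  pools <- default_pools()
  a <- window_depth(pools$case)
  b <- window_depth(pools$ctrl)
  expect_true(all(log2_fold_change(a, a)$log2fc == 0))
  fc <- log2_fold_change(a, b)
  fc_swapped <- log2_fold_change(b, a)
  expect_equal(fc$log2fc, -fc_swapped$log2fc)
  b2 <- window_depth(pools$ctrl, window_size = 2000)
  expect_error(log2_fold_change(a, b2), "mismatch")
})

test_that("case/control fold change is ~2 in duplications and ~1 in the gap", {
  ref <- default_ref()
  pools <- default_pools()
  fc <- log2_fold_change(window_depth(pools$case), window_depth(pools$ctrl))
  inside <- function(b) fc$start >= b[1] & fc$end <= b[2]
  in_dup <- inside(ref$blocks$D1) | inside(ref$blocks$D2)
  expect_equal(median(2^fc$log2fc[in_dup]), 2, tolerance = 0.05)
  expect_equal(median(2^fc$log2fc[inside(ref$blocks$S)]), 1, tolerance = 0.05)
  gain <- call_depth_gain_regions(fc)
  expect_gte(nrow(gain), 2)
  expect_true(all(gain$start >= ref$blocks$D1[1] - 2000 &
                    gain$end <= ref$blocks$D2[2] + 2000))
})

test_that("wild-type pool yields zero SV candidates", {
  pools <- default_pools()
  expect_equal(nrow(candidate_sv_windows(pools$ctrl)), 0)
})

test_that("case-pool candidates sit at the junction flanks with inversion flags", {
  ref <- default_ref()
  pools <- default_pools()
  cand <- candidate_sv_windows(pools$case)
  expect_gt(nrow(cand), 0)
  near <- function(x, b, tol = 5000) abs(x - b) <= tol
  # every candidate window hugs a planted breakpoint
  at_flank <- near(cand$start, ref$blocks$D1[1]) |
    near(cand$start, ref$blocks$D1[2]) |
    near(cand$start, ref$blocks$D2[1]) | near(cand$start, ref$blocks$D2[2])
  expect_true(all(at_flank))
  # the 5' junction feature pairs D1's 5' area with D2's 5' area, inverted
  five <- cand[near(cand$start, ref$blocks$D1[1]), ]
  expect_gt(nrow(five), 0)
  expect_true(all(near(five$partner_start, ref$blocks$D2[1])))
  expect_true(all(five$inversion))
  # implied junction span matches the planted junction distance
  planted <- ref$blocks$D2[1] - ref$blocks$D1[1]
  expect_true(all(abs(five$median_distance - planted) <= 1500 + 5000))
})

test_that("raising the discordant fraction never adds candidates", {
  pools <- default_pools()
  starts <- lapply(c(0.1, 0.2, 0.4), function(f) {
    candidate_sv_windows(pools$case,
                         sv_params(min_discordant_fraction = f))$start
  })
  expect_true(all(starts[[2]] %in% starts[[1]]))
  expect_true(all(starts[[3]] %in% starts[[2]]))
})

test_that("windows below the pair-count floor are skipped", {
  pairs <- data.frame(chrom = "toy",
                      start1 = rep(1001, 5), end1 = rep(1050, 5), strand1 = "+",
                      start2 = rep(501001, 5), end2 = rep(501050, 5),
                      strand2 = "-")
  pairs$distance <- abs(pairs$start1 - pairs$start2)
  # five discordant pairs, but chrom stats make them extreme
  out <- candidate_sv_windows(pairs, sv_params(min_pairs_per_window = 10),
                              chrom_stats = c(2450, 300),
                              locus = c(1, 600000))
  expect_equal(nrow(out), 0)
  out2 <- candidate_sv_windows(pairs, sv_params(min_pairs_per_window = 5),
                               chrom_stats = c(2450, 300),
                               locus = c(1, 600000))
  expect_equal(nrow(out2), 1)
  expect_true(out2$inversion)
  expect_equal(out2$n_support, 5)
})
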