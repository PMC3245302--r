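test_that("group-wise delta is the per-marker difference of group means", {
  m <- matrix(rnorm(40), 10, 4, dimnames = list(sprintf("m%02d", 1:10), NULL))
  track <- groupwise_delta(m[, 1:2], m[, 3:4])
  expect_equal(track$track$delta,
               unname(rowMeans(m[, 1:2]) - rowMeans(m[, 3:4])))
  # identical groups: all zero
  track0 <- groupwise_delta(m[, 1:2], m[, 1:2])
  expect_true(all(track0$track$delta == 0))
  # singleton groups: plain difference
  tr1 <- groupwise_delta(m[, 1, drop = FALSE], m[, 3, drop = FALSE])
  expect_equal(tr1$track$delta, unname(m[, 1] - m[, 3]))
  expect_error(groupwise_delta(m[, 1:2], m[1:5, 3:4]), "marker")
})

test_that("noiseless cohort delta is +0.30 inside duplications and 0 outside", {
  ref <- default_ref()
  co <- simulate_array_cohort(ref, default_allele(),
                              array_cohort_spec(lrr_noise_sd = 0, seed = 3))
  track <- groupwise_delta(co)
  in_dup <- with(co$markers,
                 (pos >= ref$blocks$D1[1] & pos <= ref$blocks$D1[2]) |
                 (pos >= ref$blocks$D2[1] & pos <= ref$blocks$D2[2]))
  expect_true(all(track$track$delta[in_dup] == 0.30))
  expect_true(all(track$track$delta[!in_dup] == 0))
  regions <- call_elevated_regions(track)
  expect_equal(nrow(regions), 2)
  # noiseless classification is perfect: boundary error below marker spacing
  err <- dermadup:::boundary_errors(regions, co$truth$breakpoints)
  expect_lte(max(err$error), co$spec$marker_spacing)
})

test_that("region calling finds the two planted duplications on the default cohort", {
  co <- default_cohort()
  ref <- default_ref()
  regions <- call_elevated_regions(groupwise_delta(co))
  expect_equal(nrow(regions), 2)
  expect_true(regions$start[1] <= ref$blocks$D1[2] &&
                regions$end[1] >= ref$blocks$D1[1])
  expect_true(regions$start[2] <= ref$blocks$D2[2] &&
                regions$end[2] >= ref$blocks$D2[1])
  expect_true(all(regions$mean_delta > 0.25))
  expect_true(all(regions$boundary_lo <= regions$start &
                    regions$boundary_hi >= regions$end))
})

test_that("sub-threshold tracks and threshold ties yield no regions", {
  track <- groupwise_delta(matrix(0, 20, 2), matrix(0, 20, 2))
  expect_equal(nrow(call_elevated_regions(track)), 0)
  # a run exactly at the threshold counts as below it
  m <- matrix(0, 20, 2, dimnames = list(sprintf("m%02d", 1:20), NULL))
  m2 <- m; m2[6:15, ] <- -0.1          # delta becomes exactly +0.1
  track2 <- groupwise_delta(m, m2)
  expect_true(all(abs(track2$track$delta[6:15] - 0.1) < 1e-12))
  expect_equal(nrow(call_elevated_regions(track2)), 0)
})

test_that("wild-type-only contrasts rarely produce spurious regions", {
  ref <- default_ref()
  al <- default_allele()
  n_spurious <- 0L
  for (s in 1:100) {
    co <- simulate_array_cohort(ref, al,
                                array_cohort_spec(n_fm = 1, n_wt = 12, seed = s))
    wt <- cohort_ids(co, "WT")
    track <- groupwise_delta(co$lrr[, wt[1:6]], co$lrr[, wt[7:12]],
                             markers = co$markers)
    if (nrow(call_elevated_regions(track)) > 0) n_spurious <- n_spurious + 1L
  }
  expect_lte(n_spurious, 5)
})

test_that("fixed-heterozygosity scan recovers the planted PSV classes", {
  co <- default_cohort()
  hits <- fixed_het_scan(co)
  expect_equal(nrow(hits), 5)
  expect_equal(sum(hits$class == "fixed_reference"), 2)
  expect_equal(sum(hits$class == "segregating"), 3)
  expect_setequal(hits$id, co$truth$psv_marker_ids)
  # a carrier homozygous everywhere kills every hit
  gt <- co$genotypes
  gt[, cohort_ids(co, "FM")[1]] <- "AA"
  expect_equal(nrow(fixed_het_scan(gt, fm_ids = cohort_ids(co, "FM"),
                                   wt_ids = cohort_ids(co, "WT"),
                                   markers = co$markers)), 0)
  expect_error(fixed_het_scan(co$genotypes, fm_ids = character(0),
                              wt_ids = cohort_ids(co, "WT")), "empty")
})

test_that("missing carrier calls disqualify a marker unless strictness is relaxed", {
  co <- default_cohort()
  gt <- co$genotypes
  psv1 <- co$truth$psv_marker_ids[1]
  gt[psv1, cohort_ids(co, "FM")[1]] <- NA
  strict <- fixed_het_scan(gt, fm_ids = cohort_ids(co, "FM"),
                           wt_ids = cohort_ids(co, "WT"), markers = co$markers)
  expect_false(psv1 %in% strict$id)
  lax <- fixed_het_scan(gt, fm_ids = cohort_ids(co, "FM"),
                        wt_ids = cohort_ids(co, "WT"), markers = co$markers,
                        strict_missing = FALSE)
  expect_true(psv1 %in% lax$id)
})

test_that("shared-haplotype interval matches the planted identity block", {
  co <- default_cohort()
  sh <- shared_haplotype_interval(co)
  expect_equal(unname(sh$interval),
               unname(co$truth$shared_marker_interval))
  expect_error(shared_haplotype_interval(co, fm_ids = cohort_ids(co, "FM")[1]),
               "at least two")
})

test_that("a recombinant carrier shrinks the shared interval to the common core", {
  co <- default_cohort()
  gt <- co$genotypes
  markers <- co$markers
  fm <- cohort_ids(co, "FM")
  shared_ids <- markers$id[markers$pos >= co$truth$shared_marker_interval[1] &
                             markers$pos <= co$truth$shared_marker_interval[2]]
  # one carrier loses the last three shared markers to a recombinant flank
  broken <- tail(shared_ids, 3)
  flip <- function(g) ifelse(g == "AA", "BB", "AA")
  gt[broken, fm[1]] <- flip(gt[broken, fm[1]])
  sh <- shared_haplotype_interval(gt, fm_ids = fm, markers = markers)
  # brute force over all candidate intervals containing the PSV block
  identical_m <- apply(gt[, fm], 1, function(x) length(unique(x)) == 1)
  fixed_het <- apply(gt[, fm], 1, function(x) all(x == "AB"))
  runs <- rle(identical_m)
  ends <- cumsum(runs$lengths); starts <- ends - runs$lengths + 1
  k <- which(runs$values & starts <= which(fixed_het)[1] &
               ends >= which(fixed_het)[1])
  expect_equal(unname(sh$interval),
               c(markers$pos[starts[k]], markers$pos[ends[k]]))
  expect_lt(sh$interval[2], co$truth$shared_marker_interval[2])
})
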