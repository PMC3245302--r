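test_that("standard-curve efficiency reproduces the slope-to-percent mapping", {
  ct_for <- function(slope) 30 + slope * log10(2000 / 5^(0:6))
  eff <- function(slope) {
    fit_standard_curve(2000 / 5^(0:6), ct_for(slope))$efficiency_percent
  }
  expect_equal(round(eff(-3.3219)), 100)
  expect_equal(round(eff(-3.7762)), 92)
  expect_equal(round(eff(-3.1035)), 105)
})

test_that("QC accepts exactly the printed slope window", {
  sim <- function(slope) {
    template <- 2000 / 5^(0:6)
    fit_standard_curve(template, 30 + slope * log10(template))
  }
  expect_true(sim(-3.7762)$pass)
  expect_true(sim(-3.1035)$pass)
  expect_true(sim(-3.4)$pass)
  expect_false(sim(-3.8)$pass)
  expect_false(sim(-3.0)$pass)
  # correlation and paired-intercept criteria
  set.seed(2)
  template <- 2000 / 5^(0:6)
  noisy <- 30 + 3.32 * log10(1 / template) + rnorm(7, 0, 1.5)
  expect_false(fit_standard_curve(template, noisy)$checks[["correlation"]])
  expect_false(fit_standard_curve(template, 30 + 3.4 * log10(1 / template),
                                  paired_intercept = 32)$checks[["intercept"]])
  expect_error(fit_standard_curve(c(1, 1, 1), c(20, 21, 22)), "distinct")
})

test_that("noiseless copy-number estimates are exact for all genotype classes", {
  ct <- simulate_qpcr_ct(cn_qpcr_design(), noise_sd = 0)
  for (assay in c("Dup1", "Dup2")) {
    cn <- copy_number_ddct(ct, assay)
    expect_equal(cn$estimated_cn[cn$group == "WT"], rep(2, 5))
    expect_equal(cn$estimated_cn[cn$group == "HET"], rep(3, 3))
    expect_equal(cn$estimated_cn[cn$group == "HOM"], rep(4, 5))
    expect_true(all(cn$cn_min <= cn$estimated_cn & cn$estimated_cn <= cn$cn_max))
  }
  # calibrator against itself is exactly 2
  cal <- copy_number_ddct(ct, "Dup1")
  expect_equal(cal$estimated_cn[cal$sample == attr(ct, "calibrator")], 2)
  expect_error(copy_number_ddct(ct, "Dup1", calibrator_sample = "nope"),
               "calibrator")
  expect_error(copy_number_ddct(ct, "Dup1", reference_assay = "nope"),
               "reference")
})

test_that("noiseless heterozygote delta-Ct difference is -log2(3/2)", {
  ct <- simulate_qpcr_ct(cn_qpcr_design(), noise_sd = 0)
  dct <- function(s) {
    mean(ct$Ct[ct$sample == s & ct$assay == "Dup1"]) -
      mean(ct$Ct[ct$sample == s & ct$assay == "SOX5"])
  }
  expect_equal(dct("HET01") - dct("WT01"), -log2(3 / 2), tolerance = 1e-12)
})

test_that("planted expression contrasts are recovered exactly in noiseless mode", {
  ct <- simulate_qpcr_ct(expression_qpcr_design(c(EDN3 = 10)), noise_sd = 0)
  res <- relative_expression_ddct(ct, "EDN3", control_group = "N")
  expect_equal(res$fold_change, 10, tolerance = 1e-9)
  # the planted contrast shows up as ddCt = -log2(10)
  # identical groups: fold 1, p ~ 1
  ct1 <- simulate_qpcr_ct(expression_qpcr_design(c(GENE = 1)), noise_sd = 0)
  res1 <- relative_expression_ddct(ct1, "GENE", control_group = "N")
  expect_equal(res1$fold_change, 1)
  expect_gte(res1$p_value, 0.99)
  # a reference shift common to both groups cancels
  ct2 <- simulate_qpcr_ct(expression_qpcr_design(c(GENE = 2), baseline = 400),
                          noise_sd = 0)
  res2 <- relative_expression_ddct(ct2, "GENE", control_group = "N")
  expect_equal(res2$fold_change, 2, tolerance = 1e-9)
})

test_that("undetected targets are flagged rather than quantified", {
  design <- expression_qpcr_design(c(TYRP2 = 5))
  design$template[design$assay == "TYRP2" & design$group == "N"] <- NA
  ct <- simulate_qpcr_ct(design, noise_sd = 0)
  res <- relative_expression_ddct(ct, "TYRP2", control_group = "N")
  expect_false(res$detected)
  expect_true(is.na(res$fold_change))
})

test_that("ddCt estimates are invariant to per-sample additive Ct offsets", {
  set.seed(31)
  ct <- simulate_qpcr_ct(cn_qpcr_design(), seed = 8, noise_sd = 0.1)
  ect <- simulate_qpcr_ct(expression_qpcr_design(c(EDN3 = 10)), seed = 9,
                          noise_sd = 0.1)
  shift_per_sample <- function(tab) {
    offs <- stats::setNames(runif(length(unique(tab$sample)), -3, 3),
                            unique(tab$sample))
    tab$Ct <- tab$Ct + offs[tab$sample]
    tab
  }
  for (rep in 1:5) {
    cn0 <- copy_number_ddct(ct, "Dup1")
    cn1 <- copy_number_ddct(shift_per_sample(ct), "Dup1")
    expect_equal(cn1$estimated_cn, cn0$estimated_cn, tolerance = 1e-9)
    ex0 <- relative_expression_ddct(ect, "EDN3", control_group = "N")
    ex1 <- relative_expression_ddct(shift_per_sample(ect), "EDN3",
                                    control_group = "N")
    expect_equal(ex1$fold_change, ex0$fold_change, tolerance = 1e-9)
  }
})

test_that("multi-group comparisons use one-way ANOVA", {
  design <- expression_qpcr_design(c(G = 4))
  extra <- design[design$group == "FM", ]
  extra$group <- "FM2"
  extra$sample <- sub("FM", "X", extra$sample)
  extra$template <- extra$template / 2
  design3 <- rbind(design, extra)
  ct <- simulate_qpcr_ct(design3, seed = 3, noise_sd = 0.05)
  res <- relative_expression_ddct(ct, "G", control_group = "N")
  expect_setequal(res$test, "anova")
  expect_equal(nrow(res), 2)
  expect_lt(res$p_value[1], 0.05)
})
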