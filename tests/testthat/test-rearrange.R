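test_that("mutant evidence admits exactly the three known architectures", {
  arr <- enumerate_arrangements()
  expect_length(arr, 3)
  labels <- vapply(arr, classify_arrangement, character(1))
  expect_setequal(labels, c("FM_1", "FM_2", "FM_3"))
  # the named token sequences are recovered up to reverse complement
  for (sc in c("FM_1", "FM_2", "FM_3")) {
    expect_true(any(vapply(arr, function(a) {
      dermadup:::canonical_arrangement(a) ==
        dermadup:::canonical_arrangement(scenario_blocks(sc))
    }, logical(1))), info = sc)
  }
})

test_that("wild-type evidence admits only the single-copy arrangement", {
  arr <- enumerate_arrangements(c(D1 = 1, S = 1, D2 = 1),
                                wt_adjacency_evidence())
  expect_length(arr, 1)
  expect_equal(classify_arrangement(arr[[1]]), "N")
})

test_that("removing the 3'-3' junction from the evidence kills all arrangements", {
  ev <- fm_adjacency_evidence()
  ev <- ev[ev != dermadup:::adjacency_key("D1.3", "D2.3")]
  # keep the multiset size by doubling the wild-type D2 boundary; infeasible
  ev <- c(ev, dermadup:::adjacency_key("D2.3", "R"))
  expect_length(enumerate_arrangements(evidence = ev), 0)
  expect_error(enumerate_arrangements(evidence = ev[1:3]), "exactly")
})

test_that("every enumerated arrangement consumes the evidence multiset exactly", {
  ev <- fm_adjacency_evidence()
  for (a in enumerate_arrangements()) {
    expect_equal(sort(dermadup:::arrangement_adjacencies(a)), sort(ev))
    cn <- dermadup:::arrangement_copy_numbers(a)
    expect_equal(unname(cn[c("D1", "S", "D2")]), c(2L, 1L, 2L))
    # reverse complement preserves the adjacency multiset (the two flanks
    # swap roles under a whole-locus reverse complement)
    rc <- dermadup:::revcomp_arrangement(a)
    swap_flanks <- function(keys) {
      vapply(strsplit(keys, "|", fixed = TRUE), function(e) {
        e[e == "L"] <- "."; e[e == "R"] <- "L"; e[e == "."] <- "R"
        dermadup:::adjacency_key(e[1], e[2])
      }, character(1))
    }
    expect_equal(sort(swap_flanks(dermadup:::arrangement_adjacencies(rc))),
                 sort(dermadup:::arrangement_adjacencies(a)))
  }
})

test_that("diagnostic in-silico PCR reproduces the reference product sizes", {
  ref <- default_ref()
  wt <- insilico_pcr(scenario_blocks("N"), ref = ref)
  expect_setequal(wt$size, c(379, 302))
  fm <- insilico_pcr(scenario_blocks("FM_2"), ref = ref)
  # carriers retain all wild-type products and add both junction products,
  # so heterozygote and homozygote band patterns are identical
  expect_setequal(fm$size, c(379, 280, 302, 159))
  het_bands <- sort(unique(c(wt$size, fm$size)))
  expect_equal(het_bands, sort(fm$size))
})

test_that("a tandem-duplication primer pair yields no product on any arrangement", {
  ref <- default_ref()
  tandem <- data.frame(name = c("234", "197"), block = "D1",
                       end = c("5p", "3p"), offset = c(150, 59),
                       orientation = "outward", max_size = 1000,
                       stringsAsFactors = FALSE)
  expect_equal(nrow(insilico_pcr(scenario_blocks("N"), tandem, ref)), 0)
  expect_equal(nrow(insilico_pcr(scenario_blocks("FM_2"), tandem, ref)), 0)
})

test_that("wild-type diagnostic products appear in every mutant architecture", {
  ref <- default_ref()
  for (sc in c("FM_1", "FM_2", "FM_3")) {
    sizes <- insilico_pcr(scenario_blocks(sc), ref = ref)$size
    expect_true(all(c(379, 302) %in% sizes), info = sc)
  }
})

test_that("crossover with the inverted-S architecture loses the chromosome", {
  out <- crossover_products(scenario_blocks("N"), scenario_blocks("FM_1"))
  expect_true(out$loss)
  expect_null(out$products)
})

test_that("crossover with FM_3 retains both duplications in the recombinant", {
  out <- crossover_products(scenario_blocks("N"), scenario_blocks("FM_3"))
  expect_false(out$loss)
  cn <- out$copy_numbers$a_left_b_right
  expect_equal(unname(cn[c("D1", "D2")]), c(2L, 2L))
  expect_true(out$novel_junction[["a_left_b_right"]])
})

test_that("crossover between identical wild types reproduces both parents", {
  out <- crossover_products(scenario_blocks("N"), scenario_blocks("N"))
  expect_false(out$loss)
  expect_identical(out$products$a_left_b_right, scenario_blocks("N"))
  expect_identical(out$products$b_left_a_right, scenario_blocks("N"))
  expect_error(crossover_products(c("+D1", "+D2"), scenario_blocks("N")),
               "absent")
})

test_that("viable crossovers conserve total block copy number", {
  parents <- c(list(scenario_blocks("N")), enumerate_arrangements())
  for (i in seq_along(parents)) {
    for (j in seq_along(parents)) {
      out <- crossover_products(parents[[i]], parents[[j]])
      if (out$loss) next
      total_in <- dermadup:::arrangement_copy_numbers(parents[[i]]) +
        dermadup:::arrangement_copy_numbers(parents[[j]])
      total_out <- out$copy_numbers$a_left_b_right +
        out$copy_numbers$b_left_a_right
      expect_equal(total_out, total_in, info = paste(i, j))
    }
  }
})

test_that("the recombinant observation eliminates all but one architecture", {
  arr <- enumerate_arrangements()
  surv <- consistent_scenarios(arr)
  expect_length(surv, 1)
  expect_equal(classify_arrangement(surv[[1]]), "FM_2")
  # no recombinant: vacuous, all survive
  surv_all <- consistent_scenarios(arr, list(recombinant = FALSE))
  expect_length(surv_all, 3)
  # requiring only viability keeps the two non-loss architectures
  surv_any <- consistent_scenarios(arr, list(recombinant = TRUE,
                                             phenotype = "any"))
  expect_setequal(vapply(surv_any, classify_arrangement, character(1)),
                  c("FM_2", "FM_3"))
  expect_error(consistent_scenarios(list()), "empty")
})
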