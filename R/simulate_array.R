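#' Specification of a synthetic SNP-array cohort
#'
#' Parameters of the simulated genotyping cohort: group sizes, marker spacing,
#' the Log R ratio (LRR) model and the paralogous-sequence-variant (PSV)
#' markers that read as constitutive heterozygosity in duplication carriers.
#'
#' The LRR model is an additive mean shift per copy state (`lrr_shift_het` for
#' three copies, `lrr_shift_hom` for four, against a diploid baseline of 0)
#' with Gaussian noise -- deliberately more compressed than the ideal
#' `log2(CN/2)`, matching the attenuation real arrays show.
#'
#' @param n_fm,n_het,n_wt Individuals homozygous for the rearranged allele,
#'   heterozygous carriers, and wild types.
#' @param marker_spacing Distance between consecutive markers, bp.
#' @param lrr_noise_sd Per-marker, per-individual Gaussian noise SD.
#' @param lrr_shift_hom,lrr_shift_het Mean LRR elevation at in-duplication
#'   markers for four-copy and three-copy individuals.
#' @param psv_marker_count Markers inside the first duplicated region planted
#'   as PSVs (heterozygous in every carrier).
#' @param psv_fixed_reference How many of the PSVs are fixed for the reference
#'   allele in wild types (the rest segregate).
#' @param genotype_noise Probability that any genotype call is replaced by a
#'   random different call.
#' @param shared_interval Bounds of the haplotype shared identically by all
#'   homozygous carriers; `NULL` places it at the same offsets inside the first
#'   duplicated region as the published 75 kb haplotype.
#' @param seed Integer seed.
#' @return A list of class `fm_array_spec`.
#' @export
array_cohort_spec <- function(n_fm = 12, n_het = 0, n_wt = 12,
                              marker_spacing = 6000,
                              lrr_noise_sd = 0.15,
                              lrr_shift_hom = 0.30,
                              lrr_shift_het = 0.15,
                              psv_marker_count = 5,
                              psv_fixed_reference = 2,
                              genotype_noise = 0,
                              shared_interval = NULL,
                              seed = 1) {
  stopifnot(n_fm >= 0, n_het >= 0, n_wt >= 0, marker_spacing > 0,
            lrr_noise_sd >= 0, psv_marker_count >= 1,
            psv_fixed_reference <= psv_marker_count,
            genotype_noise >= 0, genotype_noise < 1)
  structure(as.list(environment()), class = "fm_array_spec")
}

#' Simulate a SNP-array cohort over the locus
#'
#' Generates genotype calls and Log R ratios for a cohort of duplication
#' homozygotes, heterozygous carriers and wild types, together with a truth
#' record. Carriers are called heterozygous at every planted PSV marker;
#' homozygous carriers additionally share an identical genotype vector across
#' the planted haplotype interval (homozygous founder genotypes at non-PSV
#' markers, so no spurious fixed heterozygosity arises there). In-duplication
#' markers receive the copy-state LRR shift; everything else has mean zero.
#'
#' @param ref An `fm_reference`.
#' @param allele An `fm_allele`; its per-allele block copy numbers define the
#'   truth copy numbers of carriers.
#' @param spec An `fm_array_spec`.
#' @return An object of class `fm_array_cohort` with elements `markers`
#'   (id/chrom/pos), `genotypes` and `lrr` (marker x individual matrices),
#'   `samples` (id/group), `spec` and `truth`.
#' @export
simulate_array_cohort <- function(ref, allele = build_fm_allele(ref),
                                  spec = array_cohort_spec()) {
  stopifnot(inherits(ref, "fm_reference"), inherits(spec, "fm_array_spec"))
  if (spec$n_fm + spec$n_het == 0 || spec$n_wt == 0) {
    stop("cohort needs at least one carrier and one wild-type individual")
  }
  pos <- seq(ref$locus[1], ref$locus[2], by = spec$marker_spacing)
  n_mark <- length(pos)
  markers <- data.frame(
    id = sprintf("snp%05d", seq_len(n_mark)),
    chrom = ref$chrom,
    pos = pos,
    stringsAsFactors = FALSE
  )
  d1 <- ref$blocks$D1; d2 <- ref$blocks$D2
  shared <- spec$shared_interval
  if (is.null(shared)) {
    shared <- c(d1[1] + 306, min(d1[1] + 75314, d1[2]))
  }
  in_shared <- pos >= shared[1] & pos <= shared[2]
  if (sum(in_shared) < spec$psv_marker_count) {
    stop("shared interval holds fewer markers than psv_marker_count")
  }
  psv_idx <- which(in_shared)[
    unique(round(seq(1, sum(in_shared), length.out = spec$psv_marker_count)))
  ]
  cn_allele <- unlist(build_cn(allele))
  dup_gain <- cn_allele[c("D1", "D2")] - 1   # extra copies per mutant allele

  ids <- c(sprintf("FM%02d", seq_len(spec$n_fm)),
           sprintf("HET%02d", seq_len(spec$n_het)),
           sprintf("WT%02d", seq_len(spec$n_wt)))
  groups <- rep(c("FM", "HET", "WT"), c(spec$n_fm, spec$n_het, spec$n_wt))
  n_ind <- length(ids)

  sim <- with_seed(spec$seed, {
    p_b <- runif(n_mark, 0.2, 0.8)          # per-marker B-allele frequency
    hwe_draw <- function(p, n) {
      g <- runif(n)
      ifelse(g < (1 - p)^2, "AA", ifelse(g < (1 - p)^2 + 2 * p * (1 - p), "AB", "BB"))
    }
    founder_hap <- ifelse(runif(n_mark) < p_b, "B", "A")  # carrier haplotype
    gt <- matrix(NA_character_, n_mark, n_ind, dimnames = list(markers$id, ids))
    for (j in seq_len(n_ind)) {
      gt[, j] <- hwe_draw(p_b, n_mark)
    }
    carriers <- groups != "WT"
    # identical founder genotype across the shared interval in homozygous
    # carriers; heterozygous carriers combine the founder haplotype with a
    # population allele
    hom_shared_gt <- ifelse(founder_hap == "B", "BB", "AA")
    for (j in which(groups == "FM")) {
      gt[in_shared, j] <- hom_shared_gt[in_shared]
    }
    for (j in which(groups == "HET")) {
      other <- ifelse(runif(n_mark) < p_b, "B", "A")
      pair <- paste0(pmin(founder_hap, other), pmax(founder_hap, other))
      het_gt <- ifelse(pair == "AB", "AB", ifelse(pair == "AA", "AA", "BB"))
      gt[in_shared, j] <- het_gt[in_shared]
    }
    # PSVs exist only when the allele actually duplicates D1: collapsed
    # paralogs read as heterozygous in every carrier; wild-type classes as
    # configured
    if (dup_gain[["D1"]] > 0) {
      fixed_ref_idx <- psv_idx[seq_len(spec$psv_fixed_reference)]
      seg_idx <- setdiff(psv_idx, fixed_ref_idx)
      gt[psv_idx, carriers] <- "AB"
      gt[fixed_ref_idx, !carriers] <- "AA"
      for (m in seg_idx) {
        gt[m, !carriers] <- hwe_draw(p_b[m], sum(!carriers))
        if (all(gt[m, !carriers] == "AA")) {     # guarantee segregation
          gt[m, which(!carriers)[1]] <- "AB"
        }
      }
    }
    if (spec$genotype_noise > 0) {
      flip <- matrix(runif(n_mark * n_ind) < spec$genotype_noise, n_mark, n_ind)
      alt <- matrix(sample(c("AA", "AB", "BB"), n_mark * n_ind, replace = TRUE),
                    n_mark, n_ind)
      gt[flip] <- alt[flip]
    }
    lrr <- matrix(rnorm(n_mark * n_ind, 0, spec$lrr_noise_sd), n_mark, n_ind,
                  dimnames = list(markers$id, ids))
    shift <- ifelse(groups == "FM", spec$lrr_shift_hom,
                    ifelse(groups == "HET", spec$lrr_shift_het, 0))
    for (b in c("D1", "D2")) {
      if (dup_gain[[b]] == 0) next     # no gain planted by this allele
      in_b <- pos >= ref$blocks[[b]][1] & pos <= ref$blocks[[b]][2]
      lrr[in_b, ] <- lrr[in_b, ] + rep(shift, each = sum(in_b))
    }
    list(gt = gt, lrr = lrr)
  })

  truth <- list(
    breakpoints = c(d1_start = d1[1], d1_end = d1[2],
                    d2_start = d2[1], d2_end = d2[2]),
    psv_marker_ids = if (dup_gain[["D1"]] > 0) markers$id[psv_idx] else character(0),
    psv_fixed_reference_ids = if (dup_gain[["D1"]] > 0) {
      markers$id[psv_idx[seq_len(spec$psv_fixed_reference)]]
    } else {
      character(0)
    },
    shared_interval = c(start = shared[1], end = shared[2]),
    shared_marker_interval = c(start = min(pos[in_shared]), end = max(pos[in_shared])),
    copy_number = data.frame(
      id = ids, group = groups,
      D1 = 2 + (cn_allele["D1"] - 1) * ifelse(groups == "FM", 2,
                                              ifelse(groups == "HET", 1, 0)),
      D2 = 2 + (cn_allele["D2"] - 1) * ifelse(groups == "FM", 2,
                                              ifelse(groups == "HET", 1, 0)),
      S = 2,
      stringsAsFactors = FALSE, row.names = NULL
    )
  )
  structure(
    list(markers = markers, genotypes = sim$gt, lrr = sim$lrr,
         samples = data.frame(id = ids, group = groups, stringsAsFactors = FALSE),
         spec = spec, truth = truth),
    class = "fm_array_cohort"
  )
}

# per-allele copy number of each internal block in an allele's arrangement
build_cn <- function(allele) {
  tab <- table(factor(signed_block_name(allele$arrangement),
                      levels = c("D1", "S", "D2")))
  as.list(tab)
}

#' @export
print.fm_array_cohort <- function(x, ...) {
  cat("Synthetic SNP-array cohort:", nrow(x$markers), "markers x",
      nrow(x$samples), "individuals (",
      paste(sprintf("%s=%d", names(table(x$samples$group)),
                    table(x$samples$group)), collapse = ", "), ")\n")
  cat("  marker spacing:", x$spec$marker_spacing, "bp; LRR noise SD:",
      x$spec$lrr_noise_sd, "\n")
  invisible(x)
}

#' Sample identifiers of one cohort group
#'
#' @param cohort An `fm_array_cohort`.
#' @param group `"FM"`, `"HET"` or `"WT"`.
#' @return Character vector of individual ids.
#' @export
cohort_ids <- function(cohort, group) {
  cohort$samples$id[cohort$samples$group == group]
}
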