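#' Configuration for a full pipeline run
#'
#' Bundles every stage's parameters with a single master seed. Per-stage
#' seeds are derived from the master seed so the whole run is reproducible
#' from one integer. Any component can be overridden.
#'
#' @param seed Master seed.
#' @param scenario Mutant architecture to plant.
#' @param array An `fm_array_spec`.
#' @param pool An `fm_pool_spec` (genotype-specific seeds are derived).
#' @param sv An `fm_sv_params`.
#' @param cbs An `fm_cbs_params`, or `NULL` to skip per-individual
#'   segmentation (the group-wise scan does not need it).
#' @param expression_fold Named planted expression fold changes.
#' @param qpcr_noise_sd Ct noise for the simulated plates.
#' @return A list of class `fm_run_config`.
#' @export
fm_run_config <- function(seed = 1, scenario = "FM_2",
                          array = NULL, pool = NULL, sv = sv_params(),
                          cbs = NULL,
                          expression_fold = c(EDN3 = 10),
                          qpcr_noise_sd = 0) {
  if (is.null(array)) array <- array_cohort_spec(seed = seed)
  if (is.null(pool)) pool <- pool_spec(seed = seed)
  structure(list(seed = seed, scenario = scenario, array = array, pool = pool,
                 sv = sv, cbs = cbs, expression_fold = expression_fold,
                 qpcr_noise_sd = qpcr_noise_sd),
            class = "fm_run_config")
}

#' Run the full discovery pipeline on synthetic data
#'
#' Executes simulate -> array scan -> pooled-sequencing scan -> junction
#' refinement -> arrangement enumeration/elimination -> qPCR quantification
#' as one reproducible run, and scores every stage against the planted truth.
#'
#' @param config An `fm_run_config`.
#' @param out_dir Optional directory; when given, the stage outputs are
#'   written there (TSV/BED/BEDPE/bedGraph/FASTA/JSON).
#' @return An object of class `fm_run_report`.
#' @export
run_fm_pipeline <- function(config = fm_run_config(), out_dir = NULL) {
  stopifnot(inherits(config, "fm_run_config"))
  s <- config$seed

  ref <- build_reference(seed = s)
  allele <- build_fm_allele(ref, config$scenario)

  ## --- SNP array -----------------------------------------------------------
  cohort <- simulate_array_cohort(ref, allele, config$array)
  track <- groupwise_delta(cohort)
  regions <- call_elevated_regions(track)
  boundary_err <- boundary_errors(regions, cohort$truth$breakpoints)
  fhet <- fixed_het_scan(cohort)
  shared <- if (length(cohort_ids(cohort, "FM")) >= 2 && nrow(fhet) > 0) {
    shared_haplotype_interval(cohort)
  } else {
    NULL
  }
  cbs_out <- NULL
  if (!is.null(config$cbs) && length(cohort_ids(cohort, "FM")) > 0) {
    id1 <- cohort_ids(cohort, "FM")[1]
    cbs_out <- cbs_segment(cohort$lrr[, id1], cohort$markers$pos, config$cbs)
  }

  ## --- pooled mate-pair sequencing ----------------------------------------
  pool_case <- config$pool; pool_case$seed <- s + 101
  pool_ctrl <- config$pool; pool_ctrl$seed <- s + 202
  mp_case <- simulate_matepair_pool(allele, pool_case)
  mp_ctrl <- simulate_matepair_pool(ref, pool_ctrl)
  dt_case <- window_depth(mp_case, config$sv$window_size)
  dt_ctrl <- window_depth(mp_ctrl, config$sv$window_size)
  fc <- log2_fold_change(dt_case, dt_ctrl)
  gain <- call_depth_gain_regions(fc)
  cand <- candidate_sv_windows(mp_case, config$sv)
  in_dup <- windows_inside(fc, ref$blocks$D1) | windows_inside(fc, ref$blocks$D2)
  in_gap <- windows_inside(fc, ref$blocks$S)
  fc_summary <- c(
    median_fold_in_duplications = median(2^fc$log2fc[in_dup]),
    median_fold_single_copy_gap = median(2^fc$log2fc[in_gap])
  )
  jc <- if (length(allele$junctions) > 0) {
    list(`5p` = refine_junction(junction_fragment(allele, "5p"), ref),
         `3p` = refine_junction(junction_fragment(allele, "3p"), ref))
  } else {
    list()
  }

  ## --- rearrangement logic -------------------------------------------------
  arrangements <- enumerate_arrangements()
  surviving <- consistent_scenarios(arrangements)
  pcr <- lapply(stats::setNames(nm = c("N", config$scenario)), function(sc) {
    insilico_pcr(scenario_blocks(sc), fm_diagnostic_primers(), ref)
  })

  ## --- qPCR ----------------------------------------------------------------
  cn_ct <- simulate_qpcr_ct(cn_qpcr_design(), seed = s + 301,
                            noise_sd = config$qpcr_noise_sd)
  cn <- copy_number_ddct(cn_ct, "Dup1")
  expr_ct <- simulate_qpcr_ct(
    expression_qpcr_design(fold_changes = config$expression_fold),
    seed = s + 302, noise_sd = config$qpcr_noise_sd
  )
  expr <- do.call(rbind, lapply(names(config$expression_fold), function(g) {
    relative_expression_ddct(expr_ct, g, control_group = "N")
  }))

  report <- structure(list(
    config = config,
    package_version = as.character(utils::packageVersion("dermadup")),
    truth = cohort$truth,
    array = list(regions = regions, boundary_errors = boundary_err,
                 fixed_het = fhet, shared_haplotype = shared, cbs = cbs_out),
    pools = list(fold_change_summary = fc_summary, depth_gain = gain,
                 sv_candidates = cand, junctions = jc),
    rearrangement = list(
      n_enumerated = length(arrangements),
      enumerated = vapply(arrangements, arrangement_string, character(1)),
      surviving = vapply(surviving, arrangement_string, character(1)),
      surviving_labels = vapply(surviving, classify_arrangement, character(1)),
      diagnostic_pcr = pcr
    ),
    qpcr = list(copy_number = cn, expression = expr),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  ), class = "fm_run_report")

  if (!is.null(out_dir)) write_run_outputs(report, cohort, mp_case, mp_ctrl,
                                           dt_case, dt_ctrl, fc, ref, allele,
                                           out_dir)
  report
}

windows_inside <- function(track, block) {
  track$start >= block[1] & track$end <= block[2]
}

# absolute error of each estimated duplication boundary against the planted
# breakpoints, matching regions to duplications by overlap
boundary_errors <- function(regions, breakpoints) {
  if (nrow(regions) == 0) return(NULL)
  dups <- list(D1 = breakpoints[c("d1_start", "d1_end")],
               D2 = breakpoints[c("d2_start", "d2_end")])
  out <- NULL
  for (nm in names(dups)) {
    bp <- dups[[nm]]
    ov <- regions$start <= bp[2] & regions$end >= bp[1]
    if (!any(ov)) next
    rg <- regions[which(ov)[1], ]
    out <- rbind(out, data.frame(
      duplication = nm,
      boundary = c("start", "end"),
      estimate = c(rg$boundary_lo, rg$boundary_hi),
      truth = unname(bp),
      error = c(abs(rg$boundary_lo - bp[1]), abs(rg$boundary_hi - bp[2])),
      stringsAsFactors = FALSE
    ))
  }
  out
}

write_run_outputs <- function(report, cohort, mp_case, mp_ctrl,
                              dt_case, dt_ctrl, fc, ref, allele, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(out_dir, ...)
  write_marker_matrix_tsv(cohort$lrr, cohort$markers, p("lrr.tsv"))
  write_marker_matrix_tsv(cohort$genotypes, cohort$markers, p("genotypes.tsv"))
  write_fasta(c(reference = ref$sequence, allele = allele$sequence),
              p("sequences.fasta"))
  write_bedpe(mp_case, p("pool_case.bedpe"))
  write_bedpe(mp_ctrl, p("pool_control.bedpe"))
  write_bedgraph(dt_case, p("depth_case.bedgraph"), chrom = ref$chrom)
  write_bedgraph(dt_ctrl, p("depth_control.bedgraph"), chrom = ref$chrom)
  write_bedgraph(fc, p("log2fc.bedgraph"), value = "log2fc", chrom = ref$chrom)
  if (nrow(report$array$regions) > 0) {
    bed <- data.frame(chrom = ref$chrom, start = report$array$regions$start,
                      end = report$array$regions$end)
    write_bed(bed, p("elevated_regions.bed"))
  }
  write_truth_json(report$truth, p("truth.json"))
  write_report_json(report, p("report.json"))
  invisible(out_dir)
}

#' Serialize a run report to JSON
#'
#' Identical configurations and seeds reproduce the report byte-identically
#' apart from the timestamp field.
#'
#' @param report An `fm_run_report`.
#' @param file Path.
#' @export
write_report_json <- function(report, file) {
  x <- unclass(report)
  x$config <- lapply(unclass(x$config), function(el) {
    if (is.list(el)) unclass(el) else el
  })
  x$pools$junctions <- lapply(x$pools$junctions, unclass)
  jsonlite::write_json(x, file, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", force = TRUE)
  invisible(file)
}

#' @export
print.fm_run_report <- function(x, ...) {
  cat("Pipeline run (seed", x$config$seed, ", scenario",
      x$config$scenario, ")\n")
  cat("  array: ", nrow(x$array$regions), " elevated region(s), ",
      nrow(x$array$fixed_het), " fixed-het marker(s)\n", sep = "")
  if (!is.null(x$array$boundary_errors)) {
    cat("  max boundary error:", max(x$array$boundary_errors$error), "bp\n")
  }
  cat(sprintf("  pools: median fold %.2f in duplications, %.2f in gap; %d SV candidate window(s)\n",
              x$pools$fold_change_summary[1], x$pools$fold_change_summary[2],
              nrow(x$pools$sv_candidates)))
  if (length(x$pools$junctions) > 0) {
    cat("  junction microhomology: 5' =",
        x$pools$junctions$`5p`$microhomology_len, "bp, 3' =",
        x$pools$junctions$`3p`$microhomology_len, "bp\n")
  }
  cat("  arrangements:", x$rearrangement$n_enumerated, "enumerated ->",
      paste(x$rearrangement$surviving_labels, collapse = ", "), "surviving\n")
  invisible(x)
}
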