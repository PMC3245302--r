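#' Simulate a qPCR Ct table from a plated design
#'
#' In noiseless mode the threshold cycle is
#' `Ct = intercept - slope_factor * log2(template)`; `slope_factor = 1`
#' corresponds to 100% amplification efficiency (perfect doubling per cycle).
#' Gaussian noise of SD `noise_sd` is added per well. A missing or zero
#' template yields an undetected well (`NA` Ct).
#'
#' @param design Data frame with columns `sample`, `group`, `assay`,
#'   `template` (relative template amount; genomic copies for copy-number
#'   assays, transcript abundance for expression assays). Optional columns
#'   `n_rep` (technical replicates, default 3) and `intercept` override the
#'   defaults row-wise. Attributes set by the design constructors
#'   (`reference_assay`, `calibrator`) are carried through.
#' @param seed Integer seed.
#' @param noise_sd Per-well Ct noise SD (0 = noiseless).
#' @param intercept Default Ct at one template unit.
#' @param slope_factor Cycles per template doubling.
#' @return Data frame `sample`, `group`, `assay`, `replicate`, `Ct`.
#' @export
simulate_qpcr_ct <- function(design, seed = 1, noise_sd = 0,
                             intercept = 30, slope_factor = 1) {
  stopifnot(all(c("sample", "group", "assay", "template") %in% names(design)))
  n_rep <- if ("n_rep" %in% names(design)) design$n_rep else rep(3L, nrow(design))
  icpt <- if ("intercept" %in% names(design)) design$intercept else
    rep(intercept, nrow(design))
  idx <- rep(seq_len(nrow(design)), n_rep)
  out <- data.frame(
    sample = design$sample[idx],
    group = design$group[idx],
    assay = design$assay[idx],
    replicate = unlist(lapply(n_rep, seq_len)),
    stringsAsFactors = FALSE
  )
  template <- design$template[idx]
  ct0 <- ifelse(is.na(template) | template <= 0, NA_real_,
                icpt[idx] - slope_factor * log2(template))
  noise <- with_seed(seed, rnorm(nrow(out), 0, noise_sd))
  out$Ct <- ct0 + ifelse(is.na(ct0), 0, noise)
  attr(out, "reference_assay") <- attr(design, "reference_assay")
  attr(out, "calibrator") <- attr(design, "calibrator")
  out
}

#' Design of a genomic copy-number qPCR plate
#'
#' Target amplicons lie inside the duplicated regions (2 genomic copies in
#' wild types, 3 in heterozygous carriers, 4 in duplication homozygotes); the
#' reference amplicon is at two copies in everyone; the calibrator is a
#' wild-type individual of known diploid state.
#'
#' @param n_wt,n_het,n_hom Individuals per genotype class.
#' @param target_assays Names of in-duplication amplicons.
#' @param reference_assay Name of the two-copy reference amplicon.
#' @param calibrator Sample id used as calibrator (defaults to the first
#'   wild type).
#' @return A design data frame for [simulate_qpcr_ct()], with
#'   `reference_assay` and `calibrator` attributes.
#' @export
cn_qpcr_design <- function(n_wt = 5, n_het = 3, n_hom = 5,
                           target_assays = c("Dup1", "Dup2"),
                           reference_assay = "SOX5",
                           calibrator = NULL) {
  stopifnot(n_wt >= 1)
  samples <- data.frame(
    sample = c(sprintf("WT%02d", seq_len(n_wt)),
               sprintf("HET%02d", seq_len(n_het)),
               sprintf("HOM%02d", seq_len(n_hom))),
    group = rep(c("WT", "HET", "HOM"), c(n_wt, n_het, n_hom)),
    copies = rep(c(2, 3, 4), c(n_wt, n_het, n_hom)),
    stringsAsFactors = FALSE
  )
  rows <- lapply(c(target_assays, reference_assay), function(a) {
    data.frame(sample = samples$sample, group = samples$group, assay = a,
               template = if (a == reference_assay) 2 else samples$copies,
               stringsAsFactors = FALSE)
  })
  design <- do.call(rbind, rows)
  attr(design, "reference_assay") <- reference_assay
  attr(design, "calibrator") <- if (is.null(calibrator)) samples$sample[1] else calibrator
  design
}

#' Design of a relative-expression qPCR plate
#'
#' Plants a per-gene expression fold change in the carrier group against the
#' control group, with an invariant reference gene, emulating the tissue
#' panels used to show upregulation of the genes inside the first duplicated
#' region (about 10-fold for the endothelin gene in adult carrier skin).
#'
#' @param fold_changes Named numeric vector: planted carrier/control fold
#'   change per gene.
#' @param reference_gene Invariant normalizer gene.
#' @param n_per_group Biological replicates per group.
#' @param groups Two group labels, control last.
#' @param baseline Control-group template level.
#' @return A design data frame with a `reference_assay` attribute.
#' @export
expression_qpcr_design <- function(fold_changes = c(EDN3 = 10),
                                   reference_gene = "GAPDH",
                                   n_per_group = 3,
                                   groups = c("FM", "N"),
                                   baseline = 100) {
  stopifnot(length(groups) == 2, all(fold_changes > 0))
  samples <- data.frame(
    sample = c(sprintf("%s%02d", groups[1], seq_len(n_per_group)),
               sprintf("%s%02d", groups[2], seq_len(n_per_group))),
    group = rep(groups, each = n_per_group),
    stringsAsFactors = FALSE
  )
  rows <- lapply(names(fold_changes), function(g) {
    data.frame(sample = samples$sample, group = samples$group, assay = g,
               template = baseline *
                 ifelse(samples$group == groups[1], fold_changes[[g]], 1),
               stringsAsFactors = FALSE)
  })
  rows[[length(rows) + 1]] <- data.frame(
    sample = samples$sample, group = samples$group, assay = reference_gene,
    template = baseline, stringsAsFactors = FALSE
  )
  design <- do.call(rbind, rows)
  attr(design, "reference_assay") <- reference_gene
  design
}
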