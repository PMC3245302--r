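#' Fit and QC a qPCR standard curve
#'
#' Least-squares fit of Ct against log10 template over a dilution series.
#' QC passes when the slope lies inside the accepted window, the correlation
#' exceeds `min_r`, and (when a paired simplex/duplex curve is supplied) the
#' y-intercepts differ by less than `max_intercept_diff`.
#'
#' Efficiency is reported as percent of perfect doubling,
#' `100 * 10^(-1/slope) / 2`, the convention under which the accepted slope
#' window \[-3.7762, -3.1035\] maps to 92-105%; the textbook exponential-phase
#' efficiency `(10^(-1/slope) - 1) * 100` is also reported as a secondary
#' field.
#'
#' @param template Template amounts of the dilution points (>= 3 distinct).
#' @param ct Mean Ct per dilution point.
#' @param paired_intercept Optional y-intercept of the paired curve.
#' @param slope_range Accepted slope window.
#' @param min_r Minimum absolute correlation.
#' @param max_intercept_diff Maximum |y-intercept difference| vs the paired
#'   curve.
#' @return An object of class `fm_std_curve`: `slope`, `intercept`, `r`,
#'   `efficiency_percent`, `efficiency_standard`, `pass`, and the per-check
#'   results in `checks`.
#' @export
fit_standard_curve <- function(template, ct, paired_intercept = NULL,
                               slope_range = c(-3.7762, -3.1035),
                               min_r = 0.995, max_intercept_diff = 1) {
  stopifnot(length(template) == length(ct))
  if (length(unique(template)) < 3) {
    stop("need at least 3 distinct dilution points")
  }
  if (any(template <= 0)) stop("template amounts must be positive")
  fit <- lm(ct ~ log10(template))
  slope <- unname(coef(fit)[2])
  intercept <- unname(coef(fit)[1])
  r <- abs(stats::cor(log10(template), ct))
  eff <- 100 * 10^(-1 / slope) / 2
  eff_std <- (10^(-1 / slope) - 1) * 100
  tol <- 1e-8   # accepted window is inclusive of its printed endpoints
  checks <- c(
    slope = slope >= slope_range[1] - tol && slope <= slope_range[2] + tol,
    correlation = r > min_r,
    intercept = is.null(paired_intercept) ||
      abs(intercept - paired_intercept) < max_intercept_diff
  )
  structure(list(slope = slope, intercept = intercept, r = r,
                 efficiency_percent = eff, efficiency_standard = eff_std,
                 pass = all(checks), checks = checks,
                 n_points = length(unique(template))),
            class = "fm_std_curve")
}

#' @export
print.fm_std_curve <- function(x, ...) {
  cat(sprintf("Standard curve: slope %.4f, intercept %.2f, R %.4f\n",
              x$slope, x$intercept, x$r))
  cat(sprintf("  efficiency %.0f%% of perfect doubling (%.0f%% standard form)\n",
              x$efficiency_percent, x$efficiency_standard))
  cat("  QC:", if (x$pass) "PASS" else
    paste("FAIL (", paste(names(x$checks)[!x$checks], collapse = ", "), ")"), "\n")
  invisible(x)
}

mean_ct <- function(ct, sample, assay) {
  v <- ct$Ct[ct$sample == sample & ct$assay == assay]
  if (length(v) == 0) return(NA_real_)
  mean(v)
}

#' Genomic copy number by the delta-delta-Ct method
#'
#' For each sample, the target Ct is first normalized to the reference assay
#' within sample (`dCt = Ct_target - Ct_reference`), then to a calibrator of
#' known copy number: `CN = calibrator_cn * 2^-(dCt_sample - dCt_calibrator)`.
#' The replicate-wise minimum and maximum come from recomputing the estimate
#' per matched technical replicate.
#'
#' @param ct A Ct table (`sample`, `assay`, `replicate`, `Ct`).
#' @param target_assay,reference_assay Assay names.
#' @param calibrator_sample Sample of known copy state; defaults to the
#'   table's `calibrator` attribute.
#' @param calibrator_cn Known copies of the target in the calibrator.
#' @return Data frame `sample`, `group`, `estimated_cn`, `cn_min`, `cn_max`.
#' @export
copy_number_ddct <- function(ct, target_assay,
                             reference_assay = attr(ct, "reference_assay"),
                             calibrator_sample = attr(ct, "calibrator"),
                             calibrator_cn = 2) {
  if (is.null(reference_assay) || !(reference_assay %in% ct$assay)) {
    stop("reference assay missing from the Ct table")
  }
  if (is.null(calibrator_sample) || !(calibrator_sample %in% ct$sample)) {
    stop("calibrator sample missing from the Ct table")
  }
  samples <- unique(ct$sample[ct$assay == target_assay])
  dct_cal <- mean_ct(ct, calibrator_sample, target_assay) -
    mean_ct(ct, calibrator_sample, reference_assay)
  if (is.na(dct_cal)) stop("calibrator has no usable replicates")
  rows <- lapply(samples, function(s) {
    dct <- mean_ct(ct, s, target_assay) - mean_ct(ct, s, reference_assay)
    cn <- calibrator_cn * 2^(-(dct - dct_cal))
    # replicate-wise recomputation, pairing target and reference replicates
    tt <- ct[ct$sample == s & ct$assay == target_assay, ]
    rr <- ct[ct$sample == s & ct$assay == reference_assay, ]
    common <- intersect(tt$replicate, rr$replicate)
    reps <- vapply(common, function(k) {
      d <- tt$Ct[tt$replicate == k] - rr$Ct[rr$replicate == k]
      calibrator_cn * 2^(-(d - dct_cal))
    }, numeric(1))
    grp <- ct$group[ct$sample == s][1]
    data.frame(sample = s, group = if (is.null(grp)) NA else grp,
               estimated_cn = cn,
               cn_min = if (length(reps)) min(reps) else cn,
               cn_max = if (length(reps)) max(reps) else cn,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Relative expression by the delta-delta-Ct method, with group statistics
#'
#' Per-sample expression is normalized to a reference gene
#' (`dCt = Ct_gene - Ct_reference`); group fold change against the control
#' group is `2^-(mean dCt_group - mean dCt_control)`. The confidence interval
#' is a normal-theory (Welch) interval on the mean delta-delta-Ct,
#' back-transformed through `2^-x`. Two groups are compared by unpaired
#' t-test; more than two by one-way ANOVA. A gene with no detected signal in
#' a group is flagged rather than quantified.
#'
#' @param ct A Ct table.
#' @param gene Target gene assay name.
#' @param reference_gene Normalizer assay name.
#' @param control_group Group the fold change is expressed against.
#' @param conf_level Confidence level of the interval.
#' @return Data frame with one row per non-control group: `gene`, `group`,
#'   `fold_change`, `ci_lo`, `ci_hi`, `p_value`, `test`, `detected`.
#' @export
relative_expression_ddct <- function(ct, gene,
                                     reference_gene = attr(ct, "reference_assay"),
                                     control_group, conf_level = 0.95) {
  if (is.null(reference_gene) || !(reference_gene %in% ct$assay)) {
    stop("reference gene missing from the Ct table")
  }
  samples <- unique(ct[, c("sample", "group")])
  if (!(control_group %in% samples$group)) stop("control group is empty")
  dct <- vapply(seq_len(nrow(samples)), function(i) {
    mean_ct(ct, samples$sample[i], gene) -
      mean_ct(ct, samples$sample[i], reference_gene)
  }, numeric(1))
  samples$dct <- dct
  groups <- unique(samples$group)
  test_groups <- setdiff(groups, control_group)
  dct_c <- samples$dct[samples$group == control_group]
  multi <- length(groups) > 2
  p_anova <- NA_real_
  if (multi && !anyNA(samples$dct)) {
    p_anova <- tryCatch(
      summary(aov(dct ~ group, data = samples))[[1]][["Pr(>F)"]][1],
      error = function(e) NA_real_)
  }
  rows <- lapply(test_groups, function(g) {
    dct_g <- samples$dct[samples$group == g]
    if (anyNA(dct_g) || anyNA(dct_c)) {
      return(data.frame(gene = gene, group = g, control_group = control_group,
                        fold_change = NA_real_, ci_lo = NA_real_,
                        ci_hi = NA_real_, p_value = NA_real_,
                        test = "none", detected = FALSE,
                        stringsAsFactors = FALSE))
    }
    ddct <- mean(dct_g) - mean(dct_c)
    n_g <- length(dct_g); n_c <- length(dct_c)
    se <- sqrt(var(dct_g) / n_g + var(dct_c) / n_c)
    if (!is.finite(se)) se <- 0
    if (se > 0) {
      dfw <- se^4 / ((var(dct_g) / n_g)^2 / (n_g - 1) +
                     (var(dct_c) / n_c)^2 / (n_c - 1))
      tq <- qt(1 - (1 - conf_level) / 2, dfw)
    } else {
      tq <- 0
    }
    if (multi) {
      p <- p_anova; test <- "anova"
    } else {
      test <- "t-test"
      p <- if (se == 0) {
        # degenerate noiseless case: identical means are indistinguishable,
        # different means are separated with certainty
        if (isTRUE(all.equal(mean(dct_g), mean(dct_c)))) 1 else 0
      } else {
        t.test(dct_g, dct_c)$p.value
      }
    }
    data.frame(gene = gene, group = g, control_group = control_group,
               fold_change = 2^(-ddct),
               ci_lo = 2^(-(ddct + tq * se)),
               ci_hi = 2^(-(ddct - tq * se)),
               p_value = p, test = test, detected = TRUE,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
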