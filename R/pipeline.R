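# Orchestration: calibration -> scaling -> evaluation -> report.
#
# Each stage consumes and returns the package's plain data.frame contracts
# (artifact-tsv on disk), so stages are independently runnable and testable.

summary_to_rows <- function(s, family, dataset) {
  stats_rows <- data.frame(
    family = family, dataset = dataset,
    allele = c("Mean", "SD"),
    rbind(s$mean, s$sd),
    stringsAsFactors = FALSE
  )
  per <- data.frame(family = family, dataset = dataset,
                    s$per_allele, stringsAsFactors = FALSE)
  rows <- rbind(per[, names(stats_rows)], stats_rows)
  rownames(rows) <- NULL
  rows
}

#' Calibrate eluted-ligand thresholds and benchmark them
#'
#' Derives common and allele-specific thresholds at `target_sensitivity`
#' from the scored ligands, for both the EL-rank and IC50 metrics, and
#' evaluates each family on the ligand-vs-background task (per-allele
#' metrics plus unweighted mean/SD across alleles). Also computes per-allele
#' repertoire sizes at the calibrated allele-specific thresholds and the
#' EL-rank vs IC50 ROC/AUC comparison on the pooled dataset.
#'
#' @param ligands data.frame of scored eluted ligands.
#' @param background data.frame of scored background peptides covering the
#'   same alleles.
#' @param target_sensitivity target capture fraction (default 0.8).
#' @param out_dir optional directory; when given, writes
#'   `thresholds_<metric>.tsv` and `performance_ligands.tsv`.
#' @return list with elements `fits` (per metric), `performance`
#'   (data.frame), `repertoire` (per metric), `roc` (per metric).
#' @export
run_el_calibration <- function(ligands, background, target_sensitivity = 0.8,
                               out_dir = NULL) {
  alleles <- sort(unique(ligands$allele))
  missing <- setdiff(alleles, unique(background$allele))
  if (length(missing) > 0L)
    stop("allele(s) missing background scores: ", paste(missing, collapse = ", "))
  metrics <- c("el_rank", "ic50")
  fits <- lapply(metrics, function(m)
    calibrate_thresholds(ligands, metric = m,
                         target_sensitivity = target_sensitivity))
  names(fits) <- metrics

  eval_data <- rbind(ligands[, SCORE_COLS], background[, SCORE_COLS])
  perf <- do.call(rbind, lapply(metrics, function(m) {
    rbind(
      summary_to_rows(evaluate_thresholds(fits[[m]], eval_data, "common"),
                      family = paste0(m, "_common"), dataset = "ligands"),
      summary_to_rows(evaluate_thresholds(fits[[m]], eval_data, "allele"),
                      family = paste0(m, "_allele_specific"),
                      dataset = "ligands")
    )
  }))

  rep_sizes <- lapply(metrics, function(m)
    repertoire_size(background, metric = m, threshold = fits[[m]]$per_allele))
  names(rep_sizes) <- metrics

  roc <- lapply(metrics, function(m) {
    col <- score_column(m)
    roc_auc(ligands[[col]], background[[col]])
  })
  names(roc) <- metrics

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (m in metrics)
      write_thresholds(fits[[m]], file.path(out_dir,
                                            paste0("thresholds_", m, ".tsv")))
    utils::write.table(perf, file.path(out_dir, "performance_ligands.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(fits = fits, performance = perf, repertoire = rep_sizes, roc = roc)
}

#' Evaluate ligand-derived thresholds on epitopes and rescale them
#'
#' First measures the sensitivity gap: the unscaled EL-derived thresholds
#' applied to the epitope task (they under-capture epitopes). Then rescales
#' each family stepwise to the target mean per-allele sensitivity and
#' re-evaluates. An optional disjoint validation epitope set is evaluated
#' with the already-scaled thresholds, without re-scaling.
#'
#' @param fit an unscaled `threshold_fit` (EL-derived or binder-derived).
#' @param epitopes data.frame of scored epitopes.
#' @param background data.frame of scored background peptides for the
#'   epitope alleles.
#' @param cfg a [scaling_config()]; use step 0.05 for EL-derived and 0.1 for
#'   binder-derived families.
#' @param validation optional disjoint scored epitope set.
#' @param out_dir optional output directory for `thresholds_scaled.tsv` and
#'   `performance_epitopes.tsv`.
#' @return list with `unscaled_performance`, `scaled_fit`,
#'   `scaled_performance`, and `validation_performance` (NULL if no
#'   validation set).
#' @export
run_epitope_scaling <- function(fit, epitopes, background,
                                cfg = scaling_config(), validation = NULL,
                                out_dir = NULL) {
  stopifnot(inherits(fit, "threshold_fit"))
  ep_alleles <- sort(unique(epitopes$allele))
  sub_fit <- fit
  sub_fit$per_allele <- fit$per_allele[intersect(names(fit$per_allele),
                                                 ep_alleles)]
  bg <- background[background$allele %in% ep_alleles, , drop = FALSE]
  eval_data <- rbind(epitopes[, SCORE_COLS], bg[, SCORE_COLS])

  unscaled <- rbind(
    summary_to_rows(evaluate_thresholds(sub_fit, eval_data, "common"),
                    family = "common_unscaled", dataset = "epitopes"),
    summary_to_rows(evaluate_thresholds(sub_fit, eval_data, "allele"),
                    family = "allele_specific_unscaled", dataset = "epitopes")
  )

  scaled <- scale_to_target(sub_fit, epitopes, cfg)
  scaled_perf <- rbind(
    summary_to_rows(evaluate_thresholds(scaled, eval_data, "common"),
                    family = "common_scaled", dataset = "epitopes"),
    summary_to_rows(evaluate_thresholds(scaled, eval_data, "allele"),
                    family = "allele_specific_scaled", dataset = "epitopes")
  )

  validation_perf <- NULL
  if (!is.null(validation)) {
    val_alleles <- sort(unique(validation$allele))
    vbg <- background[background$allele %in% val_alleles, , drop = FALSE]
    vdata <- rbind(validation[, SCORE_COLS], vbg[, SCORE_COLS])
    vfit <- scaled
    vfit$per_allele <- scaled$per_allele[intersect(names(scaled$per_allele),
                                                   val_alleles)]
    validation_perf <- rbind(
      summary_to_rows(evaluate_thresholds(vfit, vdata, "common"),
                      family = "common_scaled", dataset = "validation"),
      summary_to_rows(evaluate_thresholds(vfit, vdata, "allele"),
                      family = "allele_specific_scaled",
                      dataset = "validation")
    )
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_thresholds(scaled, file.path(out_dir, "thresholds_scaled.tsv"))
    utils::write.table(rbind(unscaled, scaled_perf, validation_perf),
                       file.path(out_dir, "performance_epitopes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(unscaled_performance = unscaled, scaled_fit = scaled,
       scaled_performance = scaled_perf,
       validation_performance = validation_perf)
}

report_section <- function(con, title, body) {
  writeLines(c(paste0("== ", title, " =="), body, ""), con)
}

fmt_summary_block <- function(perf) {
  rows <- perf[perf$allele %in% c("Mean", "SD"), , drop = FALSE]
  apply(rows, 1L, function(r)
    sprintf("%-28s %-11s %-5s sens %6s  spec %6s  ppv %6s  npv %6s  acc %6s",
            r[["family"]], r[["dataset"]], r[["allele"]],
            signif(as.numeric(r[["sensitivity"]]), 4),
            signif(as.numeric(r[["specificity"]]), 4),
            signif(as.numeric(r[["ppv"]]), 4),
            signif(as.numeric(r[["npv"]]), 4),
            signif(as.numeric(r[["accuracy"]]), 4)))
}

#' Write a plain-text summary report of a full run
#'
#' Assembles threshold listings, repertoire sizes, the ROC/AUC metric
#' comparison, common-vs-allele-specific mean/SD performance tables and the
#' pooled two-allele demonstration into one human-readable file. Sections
#' whose inputs are absent are skipped with a notice.
#'
#' @param calibration result of [run_el_calibration()], or NULL.
#' @param scaling result of [run_epitope_scaling()], or NULL.
#' @param demo result of [two_allele_demo()], or NULL.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
run_report <- function(calibration = NULL, scaling = NULL, demo = NULL,
                       file) {
  con <- base::file(file, "w")
  on.exit(close(con))
  writeLines(c("HLA class I threshold calibration report", ""), con)

  if (!is.null(calibration)) {
    for (m in names(calibration$fits)) {
      f <- calibration$fits[[m]]
      report_section(con, paste("Thresholds:", m),
                     c(sprintf("common %.4g; per-allele %.4g - %.4g (median %.4g) over %d alleles",
                               f$common, min(f$per_allele), max(f$per_allele),
                               stats::median(f$per_allele),
                               length(f$per_allele))))
    }
    rep_lines <- unlist(lapply(names(calibration$repertoire), function(m) {
      r <- calibration$repertoire[[m]]
      sprintf("%s: fraction bound %.4g - %.4g (median %.4g)", m,
              min(r$fraction_bound), max(r$fraction_bound),
              stats::median(r$fraction_bound))
    }))
    report_section(con, "Repertoire sizes", rep_lines)
    report_section(con, "ROC/AUC metric comparison",
                   vapply(names(calibration$roc), function(m)
                     sprintf("%s AUC = %.4f", m, calibration$roc[[m]]$auc),
                     character(1)))
    report_section(con, "Performance on ligand task (mean/SD across alleles)",
                   fmt_summary_block(calibration$performance))
  } else {
    report_section(con, "Calibration", "[skipped: no calibration input]")
  }

  if (!is.null(scaling)) {
    report_section(con, "Performance on epitope task, unscaled thresholds",
                   fmt_summary_block(scaling$unscaled_performance))
    sf <- scaling$scaled_fit
    report_section(con, "Stepwise rescaling",
                   sprintf("fold-change: common %.3g, allele-specific %.3g",
                           sf$scale_applied[["common"]],
                           sf$scale_applied[["per_allele"]]))
    report_section(con, "Performance on epitope task, scaled thresholds",
                   fmt_summary_block(scaling$scaled_performance))
    if (!is.null(scaling$validation_performance))
      report_section(con, "Validation set (no re-scaling)",
                     fmt_summary_block(scaling$validation_performance))
  } else {
    report_section(con, "Epitope scaling", "[skipped: no scaling input]")
  }

  if (!is.null(demo)) {
    report_section(con, "Two-allele demonstration",
                   c(sprintf("allele-specific: sens %.4g, ppv %.4g",
                             demo["allele_specific", "sensitivity"],
                             demo["allele_specific", "ppv"]),
                     sprintf("common:          sens %.4g, ppv %.4g",
                             demo["common", "sensitivity"],
                             demo["common", "ppv"])))
  } else {
    report_section(con, "Two-allele demonstration", "[skipped: no demo input]")
  }
  invisible(file)
}
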