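# S3 methods for threshold_fit objects.

#' @export
print.threshold_fit <- function(x, ...) {
  cat("Threshold calibration (", x$metric, ", lower is better)\n", sep = "")
  cat("  provenance:       ", x$provenance, "\n", sep = "")
  if (!is.na(x$target_sensitivity))
    cat("  target sensitivity:", x$target_sensitivity, "\n")
  cat("  alleles:          ", length(x$per_allele), "\n", sep = " ")
  cat(sprintf("  common threshold:  %.4g\n", x$common))
  cat(sprintf("  per-allele range:  %.4g - %.4g (median %.4g)\n",
              min(x$per_allele), max(x$per_allele),
              stats::median(x$per_allele)))
  if (any(x$scale_applied != 1))
    cat(sprintf("  fold-change applied: common %.3g, allele-specific %.3g\n",
                x$scale_applied[["common"]], x$scale_applied[["per_allele"]]))
  invisible(x)
}

#' Extract calibrated thresholds
#'
#' @param object a `threshold_fit`.
#' @param type `"per_allele"` (default) for the named per-allele vector,
#'   `"common"` for the pooled scalar, `"all"` for both (common first, named
#'   `"ALL"`).
#' @param ... unused.
#' @return numeric vector of thresholds.
#' @export
coef.threshold_fit <- function(object, type = c("per_allele", "common", "all"),
                               ...) {
  type <- match.arg(type)
  switch(type,
         per_allele = object$per_allele,
         common = c(ALL = unname(object$common)),
         all = c(ALL = unname(object$common), object$per_allele))
}

#' Summarize a threshold calibration
#'
#' @param object a `threshold_fit`.
#' @param ... unused.
#' @return list of class `summary.threshold_fit` with the threshold table
#'   and spread statistics.
#' @export
summary.threshold_fit <- function(object, ...) {
  pa <- object$per_allele
  structure(list(
    metric = object$metric,
    provenance = object$provenance,
    target_sensitivity = object$target_sensitivity,
    common = object$common,
    scale_applied = object$scale_applied,
    n_alleles = length(pa),
    thresholds = data.frame(allele = names(pa), threshold = unname(pa),
                            n_positives = unname(object$n_positives),
                            stringsAsFactors = FALSE),
    stats = c(min = min(pa), median = stats::median(pa), mean = mean(pa),
              max = max(pa), sd = stats::sd(pa),
              log10_span = log10(max(pa) / min(pa)))
  ), class = "summary.threshold_fit")
}

#' @export
print.summary.threshold_fit <- function(x, ...) {
  cat("Threshold calibration summary (", x$metric, ")\n", sep = "")
  cat("  provenance:", x$provenance, " alleles:", x$n_alleles, "\n")
  cat(sprintf("  common: %.4g\n", x$common))
  cat(sprintf("  per-allele: min %.4g / median %.4g / mean %.4g / max %.4g (%.2f logs)\n",
              x$stats[["min"]], x$stats[["median"]], x$stats[["mean"]],
              x$stats[["max"]], x$stats[["log10_span"]]))
  invisible(x)
}

#' Classify scored peptides with calibrated thresholds
#'
#' A peptide is called positive when its score on the fitted metric lies at
#' or below the threshold — the allele's own threshold
#' (`thresholds = "allele"`) or the common one (`"common"`).
#'
#' @param object a `threshold_fit`.
#' @param newdata data.frame of scored peptides (columns `allele` and the
#'   metric column).
#' @param thresholds which family to apply.
#' @param type `"call"` returns a logical vector (TRUE = predicted
#'   positive); `"confusion"` returns per-allele [classify()] counts
#'   (requires a `role` column).
#' @param ... unused.
#' @export
predict.threshold_fit <- function(object, newdata,
                                  thresholds = c("allele", "common"),
                                  type = c("call", "confusion"), ...) {
  thresholds <- match.arg(thresholds)
  type <- match.arg(type)
  col <- score_column(object$metric)
  if (!col %in% names(newdata)) stop("newdata lacks metric column: ", col)
  thr <- if (thresholds == "common") {
    stats::setNames(rep(object$common, length(unique(newdata$allele))),
                    unique(newdata$allele))
  } else {
    missing <- setdiff(unique(newdata$allele), names(object$per_allele))
    if (length(missing) > 0L)
      stop("no fitted threshold for allele(s): ",
           paste(missing, collapse = ", "))
    object$per_allele
  }
  if (type == "call")
    return(newdata[[col]] <= unname(thr[newdata$allele]))
  if (!"role" %in% names(newdata))
    stop("type = 'confusion' requires a role column in newdata")
  lapply(split(newdata, newdata$allele), function(d) {
    classify(d, metric = object$metric, threshold = thr[[d$allele[1L]]])
  })
}

#' Plot per-allele thresholds
#'
#' Bar plot of the allele-specific thresholds on a log axis, with the common
#' threshold as a horizontal reference line.
#'
#' @param x a `threshold_fit`.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.threshold_fit <- function(x, ...) {
  pa <- sort(x$per_allele)
  graphics::barplot(pa, log = "y", las = 2, cex.names = 0.5,
                    ylab = paste(x$metric, "threshold"),
                    main = sprintf("Allele-specific thresholds (%s)",
                                   x$provenance), ...)
  graphics::abline(h = x$common, lty = 2, col = "red3")
  graphics::legend("topleft", legend = sprintf("common = %.3g", x$common),
                   lty = 2, col = "red3", bty = "n")
  invisible(x)
}
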