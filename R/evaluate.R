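# Confusion-matrix accounting, performance metrics, per-allele summaries and
# ROC/AUC comparison of score metrics.

#' Confusion counts for one allele at a threshold
#'
#' Positives (role ligand or epitope) scoring at or below the threshold are
#' true positives; positives above are false negatives. Negatives (role
#' background) at or below the threshold are false positives; negatives
#' above are true negatives.
#'
#' @param scores data.frame of scored peptides with `role` and the metric
#'   column.
#' @param metric thresholding metric.
#' @param threshold scalar threshold.
#' @return Integer vector of class `confusion_counts` with elements `tp`,
#'   `fp`, `tn`, `fn`.
#' @export
classify <- function(scores, metric = "el_rank", threshold) {
  col <- score_column(metric)
  if (nrow(scores) == 0L) stop("classify: no peptides to classify")
  if (!col %in% names(scores)) stop("scores lack metric column: ", col)
  pos <- scores$role %in% c("ligand", "epitope")
  below <- scores[[col]] <= threshold
  structure(c(tp = sum(pos & below), fp = sum(!pos & below),
              tn = sum(!pos & !below), fn = sum(pos & !below)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("confusion counts: TP %d  FP %d  TN %d  FN %d\n",
              x[["tp"]], x[["fp"]], x[["tn"]], x[["fn"]]))
  invisible(x)
}

#' The five performance metrics from confusion counts
#'
#' Sensitivity TP/(TP+FN), specificity TN/(TN+FP), positive predictive value
#' TP/(TP+FP), negative predictive value TN/(TN+FN) and accuracy
#' (TP+TN)/(TP+TN+FP+FN). A metric whose denominator is zero is undefined
#' and returned as `NA`, never as 0.
#'
#' @param counts a `confusion_counts` vector (or any named vector with
#'   elements tp, fp, tn, fn).
#' @return Named numeric vector of class `performance_metrics`.
#' @export
compute_metrics <- function(counts) {
  tp <- counts[["tp"]]; fp <- counts[["fp"]]
  tn <- counts[["tn"]]; fn <- counts[["fn"]]
  if (tp + fp + tn + fn == 0L) stop("all confusion counts are zero")
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  structure(c(sensitivity = ratio(tp, tp + fn),
              specificity = ratio(tn, tn + fp),
              ppv = ratio(tp, tp + fp),
              npv = ratio(tn, tn + fn),
              accuracy = (tp + tn) / (tp + tn + fp + fn)),
            class = "performance_metrics")
}

PERFORMANCE_METRICS <- c("sensitivity", "specificity", "ppv", "npv", "accuracy")

#' Mean and SD of performance metrics across alleles
#'
#' Unweighted: each allele counts once regardless of how many peptides it
#' contributed. Undefined (NA) per-allele values are excluded from that
#' metric's mean/SD and counted in `n_undefined`.
#'
#' @param per_allele_metrics named list of `performance_metrics` (or a
#'   data.frame with an `allele` column and one column per metric).
#' @return list of class `per_allele_summary`: `per_allele` data.frame,
#'   `mean`, `sd` and `n_undefined` per metric.
#' @export
summarize_across_alleles <- function(per_allele_metrics) {
  if (is.data.frame(per_allele_metrics)) {
    df <- per_allele_metrics
  } else {
    if (length(per_allele_metrics) == 0L) stop("no alleles to summarize")
    df <- data.frame(allele = names(per_allele_metrics),
                     do.call(rbind, lapply(per_allele_metrics, unclass)),
                     stringsAsFactors = FALSE)
    rownames(df) <- NULL
  }
  m <- df[, PERFORMANCE_METRICS, drop = FALSE]
  structure(list(
    per_allele = df,
    mean = vapply(m, mean, numeric(1), na.rm = TRUE),
    sd = vapply(m, stats::sd, numeric(1), na.rm = TRUE),
    n_undefined = vapply(m, function(x) sum(is.na(x)), integer(1))
  ), class = "per_allele_summary")
}

#' @export
print.per_allele_summary <- function(x, digits = 4, ...) {
  cat("Per-allele performance over", nrow(x$per_allele), "alleles\n")
  tab <- rbind(mean = x$mean, sd = x$sd)
  print(round(tab, digits))
  if (any(x$n_undefined > 0))
    cat("undefined values excluded:",
        paste(sprintf("%s=%d", names(x$n_undefined)[x$n_undefined > 0],
                      x$n_undefined[x$n_undefined > 0]), collapse = ", "), "\n")
  invisible(x)
}

#' ROC curve and AUC for a lower-is-better score
#'
#' AUC is the probability that a random positive scores strictly below a
#' random negative, with ties credited one half — the Mann-Whitney statistic
#' on negated scores, computed exactly from ranks. The ROC point list sweeps
#' thresholds over the observed score values in ascending order.
#'
#' @param positives numeric scores of positive peptides (lower is better).
#' @param negatives numeric scores of negative peptides.
#' @return list of class `roc_curve`: `auc`, and `points` (data.frame
#'   `threshold`, `sensitivity`, `fpr`).
#' @export
roc_auc <- function(positives, negatives) {
  np <- length(positives); nn <- length(negatives)
  if (np == 0L || nn == 0L) stop("need at least one positive and one negative")
  r <- rank(c(positives, negatives))       # average ranks: ties get half credit
  u <- sum(r[seq_len(np)]) - np * (np + 1) / 2   # pairs where positive > negative (+ ties/2)
  auc <- 1 - u / (np * nn)
  thr <- sort(unique(c(positives, negatives)))
  pts <- data.frame(
    threshold = c(-Inf, thr),
    sensitivity = c(0, vapply(thr, function(t) mean(positives <= t), numeric(1))),
    fpr = c(0, vapply(thr, function(t) mean(negatives <= t), numeric(1)))
  )
  structure(list(auc = auc, points = pts), class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.4f over %d threshold points\n",
              x$auc, nrow(x$points)))
  invisible(x)
}

#' @export
plot.roc_curve <- function(x, ...) {
  graphics::plot(x$points$fpr, x$points$sensitivity, type = "l",
                 xlab = "1 - specificity", ylab = "sensitivity",
                 main = sprintf("ROC (AUC = %.3f)", x$auc), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' Evaluate a threshold family on a scored dataset
#'
#' Applies either the allele-specific or the common thresholds of a fit to a
#' dataset containing positives and background negatives, computing per-
#' allele confusion counts, the five metrics, and their unweighted mean/SD
#' across alleles.
#'
#' @param fit a `threshold_fit`.
#' @param data data.frame of scored peptides with `allele`, `role` and the
#'   metric column.
#' @param thresholds `"allele"` or `"common"`.
#' @return a `per_allele_summary`.
#' @export
evaluate_thresholds <- function(fit, data, thresholds = c("allele", "common")) {
  thresholds <- match.arg(thresholds)
  stopifnot(inherits(fit, "threshold_fit"))
  alleles <- sort(unique(data$allele))
  if (thresholds == "allele") {
    missing <- setdiff(alleles, names(fit$per_allele))
    if (length(missing) > 0L)
      stop("no fitted threshold for allele(s): ", paste(missing, collapse = ", "))
  }
  metrics <- lapply(alleles, function(a) {
    t <- if (thresholds == "common") fit$common else fit$per_allele[[a]]
    compute_metrics(classify(data[data$allele == a, , drop = FALSE],
                             metric = fit$metric, threshold = t))
  })
  names(metrics) <- alleles
  summarize_across_alleles(metrics)
}

#' Pooled two-allele comparison of allele-specific vs common thresholds
#'
#' Combines the epitopes and background peptides of exactly two alleles and
#' reports pooled sensitivity and precision (PPV) when (a) each allele uses
#' its own threshold and (b) both use the common threshold. This is the
#' few-allele setting in which allele-specific thresholds are expected to
#' gain sensitivity.
#'
#' @param data data.frame of scored peptides for exactly two alleles,
#'   containing epitopes (or ligands) and background rows.
#' @param metric thresholding metric.
#' @param allele_thresholds named numeric vector of length 2.
#' @param common_threshold scalar.
#' @return data.frame with rows `allele_specific` and `common`, columns
#'   `sensitivity` and `ppv`.
#' @export
two_allele_demo <- function(data, metric = "el_rank", allele_thresholds,
                            common_threshold) {
  alleles <- sort(unique(data$allele))
  if (length(alleles) != 2L) stop("exactly two alleles required, got ",
                                  length(alleles))
  if (!all(alleles %in% names(allele_thresholds)))
    stop("allele_thresholds must name both alleles")
  n_pos <- vapply(alleles, function(a)
    sum(data$allele == a & data$role %in% c("ligand", "epitope")), integer(1))
  if (any(n_pos == 0L))
    stop("allele(s) with zero positives: ",
         paste(alleles[n_pos == 0L], collapse = ", "))
  pooled <- function(thr) {
    counts <- Reduce(`+`, lapply(alleles, function(a) {
      unclass(classify(data[data$allele == a, , drop = FALSE],
                       metric = metric, threshold = thr[[a]]))
    }))
    m <- compute_metrics(counts)
    c(sensitivity = m[["sensitivity"]], ppv = m[["ppv"]])
  }
  spec <- pooled(as.list(allele_thresholds[alleles]))
  comm <- pooled(stats::setNames(rep(common_threshold, 2), alleles))
  out <- as.data.frame(rbind(allele_specific = spec, common = comm))
  out
}
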