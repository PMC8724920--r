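# Threshold calibration at fixed sensitivity.
#
# The estimator: for one allele with n positive peptides and a
# lower-is-better score, the threshold at target sensitivity s is the k-th
# order statistic of the positive scores with k = ceiling(s * n). Peptides
# scoring at or below the threshold are called positive, so re-applying the
# threshold to its calibration data captures at least ceil(s*n)/n of them —
# exactly s when s*n is an integer and no ties fall on the cutoff.

#' Threshold for one allele at a target sensitivity
#'
#' Returns the smallest observed score `t` such that at least
#' `ceiling(target_sensitivity * n)` of the `n` positive peptides score at or
#' below `t`, i.e. the k-th order statistic with
#' `k = ceiling(target_sensitivity * n)`.
#'
#' @param scores numeric vector of positive-peptide scores for one allele
#'   (lower is better).
#' @param target_sensitivity target capture fraction in (0, 1].
#' @return a single numeric threshold.
#' @export
allele_threshold <- function(scores, target_sensitivity = 0.8) {
  scores <- as.numeric(scores)
  if (length(scores) == 0L || anyNA(scores))
    stop("allele_threshold: need a nonempty score vector without NAs")
  if (target_sensitivity <= 0 || target_sensitivity > 1)
    stop("target_sensitivity must lie in (0, 1]")
  k <- ceiling(target_sensitivity * length(scores))
  sort(scores)[k]
}

#' Common threshold over pooled alleles
#'
#' The same order-statistic rule as [allele_threshold()], applied to the
#' positive scores of all alleles pooled into one list.
#'
#' @inheritParams allele_threshold
#' @export
common_threshold <- function(scores, target_sensitivity = 0.8) {
  allele_threshold(scores, target_sensitivity)
}

#' Calibrate allele-specific and common thresholds at fixed sensitivity
#'
#' The package's central fitting function. Given a scored positive dataset
#' (eluted ligands or T-cell epitopes), it derives one threshold per allele
#' by setting the capture fraction to `target_sensitivity` within that
#' allele, and one common threshold by setting it over all alleles pooled.
#'
#' @param data data.frame of scored peptides (columns `allele`, the metric
#'   column, optionally `role`). Rows with role `"background"` are ignored;
#'   all remaining rows are treated as positives.
#' @param metric thresholding metric: `"el_rank"` (default), `"ic50"` or
#'   `"ba_rank"`; all lower-is-better.
#' @param target_sensitivity target per-allele capture fraction (default
#'   0.8, the level roughly matching the classical 500 nM binding cutoff).
#' @return An object of class `threshold_fit` with components `metric`,
#'   `target_sensitivity`, `common` (scalar), `per_allele` (named numeric),
#'   `provenance`, `scale_applied` (named fold-changes, 1 when unscaled) and
#'   `n_positives` per allele.
#' @seealso [scale_to_target()], [binder_fraction_thresholds()],
#'   [predict.threshold_fit()], [evaluate_thresholds()]
#' @examples
#' d <- data.frame(allele = rep(c("HLA-A*02:01", "HLA-B*07:02"), each = 100),
#'                 el_rank = c(rexp(100, 2), rexp(100, 1)))
#' fit <- calibrate_thresholds(d, "el_rank", 0.8)
#' coef(fit)
#' @export
calibrate_thresholds <- function(data, metric = "el_rank",
                                 target_sensitivity = 0.8) {
  col <- score_column(metric)
  if (!col %in% names(data)) stop("data lacks metric column: ", col)
  if ("role" %in% names(data))
    data <- data[data$role != "background", , drop = FALSE]
  if (nrow(data) == 0L) stop("no positive peptides in data")
  split_scores <- split(data[[col]], data$allele)
  per_allele <- vapply(split_scores, allele_threshold, numeric(1),
                       target_sensitivity = target_sensitivity)
  per_allele <- per_allele[sort(names(per_allele))]
  fit <- structure(list(
    metric = metric,
    target_sensitivity = target_sensitivity,
    common = common_threshold(data[[col]], target_sensitivity),
    per_allele = per_allele,
    provenance = "el_derived",
    scale_applied = c(common = 1, per_allele = 1),
    n_positives = vapply(split_scores, length, integer(1))[names(per_allele)],
    call = match.call()
  ), class = "threshold_fit")
  fit
}

#' Thresholds from the predicted-binder fraction of the background
#'
#' For each allele, the fraction of background peptides predicted to bind at
#' `ic50_cutoff` nM (the allele's repertoire breadth) is re-interpreted as an
#' eluted-ligand percentile-rank cutoff: a fraction f becomes the EL-rank
#' threshold 100*f. The common value applies the same computation to all
#' alleles pooled.
#'
#' @param background data.frame of scored background peptides (columns
#'   `allele`, `ic50_nm`).
#' @param ic50_cutoff binding cutoff in nM (default 500, the classical
#'   binder definition).
#' @return A `threshold_fit` with metric `"el_rank"` and provenance
#'   `"binder_derived"`.
#' @export
binder_fraction_thresholds <- function(background, ic50_cutoff = 500) {
  stopifnot(ic50_cutoff > 0)
  if (!all(c("allele", "ic50_nm") %in% names(background)))
    stop("background must carry columns allele and ic50_nm")
  if (nrow(background) == 0L) stop("background is empty")
  split_ic50 <- split(background$ic50_nm, background$allele)
  if (any(vapply(split_ic50, length, integer(1)) == 0L))
    stop("allele with zero background peptides")
  per_allele <- vapply(split_ic50, function(x) 100 * mean(x <= ic50_cutoff),
                       numeric(1))
  per_allele <- per_allele[sort(names(per_allele))]
  if (any(per_allele == 0))
    warning("degenerate binder-derived threshold 0 for allele(s): ",
            paste(names(per_allele)[per_allele == 0], collapse = ", "))
  structure(list(
    metric = "el_rank",
    target_sensitivity = NA_real_,
    common = 100 * mean(background$ic50_nm <= ic50_cutoff),
    per_allele = per_allele,
    provenance = "binder_derived",
    scale_applied = c(common = 1, per_allele = 1),
    n_positives = vapply(split_ic50, length, integer(1))[names(per_allele)],
    call = match.call()
  ), class = "threshold_fit")
}

#' Scaling configuration for stepwise threshold rescaling
#'
#' @param step multiplicative step: each iteration multiplies the thresholds
#'   by `1 + step`. Use 0.05 for ligand-derived families and 0.1 for
#'   binder-fraction families.
#' @param target_mean_sensitivity target unweighted mean per-allele
#'   sensitivity (default 0.8).
#' @param max_iterations guard against nonconvergence.
#' @return list of class `scaling_config`.
#' @export
scaling_config <- function(step = 0.05, target_mean_sensitivity = 0.8,
                           max_iterations = 1000L) {
  stopifnot(step > 0, step < 1, max_iterations > 0,
            target_mean_sensitivity > 0, target_mean_sensitivity < 1)
  structure(list(step = step,
                 target_mean_sensitivity = target_mean_sensitivity,
                 max_iterations = as.integer(max_iterations)),
            class = "scaling_config")
}

mean_sensitivity <- function(thresholds, split_scores) {
  # thresholds: named per-allele vector, or scalar applied to every allele
  sens <- vapply(names(split_scores), function(a) {
    t <- if (length(thresholds) == 1L && is.null(names(thresholds)))
      thresholds else unname(thresholds[[a]])
    mean(split_scores[[a]] <= t)
  }, numeric(1))
  mean(sens)
}

#' Rescale thresholds stepwise to a target mean epitope sensitivity
#'
#' Thresholds calibrated on eluted ligands systematically under-capture
#' T-cell epitopes; this procedure widens them. Each family (the common
#' scalar, and the per-allele map as a whole) is independently multiplied by
#' `(1 + step)` per iteration — the per-allele family moves by one shared
#' multiplier, never re-tuned allele by allele — stopping at the first
#' iteration where the unweighted mean of per-allele sensitivities on
#' `epitopes` reaches `cfg$target_mean_sensitivity`. The fold-change
#' `(1 + step)^iterations` is recorded per family in `scale_applied`.
#'
#' @param fit a `threshold_fit`.
#' @param epitopes data.frame of scored epitopes covering (a subset of) the
#'   fitted alleles, at least one epitope per allele present.
#' @param cfg a [scaling_config()].
#' @return A `threshold_fit` with provenance `"scaled"`.
#' @export
scale_to_target <- function(fit, epitopes, cfg = scaling_config()) {
  stopifnot(inherits(fit, "threshold_fit"))
  col <- score_column(fit$metric)
  if (!col %in% names(epitopes)) stop("epitopes lack metric column: ", col)
  if ("role" %in% names(epitopes))
    epitopes <- epitopes[epitopes$role != "background", , drop = FALSE]
  if (nrow(epitopes) == 0L) stop("no epitopes to evaluate")
  missing <- setdiff(unique(epitopes$allele), names(fit$per_allele))
  if (length(missing) > 0L)
    stop("epitope allele(s) without a fitted threshold: ",
         paste(missing, collapse = ", "))
  split_scores <- split(epitopes[[col]], epitopes$allele)

  find_iter <- function(values) {
    for (i in 0:cfg$max_iterations) {
      m <- mean_sensitivity(values * (1 + cfg$step)^i, split_scores)
      if (m >= cfg$target_mean_sensitivity) return(list(iter = i, mean = m))
    }
    stop("scaling did not reach mean sensitivity ",
         cfg$target_mean_sensitivity, " within ", cfg$max_iterations,
         " iterations (last mean ", signif(m, 4), ")")
  }

  res_common <- find_iter(stats::setNames(rep(fit$common,
                                              length(split_scores)),
                                          names(split_scores)))
  res_allele <- find_iter(fit$per_allele[names(split_scores)])

  out <- fit
  out$common <- fit$common * (1 + cfg$step)^res_common$iter
  out$per_allele <- fit$per_allele * (1 + cfg$step)^res_allele$iter
  out$provenance <- "scaled"
  out$scale_applied <- c(common = (1 + cfg$step)^res_common$iter,
                         per_allele = (1 + cfg$step)^res_allele$iter)
  out$scaling <- list(step = cfg$step,
                      target_mean_sensitivity = cfg$target_mean_sensitivity,
                      iterations = c(common = res_common$iter,
                                     per_allele = res_allele$iter),
                      mean_sensitivity = c(common = res_common$mean,
                                           per_allele = res_allele$mean))
  out
}

#' Per-allele repertoire size at a threshold
#'
#' The repertoire size of an allele is the fraction of a common background
#' peptide set predicted to bind, i.e. scoring at or below the threshold.
#' Promiscuous alleles have large fractions, fastidious alleles small ones.
#'
#' @param background data.frame of scored background peptides for one or
#'   more alleles.
#' @param metric thresholding metric.
#' @param threshold scalar threshold, or named per-allele vector.
#' @return data.frame with columns `allele`, `fraction_bound`,
#'   `threshold_used`, `metric`.
#' @export
repertoire_size <- function(background, metric = "el_rank", threshold) {
  col <- score_column(metric)
  if (nrow(background) == 0L) stop("background is empty")
  alleles <- sort(unique(background$allele))
  thr <- if (length(threshold) == 1L && is.null(names(threshold)))
    stats::setNames(rep(threshold, length(alleles)), alleles) else threshold
  missing <- setdiff(alleles, names(thr))
  if (length(missing) > 0L)
    stop("no threshold for allele(s): ", paste(missing, collapse = ", "))
  frac <- vapply(alleles, function(a) {
    mean(background[[col]][background$allele == a] <= thr[[a]])
  }, numeric(1))
  data.frame(allele = alleles, fraction_bound = unname(frac),
             threshold_used = unname(thr[alleles]), metric = metric,
             stringsAsFactors = FALSE)
}

#' Write a threshold family to TSV
#'
#' One row per allele plus a pooled `"ALL"` row for the common threshold,
#' with columns `allele`, `metric`, `threshold`, `provenance`,
#' `scale_applied`.
#'
#' @param fit a `threshold_fit`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_thresholds <- function(fit, path) {
  stopifnot(inherits(fit, "threshold_fit"))
  df <- data.frame(
    allele = c("ALL", names(fit$per_allele)),
    metric = fit$metric,
    threshold = c(fit$common, unname(fit$per_allele)),
    provenance = fit$provenance,
    scale_applied = c(fit$scale_applied[["common"]],
                      rep(fit$scale_applied[["per_allele"]],
                          length(fit$per_allele))),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
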