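# Model evaluation: the four accuracy metrics, k-fold cross-validation and
# cross-platform error comparison.

#' Accuracy metrics of a set of age predictions
#'
#' Errors are `point - age`. `mae` is the MEDIAN absolute error (the
#' convention for these models), `rmse` the root-mean-square error, `cp5`
#' the percentage with `|error| <= 5` years and `cpPI` the percentage
#' whose true age lies inside `[pi_lower, pi_upper]` (both inclusive).
#'
#' @param predictions data.frame from [predictAge()] (columns `point`,
#'   `pi_lower`, `pi_upper`, and `age` unless `true_ages` is given).
#' @param true_ages optional numeric vector overriding
#'   `predictions$age`, aligned with the rows.
#' @return A \linkS4class{MetricsReport}.
#' @examples
#' p <- data.frame(age = c(30, 40), point = c(31, 43),
#'                 pi_lower = c(25, 35), pi_upper = c(35, 45))
#' computeMetrics(p)
#' @export
computeMetrics <- function(predictions, true_ages = predictions$age) {
  if (is.null(nrow(predictions)) || nrow(predictions) == 0L)
    stopf("no predictions to score")
  if (length(true_ages) != nrow(predictions))
    stopf("true_ages must align with the prediction rows")
  e <- predictions$point - true_ages
  # inclusive boundaries with a 1e-8-year tolerance so degenerate
  # zero-width intervals are not broken by floating-point representation
  tol <- 1e-8
  inside <- predictions$pi_lower - tol <= true_ages &
    true_ages <= predictions$pi_upper + tol
  new("MetricsReport",
      mae = stats::median(abs(e)),
      rmse = sqrt(mean(e^2)),
      cp5 = 100 * mean(abs(e) <= 5 + tol),
      cpPI = 100 * mean(inside),
      n = nrow(predictions))
}

setMethod("show", "MetricsReport", function(object) {
  cat(sprintf(
    "MetricsReport (n = %d): MAE %.2f y, RMSE %.2f y, %%CP+/-5 %.2f%%, %%CP+/-PI %.2f%%\n",
    object@n, object@mae, object@rmse, object@cp5, object@cpPI))
  invisible(NULL)
})

#' Flatten a MetricsReport to a one-row data.frame
#' @param report a \linkS4class{MetricsReport}.
#' @return data.frame with columns `mae`, `rmse`, `cp5`, `cp_pi`, `n`.
#' @export
metricsAsDataFrame <- function(report) {
  data.frame(mae = report@mae, rmse = report@rmse, cp5 = report@cp5,
             cp_pi = report@cpPI, n = report@n)
}

#' k-fold cross-validation of the age model
#'
#' Random seeded partition into `k` near-equal folds; each fold is
#' predicted by a model fitted on the remaining folds (including any
#' z-scoring, re-estimated within the training remainder); metrics are
#' pooled over all held-out predictions rather than averaged per fold.
#' With `zscore = TRUE` the held-out fold is standardised per platform
#' with the training remainder's statistics (the remainder shares the
#' fold's platform and age design, and folds are too small for stable
#' self-standardisation).
#'
#' @param x a \linkS4class{MethylationExperiment} (training cohort).
#' @param cpgs predictor CpG ids.
#' @param taus quantile levels, as in [fitAgeModel()].
#' @param k number of folds (default 10); `k = n` is leave-one-out.
#' @param seed RNG seed for the fold assignment.
#' @param zscore as in [fitAgeModel()].
#' @return list with `metrics` (a \linkS4class{MetricsReport}),
#'   `predictions` (pooled held-out predictions) and `folds` (the
#'   assignment).
#' @export
kfoldCV <- function(x, cpgs = rownames(x), taus = c(0.1, 0.5, 0.9),
                    k = 10L, seed = 1L, zscore = FALSE) {
  stopifnot(is(x, "MethylationExperiment"))
  n <- ncol(x)
  if (k < 2L || k > n) stopf("need 2 <= k <= n (k = %d, n = %d)", k, n)
  folds <- withSeed(seed, sample(rep_len(seq_len(k), n)))
  preds <- lapply(seq_len(k), function(f) {
    tr <- x[, folds != f]
    if (ncol(tr) <= length(cpgs) + 1L)
      stopf("fold %d leaves too few training samples", f)
    m <- fitAgeModel(tr, cpgs = cpgs, taus = taus, zscore = zscore)
    predictAge(m, x[, folds == f],
               zscore_stats = if (zscore) m@trainingMeta$scaler else NULL)
  })
  pooled <- do.call(rbind, preds)
  list(metrics = computeMetrics(pooled), predictions = pooled, folds = folds)
}

#' Compare prediction errors across platforms
#'
#' One-way ANOVA on the absolute prediction errors of the same test
#' panel measured with different platforms; `significant` at p < `alpha`
#' means the platforms' errors differ beyond chance.
#'
#' @param abs_errors numeric absolute errors (years).
#' @param platform platform label per error.
#' @param alpha significance level (default 0.01).
#' @return list with `statistic` (F), `p`, `significant`.
#' @export
comparePlatformErrors <- function(abs_errors, platform, alpha = 0.01) {
  r <- anovaPlatforms(abs_errors, platform, alpha = alpha)
  list(statistic = r$F, p = r$p, significant = r$significant)
}
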