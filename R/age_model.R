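# The quantile-regression age model: training-set harmonization, optional
# per-platform z-score standardisation, q10/q50/q90 fitting and prediction
# with intervals.

#' Harmonize a training set's age distribution
#'
#' Keeps samples with `age_min <= floor(age) <= age_max` (inclusive,
#' integer years) and, within each integer year of age holding more than
#' `max_per_year` samples, retains `max_per_year` of them chosen uniformly
#' at random under `seed`. Output order is stable by (age, sample_id).
#' The operation is idempotent: re-harmonizing a harmonized set with the
#' same configuration returns it unchanged.
#'
#' @param x a \linkS4class{MethylationExperiment}.
#' @param age_min,age_max inclusive window in years (defaults 18 and 75,
#'   the usual adult training window for these models).
#' @param max_per_year maximum samples retained per integer year.
#' @param seed RNG seed for the per-year subsampling.
#' @return A \linkS4class{MethylationExperiment}.
#' @export
harmonizeTraining <- function(x, age_min = 18, age_max = 75,
                              max_per_year = 2L, seed = 1L) {
  stopifnot(is(x, "MethylationExperiment"), age_min <= age_max,
            max_per_year >= 1L)
  yr <- floor(ages(x))
  keep <- which(yr >= age_min & yr <= age_max)
  if (!length(keep)) stopf("no samples inside the age window")
  withSeed(seed, {
    sel <- unlist(lapply(split(keep, yr[keep]), function(idx) {
      if (length(idx) > max_per_year) sample(idx, max_per_year) else idx
    }), use.names = FALSE)
  })
  dropped <- length(ages(x)) - length(sel)
  if (dropped)
    logMsg(sprintf("harmonizeTraining: excluded %d sample(s)", dropped))
  sel <- sel[order(ages(x)[sel], sampleIds(x)[sel])]
  x[, sel]
}

#' Per-CpG standardisation statistics
#'
#' `zscoreFit()` computes per-CpG mean and sample SD (n - 1 denominator)
#' from a dataset; `zscoreApply()` transforms a dataset to
#' `(beta - mean) / sd` using given statistics. The transform is exactly
#' invariant to per-platform affine bias: if platform B reports
#' `a + c * beta` (c > 0), the z-scores of B equal the z-scores of the
#' underlying betas, which is the mechanism by which standardisation
#' rescues cross-platform model transfer.
#'
#' @param x a \linkS4class{MethylationExperiment}.
#' @param cpgs CpG ids to standardise (default: all).
#' @return `zscoreFit()`: data.frame with columns `cpg_id`, `mean`, `sd`.
#'   `zscoreApply()`: a \linkS4class{MethylationExperiment} whose `"beta"`
#'   assay holds z-scores (flagged by `metadata()$scale == "zscore"`).
#' @export
zscoreFit <- function(x, cpgs = rownames(x)) {
  stopifnot(is(x, "MethylationExperiment"))
  b <- betas(x)[cpgs, , drop = FALSE]
  mu <- rowMeans(b)
  sdv <- apply(b, 1L, stats::sd)
  bad <- names(sdv)[sdv == 0 | is.na(sdv)]
  if (length(bad))
    stopf("zero or undefined SD for CpG(s): %s", paste(bad, collapse = ", "))
  data.frame(cpg_id = cpgs, mean = unname(mu), sd = unname(sdv),
             stringsAsFactors = FALSE)
}

#' @rdname zscoreFit
#' @param stats a data.frame as returned by `zscoreFit()`.
#' @export
zscoreApply <- function(x, stats) {
  stopifnot(is(x, "MethylationExperiment"),
            all(c("cpg_id", "mean", "sd") %in% colnames(stats)))
  miss <- setdiff(stats$cpg_id, rownames(x))
  if (length(miss))
    stopf("CpG(s) absent from dataset: %s", paste(miss, collapse = ", "))
  b <- betas(x)[stats$cpg_id, , drop = FALSE]
  z <- (b - stats$mean) / stats$sd
  md <- metadata(x)
  md$scale <- "zscore"
  MethylationExperiment(z, age = ages(x), platform = platforms(x),
                        sample_id = sampleIds(x), replicate = replicates(x),
                        metadata = md)
}

# standardise each platform's block per CpG; by default with the block's
# own mean/SD (self-standardisation), or with reference statistics per
# platform (`ref`: named list of zscoreFit() frames, e.g. from that
# platform's training cohort). returns the predictor matrix
# (samples x CpGs) of z-scores.
zscoreByPlatform <- function(x, cpgs, ref = NULL) {
  b <- betas(x)[cpgs, , drop = FALSE]
  out <- matrix(NA_real_, ncol(b), length(cpgs),
                dimnames = list(NULL, cpgs))
  for (pl in unique(platforms(x))) {
    idx <- which(platforms(x) == pl)
    blk <- b[, idx, drop = FALSE]
    if (!is.null(ref) && !is.null(ref[[pl]])) {
      st <- ref[[pl]]
      mu <- st$mean[match(cpgs, st$cpg_id)]
      sdv <- st$sd[match(cpgs, st$cpg_id)]
      if (anyNA(mu) || anyNA(sdv))
        stopf("reference statistics for platform '%s' lack model CpGs", pl)
    } else {
      mu <- rowMeans(blk)
      sdv <- apply(blk, 1L, stats::sd)
    }
    if (any(sdv == 0 | is.na(sdv)))
      stopf("zero SD within platform '%s'; cannot z-score", pl)
    out[idx, ] <- t((blk - mu) / sdv)
  }
  out
}

predictorMatrix <- function(x, cpgs, zscored, ref = NULL) {
  miss <- setdiff(cpgs, rownames(x))
  if (length(miss))
    stopf("model CpG(s) missing from dataset: %s", paste(miss, collapse = ", "))
  if (zscored) zscoreByPlatform(x, cpgs, ref = ref)
  else t(betas(x)[cpgs, , drop = FALSE])
}

#' Fit the quantile-regression age model
#'
#' Regresses chronological age on the panel's beta-values at each
#' requested quantile (default q10/q50/q90: the outer pair defines the
#' prediction interval, the median the point estimate). With
#' `zscore = TRUE`, each platform's block of the training set is first
#' standardised with its own per-CpG mean/SD (so pooled multi-platform
#' training sets are internally comparable), and prediction standardises
#' test data the same self-referential way. Samples with any missing
#' model CpG are excluded with a logged count.
#'
#' @param train a \linkS4class{MethylationExperiment}, typically
#'   harmonized with [harmonizeTraining()].
#' @param cpgs ordered predictor CpG ids (default: all rows).
#' @param taus strictly increasing quantile levels in (0, 1).
#' @param zscore standardise per platform before fitting.
#' @return An \linkS4class{AgeModel}.
#' @export
fitAgeModel <- function(train, cpgs = rownames(train),
                        taus = c(0.1, 0.5, 0.9), zscore = FALSE) {
  stopifnot(is(train, "MethylationExperiment"))
  if (any(taus <= 0) || any(taus >= 1) || is.unsorted(taus, strictly = TRUE))
    stopf("taus must be strictly increasing values in (0, 1)")
  X <- predictorMatrix(train, cpgs, zscore)
  y <- ages(train)
  ok <- stats::complete.cases(X) & !is.na(y)
  if (any(!ok))
    logMsg(sprintf("fitAgeModel: excluded %d sample(s) with missing values",
                   sum(!ok)))
  X <- X[ok, , drop = FALSE]; y <- y[ok]
  fits <- lapply(taus, function(tau) fitQuantile(X, y, tau))
  scaler <- if (zscore) {
    lapply(split(seq_len(ncol(train))[ok],
                 platforms(train)[ok]),
           function(idx) zscoreFit(train[, idx], cpgs))
  } else NULL
  new("AgeModel", cpgIds = cpgs, taus = taus, fits = fits,
      zscored = zscore,
      trainingMeta = list(platforms = unique(platforms(train)[ok]),
                          n = sum(ok), scaler = scaler))
}

setMethod("show", "AgeModel", function(object) {
  cat(sprintf("AgeModel: %d-CpG panel (%s)\n", length(object@cpgIds),
              paste(object@cpgIds, collapse = ", ")))
  cat(sprintf("  quantiles: %s%s\n",
              paste(object@taus, collapse = ", "),
              if (object@zscored) "; z-scored predictors" else ""))
  cat(sprintf("  trained on n = %d [%s]\n", object@trainingMeta$n,
              paste(object@trainingMeta$platforms, collapse = " + ")))
  invisible(NULL)
})

#' Predict ages with q10-q90 prediction intervals
#'
#' The point estimate is the quantile fit closest to the median; the
#' interval spans the lowest- and highest-tau fits. If the fitted
#' quantiles cross for a sample (lower predicted above upper), the bounds
#' are swapped and the sample flagged `crossed`, with a logged count.
#' Samples outside the training age range are predicted as usual
#' (extrapolation is deliberate: test panels can exceed the training age
#' cap).
#'
#' For z-scored models the test set is standardised per platform. By
#' default each platform's block uses its own mean/SD
#' (self-standardisation; needs no calibration data, but assumes the test
#' cohort's age distribution resembles the training design). When
#' calibration data measured on the test platform with the training age
#' design exist - typically that platform's own training cohort - pass
#' their [zscoreFit()] statistics via `zscore_stats` (a named list,
#' platform label to statistics), which keeps z-scores comparable even
#' for test panels whose age range exceeds the training window.
#'
#' @param model an \linkS4class{AgeModel}.
#' @param test a \linkS4class{MethylationExperiment} containing the model
#'   CpGs.
#' @param zscore_stats optional named list of per-platform reference
#'   statistics for standardisation (ignored for non-z-scored models).
#' @return data.frame with columns `sample_id`, `platform`, `age`,
#'   `point`, `pi_lower`, `pi_upper`, `crossed`.
#' @export
predictAge <- function(model, test, zscore_stats = NULL) {
  stopifnot(is(model, "AgeModel"), is(test, "MethylationExperiment"))
  X <- predictorMatrix(test, model@cpgIds, model@zscored, ref = zscore_stats)
  k <- which.min(abs(model@taus - 0.5))
  point <- predict(model@fits[[k]], X)
  lower <- predict(model@fits[[1L]], X)
  upper <- predict(model@fits[[length(model@fits)]], X)
  # flag crossings beyond numerical noise only (ties at machine precision
  # are not crossings), then enforce the bound order exactly
  crossed <- (lower - upper) > 1e-9
  if (any(crossed, na.rm = TRUE))
    logMsg(sprintf("predictAge: %d quantile crossing(s) resolved by swap",
                   sum(crossed, na.rm = TRUE)))
  lo <- pmin(lower, upper)
  upper <- pmax(lower, upper)
  lower <- lo
  data.frame(sample_id = sampleIds(test), platform = platforms(test),
             age = ages(test), point = point, pi_lower = lower,
             pi_upper = upper, crossed = crossed,
             stringsAsFactors = FALSE)
}

#' Pool training sets from several platforms
#'
#' Row-wise concatenation of cohorts sharing the same CpG panel,
#' preserving platform labels; the pooled size is the sum of the input
#' sizes. Mismatched CpG panels are an error.
#'
#' @param datasets list of \linkS4class{MethylationExperiment}.
#' @return A \linkS4class{MethylationExperiment}.
#' @export
combineTraining <- function(datasets) {
  stopifnot(length(datasets) >= 1L)
  lapply(datasets, function(d) stopifnot(is(d, "MethylationExperiment")))
  if (length(datasets) == 1L) return(datasets[[1L]])
  panels <- lapply(datasets, rownames)
  if (!all(vapply(panels[-1L], identical, logical(1), panels[[1L]])))
    stopf("CpG panels differ between datasets; cannot combine")
  do.call(BiocGenerics::cbind, datasets)
}
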