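#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   colData colData<-
NULL

#' MethylationExperiment: samples x CpG beta-values with ages and platforms
#'
#' The central container of the package: a
#' \linkS4class{SummarizedExperiment} whose single `"beta"` assay holds
#' CpG-by-sample methylation beta-values in \[0, 1\], with per-sample
#' chronological age (years), detection-platform label and optional
#' technical-replicate index in `colData`.
#'
#' Validity requires every beta-value in \[0, 1\] (unless the object carries
#' z-scored values, flagged by `metadata()$scale == "zscore"`), non-negative
#' ages, and unique (sample_id, platform, replicate) triples.
#'
#' @seealso [MethylationExperiment()] for construction,
#'   [readMethylation()] / [writeMethylation()] for CSV/TSV serialisation.
#' @export
setClass("MethylationExperiment", contains = "SummarizedExperiment")

setValidity("MethylationExperiment", function(object) {
  msg <- character()
  if (!"beta" %in% assayNames(object))
    msg <- c(msg, "assay 'beta' is required")
  cd <- colData(object)
  need <- c("sample_id", "age", "platform", "replicate")
  miss <- setdiff(need, colnames(cd))
  if (length(miss))
    msg <- c(msg, paste0("colData lacks column(s): ", paste(miss, collapse = ", ")))
  if (!length(msg)) {
    b <- assay(object, "beta")
    scale <- metadata(object)$scale
    if (is.null(scale)) scale <- "beta"
    if (scale == "beta" && any(b < 0 | b > 1, na.rm = TRUE))
      msg <- c(msg, "beta-values must lie in [0, 1]")
    if (any(cd$age < 0, na.rm = TRUE))
      msg <- c(msg, "ages must be >= 0")
    key <- paste(cd$sample_id, cd$platform, cd$replicate, sep = "\r")
    if (anyDuplicated(key))
      msg <- c(msg, "(sample_id, platform, replicate) triples must be unique")
  }
  if (length(msg)) msg else TRUE
})

#' Trajectory of one CpG's methylation with age
#'
#' Linear-in-age mean trajectory `intercept + slope * age` with Gaussian
#' inter-individual (biological) noise of SD `bio_sd`, clipped to \[0, 1\].
#' Slopes may be positive (ELOVL2/FHL2-like hypermethylation with age) or
#' negative (MIR29B2-like hypomethylation).
#'
#' @slot cpg_id CpG label.
#' @slot intercept beta-value at age 0.
#' @slot slope beta-units per year.
#' @slot bio_sd biological SD in beta-units (>= 0).
#' @export
setClass("TrajectorySpec",
  representation(cpg_id = "character", intercept = "numeric",
                 slope = "numeric", bio_sd = "numeric"))

setValidity("TrajectorySpec", function(object) {
  if (length(object@cpg_id) != 1L || !nzchar(object@cpg_id))
    return("cpg_id must be a single non-empty label")
  if (object@bio_sd < 0) return("bio_sd must be >= 0")
  TRUE
})

#' Measurement model of one detection platform
#'
#' Observed beta-values are generated from true ones as
#' `clip01(offset + scale * g(beta) + N(0, tech_sd))` per replicate, where
#' `g(beta) = gain * beta / (gain * beta + 1 - beta)` is the dye-gain
#' (fluorophore-intensity) distortion of SBE-style peak-ratio calling.
#' `gain = 1` is unbiased; the distortion fixes 0 and 1 and is largest
#' mid-range, the pattern seen when semi-quantitative platforms diverge
#' from quantitative ones at intermediate methylation levels.
#'
#' `affine_offset`, `affine_scale` and `dye_gain` may be single values or
#' named per-CpG vectors (names matched against the dataset's CpG ids;
#' unnamed CpGs take the neutral value).
#'
#' @slot platform_id platform label.
#' @slot affine_offset beta-units (possibly per-CpG, named).
#' @slot affine_scale dimensionless (possibly per-CpG, named).
#' @slot dye_gain dimensionless, > 0 (possibly per-CpG, named).
#' @slot tech_sd technical replicate SD in beta-units (>= 0).
#' @slot n_replicates replicates emitted per input record.
#' @export
setClass("PlatformSpec",
  representation(platform_id = "character", affine_offset = "numeric",
                 affine_scale = "numeric", dye_gain = "numeric",
                 tech_sd = "numeric", n_replicates = "integer"))

setValidity("PlatformSpec", function(object) {
  msg <- character()
  if (length(object@platform_id) != 1L || !nzchar(object@platform_id))
    msg <- c(msg, "platform_id must be a single non-empty label")
  if (any(object@dye_gain <= 0)) msg <- c(msg, "dye_gain must be > 0")
  if (object@tech_sd < 0) msg <- c(msg, "tech_sd must be >= 0")
  if (object@n_replicates < 1L) msg <- c(msg, "n_replicates must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Sampling design of a synthetic cohort
#'
#' @slot n_samples number of individuals.
#' @slot age_min,age_max age window in integer years.
#' @slot age_sampling `"uniform"` draws integer ages uniformly in the
#'   window; `"one_per_year"` cycles through the integer years, one sample
#'   per year per pass (so designs like one- or two-per-year common-control
#'   panels are exact).
#' @slot seed RNG seed; recorded in generated datasets.
#' @export
setClass("CohortSpec",
  representation(n_samples = "integer", age_min = "numeric",
                 age_max = "numeric", age_sampling = "character",
                 seed = "integer"))

setValidity("CohortSpec", function(object) {
  msg <- character()
  if (object@n_samples < 1L) msg <- c(msg, "n_samples must be >= 1")
  if (object@age_min < 0 || object@age_min > object@age_max)
    msg <- c(msg, "need 0 <= age_min <= age_max")
  if (!object@age_sampling %in% c("uniform", "one_per_year"))
    msg <- c(msg, "age_sampling must be 'uniform' or 'one_per_year'")
  if (length(msg)) msg else TRUE
})

#' One fitted quantile-regression hyperplane
#'
#' Coefficients minimise the pinball loss exactly (linear-programming
#' optimum); `achievedLoss` is the minimal summed loss in years.
#'
#' @slot tau quantile level in (0, 1).
#' @slot coefficients named numeric, intercept first.
#' @slot achievedLoss minimal pinball loss (years).
#' @export
setClass("QRFit",
  representation(tau = "numeric", coefficients = "numeric",
                 achievedLoss = "numeric"))

setValidity("QRFit", function(object) {
  if (object@tau <= 0 || object@tau >= 1) return("tau must be in (0, 1)")
  if (object@achievedLoss < -1e-9) return("achievedLoss must be >= 0")
  TRUE
})

#' Quantile-regression age model over a CpG panel
#'
#' One \linkS4class{QRFit} per quantile level (default q10/q50/q90); the
#' middle quantile supplies the point age estimate and the outer pair the
#' prediction interval. When `zscored`, model fitting standardised each
#' platform's beta-values with that platform's own per-CpG mean/SD, and
#' prediction standardises test data the same way.
#'
#' @slot cpgIds ordered predictor CpG labels.
#' @slot taus quantile levels, strictly increasing.
#' @slot fits list of \linkS4class{QRFit}, one per tau.
#' @slot zscored logical.
#' @slot trainingMeta provenance list (platforms, n, scaler stats, seed).
#' @export
setClass("AgeModel",
  representation(cpgIds = "character", taus = "numeric", fits = "list",
                 zscored = "logical", trainingMeta = "list"))

#' Bland-Altman agreement between two platforms at one CpG
#'
#' Differences are oriented `x - y` (first-listed platform minus second).
#' Limits of agreement are `mean_diff +/- z_mult * sd_diff` (sample SD,
#' n-1 denominator); the verdict `withinThreshold` requires both limits
#' inside the a-priori acceptance band `+/- z_mult * a_priori_sd`
#' (0.098 = 1.96 x 0.05 by default).
#'
#' @slot cpgId,platformX,platformY labels.
#' @slot diffs,means per-sample x - y and (x + y) / 2.
#' @slot meanDiff,sdDiff,loaLower,loaUpper summary statistics (beta-units).
#' @slot threshold a-priori acceptance bound (beta-units).
#' @slot withinThreshold verdict.
#' @slot shapiroP Shapiro-Wilk p for normality of the differences (NA when
#'   undefined, e.g. constant differences).
#' @slot uniformitySlope,uniformityP OLS slope of differences on means and
#'   its two-sided p (trend test for non-uniform bias).
#' @export
setClass("BlandAltmanResult",
  representation(cpgId = "character", platformX = "character",
                 platformY = "character", diffs = "numeric",
                 means = "numeric", meanDiff = "numeric", sdDiff = "numeric",
                 loaLower = "numeric", loaUpper = "numeric",
                 threshold = "numeric", withinThreshold = "logical",
                 shapiroP = "numeric", uniformitySlope = "numeric",
                 uniformityP = "numeric"))

setValidity("BlandAltmanResult", function(object) {
  if (object@loaLower > object@loaUpper + 1e-12)
    return("loaLower must be <= loaUpper")
  TRUE
})

#' Age-prediction accuracy metrics
#'
#' `mae` is the MEDIAN absolute prediction error in years (the field's
#' convention for these models, not the mean); `cp5` and `cpPI` are the
#' percentages of samples predicted within +/- 5 years and within their
#' q10-q90 prediction interval (both inclusive).
#'
#' @slot mae,rmse years.
#' @slot cp5,cpPI percentages in \[0, 100\].
#' @slot n number of scored samples.
#' @export
setClass("MetricsReport",
  representation(mae = "numeric", rmse = "numeric", cp5 = "numeric",
                 cpPI = "numeric", n = "integer"))

setValidity("MetricsReport", function(object) {
  msg <- character()
  if (object@mae < 0 || object@rmse < 0) msg <- c(msg, "errors must be >= 0")
  if (any(c(object@cp5, object@cpPI) < 0) ||
      any(c(object@cp5, object@cpPI) > 100))
    msg <- c(msg, "coverage percentages must be in [0, 100]")
  if (length(msg)) msg else TRUE
})
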