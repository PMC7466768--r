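# Inter-technology agreement: Bland-Altman limits of agreement against an
# a-priori acceptance threshold, plus normality, uniformity and ANOVA.

#' A-priori limit-of-agreement acceptance threshold
#'
#' `z_mult * a_priori_sd`; with the defaults, 1.96 x 0.05 = 0.098, the
#' acceptance band derived from the intra-technical replicate variance
#' already tolerated for these assays (SD <= 0.05).
#'
#' @param z_mult normal multiplier (default 1.96, ~95% of differences).
#' @param a_priori_sd accepted intra-technical SD in beta-units.
#' @return threshold in beta-units.
#' @export
loaThreshold <- function(z_mult = 1.96, a_priori_sd = 0.05) {
  stopifnot(z_mult > 0, a_priori_sd >= 0)
  z_mult * a_priori_sd
}

#' Bland-Altman agreement between two paired measurement series
#'
#' Differences are `x - y` and means `(x + y) / 2` per sample. Limits of
#' agreement are `mean(diffs) +/- z_mult * sd(diffs)` with the sample SD
#' (n - 1 denominator). The pair is `withinThreshold` when both limits lie
#' inside the a-priori band `+/- loaThreshold(z_mult, a_priori_sd)`; the
#' mean difference alone is not sufficient. Normality of the differences
#' (Shapiro-Wilk) and uniformity (no trend of differences across the
#' measurement range, OLS slope test) are attached.
#'
#' @param x,y paired beta-values from the two platforms, equal length >= 3.
#'   Pairing is positional unless `sample_ids_x` / `sample_ids_y` are
#'   given, in which case records are matched by id and unmatched ids are
#'   an error.
#' @param cpg_id,platform_x,platform_y labels carried into the result.
#' @param z_mult,a_priori_sd see [loaThreshold()].
#' @param sample_ids_x,sample_ids_y optional ids for pairing.
#' @return A \linkS4class{BlandAltmanResult}.
#' @examples
#' r <- blandAltman(c(.2, .4, .6, .8), c(.21, .38, .63, .80))
#' c(r@meanDiff, r@loaLower, r@loaUpper)
#' @export
blandAltman <- function(x, y, cpg_id = "CpG", platform_x = "x",
                        platform_y = "y", z_mult = 1.96, a_priori_sd = 0.05,
                        sample_ids_x = NULL, sample_ids_y = NULL) {
  if (!is.null(sample_ids_x) || !is.null(sample_ids_y)) {
    if (is.null(sample_ids_x) || is.null(sample_ids_y))
      stopf("provide sample ids for both series or neither")
    only_x <- setdiff(sample_ids_x, sample_ids_y)
    only_y <- setdiff(sample_ids_y, sample_ids_x)
    if (length(only_x) || length(only_y))
      stopf("unpaired samples: %s",
            paste(c(only_x, only_y), collapse = ", "))
    y <- y[match(sample_ids_x, sample_ids_y)]
  } else if (length(x) != length(y)) {
    stopf("x and y must have equal length (got %d and %d)",
          length(x), length(y))
  }
  n <- length(x)
  if (n < 3L) stopf("at least 3 paired measurements are required")
  diffs <- x - y
  means <- (x + y) / 2
  md <- mean(diffs)
  sdd <- stats::sd(diffs)
  lo <- md - z_mult * sdd
  hi <- md + z_mult * sdd
  thr <- loaThreshold(z_mult, a_priori_sd)
  sw <- tryCatch(testNormality(diffs)$p, error = function(e) NA_real_)
  unif <- tryCatch(testUniformity(diffs = diffs, means = means),
                   error = function(e) list(slope = NA_real_, p = NA_real_))
  new("BlandAltmanResult", cpgId = cpg_id, platformX = platform_x,
      platformY = platform_y, diffs = diffs, means = means, meanDiff = md,
      sdDiff = sdd, loaLower = lo, loaUpper = hi, threshold = thr,
      withinThreshold = (abs(lo) <= thr && abs(hi) <= thr),
      shapiroP = sw, uniformitySlope = unif$slope, uniformityP = unif$p)
}

setMethod("show", "BlandAltmanResult", function(object) {
  cat(sprintf("Bland-Altman: %s, %s (x) vs %s (y), n = %d\n",
              object@cpgId, object@platformX, object@platformY,
              length(object@diffs)))
  cat(sprintf("  mean diff %+.4f, SD %.4f, LoA [%+.4f, %+.4f]\n",
              object@meanDiff, object@sdDiff, object@loaLower,
              object@loaUpper))
  cat(sprintf("  a-priori threshold +/-%.3f: %s\n", object@threshold,
              if (object@withinThreshold) "within" else "EXCEEDED"))
  cat(sprintf("  Shapiro-Wilk p = %.3g; uniformity slope %.3g (p = %.3g)\n",
              object@shapiroP, object@uniformitySlope, object@uniformityP))
  invisible(NULL)
})

#' Shapiro-Wilk normality of Bland-Altman differences
#'
#' @param diffs numeric differences, 3 <= n <= 5000, non-constant.
#' @param alpha significance level for the `normal` flag.
#' @return list with `W`, `p` and `normal` (p > alpha).
#' @export
testNormality <- function(diffs, alpha = 0.01) {
  n <- length(diffs)
  if (n < 3L || n > 5000L)
    stopf("Shapiro-Wilk requires 3 <= n <= 5000 (n = %d)", n)
  if (stats::sd(diffs) == 0)
    stopf("differences are constant: normality test undefined")
  sw <- stats::shapiro.test(diffs)
  list(W = unname(sw$statistic), p = sw$p.value, normal = sw$p.value > alpha)
}

#' Uniformity of Bland-Altman differences across the measurement range
#'
#' Ordinary least squares of differences on pair means with a two-sided t
#' test on the slope; differences are `uniform` (no trend in the bias)
#' when p >= `alpha`. A zero-residual (degenerate) regression is resolved
#' by convention: exact zero slope passes with p = 1, exact non-zero
#' trend fails with p = 0, flagged via `degenerate`.
#'
#' @param result a \linkS4class{BlandAltmanResult}; alternatively pass
#'   `diffs` and `means` directly.
#' @param diffs,means numeric vectors (used when `result` is missing).
#' @param alpha significance level.
#' @return list with `slope`, `p`, `uniform`, `degenerate`.
#' @export
testUniformity <- function(result, diffs, means, alpha = 0.01) {
  if (!missing(result) && is(result, "BlandAltmanResult")) {
    diffs <- result@diffs
    means <- result@means
  }
  if (length(diffs) < 3L) stopf("at least 3 pairs are required")
  if (stats::sd(means) == 0)
    stopf("pair means are constant: trend undefined")
  fit <- stats::lm(diffs ~ means)
  slope <- unname(stats::coef(fit)[2L])
  rss <- sum(stats::residuals(fit)^2)
  if (rss < 1e-24) {
    p <- if (abs(slope) < 1e-12) 1 else 0
    logMsg("testUniformity: zero-residual regression, p set by convention")
    return(list(slope = slope, p = p, uniform = p >= alpha, degenerate = TRUE))
  }
  p <- summary(fit)$coefficients[2L, 4L]
  list(slope = slope, p = p, uniform = p >= alpha, degenerate = FALSE)
}

#' One-way ANOVA of beta-values across platforms
#'
#' Fixed-effects one-way analysis of variance of one CpG's beta-values
#' grouped by detection platform; significance at `alpha` (0.01 by
#' convention throughout the package).
#'
#' @param values numeric beta-values.
#' @param group platform label per value.
#' @param alpha significance level.
#' @return list with `F`, `p`, `significant`.
#' @export
anovaPlatforms <- function(values, group, alpha = 0.01) {
  group <- as.factor(group)
  if (nlevels(droplevels(group)) < 2L)
    stopf("at least 2 platform groups are required")
  if (any(table(group) < 2L))
    stopf("every group needs n >= 2")
  fit <- stats::aov(values ~ group)
  tab <- summary(fit)[[1L]]
  Fv <- tab[1L, "F value"]
  p <- tab[1L, "Pr(>F)"]
  if (is.na(Fv)) { Fv <- 0; p <- 1 }  # zero within-group variance everywhere
  list(F = unname(Fv), p = unname(p), significant = p < alpha)
}
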