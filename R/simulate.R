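# Synthetic cohorts: linear age trajectories with biological noise, pushed
# through per-platform measurement models. These stand in for blood cohorts
# measured on quantitative (EpiTYPER/pyrosequencing/MiSeq-like) and
# semi-quantitative (SNaPshot-like) methylation platforms.

#' @rdname TrajectorySpec-class
#' @param cpg_id,intercept,slope,bio_sd see slot documentation.
#' @export
trajectorySpec <- function(cpg_id, intercept, slope, bio_sd = 0) {
  new("TrajectorySpec", cpg_id = as.character(cpg_id),
      intercept = as.numeric(intercept), slope = as.numeric(slope),
      bio_sd = as.numeric(bio_sd))
}

#' @rdname PlatformSpec-class
#' @param platform_id,affine_offset,affine_scale,dye_gain,tech_sd,n_replicates
#'   see slot documentation.
#' @export
platformSpec <- function(platform_id, affine_offset = 0, affine_scale = 1,
                         dye_gain = 1, tech_sd = 0, n_replicates = 1L) {
  new("PlatformSpec", platform_id = as.character(platform_id),
      affine_offset = affine_offset, affine_scale = affine_scale,
      dye_gain = dye_gain, tech_sd = as.numeric(tech_sd),
      n_replicates = as.integer(n_replicates))
}

#' @rdname CohortSpec-class
#' @param n_samples,age_min,age_max,age_sampling,seed see slot
#'   documentation.
#' @export
cohortSpec <- function(n_samples, age_min = 18, age_max = 75,
                       age_sampling = c("uniform", "one_per_year"),
                       seed = 1L) {
  new("CohortSpec", n_samples = as.integer(n_samples),
      age_min = as.numeric(age_min), age_max = as.numeric(age_max),
      age_sampling = match.arg(age_sampling), seed = as.integer(seed))
}

#' Default CpG panel emulating blood age markers
#'
#' Three markers shaped like the classic blood panel: two hypermethylating
#' with age (ELOVL2-like, steep; FHL2-like, shallower) and one
#' hypomethylating (MIR29B2-like). Intercepts/slopes are chosen so betas
#' traverse roughly 0.2-0.65 (ELOVL2), 0.18-0.45 (FHL2) and 0.55-0.82
#' (MIR29B2, downward) over ages 18-75; biological SDs of 0.03-0.035
#' beta-units give single-marker age SDs of about 5-8 years and a 3-marker
#' model with median errors in the 2-4 year range typical of such panels.
#'
#' @return list of \linkS4class{TrajectorySpec}.
#' @export
defaultTrajectories <- function() {
  list(trajectorySpec("ELOVL2",  intercept = 0.08, slope =  0.0075, bio_sd = 0.035),
       trajectorySpec("FHL2",    intercept = 0.10, slope =  0.0045, bio_sd = 0.030),
       trajectorySpec("MIR29B2", intercept = 0.90, slope = -0.0045, bio_sd = 0.035))
}

#' Default platform measurement models
#'
#' Four platforms emulating the behaviour of the common detection
#' technologies: three near-quantitative ones differing only by small
#' affine shifts and low technical noise, and an SBE platform
#' (`"SNaPshot"`) with a per-CpG affine offset of +0.12 on the ELOVL2-like
#' marker, a dye-gain distortion of 1.6 on the MIR29B2-like marker,
#' duplicate measurements and technical SD 0.05 (the accepted
#' intra-technical replicate variance for these assays).
#'
#' @return named list of \linkS4class{PlatformSpec}.
#' @export
defaultPlatforms <- function() {
  list(
    EpiTYPER = platformSpec("EpiTYPER", tech_sd = 0.015),
    pyrosequencing = platformSpec("pyrosequencing", affine_offset = -0.02,
                                  tech_sd = 0.015),
    MiSeq = platformSpec("MiSeq", affine_offset = 0.01, tech_sd = 0.015),
    SNaPshot = platformSpec("SNaPshot",
                            affine_offset = c(ELOVL2 = 0.12, FHL2 = 0.03),
                            dye_gain = c(MIR29B2 = 1.6),
                            tech_sd = 0.05, n_replicates = 2L))
}

drawAges <- function(cohort) {
  yrs <- seq(floor(cohort@age_min), floor(cohort@age_max))
  if (cohort@age_sampling == "one_per_year") {
    rep_len(yrs, cohort@n_samples)
  } else {
    yrs[sample.int(length(yrs), cohort@n_samples, replace = TRUE)]
  }
}

#' Generate noise-free-platform ("truth") cohorts
#'
#' Draws ages per the cohort design and evaluates each CpG trajectory with
#' Gaussian biological noise, clipping betas to \[0, 1\]. Output platform
#' label is `"truth"`; the seed is recorded in `metadata()`.
#'
#' @param cohort a \linkS4class{CohortSpec}.
#' @param trajectories non-empty list of \linkS4class{TrajectorySpec}.
#' @return A \linkS4class{MethylationExperiment}.
#' @examples
#' me <- simulateTrueBetas(cohortSpec(10, seed = 7), defaultTrajectories())
#' range(betas(me))
#' @export
simulateTrueBetas <- function(cohort, trajectories) {
  stopifnot(is(cohort, "CohortSpec"))
  if (!length(trajectories))
    stopf("at least one TrajectorySpec is required")
  lapply(trajectories, function(tr) stopifnot(is(tr, "TrajectorySpec")))
  n <- cohort@n_samples
  withSeed(cohort@seed, {
    age <- drawAges(cohort)
    b <- vapply(trajectories, function(tr) {
      clip01(tr@intercept + tr@slope * age + rnorm(n, 0, tr@bio_sd))
    }, numeric(n))
    b <- matrix(b, nrow = n)
    colnames(b) <- vapply(trajectories, slot, character(1), "cpg_id")
    MethylationExperiment(t(b), age = age, platform = "truth",
                          sample_id = sprintf("S%04d", seq_len(n)),
                          metadata = list(seed = cohort@seed))
  })
}

#' Dye-gain distortion of a beta-value
#'
#' `g * beta / (g * beta + 1 - beta)`: the beta-value recovered from a
#' fluorescence peak ratio when the methylated dye is `g` times brighter
#' than the unmethylated one. Strictly increasing in beta for any `g > 0`,
#' fixes 0 and 1, and deviates most in the mid-range, so platforms agree
#' at extreme methylation levels and diverge at intermediate ones.
#'
#' @param beta beta-values in \[0, 1\].
#' @param gain dye intensity ratio, > 0.
#' @return distorted beta-values.
#' @examples
#' dyeGainDistortion(0.5, 3)  # 0.75
#' @export
dyeGainDistortion <- function(beta, gain) {
  if (any(gain <= 0)) stopf("dye gain must be > 0")
  gain * beta / (gain * beta + 1 - beta)
}

perCpG <- function(values, cpgs, neutral) {
  out <- rep(neutral, length(cpgs))
  names(out) <- cpgs
  if (is.null(names(values))) {
    out[] <- rep_len(values, length(cpgs))
  } else {
    hit <- intersect(names(values), cpgs)
    out[hit] <- values[hit]
  }
  out
}

#' Push a truth cohort through a platform's measurement model
#'
#' Per input record and replicate, the observed value is
#' `clip01(offset + scale * dyeGainDistortion(beta, gain) + N(0, tech_sd))`.
#' The identity platform (offset 0, scale 1, gain 1, tech_sd 0) reproduces
#' the input betas exactly.
#'
#' @param truth a \linkS4class{MethylationExperiment} (any platform label).
#' @param platform a \linkS4class{PlatformSpec}.
#' @param seed RNG seed for the technical noise; recorded in `metadata()`.
#' @return A \linkS4class{MethylationExperiment} with
#'   `platform@n_replicates` records per input record.
#' @export
applyPlatform <- function(truth, platform, seed = 1L) {
  stopifnot(is(truth, "MethylationExperiment"), is(platform, "PlatformSpec"))
  validObject(platform)
  b <- betas(truth)
  cpgs <- rownames(b)
  off <- perCpG(platform@affine_offset, cpgs, 0)
  scl <- perCpG(platform@affine_scale, cpgs, 1)
  gn <- perCpG(platform@dye_gain, cpgs, 1)
  nrep <- platform@n_replicates
  withSeed(seed, {
    reps <- lapply(seq_len(nrep), function(r) {
      obs <- off + scl * dyeGainDistortion(b, gn)  # recycles by row (CpG)
      noise <- matrix(rnorm(length(obs), 0, platform@tech_sd), nrow(obs))
      clip01(obs + noise)
    })
    bigb <- do.call(cbind, reps)
    MethylationExperiment(
      bigb,
      age = rep(ages(truth), nrep),
      platform = platform@platform_id,
      sample_id = rep(sampleIds(truth), nrep),
      replicate = if (nrep > 1L) rep(seq_len(nrep), each = ncol(b)) else NA_integer_,
      metadata = list(seed = seed, source_platform = unique(platforms(truth))))
  })
}
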