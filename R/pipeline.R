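# Study orchestration: the full agreement report and the training-set x
# test-platform prediction grid, from a config object or file.

#' Pairwise agreement report across platforms
#'
#' Averages replicates, then for every CpG and every pair of platforms
#' sharing at least `min_n` samples computes the Bland-Altman summary,
#' the a-priori threshold verdict, normality and uniformity tests, and a
#' per-pair ANOVA of the raw beta-values. Difference orientation is
#' (first platform) - (second platform) in the platform order of
#' appearance.
#'
#' @param x a \linkS4class{MethylationExperiment} with >= 2 platforms
#'   measuring shared sample ids.
#' @param cpgs CpG ids to report (default: all rows).
#' @param z_mult,a_priori_sd,alpha see [blandAltman()].
#' @param min_n minimum shared samples per pair (default 3).
#' @param out_dir optional directory for `agreement.csv`, Bland-Altman
#'   plots and a manifest; created if needed. Plotting is best-effort and
#'   never fails the run.
#' @return data.frame, one row per (CpG, platform pair).
#' @export
runAgreement <- function(x, cpgs = rownames(x), z_mult = 1.96,
                         a_priori_sd = 0.05, alpha = 0.01, min_n = 3L,
                         out_dir = NULL) {
  stopifnot(is(x, "MethylationExperiment"))
  x <- averageReplicates(x)
  pls <- unique(platforms(x))
  if (length(pls) < 2L)
    stopf("agreement needs >= 2 platforms (found: %s)",
          paste(pls, collapse = ", "))
  pairs <- utils::combn(pls, 2L, simplify = FALSE)
  rows <- list()
  results <- list()
  for (cg in cpgs) {
    for (pr in pairs) {
      ix <- which(platforms(x) == pr[1L])
      iy <- which(platforms(x) == pr[2L])
      shared <- intersect(sampleIds(x)[ix], sampleIds(x)[iy])
      if (length(shared) < min_n) next
      bx <- betas(x)[cg, ix[match(shared, sampleIds(x)[ix])]]
      by <- betas(x)[cg, iy[match(shared, sampleIds(x)[iy])]]
      ok <- !is.na(bx) & !is.na(by)
      if (sum(ok) < min_n) next
      r <- blandAltman(bx[ok], by[ok], cpg_id = cg, platform_x = pr[1L],
                       platform_y = pr[2L], z_mult = z_mult,
                       a_priori_sd = a_priori_sd)
      av <- anovaPlatforms(c(bx[ok], by[ok]),
                           rep(pr, each = sum(ok)), alpha = alpha)
      results[[length(results) + 1L]] <- r
      rows[[length(rows) + 1L]] <- data.frame(
        cpg_id = cg, platform_x = pr[1L], platform_y = pr[2L],
        n = sum(ok), mean_diff = r@meanDiff, sd_diff = r@sdDiff,
        loa_lower = r@loaLower, loa_upper = r@loaUpper,
        threshold = r@threshold, within_threshold = r@withinThreshold,
        shapiro_p = r@shapiroP, uniformity_slope = r@uniformitySlope,
        uniformity_p = r@uniformityP, anova_F = av$F, anova_p = av$p,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    stopf("no platform pair shares >= %d samples", min_n)
  report <- do.call(rbind, rows)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(report, file.path(out_dir, "agreement.csv"),
                     row.names = FALSE)
    writeManifest(out_dir, list(step = "agreement", cpgs = cpgs,
                                z_mult = z_mult, a_priori_sd = a_priori_sd))
    for (r in results) {
      try(ggplot2::ggsave(
        file.path(out_dir, sprintf("bland_altman_%s_%s_vs_%s.png",
                                   r@cpgId, r@platformX, r@platformY)),
        plotBlandAltman(r), width = 5, height = 4, dpi = 120),
        silent = TRUE)
    }
  }
  report
}

#' Assemble a cross-platform study configuration
#'
#' Defaults reproduce the package's reference design: four platforms over
#' the default 3-CpG panel, per-platform training cohorts harmonized to
#' ages 18-75 with at most two samples per year of age, and one shared
#' common-control test panel of 84 individuals spanning 18-99 years (one
#' per year, cycling).
#'
#' @param trajectories list of \linkS4class{TrajectorySpec}.
#' @param platforms named list of \linkS4class{PlatformSpec}.
#' @param train_n named integer vector: truth-cohort size per platform
#'   (names must match `platforms`).
#' @param test_n common-control panel size.
#' @param test_age_max upper test age (extrapolation beyond the training
#'   cap is intended).
#' @param harmonization list(age_min, age_max, max_per_year).
#' @param taus quantile levels.
#' @param cv_k folds for training-set cross-validation.
#' @param zscore_modes logical vector of standardisation modes to run.
#' @param seed master seed; per-cohort seeds are derived from it.
#' @param out_dir optional output directory.
#' @return list ready for [runCrossPlatformStudy()].
#' @export
studyConfig <- function(trajectories = defaultTrajectories(),
                        platforms = defaultPlatforms(),
                        train_n = NULL, test_n = 84L, test_age_max = 99,
                        harmonization = list(age_min = 18, age_max = 75,
                                             max_per_year = 2L),
                        taus = c(0.1, 0.5, 0.9), cv_k = 10L,
                        zscore_modes = c(FALSE, TRUE), seed = 1L,
                        out_dir = NULL) {
  if (is.null(train_n))
    train_n <- stats::setNames(rep(150L, length(platforms)),
                               vapply(platforms, slot, character(1),
                                      "platform_id"))
  list(trajectories = trajectories, platforms = platforms,
       train_n = train_n, test_n = as.integer(test_n),
       test_age_max = test_age_max, harmonization = harmonization,
       taus = taus, cv_k = as.integer(cv_k), zscore_modes = zscore_modes,
       seed = as.integer(seed), out_dir = out_dir)
}

#' Read a study configuration from YAML or JSON
#'
#' The file mirrors [studyConfig()]: top-level keys `trajectories`
#' (list of cpg_id/intercept/slope/bio_sd), `platforms` (list of
#' platform_id/affine_offset/affine_scale/dye_gain/tech_sd/n_replicates),
#' and the scalar options. Omitted keys take the defaults.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return list as from [studyConfig()].
#' @export
readStudyConfig <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  }
  args <- list()
  if (!is.null(raw$trajectories))
    args$trajectories <- lapply(raw$trajectories, function(t)
      trajectorySpec(t$cpg_id, t$intercept, t$slope,
                     if (is.null(t$bio_sd)) 0 else t$bio_sd))
  if (!is.null(raw$platforms)) {
    pls <- lapply(raw$platforms, function(p)
      platformSpec(p$platform_id,
                   affine_offset = unlist(p$affine_offset %||% 0),
                   affine_scale = unlist(p$affine_scale %||% 1),
                   dye_gain = unlist(p$dye_gain %||% 1),
                   tech_sd = p$tech_sd %||% 0,
                   n_replicates = p$n_replicates %||% 1L))
    names(pls) <- vapply(pls, slot, character(1), "platform_id")
    args$platforms <- pls
  }
  for (k in c("test_n", "test_age_max", "harmonization", "taus", "cv_k",
              "zscore_modes", "seed", "out_dir"))
    if (!is.null(raw[[k]])) args[[k]] <- raw[[k]]
  if (!is.null(raw$train_n)) args$train_n <- unlist(raw$train_n)
  do.call(studyConfig, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

buildStudyDatasets <- function(config) {
  cpgs <- vapply(config$trajectories, slot, character(1), "cpg_id")
  h <- config$harmonization
  train <- list()
  for (i in seq_along(config$platforms)) {
    pl <- config$platforms[[i]]
    id <- pl@platform_id
    truth <- simulateTrueBetas(
      cohortSpec(config$train_n[[id]], age_min = h$age_min,
                 age_max = h$age_max, age_sampling = "uniform",
                 seed = config$seed + i),
      config$trajectories)
    obs <- averageReplicates(applyPlatform(truth, pl,
                                           seed = config$seed + 100L + i))
    train[[id]] <- harmonizeTraining(obs, age_min = h$age_min,
                                     age_max = h$age_max,
                                     max_per_year = h$max_per_year,
                                     seed = config$seed)
  }
  test_truth <- simulateTrueBetas(
    cohortSpec(config$test_n, age_min = h$age_min,
               age_max = config$test_age_max,
               age_sampling = "one_per_year", seed = config$seed + 999L),
    config$trajectories)
  test <- list()
  for (i in seq_along(config$platforms)) {
    pl <- config$platforms[[i]]
    test[[pl@platform_id]] <-
      averageReplicates(applyPlatform(test_truth, pl,
                                      seed = config$seed + 200L + i))
  }
  list(train = train, test = test, cpgs = cpgs)
}

#' Run the full cross-platform prediction study
#'
#' For each per-platform training set and their pooled combination, fits
#' the quantile-regression age model, cross-validates it on its own
#' training data, and scores every platform's common-control test set;
#' the whole grid is repeated for each standardisation mode. Per training
#' set, a one-way ANOVA compares absolute prediction errors across test
#' platforms.
#'
#' @param config list from [studyConfig()] or [readStudyConfig()].
#' @return list with `grid` (data.frame: zscore, training, group, n, mae,
#'   rmse, cp5, cp_pi), `error_anova` (per training set and mode),
#'   `predictions` (nested list) and `datasets`. With `config$out_dir`
#'   set, writes `grid.csv`, `grid.json`, `error_anova.csv`, a manifest
#'   and best-effort predicted-vs-chronological plots.
#' @export
runCrossPlatformStudy <- function(config) {
  ds <- buildStudyDatasets(config)
  sets <- ds$train
  sets$Combined <- combineTraining(unname(ds$train))
  # per-platform reference statistics for z-scoring test panels: each test
  # platform is standardised with its own training cohort's mean/SD, which
  # shares the harmonized age design (test panels exceed the training age
  # window, so self-standardisation would distort their z-scores)
  ref_stats <- lapply(ds$train, zscoreFit, cpgs = ds$cpgs)
  grid <- list(); anova_rows <- list(); preds <- list()
  for (zs in config$zscore_modes) {
    ztag <- if (zs) "zscore" else "raw"
    preds[[ztag]] <- list()
    for (tr_name in names(sets)) {
      tr <- sets[[tr_name]]
      cv <- kfoldCV(tr, cpgs = ds$cpgs, taus = config$taus,
                    k = min(config$cv_k, ncol(tr)), seed = config$seed,
                    zscore = zs)
      grid[[length(grid) + 1L]] <- cbind(
        data.frame(zscore = zs, training = tr_name, group = "Training (CV)"),
        metricsAsDataFrame(cv$metrics))
      model <- fitAgeModel(tr, cpgs = ds$cpgs, taus = config$taus,
                           zscore = zs)
      errs <- list()
      preds[[ztag]][[tr_name]] <- list()
      for (te_name in names(ds$test)) {
        p <- predictAge(model, ds$test[[te_name]],
                        zscore_stats = if (zs) ref_stats else NULL)
        preds[[ztag]][[tr_name]][[te_name]] <- p
        m <- computeMetrics(p)
        grid[[length(grid) + 1L]] <- cbind(
          data.frame(zscore = zs, training = tr_name,
                     group = paste("Testing:", te_name)),
          metricsAsDataFrame(m))
        errs[[te_name]] <- abs(p$point - p$age)
      }
      av <- comparePlatformErrors(unlist(errs),
                                  rep(names(errs), lengths(errs)))
      anova_rows[[length(anova_rows) + 1L]] <- data.frame(
        zscore = zs, training = tr_name, F = av$statistic, p = av$p,
        significant = av$significant)
    }
  }
  grid <- do.call(rbind, grid)
  error_anova <- do.call(rbind, anova_rows)
  out <- list(grid = grid, error_anova = error_anova, predictions = preds,
              datasets = ds)
  if (!is.null(config$out_dir)) {
    od <- config$out_dir
    dir.create(od, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(grid, file.path(od, "grid.csv"), row.names = FALSE)
    jsonlite::write_json(grid, file.path(od, "grid.json"), dataframe = "rows",
                         auto_unbox = TRUE, digits = NA)
    utils::write.csv(error_anova, file.path(od, "error_anova.csv"),
                     row.names = FALSE)
    writeManifest(od, configDigestable(config))
    for (ztag in names(preds)) for (tr_name in names(preds[[ztag]])) {
      p <- do.call(rbind, preds[[ztag]][[tr_name]])
      try(ggplot2::ggsave(
        file.path(od, sprintf("predicted_vs_chronological_%s_%s.png",
                              tr_name, ztag)),
        plotPredictions(p) + ggplot2::facet_wrap(~platform),
        width = 9, height = 3.2, dpi = 120), silent = TRUE)
    }
  }
  out
}

# reduce a config to plain digestable values (specs -> lists)
configDigestable <- function(config) {
  list(
    trajectories = lapply(config$trajectories, function(t)
      list(cpg_id = t@cpg_id, intercept = t@intercept, slope = t@slope,
           bio_sd = t@bio_sd)),
    platforms = lapply(config$platforms, function(p)
      list(platform_id = p@platform_id, affine_offset = p@affine_offset,
           affine_scale = p@affine_scale, dye_gain = p@dye_gain,
           tech_sd = p@tech_sd, n_replicates = p@n_replicates)),
    train_n = as.list(config$train_n), test_n = config$test_n,
    test_age_max = config$test_age_max,
    harmonization = config$harmonization, taus = config$taus,
    cv_k = config$cv_k, zscore_modes = config$zscore_modes,
    seed = config$seed)
}

#' @noRd
writeManifest <- function(out_dir, config_like) {
  tmp <- tempfile(fileext = ".json")
  jsonlite::write_json(config_like, tmp, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  digest <- unname(tools::md5sum(tmp))
  unlink(tmp)
  manifest <- list(
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    package = "methAgeQR",
    package_version = as.character(utils::packageVersion("methAgeQR")),
    r_version = R.version.string,
    config_md5 = digest,
    config = config_like)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       pretty = TRUE)
  invisible(manifest)
}
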