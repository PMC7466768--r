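# Beta-table utilities: SBE peak-ratio calling, replicate handling and
# CpG-cluster averaging.

#' Beta-value from single-base-extension peak heights
#'
#' The SBE (SNaPshot-style) methylation call is the peak-height ratio
#' `meth / (meth + unmeth)` in relative fluorescence units.
#'
#' @param meth_rfu,unmeth_rfu non-negative peak heights (vectorised).
#' @param sample_id,cpg_id optional labels used in error messages when a
#'   site has no signal on either peak.
#' @return beta-values in \[0, 1\].
#' @examples
#' computeSBEBeta(300, 100)  # 0.75
#' @export
computeSBEBeta <- function(meth_rfu, unmeth_rfu,
                           sample_id = NULL, cpg_id = NULL) {
  if (any(meth_rfu < 0 | unmeth_rfu < 0, na.rm = TRUE))
    stopf("peak heights must be >= 0")
  tot <- meth_rfu + unmeth_rfu
  bad <- which(tot == 0)
  if (length(bad)) {
    lab <- if (!is.null(sample_id) || !is.null(cpg_id)) {
      paste0(" (", paste(sample_id[bad], cpg_id[bad], sep = "/",
                         collapse = ", "), ")")
    } else paste0(" at position(s) ", paste(bad, collapse = ", "))
    stopf("no signal on either peak%s: beta-value undefined", lab)
  }
  meth_rfu / tot
}

#' Paired replicate-concordance test
#'
#' For a platform run in duplicate, tests per CpG whether the two
#' replicates differ systematically (paired two-sided t-test across
#' samples); a CpG passes when p > `alpha`. Degenerate difference vectors
#' are resolved by convention: all-zero differences pass with p = 1;
#' constant non-zero differences fail with p = 0 (the t statistic is
#' unbounded there).
#'
#' @param x a \linkS4class{MethylationExperiment} containing one platform
#'   with exactly two replicates per sample.
#' @param alpha significance level (default 0.01).
#' @return data.frame with columns `cpg_id`, `statistic`, `p`, `pass`.
#' @export
testReplicateConcordance <- function(x, alpha = 0.01) {
  stopifnot(is(x, "MethylationExperiment"))
  pl <- unique(platforms(x))
  if (length(pl) != 1L)
    stopf("subset to a single platform first (found: %s)",
          paste(pl, collapse = ", "))
  tab <- table(sampleIds(x))
  if (any(tab != 2L))
    stopf("exactly two replicates per sample are required")
  sids <- names(tab)
  if (length(sids) < 3L)
    stopf("at least 3 paired samples are required")
  ord <- order(sampleIds(x), replicates(x))
  b <- betas(x)[, ord, drop = FALSE]
  i1 <- seq(1L, ncol(b), by = 2L)
  r1 <- b[, i1, drop = FALSE]
  r2 <- b[, i1 + 1L, drop = FALSE]
  res <- lapply(rownames(b), function(cg) {
    d <- r1[cg, ] - r2[cg, ]
    if (isTRUE(all.equal(stats::sd(d), 0, tolerance = 1e-12)) ||
        stats::sd(d) == 0) {
      if (all(abs(d) < 1e-12)) {
        data.frame(cpg_id = cg, statistic = 0, p = 1, pass = TRUE)
      } else {
        data.frame(cpg_id = cg, statistic = Inf, p = 0, pass = FALSE)
      }
    } else {
      tt <- stats::t.test(d)
      data.frame(cpg_id = cg, statistic = unname(tt$statistic),
                 p = tt$p.value, pass = tt$p.value > alpha)
    }
  })
  do.call(rbind, res)
}

#' Average technical replicates
#'
#' Collapses to one record per (sample, platform) by the arithmetic mean
#' of the replicates' beta-values; single-replicate records pass through
#' and the replicate index is dropped (set to NA).
#'
#' @param x a \linkS4class{MethylationExperiment}.
#' @return A \linkS4class{MethylationExperiment}.
#' @export
averageReplicates <- function(x) {
  stopifnot(is(x, "MethylationExperiment"))
  key <- paste(sampleIds(x), platforms(x), sep = "\r")
  first <- !duplicated(key)
  grp <- match(key, key[first])
  b <- betas(x)
  avg <- vapply(seq_len(sum(first)),
                function(g) rowMeans(b[, grp == g, drop = FALSE]),
                numeric(nrow(b)))
  avg <- matrix(avg, nrow = nrow(b), dimnames = list(rownames(b), NULL))
  MethylationExperiment(avg,
                        age = ages(x)[first],
                        platform = platforms(x)[first],
                        sample_id = sampleIds(x)[first],
                        replicate = NA_integer_,
                        metadata = metadata(x))
}

#' Collapse a CpG cluster to its average
#'
#' Adds a row `cluster_id` holding the unweighted mean of the member CpGs
#' (as when a platform reports close CpGs only as a block and the
#' per-site technologies must be averaged to match). Member rows are
#' retained. Samples with any missing member get a missing cluster value,
#' with a logged count.
#'
#' @param x a \linkS4class{MethylationExperiment}.
#' @param cluster_id label of the new row.
#' @param members >= 2 CpG ids already present in `x`.
#' @return A \linkS4class{MethylationExperiment} with one added row.
#' @export
collapseCluster <- function(x, cluster_id, members) {
  stopifnot(is(x, "MethylationExperiment"))
  if (length(members) < 2L)
    stopf("a cluster needs at least 2 member CpGs")
  miss <- setdiff(members, rownames(x))
  if (length(miss))
    stopf("cluster member(s) absent from dataset: %s",
          paste(miss, collapse = ", "))
  b <- betas(x)
  cl <- colMeans(b[members, , drop = FALSE])
  nmiss <- sum(is.na(cl))
  if (nmiss)
    logMsg(sprintf("collapseCluster('%s'): %d sample(s) with a missing member; cluster value set to NA",
                   cluster_id, nmiss))
  b2 <- rbind(b, matrix(cl, nrow = 1, dimnames = list(cluster_id, NULL)))
  MethylationExperiment(b2, age = ages(x), platform = platforms(x),
                        sample_id = sampleIds(x), replicate = replicates(x),
                        metadata = metadata(x))
}
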