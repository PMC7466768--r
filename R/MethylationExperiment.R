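#' Construct a MethylationExperiment
#'
#' @param beta numeric matrix of beta-values, CpGs in rows, samples in
#'   columns; rownames are CpG ids.
#' @param age numeric vector of chronological ages (years), one per column.
#' @param platform character vector of platform labels, one per column (or
#'   a single label, recycled).
#' @param sample_id sample identifiers; defaults to `colnames(beta)`.
#' @param replicate optional integer replicate indices (NA when the
#'   platform was run once).
#' @param metadata list stored in `metadata()`; the generators record
#'   their seeds here.
#'
#' @return A \linkS4class{MethylationExperiment}.
#' @examples
#' b <- matrix(c(0.2, 0.8, 0.3, 0.7), nrow = 2,
#'             dimnames = list(c("ELOVL2", "MIR29B2"), NULL))
#' me <- MethylationExperiment(b, age = c(30, 60), platform = "EpiTYPER",
#'                             sample_id = c("S1", "S2"))
#' betas(me)
#' @export
MethylationExperiment <- function(beta, age, platform,
                                  sample_id = colnames(beta),
                                  replicate = NA_integer_,
                                  metadata = list()) {
  beta <- as.matrix(beta)
  n <- ncol(beta)
  if (is.null(sample_id))
    sample_id <- sprintf("S%03d", seq_len(n))
  platform <- rep_len(as.character(platform), n)
  replicate <- rep_len(as.integer(replicate), n)
  age <- rep_len(as.numeric(age), n)
  if (is.null(rownames(beta)))
    stopf("beta matrix must carry CpG ids as rownames")
  cd <- DataFrame(sample_id = as.character(sample_id), age = age,
                  platform = platform, replicate = replicate)
  colnames(beta) <- make.unique(paste(sample_id, platform,
                                      ifelse(is.na(replicate), "", replicate),
                                      sep = "."))
  rownames(cd) <- colnames(beta)
  se <- SummarizedExperiment(assays = list(beta = beta), colData = cd,
                             metadata = metadata)
  new("MethylationExperiment", se)
}

#' Accessors for MethylationExperiment
#'
#' `betas()` returns the CpG-by-sample beta matrix, `ages()`,
#' `platforms()`, `replicates()` and `sampleIds()` the per-sample
#' annotations, and `cpgIds()` the CpG labels.
#'
#' @param x a \linkS4class{MethylationExperiment}.
#' @param ... unused.
#' @return matrix or vector as described.
#' @name MethylationExperiment-accessors
NULL

#' @rdname MethylationExperiment-accessors
#' @export
setMethod("betas", "MethylationExperiment", function(x, ...)
  assay(x, "beta"))

#' @rdname MethylationExperiment-accessors
#' @export
setMethod("ages", "MethylationExperiment", function(x, ...)
  colData(x)$age)

#' @rdname MethylationExperiment-accessors
#' @export
setMethod("platforms", "MethylationExperiment", function(x, ...)
  colData(x)$platform)

#' @rdname MethylationExperiment-accessors
#' @export
setMethod("replicates", "MethylationExperiment", function(x, ...)
  colData(x)$replicate)

#' @rdname MethylationExperiment-accessors
#' @export
setMethod("sampleIds", "MethylationExperiment", function(x, ...)
  colData(x)$sample_id)

#' @rdname MethylationExperiment-accessors
#' @export
setMethod("cpgIds", "MethylationExperiment", function(x, ...)
  rownames(x))

setMethod("show", "MethylationExperiment", function(object) {
  cat("MethylationExperiment:", nrow(object), "CpG site(s) x",
      ncol(object), "record(s)\n")
  pl <- table(platforms(object))
  cat("  platforms:",
      paste(sprintf("%s (%d)", names(pl), pl), collapse = ", "), "\n")
  a <- ages(object)
  if (length(a))
    cat(sprintf("  ages: %.0f-%.0f years\n", min(a), max(a)))
  cat("  CpGs:", paste(rownames(object), collapse = ", "), "\n")
  invisible(NULL)
})

# ---- serialisation ---------------------------------------------------------

#' Read / write methylation tables
#'
#' Delimited text with header `sample_id, age, platform, replicate`
#' followed by one column per CpG; comma-separated by default (`sep = "\t"`
#' for TSV), UTF-8, `"."` decimal separator. Beta-values must be fractions
#' in \[0, 1\]; tables that look like percentages are rejected with a hint
#' to rescale. `writeMethylation()` stores betas with 6 decimal places, so
#' a write/read round trip preserves values to that precision.
#'
#' @param path file path.
#' @param sep field separator.
#' @param x a \linkS4class{MethylationExperiment}.
#' @return `readMethylation()` returns a
#'   \linkS4class{MethylationExperiment}; `writeMethylation()` returns
#'   `path` invisibly.
#' @export
readMethylation <- function(path, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          fileEncoding = "UTF-8")
  need <- c("sample_id", "age", "platform")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stopf("methylation table lacks column(s): %s", paste(miss, collapse = ", "))
  if (!"replicate" %in% colnames(df)) df$replicate <- NA_integer_
  cpgs <- setdiff(colnames(df), c("sample_id", "age", "platform", "replicate"))
  if (!length(cpgs)) stopf("no CpG beta columns found in '%s'", path)
  b <- t(as.matrix(df[, cpgs, drop = FALSE]))
  if (any(b > 1 & b <= 100, na.rm = TRUE))
    stopf(paste0("beta-values > 1 found; they look like percentages - ",
                 "rescale to fractions in [0, 1]"))
  MethylationExperiment(b, age = df$age, platform = df$platform,
                        sample_id = df$sample_id, replicate = df$replicate)
}

#' @rdname readMethylation
#' @export
writeMethylation <- function(x, path, sep = ",") {
  stopifnot(is(x, "MethylationExperiment"))
  b <- t(betas(x))
  df <- data.frame(sample_id = sampleIds(x), age = ages(x),
                   platform = platforms(x), replicate = replicates(x),
                   stringsAsFactors = FALSE, check.names = FALSE)
  for (cg in colnames(b)) df[[cg]] <- sprintf("%.6f", b[, cg])
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
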