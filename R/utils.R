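# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the seed, runs `expr`, then restores the caller's RNG state, so
#' seeded operations never perturb the global stream.
#' @noRd
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# clamp beta-values to the unit interval (measurement floor/ceiling);
# preserves dim/dimnames
clip01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

# ISO-8601 timestamped log line; messages are suppressible by callers
logMsg <- function(...) {
  message(format(Sys.time(), "[%Y-%m-%dT%H:%M:%S%z] "), ...)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

isCount <- function(x) length(x) == 1L && is.numeric(x) && !is.na(x) &&
  x == floor(x) && x >= 1
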