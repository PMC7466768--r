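# Independent brute-force oracle for linear quantile regression: the
# optimum is attained by a hyperplane through p + 1 sample points, so
# enumerating all such hyperplanes and taking the minimal pinball loss
# gives the exact optimum on small instances.
oracleQuantileLoss <- function(x, y, tau) {
  X <- cbind(1, as.matrix(x))
  n <- nrow(X); m <- ncol(X)
  best <- Inf
  idx <- utils::combn(n, m)
  for (k in seq_len(ncol(idx))) {
    S <- idx[, k]
    XS <- X[S, , drop = FALSE]
    if (abs(det(XS)) < 1e-10) next
    b <- solve(XS, y[S])
    u <- y - as.vector(X %*% b)
    L <- sum(u * (tau - (u < 0)))
    if (L < best) best <- L
  }
  best
}

# small deterministic dataset builder used across test files
makeME <- function(beta, age, platform = "P", sample_id = NULL,
                   replicate = NA_integer_) {
  if (is.null(dim(beta))) beta <- matrix(beta, nrow = 1,
                                         dimnames = list("CpG1", NULL))
  if (is.null(sample_id)) sample_id <- sprintf("S%02d", seq_len(ncol(beta)))
  MethylationExperiment(beta, age = age, platform = platform,
                        sample_id = sample_id, replicate = replicate)
}
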