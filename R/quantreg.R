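# Exact linear quantile regression.
#
# The tau-th regression quantile minimises the pinball loss
#   R(b) = sum_i rho_tau(y_i - x_i'b),  rho_tau(u) = u * (tau - 1[u < 0]),
# an LP whose dual is
#   max y'a  s.t.  X'a = (1 - tau) X'1,  0 <= a <= 1.
# A bounded-variable two-phase simplex solves the dual; at optimality the
# simplex multipliers pi satisfy y_j = x_j'pi on the basic observations,
# i.e. pi is the coefficient vector of a hyperplane through p + 1 sample
# points attaining the global optimum. Basis size is p + 1, so each
# iteration is O(n * p) and instances with thousands of observations and a
# handful of CpG predictors solve in fractions of a second.

#' Pinball (check) loss
#'
#' `sum(u * (tau - (u < 0)))` over residuals `u`; the objective whose
#' minimiser is the tau-th conditional quantile.
#'
#' @param residuals numeric residuals (years, for age models).
#' @param tau quantile level in (0, 1).
#' @return total loss (same units as the residuals).
#' @examples
#' pinballLoss(c(1, -1), 0.5)  # 1
#' pinballLoss(2, 0.9)         # 1.8
#' @export
pinballLoss <- function(residuals, tau) {
  if (length(tau) != 1L || is.na(tau) || tau <= 0 || tau >= 1)
    stopf("tau must be a single value in (0, 1)")
  sum(residuals * (tau - (residuals < 0)))
}

# Bounded-variable two-phase primal simplex:
#   max obj'x  s.t.  A x = bvec,  0 <= x <= ub   (m = nrow(A) small).
# Dantzig pricing with a Bland's-rule fallback after runs of degenerate
# pivots guarantees termination.
simplexBounded <- function(A, bvec, obj, ub, tol = 1e-9) {
  m <- nrow(A); n <- ncol(A)
  maxit <- 100L * (n + m) + 1000L
  sgn <- ifelse(bvec >= 0, 1, -1)
  Afull <- cbind(A, diag(sgn, m))
  ubfull <- c(ub, rep(Inf, m))
  nfull <- n + m
  basis <- (n + 1L):nfull
  at_upper <- rep(FALSE, nfull)
  xval <- rep(0, nfull)
  xval[basis] <- abs(bvec)

  runPhase <- function(cvec, basis, at_upper, xval, ncols) {
    it <- 0L; bland <- FALSE; degen <- 0L
    allcols <- seq_len(ncols)
    repeat {
      it <- it + 1L
      if (it > maxit) stopf("quantile-regression simplex: iteration limit")
      AB <- Afull[, basis, drop = FALSE]
      pivec <- solve(t(AB), cvec[basis])
      nb <- setdiff(allcols, basis)
      d <- cvec[nb] - as.vector(crossprod(Afull[, nb, drop = FALSE], pivec))
      up <- at_upper[nb]
      cand_inc <- nb[!up & d > tol]
      cand_dec <- nb[up & d < -tol]
      if (!length(cand_inc) && !length(cand_dec))
        return(list(basis = basis, at_upper = at_upper, xval = xval,
                    pi = pivec, obj = sum(cvec * xval)))
      if (bland) {
        j <- min(c(cand_inc, cand_dec))
      } else {
        gains <- c(d[!up & d > tol], -d[up & d < -tol])
        j <- c(cand_inc, cand_dec)[which.max(gains)]
      }
      inc <- !at_upper[j]
      w <- solve(AB, Afull[, j])
      delta <- if (inc) -w else w          # basic change per unit step
      xB <- xval[basis]
      tmax <- ubfull[j]
      leave <- 0L; leave_up <- FALSE
      for (k in seq_len(m)) {
        if (delta[k] < -tol) {
          tk <- xB[k] / (-delta[k])
          if (tk < tmax - 1e-12) { tmax <- tk; leave <- k; leave_up <- FALSE }
        } else if (delta[k] > tol) {
          ubk <- ubfull[basis[k]]
          if (is.finite(ubk)) {
            tk <- (ubk - xB[k]) / delta[k]
            if (tk < tmax - 1e-12) { tmax <- tk; leave <- k; leave_up <- TRUE }
          }
        }
      }
      if (!is.finite(tmax))
        stopf("quantile-regression simplex: unbounded subproblem")
      degen <- if (tmax < 1e-11) degen + 1L else 0L
      if (degen > 50L) bland <- TRUE
      xval[basis] <- xB + delta * tmax
      xval[j] <- xval[j] + (if (inc) tmax else -tmax)
      if (leave == 0L) {
        at_upper[j] <- !at_upper[j]
      } else {
        lv <- basis[leave]
        xval[lv] <- if (leave_up) ubfull[lv] else 0
        at_upper[lv] <- leave_up
        basis[leave] <- j
        at_upper[j] <- FALSE
      }
    }
  }

  # phase 1: drive artificials to zero
  c1 <- c(rep(0, n), rep(-1, m))
  r1 <- runPhase(c1, basis, at_upper, xval, nfull)
  if (r1$obj < -1e-7)
    stopf("quantile-regression simplex: infeasible system")
  basis <- r1$basis; at_upper <- r1$at_upper; xval <- r1$xval
  for (k in which(basis > n)) {  # swap out artificials stuck (at 0) in basis
    AB <- Afull[, basis, drop = FALSE]
    for (j in setdiff(seq_len(n), basis)) {
      if (abs(solve(AB, Afull[, j])[k]) > 1e-7) { basis[k] <- j; break }
    }
  }
  r2 <- runPhase(c(obj, rep(0, m)), basis, at_upper, xval, n)
  list(x = r2$xval[seq_len(n)], pi = r2$pi, obj = r2$obj)
}

#' Fit one regression quantile exactly
#'
#' Minimises the pinball loss of `y - (b0 + x b)` over all affine
#' coefficient vectors by an exact LP (simplex on the dual), so the
#' returned `achievedLoss` is the global optimum, not an iteratively
#' reweighted approximation. With multiple optimal bases any optimum may
#' be returned; the loss is unique.
#'
#' @param x numeric predictor matrix, n rows (samples) by p columns
#'   (CpG beta-values or z-scores); an intercept is added internally.
#' @param y numeric response (ages in years).
#' @param tau quantile level in (0, 1).
#' @return A \linkS4class{QRFit}.
#' @examples
#' x <- matrix(runif(40), 20)
#' f <- fitQuantile(x, 20 + 30 * x[, 1] + 10 * x[, 2], 0.5)
#' coef(f)
#' @export
fitQuantile <- function(x, y, tau) {
  x <- as.matrix(x)
  n <- nrow(x); p <- ncol(x)
  if (length(y) != n) stopf("length(y) must equal nrow(x)")
  if (anyNA(x) || anyNA(y)) stopf("missing values are not allowed in fit")
  if (length(tau) != 1L || tau <= 0 || tau >= 1)
    stopf("tau must be a single value in (0, 1)")
  X <- cbind(`(Intercept)` = 1, x)
  if (is.null(colnames(x)))
    colnames(X)[-1L] <- paste0("x", seq_len(p))
  if (n <= p + 1L)
    stopf("need n > p + 1 observations (n = %d, p = %d)", n, p)
  if (qr(X)$rank < p + 1L)
    stopf("collinear predictors: design matrix is rank deficient")
  sol <- simplexBounded(t(X), (1 - tau) * colSums(X), y, rep(1, n))
  b <- as.vector(sol$pi)
  names(b) <- colnames(X)
  loss <- pinballLoss(y - as.vector(X %*% b), tau)
  new("QRFit", tau = tau, coefficients = b, achievedLoss = loss)
}

#' @describeIn QRFit-class fitted coefficients, intercept first.
#' @param object a `QRFit`.
#' @param ... unused.
#' @export
setMethod("coef", "QRFit", function(object, ...) object@coefficients)

#' Achieved (minimal) pinball loss of a fit
#' @param fit a \linkS4class{QRFit}.
#' @return numeric loss.
#' @export
achievedLoss <- function(fit) fit@achievedLoss

#' @describeIn QRFit-class affine evaluation of the fitted quantile on new
#'   predictors (matrix with the same column count the fit was made with);
#'   no clipping is applied.
#' @param newdata predictor matrix.
#' @export
setMethod("predict", "QRFit", function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  p <- length(object@coefficients) - 1L
  if (ncol(newdata) != p)
    stopf("fit expects %d predictor(s), got %d", p, ncol(newdata))
  as.vector(cbind(1, newdata) %*% object@coefficients)
})

setMethod("show", "QRFit", function(object) {
  cat(sprintf("QRFit (tau = %.2f), achieved pinball loss %.4f\n",
              object@tau, object@achievedLoss))
  print(object@coefficients)
  invisible(NULL)
})
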