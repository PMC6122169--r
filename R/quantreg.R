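# Linear quantile regression by pinball-loss minimization.
#
# The fitter implements the classical exchange (simplex) algorithm on basic
# solutions: an optimal tau-quantile regression plane interpolates p of the
# n observations, so the algorithm walks from basis to basis, relaxing one
# interpolated point at a time along the direction of steepest descent of
# the pinball loss until all one-sided directional derivatives are
# non-negative. For p = 1 this reduces to the sample tau-quantile; for the
# gap-filler p is at most 3 (intercept, slice anomaly, elevation).

#' Pinball (check) loss
#'
#' @param r Residual vector.
#' @param tau Quantile level in (0, 1).
#' @return The summed check-function loss `sum(r * (tau - (r < 0)))`.
#' @export
pinball_loss <- function(r, tau) sum(r * (tau - (r < 0)))

#' Fit a linear quantile regression
#'
#' Minimizes the pinball loss at level `tau` for the linear model
#' `y = X beta` with no implicit intercept (include a column of ones).
#'
#' @param X Numeric design matrix, n x p, full column rank.
#' @param y Numeric response vector of length n >= p.
#' @param tau Quantile level, strictly inside (0, 1).
#' @param max_iter Safety cap on basis exchanges.
#' @param basis0 Optional starting basis (p row indices spanning a
#'   nonsingular system), e.g. from a fit at a nearby tau.
#' @return List with `coefficients`, `tau`, `basis` (row indices the fitted
#'   plane interpolates), `loss`, `iterations` and `converged`.
#' @export
rq_fit <- function(X, y, tau, max_iter = 500L, basis0 = NULL) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  stopifnot(length(y) == n, n >= p, p >= 1, tau > 0, tau < 1,
            all(is.finite(X)), all(is.finite(y)))
  tol <- 1e-9 * (1 + max(abs(y)))
  utol <- 1e-9 * (1 + max(abs(X)))

  B <- NULL
  if (!is.null(basis0) && length(basis0) == p &&
      all(basis0 >= 1 & basis0 <= n)) {
    if (abs(det(X[basis0, , drop = FALSE])) > 1e-12) B <- as.integer(basis0)
  }
  if (is.null(B)) B <- rq_start_basis(X, y, p)
  converged <- FALSE
  iter <- 0L
  # Bases already examined at the current (possibly degenerate) vertex; a
  # vertex where > p points have zero residual has several basis
  # representations and its full edge set is only visible across all of them.
  seen <- character(0)
  repeat {
    iter <- iter + 1L
    XB <- X[B, , drop = FALSE]
    A <- solve(XB)                       # p x p; columns are basis directions
    beta <- drop(A %*% y[B])
    r <- drop(y - X %*% beta)
    r[B] <- 0
    if (max(abs(r)) <= tol) { converged <- TRUE; break }  # perfect fit: loss 0
    U <- X %*% A                         # u[i, k] = response of r_i to d_k
    nonbasis <- rep(TRUE, n); nonbasis[B] <- FALSE
    pos <- nonbasis & (r > tol)
    neg <- nonbasis & (r < -tol)
    zer <- which(nonbasis & !pos & !neg)
    # one-sided directional derivatives for relaxing basis point k by +/- 1:
    # smooth part as one weighted cross-product, zero-residual corrections
    # (usually few rows) added one-sidedly
    w <- numeric(n)
    w[pos] <- -tau
    w[neg] <- 1 - tau
    base <- drop(crossprod(w, U))
    Dplus <- (1 - tau) + base
    Dminus <- tau - base
    if (length(zer)) {
      Uz <- U[zer, , drop = FALSE]
      Dplus <- Dplus + colSums(tau * pmax(-Uz, 0) + (1 - tau) * pmax(Uz, 0))
      Dminus <- Dminus + colSums(tau * pmax(Uz, 0) + (1 - tau) * pmax(-Uz, 0))
    }
    k <- which.min(pmin(Dplus, Dminus))
    s <- if (Dplus[k] <= Dminus[k]) 1 else -1
    D0 <- min(Dplus[k], Dminus[k])
    if (D0 >= -tol) {
      # No descent from this basis. If the vertex is degenerate, pivot to a
      # not-yet-seen basis of the same vertex and re-test before accepting.
      zidx <- zer
      B2 <- NULL
      if (length(zidx)) {
        seen <- c(seen, paste(sort(B), collapse = ","))
        for (j in zidx) {
          for (kk in seq_len(p)) {
            if (abs(U[j, kk]) > utol) {
              cand <- B; cand[kk] <- j
              if (!(paste(sort(cand), collapse = ",") %in% seen)) {
                B2 <- cand; break
              }
            }
          }
          if (!is.null(B2)) break
        }
      }
      if (is.null(B2)) { converged <- TRUE; break }
      B <- B2
      if (iter > max_iter) break
      next
    }
    if (iter > max_iter) break
    seen <- character(0)                 # leaving the vertex: real move

    u <- s * U[, k]
    cand <- which(nonbasis & abs(u) > utol & (r / u) > 0 & abs(r) > tol)
    if (!length(cand)) stop("quantile regression fit is unbounded")
    ord <- cand[order(r[cand] / u[cand])]
    cum <- D0
    enter <- NA_integer_
    for (i in ord) {
      cum <- cum + abs(u[i])
      if (cum >= -tol) { enter <- i; break }
    }
    if (is.na(enter)) enter <- ord[length(ord)]
    B[k] <- enter
  }
  XB <- X[B, , drop = FALSE]
  beta <- drop(solve(XB, y[B]))
  list(coefficients = beta, tau = tau, basis = sort(B),
       loss = pinball_loss(drop(y - X %*% beta), tau),
       iterations = iter, converged = converged)
}

# Initial basis: the p rows with smallest least-squares residuals that form
# a nonsingular system (greedy rank-building scan).
rq_start_basis <- function(X, y, p) {
  n <- nrow(X)
  qx <- qr(X)
  if (qx$rank < p) stop("design matrix is rank deficient")
  rhat <- abs(y - X %*% qr.coef(qx, y))
  ord <- order(rhat)
  B <- integer(0)
  for (i in ord) {
    cand <- c(B, i)
    if (qr(X[cand, , drop = FALSE])$rank == length(cand)) B <- cand
    if (length(B) == p) break
  }
  if (length(B) < p) stop("could not find a nonsingular starting basis")
  B
}

#' Koenker-Machado goodness of fit for a quantile regression
#'
#' The R1 criterion: one minus the ratio of the tau-weighted absolute
#' residual sums of the full fit and of the intercept-only (sample
#' tau-quantile) fit.
#'
#' @param fit Result of [rq_fit()].
#' @param X,y The design matrix and response the fit was computed from.
#' @return Pseudo-R2 value in `[0, 1]`.
#' @export
rq_pseudo_r2 <- function(fit, X, y) {
  tau <- fit$tau
  v_full <- pinball_loss(drop(y - as.matrix(X) %*% fit$coefficients), tau)
  null_fit <- rq_fit(matrix(1, length(y), 1), y, tau)
  v_null <- null_fit$loss
  if (v_null <= 0) return(if (v_full <= 0) 0 else NA_real_)
  max(0, min(1, 1 - v_full / v_null))
}
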