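#' Correlation-derived penalty weights
#'
#' Weighted sparse representation penalizes each candidate edge in inverse
#' proportion to its marginal correlation: `C[j, i] = exp(-P[j, i]^2 / sigma)`.
#' Strongly correlated pairs get a small penalty (their edge survives the
#' lasso longer), weakly correlated pairs a penalty near 1. `sigma` tunes
#' how fast the penalty decays with correlation strength; 0.2 is the
#' conventional choice for resting-state connectivity work.
#'
#' @param P N x N Pearson correlation matrix.
#' @param sigma positive decay parameter (default 0.2).
#' @return N x N matrix of weights in (0, 1].
#' @export
penalty_weights <- function(P, sigma = 0.2) {
  if (!is.numeric(sigma) || length(sigma) != 1 || !is.finite(sigma) || sigma <= 0)
    rlang::abort("sigma must be a single positive number")
  stopifnot(is.matrix(P), nrow(P) == ncol(P))
  exp(-P^2 / sigma)
}

#' Smallest penalty that zeroes the whole WSR solution
#'
#' For the weighted lasso objective `0.5 * ||x_i - X_i w||^2 +
#' lambda * ||c_i * w||_1` the zero solution is optimal exactly when
#' `|X_i' x_i| <= lambda * c_i` elementwise, so the critical value over all
#' columns is `max |P[j, i]| / C[j, i]` off the diagonal.
#'
#' @param ts normalized [ts_matrix][new_ts_matrix].
#' @param C penalty weight matrix from [penalty_weights()].
#' @return single positive number.
#' @export
wsr_lambda_max <- function(ts, C) {
  P <- pearson_matrix(ts)
  off <- abs(P) / C
  diag(off) <- 0
  max(off)
}

# ADMM for one column of the WSR problem:
#   min_w 0.5 * ||x - D w||^2 + lambda * ||c * w||_1
# with D the dictionary whose i-th column is zeroed. Splitting w = z,
# the w-update solves (D'D + rho I) w = D'x + rho (z - u), the z-update is
# an elementwise soft threshold at lambda * c / rho, and u accumulates the
# scaled dual. Stopping follows the standard primal/dual residual rule.
solve_wsr_column <- function(Dtx, R, c_i, lam, rho, max_iter, abstol, reltol,
                             track = NULL) {
  n <- length(Dtx)
  w <- numeric(n); z <- numeric(n); u <- numeric(n)
  thr <- lam * c_i / rho
  converged <- FALSE
  iters <- max_iter
  obj <- if (is.null(track)) NULL else numeric(0)
  for (it in seq_len(max_iter)) {
    w <- backsolve(R, backsolve(R, Dtx + rho * (z - u), transpose = TRUE))
    z_old <- z
    v <- w + u
    z <- sign(v) * pmax(abs(v) - thr, 0)
    u <- u + w - z
    if (!is.null(track)) {
      obj <- c(obj, 0.5 * sum((track$x - track$D %*% z)^2) +
                 lam * sum(abs(c_i * z)))
    }
    r_norm <- sqrt(sum((w - z)^2))
    s_norm <- rho * sqrt(sum((z - z_old)^2))
    eps_pri <- sqrt(n) * abstol + reltol * max(sqrt(sum(w^2)), sqrt(sum(z^2)))
    eps_dual <- sqrt(n) * abstol + reltol * rho * sqrt(sum(u^2))
    if (r_norm < eps_pri && s_norm < eps_dual) {
      converged <- TRUE
      iters <- it
      break
    }
  }
  list(z = z, converged = converged, iters = iters, objective = obj)
}

#' Weighted sparse representation of a subject's connectivity
#'
#' Solves, by ADMM, the weighted lasso
#' \deqn{\min_W \tfrac12 \|X - XW\|_F^2 + \lambda \|C \odot W\|_1,
#'       \quad W_{ii}=0,}
#' column by column: region i's normalized signal is regressed on all other
#' regions (the i-th dictionary column is zeroed to forbid the trivial
#' self-representation), with each coefficient's L1 penalty scaled by the
#' correlation-derived weight `C[j, i]`. The returned coefficient matrix is
#' asymmetric with an exactly zero diagonal; its sparsity grows with
#' `lambda`.
#'
#' @param ts normalized [ts_matrix][new_ts_matrix].
#' @param C penalty weights from [penalty_weights()] (same dimension as the
#'   correlation matrix).
#' @param lam positive sparsity prior.
#' @param rho ADMM penalty parameter.
#' @param max_iter iteration cap per column; if any column fails to meet the
#'   primal/dual tolerances within the cap the best iterate is returned and
#'   the `converged` flag is set to `FALSE` with a warning.
#' @param abstol,reltol absolute / relative stopping tolerances.
#'
#' @return A list of class `wsr_fit` with elements `W` (N x N coefficient
#'   matrix, zero diagonal), `lam`, `converged`, `iterations` (per column)
#'   and `objective` (value of the penalized objective at `W`).
#' @export
solve_wsr <- function(ts, C, lam, rho = 1.0, max_iter = 1000,
                      abstol = 1e-8, reltol = 1e-6) {
  stopifnot(inherits(ts, "ts_matrix"))
  if (!isTRUE(ts$normalized)) rlang::abort("time series must be normalized")
  if (!is.numeric(lam) || length(lam) != 1 || lam <= 0)
    rlang::abort("lam must be a single positive number")
  X <- ts$values
  N <- ncol(X)
  stopifnot(all(dim(C) == c(N, N)), all(C > 0))
  G <- crossprod(X)                       # X'X, shared across columns
  W <- matrix(0, N, N)
  iters <- integer(N)
  ok <- logical(N)
  for (i in seq_len(N)) {
    # dictionary D = X with column i zeroed: D'D is G with row/col i zeroed
    A <- G
    A[i, ] <- 0
    A[, i] <- 0
    Dtx <- G[, i]
    Dtx[i] <- 0
    R <- chol(A + diag(rho, N))
    sol <- solve_wsr_column(Dtx, R, C[, i], lam, rho, max_iter, abstol, reltol)
    w <- sol$z
    w[i] <- 0                             # exact structural zero
    W[, i] <- w
    iters[i] <- sol$iters
    ok[i] <- sol$converged
  }
  if (!all(ok)) {
    rlang::warn(sprintf("WSR ADMM did not converge for %d column(s) within %d iterations; best iterate returned",
                        sum(!ok), max_iter))
  }
  obj <- 0.5 * sum((X - X %*% W)^2) + lam * sum(abs(C * W))
  structure(list(W = W, lam = lam, converged = all(ok),
                 iterations = iters, objective = obj),
            class = "wsr_fit")
}

#' Objective value of the WSR problem
#'
#' @param ts normalized [ts_matrix][new_ts_matrix].
#' @param W coefficient matrix.
#' @param C penalty weights.
#' @param lam sparsity prior.
#' @return the penalized objective `0.5||X - XW||_F^2 + lam ||C * W||_1`.
#' @export
wsr_objective <- function(ts, W, C, lam) {
  X <- ts$values
  0.5 * sum((X - X %*% W)^2) + lam * sum(abs(C * W))
}
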