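test_that("lambda at or above the critical value gives the empty solution", {
  ts <- random_normalized_ts(30, 5, seed = 10)
  P <- pearson_matrix(ts)
  C <- penalty_weights(P)
  lmax <- wsr_lambda_max(ts, C)
  fit <- solve_wsr(ts, C, lmax * (1 + 1e-8))
  expect_equal(fit$W, matrix(0, 5, 5))
  # just below the critical value something survives
  fit2 <- solve_wsr(ts, C, lmax * 0.95)
  expect_gt(sum(fit2$W != 0), 0)
})

test_that("two-ROI problem matches the closed-form soft threshold", {
  # with unit-norm columns the univariate lasso solution is
  # S(x2'x1, lam * C21) since x2'x2 = 1
  set.seed(11)
  for (i in 1:5) {
    ts <- random_normalized_ts(25, 2, seed = 100 + i)
    r <- sum(ts$values[, 1] * ts$values[, 2])
    C <- penalty_weights(pearson_matrix(ts))
    lam <- runif(1, 0.05, 1) * abs(r) / C[2, 1]
    fit <- solve_wsr(ts, C, lam)
    expected <- sign(r) * max(abs(r) - lam * C[2, 1], 0)
    expect_lt(abs(fit$W[2, 1] - expected), 1e-6)
    expect_lt(abs(fit$W[1, 2] - sign(r) * max(abs(r) - lam * C[1, 2], 0)),
              1e-6)
    expect_identical(diag(fit$W), rep(0, 2))
  }
})

test_that("unweighted solutions match a brute-force coordinate-descent lasso", {
  set.seed(12)
  ts <- random_normalized_ts(30, 6, seed = 12)
  C1 <- matrix(1, 6, 6)
  for (lam in c(0.02, 0.08, 0.2)) {
    fit <- solve_wsr(ts, C1, lam)
    X <- ts$values
    for (i in 1:6) {
      D <- X; D[, i] <- 0
      w_ref <- cd_lasso(D, X[, i], lam, rep(1, 6))
      expect_lt(max(abs(fit$W[, i] - w_ref)), 1e-5)
    }
  }
})

test_that("weighted solutions match the weighted coordinate-descent oracle", {
  ts <- random_normalized_ts(40, 7, seed = 13)
  P <- pearson_matrix(ts)
  C <- penalty_weights(P)
  fit <- solve_wsr(ts, C, 0.1)
  X <- ts$values
  for (i in 1:7) {
    D <- X; D[, i] <- 0
    w_ref <- cd_lasso(D, X[, i], 0.1, C[, i])
    expect_lt(max(abs(fit$W[, i] - w_ref)), 1e-5)
  }
})

test_that("unweighted solutions agree with glmnet as a second reference", {
  skip_if_not_installed("glmnet")
  ts <- random_normalized_ts(30, 6, seed = 14)
  X <- ts$values
  L <- nrow(X)
  lam <- 0.05
  fit <- solve_wsr(ts, matrix(1, 6, 6), lam)
  for (i in c(1, 4)) {
    D <- X[, -i]
    g <- glmnet::glmnet(D, X[, i], lambda = lam / L, standardize = FALSE,
                        intercept = FALSE, thresh = 1e-14)
    w_ref <- as.vector(g$beta)
    expect_equal(fit$W[-i, i], w_ref, tolerance = 1e-4, ignore_attr = TRUE)
  }
})

test_that("ADMM objective decreases after burn-in and beats the zero solution", {
  ts <- random_normalized_ts(30, 6, seed = 15)
  P <- pearson_matrix(ts)
  C <- penalty_weights(P)
  lam <- 0.05
  fit <- solve_wsr(ts, C, lam)
  obj0 <- wsr_objective(ts, matrix(0, 6, 6), C, lam)
  expect_lte(fit$objective, obj0)
  expect_true(fit$converged)

  # per-column iterate objective is non-increasing after burn-in
  X <- ts$values
  i <- 1
  D <- X; D[, i] <- 0
  A <- crossprod(D)
  R <- chol(A + diag(1, 6))
  sol <- smfcnet:::solve_wsr_column(crossprod(D, X[, i]), R, C[, i], lam,
                                    rho = 1, max_iter = 200,
                                    abstol = 0, reltol = 0,
                                    track = list(D = D, x = X[, i]))
  burn <- 10
  diffs <- diff(sol$objective[burn:length(sol$objective)])
  expect_true(all(diffs <= 1e-10))
})

test_that("a smaller penalty weight lets an equally correlated predictor survive longer", {
  # two predictors with identical correlation to the target but different
  # penalty weights: the lightly penalized one outlives the other as
  # lambda grows
  set.seed(16)
  z <- rnorm(50); e1 <- rnorm(50); e2 <- rnorm(50)
  raw <- cbind(z, z + 0.8 * e1, z + 0.8 * e2)
  ts <- normalize_series(raw)
  r12 <- sum(ts$values[, 1] * ts$values[, 2])
  r13 <- sum(ts$values[, 1] * ts$values[, 3])
  expect_equal(r12, r13, tolerance = 0.25)       # comparable by design
  C <- matrix(1, 3, 3)
  C[2, 1] <- 0.2                                 # predictor 2 lightly penalized
  C[3, 1] <- 0.9
  lam <- 0.9 * max(abs(r12), abs(r13)) / C[3, 1]
  fit <- solve_wsr(ts, C, lam)
  expect_gt(abs(fit$W[2, 1]), 1e-5)
  expect_lt(abs(fit$W[3, 1]), 1e-8)
})

test_that("network density is non-increasing along the sparsity grid", {
  for (s in 1:3) {
    ts <- random_normalized_ts(40, 10, seed = 20 + s)
    st <- build_fcn_stack(ts, lam_grid = dyadic_grid(-4, 5))
    dens <- apply(st$M, 3, network_density)
    expect_true(all(diff(dens) <= 0))
    expect_equal(dim(st$M)[3], 10)
    # a sufficiently large lambda empties the network
    expect_equal(dens[10], 0)
    # masks are symmetric with zero diagonal, and M entries equal P on
    # the support
    P <- pearson_matrix(ts)
    for (k in c(1, 3)) {
      m <- st$M[, , k]
      expect_identical(m, t(m))
      expect_identical(diag(m), rep(0, 10))
      expect_true(all(m[m != 0] == P[m != 0]))
    }
  }
})

test_that("the non-convergence path flags and returns the best iterate", {
  ts <- random_normalized_ts(30, 8, seed = 30)
  C <- penalty_weights(pearson_matrix(ts))
  expect_warning(fit <- solve_wsr(ts, C, 0.01, max_iter = 2), "converge")
  expect_false(fit$converged)
  expect_true(all(is.finite(fit$W)))
})
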