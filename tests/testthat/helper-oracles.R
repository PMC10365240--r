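# Independent oracles and shared fixtures for the suite.

# Brute-force coordinate-descent lasso, run to tight tolerance; the
# independent reference for the ADMM solver. Objective convention matches
# the solver: 0.5 * ||x - D w||^2 + lam * ||pen * w||_1.
cd_lasso <- function(D, x, lam, pen, tol = 1e-10, maxit = 50000) {
  w <- numeric(ncol(D))
  G <- crossprod(D)
  Dx <- crossprod(D, x)
  dg <- diag(G)
  for (it in seq_len(maxit)) {
    w_old <- w
    for (j in seq_along(w)) {
      if (dg[j] == 0) { w[j] <- 0; next }
      r <- Dx[j] - sum(G[j, ] * w) + dg[j] * w[j]
      w[j] <- sign(r) * max(abs(r) - lam * pen[j], 0) / dg[j]
    }
    if (max(abs(w - w_old)) < tol) break
  }
  w
}

# A stack whose only information is the sign of one edge (1,2); subjects
# with value v get M[1,2] = M[2,1] = v in every level.
one_edge_stack <- function(v, N = 6, d = 2, id = NA_character_) {
  M <- array(0, c(N, N, d))
  M[1, 2, ] <- v
  M[2, 1, ] <- v
  smfcnet:::new_fcn_stack(M, seq_len(d), paste0("ROI", seq_len(N)),
                          subject_id = id)
}

# Separable two-class cohort of one-edge stacks: class 1 positive values,
# class 0 negative.
one_edge_cohort <- function(n_per_class = 20, N = 6, d = 2, seed = 1) {
  set.seed(seed)
  v1 <- runif(n_per_class, 0.5, 0.9)
  v0 <- runif(n_per_class, -0.9, -0.5)
  list(stacks = c(lapply(v1, one_edge_stack, N = N, d = d),
                  lapply(v0, one_edge_stack, N = N, d = d)),
       labels = rep(c(1L, 0L), each = n_per_class))
}

tiny_cfg <- function(N = 6, d = 2, epochs = 15, seed = 1) {
  smfc_config(N = N, d = d, H = 4, V = 2, D1 = 8, D2 = 4,
              epochs = epochs, batch_size = 10, seed = seed)
}

# One small nested-CV run on the separable cohort, computed once and
# shared by the evaluation, occlusion and acceptance tests.
tiny_cv_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      dat <- one_edge_cohort(n_per_class = 20)
      cv <- nested_cv(dat$stacks, dat$labels,
                      cv_plan(outer_reps = 1, seed = 5),
                      tiny_cfg(), keep_models = TRUE)
      cache <<- list(cv = cv, stacks = dat$stacks, labels = dat$labels)
    }
    cache
  }
})

random_normalized_ts <- function(L, N, seed) {
  set.seed(seed)
  normalize_series(matrix(rnorm(L * N), L, N))
}
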