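test_that("normalization centers columns and makes cross-products correlations", {
  x <- normalize_series(matrix(c(1, 2, 3), 3, 1))
  expect_equal(as.vector(x$values), c(-1, 0, 1) / sqrt(2))
  expect_equal(sum(x$values^2), 1)

  # two identical columns correlate perfectly
  x2 <- normalize_series(cbind(c(1, 2, 3), c(1, 2, 3) * 2 + 5))
  expect_equal(sum(x2$values[, 1] * x2$values[, 2]), 1)

  # hand-evaluated Pearson of (1,2,3) and (1,3,2)
  x3 <- normalize_series(cbind(c(1, 2, 3), c(1, 3, 2)))
  expect_equal(sum(x3$values[, 1] * x3$values[, 2]), 0.5)

  set.seed(1)
  m <- matrix(rnorm(200), 20, 10)
  ts <- normalize_series(m)
  expect_lt(max(abs(colMeans(ts$values))), 1e-10)
  expect_equal(colSums(ts$values^2), rep(1, 10), tolerance = 1e-12)
})

test_that("degenerate inputs are rejected with a column diagnostic", {
  m <- cbind(rnorm(5), rep(2, 5))
  expect_error(normalize_series(m), "column 2")
  expect_error(normalize_series(m[1, , drop = FALSE]), "2 time points")
  m2 <- matrix(rnorm(10), 5, 2)
  m2[3, 1] <- NA
  expect_error(normalize_series(m2), "non-finite")
  expect_error(normalize_series(cbind(rnorm(5), rep(1, 5)),
                                roi_ids = c("A", "Thalamus")),
               "Thalamus")
})

test_that("pearson_matrix agrees with the textbook correlation entrywise", {
  set.seed(2)
  for (i in 1:3) {
    m <- matrix(rnorm(3 * (15 + i)), 15 + i, 3)
    ts <- normalize_series(m)
    P <- pearson_matrix(ts)
    expect_equal(P, cor(m), ignore_attr = TRUE, tolerance = 1e-12)
    expect_true(all(P >= -1 & P <= 1))
    expect_equal(diag(P), rep(1, 3), ignore_attr = TRUE)
    expect_identical(P, t(P))
  }
  # anti-parallel series give exactly -1
  ts <- normalize_series(cbind(c(1, 2, 3), c(3, 2, 1)))
  expect_equal(pearson_matrix(ts)[1, 2], -1)
  expect_error(pearson_matrix(smfcnet:::new_ts_matrix(matrix(1:4, 2))),
               "normalized")
})

test_that("penalty weights follow the Gaussian decay in squared correlation", {
  P <- matrix(c(1, 0, 0.5, 0, 1, 1, 0.5, 1, 1), 3, 3)
  C <- penalty_weights(P, sigma = 0.2)
  expect_equal(C[1, 2], 1)                      # r = 0 -> weight 1
  expect_equal(C[2, 3], exp(-5))                # r = 1, sigma 0.2
  expect_equal(C[1, 3], exp(-1.25))             # r = 0.5
  expect_identical(C, t(C))
  expect_true(all(C > 0 & C <= 1))
  expect_error(penalty_weights(P, sigma = 0), "positive")
  expect_error(penalty_weights(P, sigma = -1), "positive")
  # monotone: larger |r| means smaller penalty
  r <- seq(0, 1, by = 0.1)
  w <- vapply(r, function(x) penalty_weights(matrix(x, 1, 1), 0.2)[1, 1],
              numeric(1))
  expect_true(all(diff(w) < 0))
})

test_that("support binarization applies the OR rule and is idempotent", {
  W <- matrix(c(0, -0.2, 0.3, 0), 2, 2)
  G <- binarize_symmetric_support(W)
  expect_equal(G, matrix(c(0, 1, 1, 0), 2, 2))

  W2 <- matrix(0, 3, 3)
  W2[1, 2] <- 0.3                               # one direction only
  G2 <- binarize_symmetric_support(W2)
  expect_equal(G2[1, 2], 1)
  expect_equal(G2[2, 1], 1)
  expect_equal(binarize_symmetric_support(matrix(0, 4, 4)), matrix(0, 4, 4))
  # idempotent under re-binarization
  expect_equal(binarize_symmetric_support(G2), G2)
  # eps decides what counts as zero
  expect_equal(binarize_symmetric_support(W2, eps = 0.5), matrix(0, 3, 3))
})

test_that("masking keeps retained Pearson entries bit-exactly", {
  set.seed(3)
  ts <- normalize_series(matrix(rnorm(80), 20, 4))
  P <- pearson_matrix(ts)
  G <- matrix(rbinom(16, 1, 0.5), 4, 4)
  G <- G * t(G); diag(G) <- 0
  M <- sparsity_guided_fcn(P, G)
  # explicit double-loop oracle
  for (i in 1:4) for (j in 1:4) {
    if (i == j) expect_identical(M[i, j], 0)
    else expect_identical(M[i, j], G[i, j] * P[i, j])
  }
  expect_true(all(M[M != 0] == P[M != 0]))
  expect_equal(sparsity_guided_fcn(P, matrix(0, 4, 4)), matrix(0, 4, 4),
               ignore_attr = TRUE)
  ones <- 1 - diag(4)
  M1 <- sparsity_guided_fcn(P, ones)
  expect_equal(M1 + diag(4), P, ignore_attr = TRUE)
  expect_error(sparsity_guided_fcn(P, matrix(0, 3, 3)), "shape mismatch")
})

test_that("hard thresholding keeps exactly the strongest edge pairs", {
  set.seed(4)
  ts <- random_normalized_ts(140, 120, seed = 4)
  P <- pearson_matrix(ts)
  st <- hard_threshold_stack(P, percents = c(50, 99))
  # 99% discard on 120 ROIs leaves floor(0.01 * 7140) = 71 edge pairs
  expect_equal(sum(st$M[, , 2] != 0) / 2, 71)
  expect_equal(sum(st$M[, , 1] != 0) / 2, floor(0.5 * 7140))
  # survivors' weakest |value| dominates discarded strongest
  m <- st$M[, , 1]
  surv <- abs(m[upper.tri(m)][m[upper.tri(m)] != 0])
  disc <- abs(P[upper.tri(P)])[m[upper.tri(m)] == 0]
  expect_gte(min(surv), max(disc))
  expect_identical(st$M[, , 1], t(st$M[, , 1]))
  # a vanishing threshold retains (all but the floor rounding of) the
  # off-diagonal matrix, every survivor keeping its Pearson value
  st0 <- hard_threshold_stack(P, percents = 1e-6)
  m0 <- st0$M[, , 1]
  expect_equal(sum(m0 != 0) / 2, floor((1 - 1e-8) * 7140))
  expect_true(all(m0[m0 != 0] == P[m0 != 0]))
  expect_error(hard_threshold_stack(P, percents = 100), "between 0 and 100")
})

test_that("hard-threshold ties break deterministically by edge order", {
  P <- matrix(0.5, 4, 4); diag(P) <- 1   # all off-diagonal entries tie
  st1 <- hard_threshold_stack(P, percents = 50)
  st2 <- hard_threshold_stack(P, percents = 50)
  expect_identical(st1$M, st2$M)
  expect_equal(sum(st1$M[, , 1] != 0) / 2, 3)   # floor(0.5 * 6)
  kept <- which(upper.tri(P) & st1$M[, , 1] != 0, arr.ind = TRUE)
  expect_equal(kept[order(kept[, 1], kept[, 2]), , drop = FALSE],
               cbind(row = c(1, 1, 1), col = c(2, 3, 4)),
               ignore_attr = TRUE)
})

test_that("initial-volume discarding trims leading time points", {
  raw <- matrix(rnorm(150 * 3), 150, 3)
  trimmed <- discard_initial_volumes(raw)
  expect_equal(nrow(trimmed), 140)
  expect_identical(trimmed, raw[11:150, ])
  expect_identical(discard_initial_volumes(raw, 0), raw)
})

test_that("cohort stack variants dispatch to the right construction", {
  sim <- sample_cohort(cohort_spec(n_per_group = c(2, 2), N = 8, L = 40,
                                   seed = 90))
  ht <- build_cohort_stacks(sim$cohort, variant = "htfc",
                            percents = c(50, 90))
  expect_length(ht, 4)
  expect_equal(ht[[1]]$kind, "hard_threshold")
  expect_equal(dim(ht[[1]]$M)[3], 2)
  ss <- build_cohort_stacks(sim$cohort[1:2], variant = "ssfc:2",
                            lam_grid = dyadic_grid(-4, -2))
  expect_equal(dim(ss[[1]]$M)[3], 1)
  expect_equal(ss[[1]]$lam_grid, 2^-3)
  expect_error(build_cohort_stacks(sim$cohort, variant = "nope"),
               "unknown variant")
})
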