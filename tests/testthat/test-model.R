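test_that("the layer chain produces the contracted tensor shapes", {
  set.seed(40)
  for (i in 1:4) {
    N <- sample(4:12, 1); d <- sample(1:3, 1)
    H <- sample(3:8, 1); V <- sample(2:5, 1)
    cfg <- smfc_config(N = N, d = d, H = H, V = V, D1 = 7, D2 = 5,
                       epochs = 1, seed = i)
    model <- build_smfc(cfg)
    B <- 3
    S <- array(rnorm(N * N * d * B), c(N, N, d, B))
    cc <- smfcnet:::smfc_forward(model$params, cfg, S, cache = TRUE)
    # branch conv1: one N x H activation per subject (i.e. N x 1 x H)
    expect_equal(dim(cc$A1pre[[1]]), c(N * B, H))
    # branch conv2: one V-vector per subject (1 x 1 x V)
    expect_equal(dim(cc$F2pre[[1]]), c(B, V))
    # concatenation of d branches
    expect_equal(dim(cc$Fc), c(B, d * V))
    expect_equal(dim(cc$H1pre), c(B, 7))
    expect_equal(dim(cc$H2pre), c(B, 5))
    expect_equal(dim(cc$prob), c(B, 2))
    sh <- smfc_shapes(cfg)
    expect_equal(sh$shape[[2]], c(N, 1L, H))
    expect_equal(sh$shape[[3]], c(1L, 1L, V))
    expect_equal(sh$shape[[4]], d * V)
  }
})

test_that("parameter counts follow the kernel-size formulas", {
  cfg <- smfc_config(N = 120, d = 10, seed = 1)
  counts <- smfc_parameter_counts(cfg)
  # 1 x N kernel with H channels plus biases
  expect_equal(counts$n_parameters[counts$layer == "conv1_per_branch"],
               64 * (120 + 1))
  expect_equal(counts$n_parameters[counts$layer == "conv1_per_branch"], 7744)
  # actual tensors agree with the formulas
  cfg_small <- smfc_config(N = 9, d = 2, H = 5, V = 3, D1 = 7, D2 = 4, seed = 1)
  model <- build_smfc(cfg_small)
  counts_small <- smfc_parameter_counts(cfg_small)
  expect_equal(length(model$params$K1.1) + length(model$params$b1.1),
               counts_small$n_parameters[1])
  expect_equal(length(model$params$K2.1) + length(model$params$b2.1),
               counts_small$n_parameters[2])
  expect_equal(length(model$params$W1) + length(model$params$c1),
               counts_small$n_parameters[3])
})

test_that("analytic gradients match finite differences", {
  cfg <- smfc_config(N = 4, d = 2, H = 3, V = 2, D1 = 5, D2 = 4,
                     dropout = 0, l2 = 1e-3, epochs = 1, seed = 7)
  model <- build_smfc(cfg)
  set.seed(8)
  B <- 5
  S <- array(rnorm(4 * 4 * 2 * B), c(4, 4, 2, B))
  y <- c(0L, 1L, 1L, 0L, 1L)
  params <- model$params
  cc <- smfcnet:::smfc_forward(params, cfg, S, train = FALSE, cache = TRUE)
  grads <- smfcnet:::smfc_backward(params, cfg, cc, y)
  eps <- 1e-6
  loss_at <- function(p) {
    out <- smfcnet:::smfc_forward(p, cfg, S, train = FALSE)
    smfcnet:::smfc_loss(p, cfg, out$prob, y)
  }
  for (nm in c("K1.1", "K2.2", "b1.2", "W1", "W3", "c2")) {
    idx <- sample(length(params[[nm]]), min(4, length(params[[nm]])))
    for (j in idx) {
      pp <- params; pp[[nm]][j] <- pp[[nm]][j] + eps
      pm <- params; pm[[nm]][j] <- pm[[nm]][j] - eps
      num <- (loss_at(pp) - loss_at(pm)) / (2 * eps)
      expect_equal(grads[[nm]][j], num, tolerance = 1e-4)
    }
  }
})

test_that("training separates a linearly separable one-edge cohort", {
  dat <- one_edge_cohort(n_per_class = 10, seed = 41)
  cfg <- tiny_cfg(epochs = 60, seed = 41)
  model <- train_smfc(dat$stacks, dat$labels, cfg)
  expect_equal(mean(predict_label(model, dat$stacks) == dat$labels), 1)
  expect_lte(model$history[length(model$history)], model$history[1])
  expect_length(model$history, 60)
})

test_that("identical inputs with mixed labels train to the class prior", {
  stacks <- lapply(1:12, function(i) one_edge_stack(0.5))
  y <- rep(c(1L, 0L), times = c(7, 5))
  model <- train_smfc(stacks, y, tiny_cfg(epochs = 30, seed = 42))
  acc <- mean(predict_label(model, stacks) == y)
  # no signal: accuracy can only reflect the majority class
  expect_lte(acc, 7 / 12 + 1e-9)
  expect_gte(acc, 5 / 12 - 1e-9)
})

test_that("training is bitwise reproducible under a fixed seed", {
  dat <- one_edge_cohort(n_per_class = 6, seed = 43)
  cfg <- tiny_cfg(epochs = 10, seed = 43)
  m1 <- train_smfc(dat$stacks, dat$labels, cfg)
  m2 <- train_smfc(dat$stacks, dat$labels, cfg)
  expect_identical(m1$history, m2$history)
  expect_identical(m1$params, m2$params)
})

test_that("predicted probabilities are a proper, stable distribution", {
  dat <- one_edge_cohort(n_per_class = 6, seed = 44)
  model <- train_smfc(dat$stacks, dat$labels, tiny_cfg(epochs = 5, seed = 44))
  p1 <- predict_proba(model, dat$stacks)
  expect_equal(rowSums(p1), rep(1, 12), tolerance = 1e-6)
  expect_true(all(p1 >= 0))
  # eval mode is deterministic
  expect_identical(p1, predict_proba(model, dat$stacks))
  # zero logits give the uniform distribution
  model0 <- build_smfc(tiny_cfg(seed = 1))
  model0$params$W3[] <- 0
  model0$params$c3[] <- 0
  S <- smfcnet:::stacks_to_array(dat$stacks[1])
  p0 <- smfcnet:::smfc_forward(model0$params, model0$config, S)$prob
  expect_equal(as.vector(p0), c(0.5, 0.5))
})

test_that("training-mode dropout is stochastic, evaluation is not", {
  cfg <- tiny_cfg(seed = 2)
  model <- build_smfc(cfg)
  set.seed(9)
  S <- array(rnorm(6 * 6 * 2 * 3), c(6, 6, 2, 3))   # dense: live activations
  set.seed(1)
  a <- smfcnet:::smfc_forward(model$params, cfg, S, train = TRUE)$prob
  b <- smfcnet:::smfc_forward(model$params, cfg, S, train = TRUE)$prob
  expect_false(identical(a, b))
  c1 <- smfcnet:::smfc_forward(model$params, cfg, S, train = FALSE)$prob
  c2 <- smfcnet:::smfc_forward(model$params, cfg, S, train = FALSE)$prob
  expect_identical(c1, c2)
})

test_that("invalid training inputs are rejected", {
  dat <- one_edge_cohort(n_per_class = 4, seed = 45)
  expect_error(train_smfc(dat$stacks, rep(1L, 8), tiny_cfg()),
               "single class")
  model <- train_smfc(dat$stacks, dat$labels, tiny_cfg(epochs = 2, seed = 3))
  wrong <- one_edge_stack(0.5, N = 7, d = 2)
  expect_error(predict_proba(model, wrong), "shape")
  expect_error(smfc_config(N = 5, d = 1, dropout = 1), "dropout")
})

test_that("a single-branch model is the d = 1 special case of the same code", {
  dat <- one_edge_cohort(n_per_class = 8, d = 1, seed = 46)
  cfg <- smfc_config(N = 6, d = 1, H = 8, V = 4, D1 = 8, D2 = 4,
                     epochs = 100, batch_size = 8, seed = 46)
  model <- train_smfc(dat$stacks, dat$labels, cfg)
  expect_gte(mean(predict_label(model, dat$stacks) == dat$labels), 0.9)
  expect_equal(dim(predict_proba(model, dat$stacks[[1]])), c(1L, 2L))
})
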