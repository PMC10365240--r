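#' Classifier configuration
#'
#' Hyperparameters of the connectome convolution network. Defaults follow
#' the standard setting for a 120-ROI, ten-level stack: 64 regional-
#' connectivity channels, 32 spatial-integration channels, dense layers of
#' 128 and 64 units, 0.2 dropout after the concatenation and after the
#' first dense layer, an L2 penalty of 1e-5 on both convolution kernels,
#' and Adam with learning rate 0.001, batch size 20, 200 epochs.
#'
#' @param N number of ROIs.
#' @param d number of network branches (sparsity levels).
#' @param H regional-connectivity convolution channels.
#' @param V spatial-integration convolution channels.
#' @param D1,D2 dense-layer widths.
#' @param dropout dropout rate in \[0, 1).
#' @param l2 L2 coefficient on convolution kernel weights.
#' @param lr Adam learning rate.
#' @param batch_size minibatch size.
#' @param epochs training epochs (fixed; no early stopping).
#' @param seed integer seed for initialization and shuffling.
#' @return a list of class `smfc_config`.
#' @export
smfc_config <- function(N, d, H = 64, V = 32, D1 = 128, D2 = 64,
                        dropout = 0.2, l2 = 1e-5, lr = 0.001,
                        batch_size = 20, epochs = 200, seed = 1L) {
  cfg <- list(N = as.integer(N), d = as.integer(d), H = as.integer(H),
              V = as.integer(V), D1 = as.integer(D1), D2 = as.integer(D2),
              dropout = dropout, l2 = l2, lr = lr,
              batch_size = as.integer(batch_size),
              epochs = as.integer(epochs), seed = as.integer(seed))
  with(cfg, stopifnot(N > 0, d > 0, H > 0, V > 0, D1 > 0, D2 > 0,
                      dropout >= 0, dropout < 1, l2 >= 0, lr > 0,
                      batch_size > 0, epochs > 0))
  structure(cfg, class = "smfc_config")
}

he_normal <- function(nr, nc, fan_in) {
  matrix(stats::rnorm(nr * nc, sd = sqrt(2 / fan_in)), nr, nc)
}

init_params <- function(cfg) {
  p <- list()
  for (k in seq_len(cfg$d)) {
    p[[paste0("K1.", k)]] <- he_normal(cfg$N, cfg$H, cfg$N)
    p[[paste0("b1.", k)]] <- numeric(cfg$H)
    p[[paste0("K2.", k)]] <- he_normal(cfg$N * cfg$H, cfg$V, cfg$N * cfg$H)
    p[[paste0("b2.", k)]] <- numeric(cfg$V)
  }
  p$W1 <- he_normal(cfg$d * cfg$V, cfg$D1, cfg$d * cfg$V)
  p$c1 <- numeric(cfg$D1)
  p$W2 <- he_normal(cfg$D1, cfg$D2, cfg$D1)
  p$c2 <- numeric(cfg$D2)
  p$W3 <- he_normal(cfg$D2, 2L, cfg$D2)
  p$c3 <- numeric(2L)
  p
}

#' Untrained classifier
#'
#' Builds the network with he_normal-initialized convolution and dense
#' weights. With `d = 1` the same architecture is the single-network
#' variant; no structural change is needed.
#'
#' @param cfg an [smfc_config()].
#' @return object of class `smfc_model` (untrained).
#' @export
build_smfc <- function(cfg) {
  stopifnot(inherits(cfg, "smfc_config"))
  set.seed(cfg$seed)
  structure(list(params = init_params(cfg), config = cfg,
                 trained = FALSE, history = numeric(0)),
            class = "smfc_model")
}

# Coerce a list of fcn_stack objects (or a single one) to an N x N x d x B
# array, checking dimension agreement.
stacks_to_array <- function(stacks) {
  if (inherits(stacks, "fcn_stack")) stacks <- list(stacks)
  if (is.array(stacks) && length(dim(stacks)) == 4) return(stacks)
  dims <- dim(stacks[[1]]$M)
  B <- length(stacks)
  out <- array(0, c(dims[1], dims[2], dims[3], B))
  for (b in seq_len(B)) {
    if (!all(dim(stacks[[b]]$M) == dims))
      rlang::abort("all subjects must share the same N and d")
    out[, , , b] <- stacks[[b]]$M
  }
  out
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

# Forward pass over a batch. S: N x N x d x B array. Returns class
# probabilities and, when `cache = TRUE`, the intermediate tensors needed
# for the backward pass (and for shape auditing).
smfc_forward <- function(params, cfg, S, train = FALSE, cache = FALSE) {
  N <- cfg$N; d <- cfg$d; H <- cfg$H; V <- cfg$V
  B <- dim(S)[4]
  stopifnot(dim(S)[1] == N, dim(S)[2] == N, dim(S)[3] == d)
  Tk <- vector("list", d); A1pre <- vector("list", d)
  Zk <- vector("list", d); F2pre <- vector("list", d)
  Fparts <- vector("list", d)
  for (k in seq_len(d)) {
    arr <- array(S[, , k, , drop = FALSE], c(N, N, B))
    # rows: subject-major blocks of N; row r + (b-1)N is subject b, ROI row r
    tk <- matrix(aperm(arr, c(1, 3, 2)), N * B, N)
    a1 <- tk %*% params[[paste0("K1.", k)]]
    a1 <- a1 + matrix(params[[paste0("b1.", k)]], N * B, H, byrow = TRUE)
    a1r <- relu(a1)
    # flatten each subject's N x H activation (column-major) into one row
    zk <- t(matrix(aperm(array(a1r, c(N, B, H)), c(1, 3, 2)), N * H, B))
    f2 <- zk %*% params[[paste0("K2.", k)]]
    f2 <- f2 + matrix(params[[paste0("b2.", k)]], B, V, byrow = TRUE)
    Tk[[k]] <- tk; A1pre[[k]] <- a1; Zk[[k]] <- zk; F2pre[[k]] <- f2
    Fparts[[k]] <- relu(f2)
  }
  Fc <- do.call(cbind, Fparts)                       # B x dV
  p_drop <- if (train) cfg$dropout else 0
  mask1 <- if (p_drop > 0)
    matrix((stats::runif(B * d * V) >= p_drop) / (1 - p_drop), B, d * V)
  else NULL
  Fd <- if (is.null(mask1)) Fc else Fc * mask1
  H1pre <- Fd %*% params$W1 +
    matrix(params$c1, B, cfg$D1, byrow = TRUE)
  H1 <- relu(H1pre)
  mask2 <- if (p_drop > 0)
    matrix((stats::runif(B * cfg$D1) >= p_drop) / (1 - p_drop), B, cfg$D1)
  else NULL
  H1d <- if (is.null(mask2)) H1 else H1 * mask2
  H2pre <- H1d %*% params$W2 + matrix(params$c2, B, cfg$D2, byrow = TRUE)
  H2 <- relu(H2pre)
  logits <- H2 %*% params$W3 + matrix(params$c3, B, 2, byrow = TRUE)
  z <- logits - apply(logits, 1, max)
  ez <- exp(z)
  prob <- ez / rowSums(ez)
  if (!cache) return(list(prob = prob))
  list(prob = prob, Tk = Tk, A1pre = A1pre, Zk = Zk, F2pre = F2pre,
       Fc = Fc, Fd = Fd, mask1 = mask1, mask2 = mask2,
       H1pre = H1pre, H1d = H1d, H2pre = H2pre, H2 = H2, logits = logits)
}

smfc_backward <- function(params, cfg, cc, y) {
  N <- cfg$N; d <- cfg$d; H <- cfg$H; V <- cfg$V
  B <- nrow(cc$prob)
  Y <- matrix(0, B, 2)
  Y[cbind(seq_len(B), y + 1L)] <- 1
  g <- list()
  dlogits <- (cc$prob - Y) / B
  g$W3 <- crossprod(cc$H2, dlogits)
  g$c3 <- colSums(dlogits)
  dH2 <- (dlogits %*% t(params$W3)) * (cc$H2pre > 0)
  g$W2 <- crossprod(cc$H1d, dH2)
  g$c2 <- colSums(dH2)
  dH1d <- dH2 %*% t(params$W2)
  dH1 <- if (is.null(cc$mask2)) dH1d else dH1d * cc$mask2
  dH1pre <- dH1 * (cc$H1pre > 0)
  g$W1 <- crossprod(cc$Fd, dH1pre)
  g$c1 <- colSums(dH1pre)
  dFd <- dH1pre %*% t(params$W1)
  dFc <- if (is.null(cc$mask1)) dFd else dFd * cc$mask1
  for (k in seq_len(d)) {
    dF2 <- dFc[, (k - 1) * V + seq_len(V), drop = FALSE] *
      (cc$F2pre[[k]] > 0)
    g[[paste0("K2.", k)]] <- crossprod(cc$Zk[[k]], dF2) +
      2 * cfg$l2 * params[[paste0("K2.", k)]]
    g[[paste0("b2.", k)]] <- colSums(dF2)
    dZ <- dF2 %*% t(params[[paste0("K2.", k)]])      # B x NH
    dA1 <- matrix(aperm(array(t(dZ), c(N, H, B)), c(1, 3, 2)), N * B, H)
    dA1pre <- dA1 * (cc$A1pre[[k]] > 0)
    g[[paste0("K1.", k)]] <- crossprod(cc$Tk[[k]], dA1pre) +
      2 * cfg$l2 * params[[paste0("K1.", k)]]
    g[[paste0("b1.", k)]] <- colSums(dA1pre)
  }
  g
}

smfc_loss <- function(params, cfg, prob, y) {
  B <- nrow(prob)
  ce <- -mean(log(pmax(prob[cbind(seq_len(B), y + 1L)], 1e-12)))
  pen <- 0
  for (k in seq_len(cfg$d)) {
    pen <- pen + sum(params[[paste0("K1.", k)]]^2) +
      sum(params[[paste0("K2.", k)]]^2)
  }
  ce + cfg$l2 * pen
}

#' Train the classifier
#'
#' Minimizes the softmax cross-entropy (plus the L2 kernel penalty) with
#' Adam for a fixed number of epochs; minibatches are reshuffled each
#' epoch. All randomness (initialization, shuffling, dropout) flows from
#' `cfg$seed` through R's RNG, so a fixed seed and fixed data give a
#' bitwise-identical training history.
#'
#' @param stacks list of `fcn_stack` objects (one per subject) or an
#'   N x N x d x B array.
#' @param labels integer vector of 0/1 labels, one per subject.
#' @param cfg an [smfc_config()].
#' @param model optionally an existing untrained [build_smfc()] model.
#' @return a trained `smfc_model` with per-epoch `history` of training loss.
#' @export
train_smfc <- function(stacks, labels, cfg, model = NULL) {
  S <- stacks_to_array(stacks)
  y <- as.integer(labels)
  B_total <- dim(S)[4]
  stopifnot(length(y) == B_total, all(y %in% c(0L, 1L)))
  if (length(unique(y)) < 2)
    rlang::abort("training set contains a single class; need both labels")
  if (is.null(model)) model <- build_smfc(cfg) else set.seed(cfg$seed)
  params <- model$params
  m <- lapply(params, function(p) p * 0)
  v <- lapply(params, function(p) p * 0)
  beta1 <- 0.9; beta2 <- 0.999; adam_eps <- 1e-8
  t_step <- 0
  history <- numeric(cfg$epochs)
  for (epoch in seq_len(cfg$epochs)) {
    perm <- sample.int(B_total)
    loss_sum <- 0
    for (start in seq(1, B_total, by = cfg$batch_size)) {
      idx <- perm[start:min(start + cfg$batch_size - 1, B_total)]
      Sb <- S[, , , idx, drop = FALSE]
      yb <- y[idx]
      cc <- smfc_forward(params, cfg, Sb, train = TRUE, cache = TRUE)
      loss_sum <- loss_sum + smfc_loss(params, cfg, cc$prob, yb) * length(idx)
      grads <- smfc_backward(params, cfg, cc, yb)
      t_step <- t_step + 1
      for (nm in names(params)) {
        gmat <- grads[[nm]]
        m[[nm]] <- beta1 * m[[nm]] + (1 - beta1) * gmat
        v[[nm]] <- beta2 * v[[nm]] + (1 - beta2) * gmat^2
        mhat <- m[[nm]] / (1 - beta1^t_step)
        vhat <- v[[nm]] / (1 - beta2^t_step)
        params[[nm]] <- params[[nm]] - cfg$lr * mhat / (sqrt(vhat) + adam_eps)
      }
    }
    history[epoch] <- loss_sum / B_total
  }
  structure(list(params = params, config = cfg, trained = TRUE,
                 history = history),
            class = "smfc_model")
}

#' Class probabilities for subjects
#'
#' Deterministic evaluation-mode forward pass (dropout disabled). Each row
#' is a probability pair `(p0, p1)` summing to 1.
#'
#' @param model trained `smfc_model`.
#' @param stacks `fcn_stack`, list of them, or an N x N x d x B array.
#' @return B x 2 matrix of class probabilities.
#' @export
predict_proba <- function(model, stacks) {
  stopifnot(inherits(model, "smfc_model"))
  S <- stacks_to_array(stacks)
  cfg <- model$config
  if (dim(S)[1] != cfg$N || dim(S)[3] != cfg$d)
    rlang::abort(sprintf(
      "input shape %dx%dx%d does not match model config N=%d, d=%d",
      dim(S)[1], dim(S)[2], dim(S)[3], cfg$N, cfg$d))
  out <- smfc_forward(model$params, cfg, S, train = FALSE)$prob
  colnames(out) <- c("p0", "p1")
  out
}

#' Hard label predictions
#'
#' @inheritParams predict_proba
#' @return integer vector of 0/1 labels.
#' @export
predict_label <- function(model, stacks) {
  as.integer(predict_proba(model, stacks)[, 2] > 0.5)
}

#' Layer-by-layer shape contract of the architecture
#'
#' The tensor shapes each stage must produce for a valid configuration:
#' each branch maps the N x N network through an N x 1 x H activation and
#' a 1 x 1 x V feature; concatenation yields d*V features, followed by the
#' two dense layers and the 2-way softmax.
#'
#' @param cfg an [smfc_config()].
#' @return tibble with columns `stage` and `shape` (list of integer dims).
#' @export
smfc_shapes <- function(cfg) {
  tibble::tibble(
    stage = c("input_branch", "conv1_out", "conv2_out",
              "concat", "dense1", "dense2", "softmax"),
    shape = list(c(cfg$N, cfg$N), c(cfg$N, 1L, cfg$H), c(1L, 1L, cfg$V),
                 cfg$d * cfg$V, cfg$D1, cfg$D2, 2L)
  )
}

#' Parameter counts per layer
#'
#' @param cfg an [smfc_config()].
#' @return tibble with `layer` and `n_parameters` (per branch for the two
#'   convolution layers).
#' @export
smfc_parameter_counts <- function(cfg) {
  tibble::tibble(
    layer = c("conv1_per_branch", "conv2_per_branch",
              "dense1", "dense2", "softmax"),
    n_parameters = c(cfg$N * cfg$H + cfg$H,
                     cfg$N * cfg$H * cfg$V + cfg$V,
                     cfg$d * cfg$V * cfg$D1 + cfg$D1,
                     cfg$D1 * cfg$D2 + cfg$D2,
                     cfg$D2 * 2 + 2)
  )
}

#' @export
print.smfc_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<smfc_model> N=%d d=%d H=%d V=%d D1=%d D2=%d (%s)\n",
              cfg$N, cfg$d, cfg$H, cfg$V, cfg$D1, cfg$D2,
              if (x$trained)
                sprintf("trained, final loss %.4f", tail(x$history, 1))
              else "untrained"))
  invisible(x)
}

# Sum of all parameters; used to assert that evaluation-only procedures
# (prediction, occlusion) leave weights untouched.
param_checksum <- function(model) {
  sum(vapply(model$params, sum, numeric(1)))
}
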