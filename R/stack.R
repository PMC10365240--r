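#' Dyadic sparsity grid
#'
#' Powers of two `2^lo, ..., 2^hi`; the default `-4:5` gives the standard
#' ten-level grid `2^-4, 2^-3, ..., 2^5`.
#'
#' @param lo,hi integer exponents, `lo < hi`.
#' @return strictly increasing numeric vector of length `hi - lo + 1`.
#' @export
dyadic_grid <- function(lo = -4, hi = 5) {
  stopifnot(lo < hi)
  2^seq(lo, hi)
}

#' Binarized symmetric support of a sparse coefficient matrix
#'
#' An undirected edge (i, j) is kept when either directed coefficient
#' exceeds `eps` in magnitude (OR-symmetrization, equivalently the support
#' of `|W| + |W'|`). The diagonal is forced to zero and the result is an
#' idempotent 0/1 adjacency matrix.
#'
#' @param W N x N coefficient matrix or a `wsr_fit`.
#' @param eps nonnegative tolerance below which a coefficient counts as
#'   zero (ADMM iterates are never exactly zero in floating point).
#' @return N x N symmetric binary matrix with zero diagonal.
#' @export
binarize_symmetric_support <- function(W, eps = 1e-5) {
  if (inherits(W, "wsr_fit")) W <- W$W
  stopifnot(is.matrix(W), nrow(W) == ncol(W), eps >= 0)
  G <- (abs(W) > eps) | (abs(t(W)) > eps)
  G <- G * 1
  diag(G) <- 0
  G
}

#' Mask a correlation matrix with a binary topology
#'
#' Elementwise product `M = G * P`: the sparse support decides which edges
#' exist, while the surviving entries keep the full Pearson correlation
#' (sign included) rather than the shrunken lasso coefficients.
#'
#' @param P N x N correlation matrix.
#' @param G N x N binary mask of the same dimension.
#' @return N x N masked matrix.
#' @export
sparsity_guided_fcn <- function(P, G) {
  if (!all(dim(P) == dim(G)))
    rlang::abort(sprintf("shape mismatch: P is %dx%d, G is %dx%d",
                         nrow(P), ncol(P), nrow(G), ncol(G)))
  M <- G * P
  diag(M) <- 0
  M
}

new_fcn_stack <- function(M, lam_grid, roi_ids, subject_id = NA_character_,
                          label = NA_integer_, kind = "wsr", extra = list()) {
  structure(
    c(list(M = M, lam_grid = lam_grid, roi_ids = roi_ids,
           subject_id = subject_id,
           label = if (is.na(label)) NA_integer_ else as.integer(label),
           kind = kind),
      extra),
    class = "fcn_stack"
  )
}

#' @export
print.fcn_stack <- function(x, ...) {
  cat(sprintf("<fcn_stack> subject %s: %d x %d x %d (%s), densities %s\n",
              x$subject_id, dim(x$M)[1], dim(x$M)[2], dim(x$M)[3], x$kind,
              paste(sprintf("%.2f", apply(x$M, 3, network_density)),
                    collapse = " ")))
  invisible(x)
}

#' Off-diagonal density of a network
#'
#' Fraction of off-diagonal entries that are nonzero.
#'
#' @param M square matrix.
#' @return number in \[0, 1\].
#' @export
network_density <- function(M) {
  N <- nrow(M)
  diag(M) <- 0
  sum(M != 0) / (N * (N - 1))
}

#' Sparsity-guided FCN stack for one subject
#'
#' Runs the full single-subject construction: Pearson matrix, penalty
#' weights, one WSR solve per sparsity level, binarization, and masking.
#' Densities are non-increasing along the grid (larger `lambda` means a
#' sparser support).
#'
#' @param ts normalized [ts_matrix][new_ts_matrix].
#' @param lam_grid strictly increasing positive sparsity levels
#'   (default [dyadic_grid()], ten levels).
#' @param sigma penalty-weight decay (default 0.2).
#' @param eps support tolerance passed to [binarize_symmetric_support()].
#' @param ... further arguments to [solve_wsr()].
#'
#' @return An `fcn_stack`: array `M` of dimension N x N x d, the grid, the
#'   binary supports `G` (same dimension) and per-level solver diagnostics.
#' @export
build_fcn_stack <- function(ts, lam_grid = dyadic_grid(), sigma = 0.2,
                            eps = 1e-5, ...) {
  stopifnot(inherits(ts, "ts_matrix"))
  if (any(diff(lam_grid) <= 0) || any(lam_grid <= 0))
    rlang::abort("lam_grid must be strictly increasing and positive")
  P <- pearson_matrix(ts)
  C <- penalty_weights(P, sigma)
  N <- nrow(P)
  d <- length(lam_grid)
  M <- array(0, c(N, N, d))
  G <- array(0L, c(N, N, d))
  conv <- logical(d)
  for (k in seq_len(d)) {
    fit <- solve_wsr(ts, C, lam_grid[k], ...)
    g <- binarize_symmetric_support(fit$W, eps)
    G[, , k] <- g
    M[, , k] <- sparsity_guided_fcn(P, g)
    conv[k] <- fit$converged
  }
  new_fcn_stack(M, lam_grid, ts$roi_ids, ts$subject_id, ts$label,
                kind = "wsr",
                extra = list(G = G, sigma = sigma, converged = conv))
}

#' Hard-thresholded FCN stack for one subject
#'
#' The proportional-thresholding alternative to sparsity guidance: for each
#' percentage `q` the `q`% of upper-triangle edges with the smallest
#' absolute correlation are discarded and the rest keep their Pearson
#' value. Exactly `floor((1 - q/100) * N(N-1)/2)` edge pairs survive; ties
#' in |value| are broken by (row, column) lexicographic order so the result
#' is deterministic.
#'
#' @param P N x N correlation matrix.
#' @param percents percentages in (0, 100), default the conventional
#'   `10, 20, ..., 90, 99` ten-level ladder.
#' @param roi_ids,subject_id,label metadata for the container.
#' @return An `fcn_stack` of `length(percents)` masked matrices.
#' @export
hard_threshold_stack <- function(P, percents = c(seq(10, 90, by = 10), 99),
                                 roi_ids = rownames(P),
                                 subject_id = NA_character_,
                                 label = NA_integer_) {
  stopifnot(is.matrix(P), nrow(P) == ncol(P))
  if (any(percents <= 0 | percents >= 100))
    rlang::abort("percents must lie strictly between 0 and 100")
  N <- nrow(P)
  ut <- which(upper.tri(P), arr.ind = TRUE)
  vals <- P[ut]
  # order: decreasing |value|, ties by (row, col)
  ord <- order(-abs(vals), ut[, 1], ut[, 2])
  E <- nrow(ut)
  d <- length(percents)
  M <- array(0, c(N, N, d))
  for (k in seq_len(d)) {
    keep <- floor((1 - percents[k] / 100) * E)
    m <- matrix(0, N, N)
    if (keep > 0) {
      sel <- ord[seq_len(keep)]
      m[ut[sel, , drop = FALSE]] <- vals[sel]
      m <- m + t(m)
    }
    M[, , k] <- m
  }
  if (is.null(roi_ids)) roi_ids <- paste0("ROI", seq_len(N))
  new_fcn_stack(M, lam_grid = percents, roi_ids = roi_ids,
                subject_id = subject_id, label = label,
                kind = "hard_threshold")
}

#' Keep a single level of a stack
#'
#' Restricts an `fcn_stack` to one sparsity level (1-based index into the
#' grid), the single-network variant of the classifier.
#'
#' @param stack an `fcn_stack`.
#' @param k level index.
#' @return an `fcn_stack` with `d = 1`.
#' @export
stack_select_level <- function(stack, k) {
  stopifnot(inherits(stack, "fcn_stack"), k >= 1, k <= dim(stack$M)[3])
  M <- stack$M[, , k, drop = FALSE]
  new_fcn_stack(M, stack$lam_grid[k], stack$roi_ids, stack$subject_id,
                stack$label, kind = paste0(stack$kind, ":single"))
}

#' Build stacks for a whole cohort
#'
#' @param cohort list of normalized [ts_matrix][new_ts_matrix] objects.
#' @param variant `"smfc"` (sparsity-guided, default), `"htfc"` (hard
#'   threshold ladder) or `"ssfc:<k>"` (single guided level `k`).
#' @param lam_grid,sigma,percents construction parameters.
#' @param ... passed to [build_fcn_stack()].
#' @return list of `fcn_stack` objects, one per subject.
#' @export
build_cohort_stacks <- function(cohort, variant = "smfc",
                                lam_grid = dyadic_grid(), sigma = 0.2,
                                percents = c(seq(10, 90, by = 10), 99), ...) {
  ssfc_k <- NULL
  if (grepl("^ssfc:", variant)) {
    ssfc_k <- as.integer(sub("^ssfc:", "", variant))
    variant <- "ssfc"
  }
  purrr::map(cohort, function(ts) {
    switch(variant,
      smfc = build_fcn_stack(ts, lam_grid = lam_grid, sigma = sigma, ...),
      htfc = hard_threshold_stack(pearson_matrix(ts), percents = percents,
                                  roi_ids = ts$roi_ids,
                                  subject_id = ts$subject_id,
                                  label = ts$label),
      ssfc = stack_select_level(
        build_fcn_stack(ts, lam_grid = lam_grid, sigma = sigma, ...), ssfc_k),
      rlang::abort(sprintf("unknown variant '%s'", variant))
    )
  })
}

#' F1 score of an estimated edge support
#'
#' Compares the off-diagonal support of a binary adjacency (or masked)
#' matrix against a reference edge set, counting each unordered pair once.
#'
#' @param G estimated N x N matrix (nonzero = edge).
#' @param true_edges two-column matrix of reference edges (i, j).
#' @return F1 in \[0, 1\] (0 when the estimate or reference is empty).
#' @export
support_f1 <- function(G, true_edges) {
  N <- nrow(G)
  est <- (G != 0) | (t(G) != 0)
  est_pairs <- which(upper.tri(est) & est, arr.ind = TRUE)
  key <- function(e) paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  if (nrow(est_pairs) == 0 || nrow(true_edges) == 0) return(0)
  tp <- sum(key(est_pairs) %in% key(true_edges))
  prec <- tp / nrow(est_pairs)
  rec <- tp / nrow(true_edges)
  if (prec + rec == 0) return(0)
  2 * prec * rec / (prec + rec)
}
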