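#' Ensemble accuracy on the cross-validation structure
#'
#' Re-evaluates the stored base-classifier ensembles on (optionally
#' transformed) input stacks: per repetition, every fold's ensemble
#' predicts its own held-out test subjects by majority vote and the
#' repetition's accuracy is computed; the mean over repetitions is the
#' ensemble accuracy. With `transform = identity` this reproduces the
#' accuracy of the original evaluation exactly.
#'
#' @param cv an `smfc_cv` fitted with `keep_models = TRUE`.
#' @param stacks the evaluation stacks (list or N x N x d x B array).
#' @param transform function applied to the 4-d array before prediction
#'   (e.g. an occlusion mask).
#' @return list with `per_rep` (accuracy per repetition, fraction) and
#'   `mean`.
#' @export
ensemble_accuracy <- function(cv, stacks, transform = identity) {
  stopifnot(inherits(cv, "smfc_cv"))
  if (!isTRUE(cv$keep_models))
    rlang::abort("smfc_cv was run with keep_models = FALSE")
  S <- transform(stacks_to_array(stacks))
  y <- cv$labels
  n_rep <- cv$plan$outer_reps
  correct <- numeric(n_rep)
  total <- numeric(n_rep)
  for (e in cv$ensembles) {
    Ste <- S[, , , e$test_idx, drop = FALSE]
    probs <- vapply(e$models, function(m) predict_proba(m, Ste)[, 2],
                    numeric(length(e$test_idx)))
    probs <- matrix(probs, nrow = length(e$test_idx))
    pred <- apply(probs > 0.5, 1, function(v) majority_vote(as.integer(v)))
    correct[e$rep] <- correct[e$rep] + sum(pred == y[e$test_idx])
    total[e$rep] <- total[e$rep] + length(e$test_idx)
  }
  per_rep <- correct / total
  list(per_rep = per_rep, mean = mean(per_rep))
}

occlude_edge <- function(i, j) {
  function(S) {
    S[i, j, , ] <- 0
    S[j, i, , ] <- 0
    S
  }
}

occlude_region <- function(n) {
  function(S) {
    S[n, , , ] <- 0
    S[, n, , ] <- 0
    S
  }
}

#' Occlusion importance of every connection
#'
#' For each unordered ROI pair (i, j), the entries (i, j) and (j, i) are
#' zeroed simultaneously in all `d` networks of every subject's stack, the
#' trained ensembles re-predict their held-out test subjects, and the drop
#' in ensemble accuracy relative to the unoccluded accuracy is recorded as
#' that connection's contribution. Model weights are untouched (asserted
#' by a parameter checksum).
#'
#' @param cv an `smfc_cv` with kept models.
#' @param stacks the evaluation stacks used by `cv`.
#' @return `edge_importance` tibble with N(N-1)/2 rows: `roi_i`, `roi_j`
#'   (indices, i < j), ROI names and `accuracy_drop` in percentage points.
#' @export
edge_importance <- function(cv, stacks) {
  S <- stacks_to_array(stacks)
  N <- dim(S)[1]
  roi_ids <- if (inherits(stacks, "fcn_stack")) stacks$roi_ids
             else if (is.list(stacks)) stacks[[1]]$roi_ids
             else paste0("ROI", seq_len(N))
  checksum <- sum(vapply(cv$ensembles, function(e)
    sum(vapply(e$models, param_checksum, numeric(1))), numeric(1)))
  base <- ensemble_accuracy(cv, S)
  pairs <- which(upper.tri(matrix(0, N, N)), arr.ind = TRUE)
  drops <- numeric(nrow(pairs))
  for (p in seq_len(nrow(pairs))) {
    occ <- ensemble_accuracy(cv, S,
                             transform = occlude_edge(pairs[p, 1],
                                                      pairs[p, 2]))
    drops[p] <- mean(base$per_rep - occ$per_rep)
  }
  checksum2 <- sum(vapply(cv$ensembles, function(e)
    sum(vapply(e$models, param_checksum, numeric(1))), numeric(1)))
  stopifnot(identical(checksum, checksum2))
  out <- tibble::tibble(
    roi_i = as.integer(pairs[, 1]), roi_j = as.integer(pairs[, 2]),
    name_i = roi_ids[pairs[, 1]], name_j = roi_ids[pairs[, 2]],
    accuracy_drop = 100 * drops)
  class(out) <- c("edge_importance", class(out))
  attr(out, "acc_base") <- base$mean
  out
}

#' Occlusion contribution of every region
#'
#' For each ROI n, row n and column n are zeroed in all networks of every
#' subject's stack and the ensembles are re-evaluated. Per repetition the
#' degradation is exponentiated, `D_n = exp(ACC - ACC_masked_n)` (both as
#' fractions), and min-max normalized across regions to a contribution
#' `C_n` in \[0, 1\]; contributions are then averaged over repetitions.
#' If all regions degrade identically in a repetition the normalization is
#' undefined and a uniform 0 is returned for it with a warning.
#'
#' @param cv an `smfc_cv` with kept models.
#' @param stacks the evaluation stacks used by `cv`.
#' @return `region_contribution` tibble with N rows: `roi`, `name`,
#'   mean `D` and mean contribution `C`; per-repetition contributions are
#'   attached as attribute `per_rep` (N x reps matrix).
#' @export
region_contribution <- function(cv, stacks) {
  S <- stacks_to_array(stacks)
  N <- dim(S)[1]
  roi_ids <- if (inherits(stacks, "fcn_stack")) stacks$roi_ids
             else if (is.list(stacks)) stacks[[1]]$roi_ids
             else paste0("ROI", seq_len(N))
  base <- ensemble_accuracy(cv, S)
  n_rep <- length(base$per_rep)
  acc_masked <- matrix(0, N, n_rep)
  for (n in seq_len(N)) {
    acc_masked[n, ] <- ensemble_accuracy(cv, S,
                                         transform = occlude_region(n))$per_rep
  }
  D <- exp(sweep(-acc_masked, 2, base$per_rep, "+"))   # exp(acc - acc_masked)
  C <- matrix(0, N, n_rep)
  for (r in seq_len(n_rep)) {
    rng <- range(D[, r])
    if (diff(rng) < .Machine$double.eps) {
      rlang::warn(sprintf(
        "all regions degrade equally in repetition %d; contribution undefined, returning 0",
        r))
      C[, r] <- 0
    } else {
      C[, r] <- (D[, r] - rng[1]) / (rng[2] - rng[1])
    }
  }
  out <- tibble::tibble(roi = seq_len(N), name = roi_ids,
                        D = rowMeans(D), C = rowMeans(C))
  class(out) <- c("region_contribution", class(out))
  attr(out, "per_rep") <- C
  attr(out, "acc_base") <- base$mean
  out
}

#' Top-k most important connections
#'
#' @param table an [edge_importance()] tibble.
#' @param k number of rows to keep.
#' @return the k rows with the largest accuracy drop, ties broken by
#'   (roi_i, roi_j) lexicographic order.
#' @export
top_k_report <- function(table, k) {
  stopifnot(k >= 1, k <= nrow(table))
  out <- dplyr::arrange(table, dplyr::desc(.data$accuracy_drop),
                        .data$roi_i, .data$roi_j)
  out[seq_len(k), , drop = FALSE]
}
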