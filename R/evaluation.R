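#' Cross-validation plan
#'
#' The nested design: subjects are split into `outer_folds` stratified
#' folds; within each outer training set, 20% is repeatedly held out as a
#' validation set and a stratified `inner_folds`-fold CV is run on the
#' remaining internal training set, `inner_reps` times. The
#' `inner_folds * inner_reps` fitted networks (25 by default) are kept as
#' base classifiers and vote on the outer test fold by majority. The whole
#' procedure is repeated `outer_reps` times with fresh fold assignments,
#' and metrics are reported as mean and standard deviation over the
#' repetitions.
#'
#' @param outer_folds,inner_folds fold counts (default 5 and 5).
#' @param inner_reps inner repetitions (default 5; 5 x 5 = 25 base
#'   classifiers per outer fold).
#' @param outer_reps independent repetitions of the whole CV (default 10).
#' @param validation_fraction fraction of the outer training set held out
#'   for hyperparameter validation (default 0.2).
#' @param seed integer seed governing all fold assignments and model seeds.
#' @return list of class `cv_plan`.
#' @export
cv_plan <- function(outer_folds = 5, inner_folds = 5, inner_reps = 5,
                    outer_reps = 10, validation_fraction = 0.2, seed = 1L) {
  stopifnot(outer_folds >= 2, inner_folds >= 2, inner_reps >= 1,
            outer_reps >= 1,
            validation_fraction > 0, validation_fraction < 1)
  structure(list(outer_folds = as.integer(outer_folds),
                 inner_folds = as.integer(inner_folds),
                 inner_reps = as.integer(inner_reps),
                 outer_reps = as.integer(outer_reps),
                 validation_fraction = validation_fraction,
                 seed = as.integer(seed)),
            class = "cv_plan")
}

derive_seed <- function(seed, ...) {
  k <- sum(c(...) * seq_along(c(...)) * 9973)
  as.integer((abs(seed) * 48271 + k) %% 2147483629L)
}

#' Stratified fold assignment
#'
#' Deals each class's shuffled indices round-robin over `k` folds so every
#' fold contains both classes; errors if a class has fewer members than
#' folds.
#'
#' @param y 0/1 labels.
#' @param k number of folds.
#' @param seed integer seed.
#' @return integer vector of fold ids in `1..k`.
#' @export
stratified_folds <- function(y, k, seed = 1L) {
  y <- as.integer(y)
  if (any(table(factor(y, levels = c(0, 1))) < k))
    rlang::abort(sprintf(
      "cannot stratify: a class has fewer than %d members", k))
  set.seed(seed)
  fold <- integer(length(y))
  for (cls in c(0L, 1L)) {
    idx <- sample(which(y == cls))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Majority vote of an odd ensemble
#'
#' @param votes vector of 0/1 predictions from an odd number of base
#'   classifiers (odd so no tie is possible).
#' @return the label predicted by more than half the classifiers.
#' @export
majority_vote <- function(votes) {
  votes <- as.integer(votes)
  if (length(votes) %% 2 == 0)
    rlang::abort("majority_vote requires an odd number of votes")
  as.integer(sum(votes == 1L) > length(votes) / 2)
}

#' Rank-statistic AUC
#'
#' Area under the ROC curve computed as the normalized Mann-Whitney
#' statistic (ties get average ranks).
#'
#' @param scores numeric scores, larger = more positive.
#' @param truth 0/1 labels.
#' @return AUC in \[0, 1\], or NA if a class is absent.
#' @export
auc_rank <- function(scores, truth) {
  truth <- as.integer(truth)
  n1 <- sum(truth == 1L)
  n0 <- sum(truth == 0L)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[truth == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

safe_ratio <- function(num, den) if (den == 0) NA_real_ else num / den

#' Binary classification metrics
#'
#' Accuracy, sensitivity, specificity, balanced accuracy, AUC, F1 and
#' positive predictive value from a confusion table (positives = label 1).
#' Ratios with a zero denominator are reported as `NA` (undefined), never
#' as 0.
#'
#' @param TP,TN,FP,FN confusion counts.
#' @param scores optional per-subject scores for AUC.
#' @param truth 0/1 labels matching `scores`.
#' @return one-row tibble with columns ACC, SEN, SPE, BAC, AUC, F1, PPV
#'   (fractions in \[0, 1\]).
#' @export
compute_metrics <- function(TP, TN, FP, FN, scores = NULL, truth = NULL) {
  stopifnot(TP >= 0, TN >= 0, FP >= 0, FN >= 0, TP + TN + FP + FN > 0)
  acc <- safe_ratio(TP + TN, TP + TN + FP + FN)
  sen <- safe_ratio(TP, TP + FN)
  spe <- safe_ratio(TN, TN + FP)
  ppv <- safe_ratio(TP, TP + FP)
  bac <- (sen + spe) / 2
  f1 <- if (is.na(sen) || is.na(ppv) || (sen + ppv) == 0) NA_real_
        else 2 * sen * ppv / (sen + ppv)
  auc <- if (is.null(scores)) NA_real_ else auc_rank(scores, truth)
  tibble::tibble(ACC = acc, SEN = sen, SPE = spe, BAC = bac,
                 AUC = auc, F1 = f1, PPV = ppv)
}

metrics_from_predictions <- function(truth, pred, scores = NULL) {
  truth <- as.integer(truth); pred <- as.integer(pred)
  compute_metrics(TP = sum(truth == 1 & pred == 1),
                  TN = sum(truth == 0 & pred == 0),
                  FP = sum(truth == 0 & pred == 1),
                  FN = sum(truth == 1 & pred == 0),
                  scores = scores, truth = truth)
}

# Train the base-classifier ensemble for one outer fold. Returns the list
# of trained models plus bookkeeping of every index set used.
train_fold_ensemble <- function(S, y, train_idx, plan, cfg, grid, seed0,
                                counter_env) {
  models <- list()
  model_train_idx <- list()
  for (r in seq_len(plan$inner_reps)) {
    seed_r <- derive_seed(seed0, r)
    set.seed(seed_r)
    # fresh validation split each inner repetition
    pick <- function(x, k) x[sample.int(length(x), min(k, length(x)))]
    n_val <- max(2L, round(plan$validation_fraction * length(train_idx)))
    pos <- train_idx[y[train_idx] == 1L]
    neg <- train_idx[y[train_idx] == 0L]
    val_pos <- pick(pos, max(1L, round(n_val * length(pos) / length(train_idx))))
    val_neg <- pick(neg, max(1L, n_val - length(val_pos)))
    val_idx <- c(val_pos, val_neg)
    internal <- setdiff(train_idx, val_idx)
    inner_fold <- stratified_folds(y[internal], plan$inner_folds,
                                   seed = derive_seed(seed0, r, 77))
    cfg_use <- cfg
    if (!is.null(grid) && length(grid)) {
      # pick the candidate with best mean validation accuracy across folds
      val_acc <- vapply(grid, function(over) {
        cfg_c <- do.call(smfc_config, utils::modifyList(unclass(cfg), over))
        accs <- vapply(seq_len(plan$inner_folds), function(g) {
          tr <- internal[inner_fold != g]
          cfg_c$seed <- derive_seed(seed0, r, g, 5)
          mdl <- train_smfc(S[, , , tr, drop = FALSE], y[tr], cfg_c)
          mean(predict_label(mdl, S[, , , val_idx, drop = FALSE]) ==
                 y[val_idx])
        }, numeric(1))
        mean(accs)
      }, numeric(1))
      cfg_use <- do.call(smfc_config,
                         utils::modifyList(unclass(cfg),
                                           grid[[which.max(val_acc)]]))
    }
    for (g in seq_len(plan$inner_folds)) {
      tr <- internal[inner_fold != g]
      cfg_m <- cfg_use
      counter_env$n <- counter_env$n + 1L
      cfg_m$seed <- derive_seed(seed0, r, g, counter_env$n)
      mdl <- train_smfc(S[, , , tr, drop = FALSE], y[tr], cfg_m)
      models[[length(models) + 1L]] <- mdl
      model_train_idx[[length(model_train_idx) + 1L]] <- tr
    }
  }
  list(models = models, model_train_idx = model_train_idx)
}

#' Nested cross-validation with a voting ensemble
#'
#' Runs the full evaluation design of [cv_plan()] on a cohort of network
#' stacks: per outer repetition, stratified outer folds; per fold, an
#' ensemble of `inner_folds * inner_reps` base classifiers trained on
#' inner splits of the outer training set; majority voting on the held-out
#' fold; metrics per repetition and mean/sd across repetitions. The
#' ensemble score of a subject is the mean positive-class probability
#' across the fold's base classifiers.
#'
#' @param stacks list of `fcn_stack` objects or an N x N x d x B array.
#' @param labels 0/1 labels per subject.
#' @param plan a [cv_plan()].
#' @param cfg an [smfc_config()]; its `N` and `d` must match the stacks.
#' @param grid optional list of named config overrides searched on the
#'   validation split (defaults-only when `NULL`).
#' @param keep_models keep the trained ensembles in the result (needed for
#'   occlusion analysis).
#' @return object of class `smfc_cv` with per-repetition metrics,
#'   predictions, and (optionally) all trained ensembles with their fold
#'   index bookkeeping.
#' @export
nested_cv <- function(stacks, labels, plan = cv_plan(), cfg,
                      grid = NULL, keep_models = TRUE) {
  S <- stacks_to_array(stacks)
  y <- as.integer(labels)
  n <- dim(S)[4]
  stopifnot(length(y) == n)
  counter_env <- new.env()
  counter_env$n <- 0L
  per_rep <- vector("list", plan$outer_reps)
  predictions <- vector("list", plan$outer_reps)
  ensembles <- list()
  for (rep_i in seq_len(plan$outer_reps)) {
    fold <- stratified_folds(y, plan$outer_folds,
                             seed = derive_seed(plan$seed, rep_i))
    pred <- integer(n); score <- numeric(n)
    for (f in seq_len(plan$outer_folds)) {
      test_idx <- which(fold == f)
      train_idx <- which(fold != f)
      ens <- train_fold_ensemble(S, y, train_idx, plan, cfg, grid,
                                 seed0 = derive_seed(plan$seed, rep_i, f),
                                 counter_env = counter_env)
      probs <- vapply(ens$models, function(m)
        predict_proba(m, S[, , , test_idx, drop = FALSE])[, 2],
        numeric(length(test_idx)))
      probs <- matrix(probs, nrow = length(test_idx))
      votes <- probs > 0.5
      pred[test_idx] <- apply(votes, 1, function(v)
        majority_vote(as.integer(v)))
      score[test_idx] <- rowMeans(probs)
      ensembles[[length(ensembles) + 1L]] <- list(
        rep = rep_i, fold = f,
        test_idx = test_idx, train_idx = train_idx,
        model_train_idx = ens$model_train_idx,
        models = if (keep_models) ens$models else NULL)
    }
    per_rep[[rep_i]] <- dplyr::mutate(
      metrics_from_predictions(y, pred, score), repetition = rep_i,
      .before = 1)
    predictions[[rep_i]] <- tibble::tibble(
      repetition = rep_i, subject = seq_len(n), truth = y,
      predicted = pred, score = score, fold = fold)
  }
  per_rep <- dplyr::bind_rows(per_rep)
  structure(list(per_rep = per_rep,
                 predictions = dplyr::bind_rows(predictions),
                 ensembles = ensembles, plan = plan, config = cfg,
                 labels = y, keep_models = keep_models),
            class = "smfc_cv")
}

#' @export
print.smfc_cv <- function(x, ...) {
  m <- colMeans(x$per_rep[, c("ACC", "BAC", "AUC")], na.rm = TRUE)
  cat(sprintf(
    "<smfc_cv> %d repetition(s) x %d folds, %d base classifiers/fold\n",
    x$plan$outer_reps, x$plan$outer_folds,
    x$plan$inner_folds * x$plan$inner_reps))
  cat(sprintf("  mean ACC %.1f%%, BAC %.1f%%, AUC %.1f%%\n",
              100 * m[1], 100 * m[2], 100 * m[3]))
  invisible(x)
}
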