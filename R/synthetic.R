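#' Synthetic cohort specification
#'
#' Describes a two-group cohort of multivariate Gaussian time series whose
#' population covariance has sparse off-diagonal structure, a subset of
#' which differs between groups (the planted discriminative edges). The
#' defaults are a desk-scale condition — 40 + 40 subjects, 20 ROIs, 200
#' time points, 8 planted edges of effect 0.5 under substantial
#' observation noise — small enough for full pipeline runs, strong enough
#' for the classifier to recover the planted structure, and noisy enough
#' that accuracy does not saturate (so occlusion analysis retains signal).
#'
#' @param n_per_group integer pair of group sizes (group 1 is labeled 0,
#'   group 2 labeled 1).
#' @param N number of ROIs.
#' @param L time points per subject.
#' @param base_density Erdos-Renyi density of the shared off-diagonal
#'   support.
#' @param n_discriminative_edges number of planted group-difference edges.
#' @param effect_size covariance (or precision) difference on the planted
#'   edges; shrunk with a warning if it breaks positive definiteness.
#' @param noise_sd standard deviation of additive white observation noise.
#' @param temporal_corr AR(1) coefficient in \[0, 1) giving the signals
#'   temporal smoothness (the innovation is scaled so the stationary
#'   covariance stays the specified one).
#' @param mode `"covariance"` (plant in the covariance; directly visible
#'   to Pearson correlation) or `"precision"` (plant in the inverse
#'   covariance; the natural ground truth for conditional-dependence
#'   support recovery).
#' @param seed integer seed.
#' @return list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = c(40, 40), N = 20, L = 200,
                        base_density = 0.15, n_discriminative_edges = 8,
                        effect_size = 0.5, noise_sd = 1.5,
                        temporal_corr = 0.3,
                        mode = c("covariance", "precision"), seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(length(n_per_group) == 2, all(n_per_group >= 1),
            N >= 2, L >= 2, base_density >= 0, base_density <= 1,
            n_discriminative_edges >= 0,
            n_discriminative_edges <= N * (N - 1) / 2,
            effect_size >= 0, noise_sd >= 0,
            temporal_corr >= 0, temporal_corr < 1)
  structure(list(n_per_group = as.integer(n_per_group), N = as.integer(N),
                 L = as.integer(L), base_density = base_density,
                 n_discriminative_edges = as.integer(n_discriminative_edges),
                 effect_size = effect_size, noise_sd = noise_sd,
                 temporal_corr = temporal_corr, mode = mode,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

min_eig <- function(M) min(eigen(M, symmetric = TRUE, only.values = TRUE)$values)

sym_from_edges <- function(N, edges, values) {
  M <- matrix(0, N, N)
  if (nrow(edges)) {
    M[edges] <- values
    M <- M + t(M)
  }
  M
}

#' Group covariance matrices with known structure
#'
#' Draws a shared Erdos-Renyi support for the off-diagonal baseline
#' structure, plants the group difference on randomly chosen edges, and
#' enforces positive definiteness: the baseline is diagonally loaded if
#' needed, and the planted effect is shrunk (with a warning) until both
#' matrices have smallest eigenvalue above 1e-8. In `"precision"` mode the
#' same construction is applied to the inverse covariance (with
#' diagonal-dominance loading) and the covariances are its standardized
#' inverses.
#'
#' @param spec a [cohort_spec()].
#' @return list with `sigma` (list of two N x N covariance matrices),
#'   `support_edges` (two-column matrix, the shared baseline support),
#'   `discriminative_edges` (two-column matrix of planted differences),
#'   `effect_size_used`, and in precision mode `omega` (the two precision
#'   matrices).
#' @export
make_group_covariances <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  N <- spec$N
  all_pairs <- which(upper.tri(matrix(0, N, N)), arr.ind = TRUE)
  E <- nrow(all_pairs)
  n_base <- round(spec$base_density * E)
  if (n_base > E) rlang::abort("base_density implies more edges than exist")
  sel <- sample.int(E, n_base)
  support <- all_pairs[sel, , drop = FALSE]
  base_vals <- stats::runif(n_base, 0.15, 0.3) *
    sample(c(-1, 1), n_base, replace = TRUE)
  # planted group differences live on edges disjoint from the baseline
  # support and are split symmetrically (-e/2 vs +e/2) so neither group's
  # matrix carries the full effect magnitude
  free <- setdiff(seq_len(E), sel)
  if (length(free) < spec$n_discriminative_edges)
    rlang::abort("not enough free edges to plant the group difference")
  disc_sel <- free[sample.int(length(free), spec$n_discriminative_edges)]
  disc <- all_pairs[disc_sel, , drop = FALSE]

  build <- function(effect) {
    base <- sym_from_edges(N, support, base_vals)
    B0 <- diag(N) + base + sym_from_edges(N, disc, rep(-effect / 2, nrow(disc)))
    B1 <- diag(N) + base + sym_from_edges(N, disc, rep(effect / 2, nrow(disc)))
    list(B0, B1)
  }
  load_pd <- function(M) {
    ev <- min_eig(M)
    if (ev <= 1e-8) M <- M + diag(1e-6 + abs(ev), nrow(M))
    M
  }
  effect <- spec$effect_size
  if (spec$mode == "covariance") {
    # shrink the planted effect until both covariances are PD
    repeat {
      mats <- build(effect)
      mats[[1]] <- load_pd(mats[[1]])
      if (min_eig(mats[[2]]) > 1e-8 || effect < 1e-6) break
      effect <- 0.9 * effect
    }
    if (effect < spec$effect_size)
      rlang::warn(sprintf(
        "effect_size shrunk from %.3g to %.3g to keep covariances positive definite",
        spec$effect_size, effect))
    mats[[2]] <- load_pd(mats[[2]])
    list(sigma = mats, support_edges = support,
         discriminative_edges = disc, effect_size_used = effect)
  } else {
    mats <- build(effect)
    dominate <- function(M) {
      diag(M) <- 0
      rs <- rowSums(abs(M))
      diag(M) <- pmax(1, 1.05 * rs)
      M
    }
    omega <- lapply(mats, dominate)
    sigma <- lapply(omega, function(o) {
      s <- stats::cov2cor(solve(o))
      (s + t(s)) / 2
    })
    list(sigma = sigma, omega = omega, support_edges = support,
         discriminative_edges = disc, effect_size_used = effect)
  }
}

#' Sample a labeled synthetic cohort
#'
#' Draws each subject as L multivariate normal observations from the
#' subject's group covariance, optionally AR(1)-filtered in time, plus
#' white observation noise, then normalizes columns to zero mean and unit
#' norm (the package convention). Everything is reproducible from
#' `spec$seed`.
#'
#' @param spec a [cohort_spec()].
#' @return list with `cohort` (list of normalized
#'   [ts_matrix][new_ts_matrix] objects), `labels` (0 for group 1, 1 for
#'   group 2), and `truth` (the [make_group_covariances()] output).
#' @export
sample_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  truth <- make_group_covariances(spec)
  phi <- spec$temporal_corr
  cohort <- list()
  labels <- integer(0)
  for (g in 1:2) {
    Sg <- truth$sigma[[g]]
    for (s in seq_len(spec$n_per_group[g])) {
      eps <- MASS::mvrnorm(spec$L, mu = rep(0, spec$N), Sigma = Sg)
      if (phi > 0) {
        x <- eps
        scale_innov <- sqrt(1 - phi^2)
        for (t in 2:spec$L) x[t, ] <- phi * x[t - 1, ] + scale_innov * eps[t, ]
      } else {
        x <- eps
      }
      if (spec$noise_sd > 0)
        x <- x + matrix(stats::rnorm(length(x), sd = spec$noise_sd),
                        nrow(x), ncol(x))
      id <- sprintf("g%d_s%03d", g, s)
      cohort[[length(cohort) + 1L]] <-
        normalize_series(x, subject_id = id, label = g - 1L)
      labels <- c(labels, g - 1L)
    }
  }
  list(cohort = cohort, labels = labels, truth = truth, spec = spec)
}
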