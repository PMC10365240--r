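#' Default pipeline configuration
#'
#' A nested list of every tunable the pipeline reads; values not supplied
#' by the user fall back to these. `lam_grid` may be numeric or a string
#' `"dyadic:<lo>:<hi>"` of exponents of two.
#'
#' @return named list.
#' @export
default_config <- function() {
  list(
    variant = "smfc",            # smfc | htfc | ssfc:<k>
    sigma = 0.2,
    lam_grid = "dyadic:-4:5",
    percents = c(seq(10, 90, by = 10), 99),
    orientation = "time-by-roi",
    seed = 1L,
    model = list(H = 64, V = 32, D1 = 128, D2 = 64, dropout = 0.2,
                 l2 = 1e-5, lr = 0.001, batch_size = 20, epochs = 200),
    cv = list(outer_folds = 5, inner_folds = 5, inner_reps = 5,
              outer_reps = 10, validation_fraction = 0.2),
    occlusion = list(edges = FALSE, regions = FALSE)
  )
}

parse_lam_grid <- function(x) {
  if (is.numeric(x)) return(x)
  if (is.character(x) && grepl("^dyadic:", x)) {
    parts <- as.integer(strsplit(sub("^dyadic:", "", x), ":")[[1]])
    return(dyadic_grid(parts[1], parts[2]))
  }
  rlang::abort("lam_grid must be numeric or 'dyadic:<lo>:<hi>'")
}

#' Load a pipeline configuration
#'
#' Reads a YAML file (or takes a list) and merges it over
#' [default_config()].
#'
#' @param config path to a YAML file, a list of overrides, or `NULL`.
#' @return merged configuration list.
#' @export
load_config <- function(config = NULL) {
  base <- default_config()
  if (is.null(config)) return(base)
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  utils::modifyList(base, config)
}

stage_msg <- function(fmt, ...) {
  message(sprintf("[smfcnet %s] %s", format(Sys.time(), "%H:%M:%S"),
                  sprintf(fmt, ...)))
}

#' Run the full pipeline on a cohort
#'
#' Manifest to metrics: reads the time series, builds the connectivity
#' stacks for the requested variant (`smfc` sparsity-guided, `htfc` hard
#' threshold ladder, or `ssfc:<k>` single guided level), runs nested
#' cross-validation with the voting ensemble, optionally runs occlusion
#' analyses, and writes everything (plus the resolved configuration and a
#' content hash of it) to `out_dir`.
#'
#' @param manifest path to a manifest CSV or a manifest tibble.
#' @param config configuration (see [load_config()]).
#' @param out_dir output directory.
#' @return invisibly, a list with the `smfc_cv` result and output paths.
#' @export
run_pipeline <- function(manifest, config = NULL, out_dir) {
  cfg_all <- load_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  stage_msg("loading cohort")
  dat <- load_cohort(manifest, orientation = cfg_all$orientation)
  n <- length(dat$cohort)
  N <- ncol(dat$cohort[[1]]$values)
  stage_msg("loaded %d subjects, %d ROIs", n, N)

  lam_grid <- parse_lam_grid(cfg_all$lam_grid)
  stage_msg("building %s stacks", cfg_all$variant)
  stacks <- build_cohort_stacks(dat$cohort, variant = cfg_all$variant,
                                lam_grid = lam_grid, sigma = cfg_all$sigma,
                                percents = cfg_all$percents)
  if (cfg_all$variant == "smfc") {
    n_conv <- sum(vapply(stacks, function(s) sum(!s$converged), numeric(1)))
    if (n_conv > 0)
      stage_msg("WSR solver hit the iteration cap on %d subject-levels", n_conv)
  }
  d <- dim(stacks[[1]]$M)[3]

  model_cfg <- do.call(smfc_config,
                       c(list(N = N, d = d, seed = cfg_all$seed),
                         cfg_all$model))
  plan <- do.call(cv_plan, c(cfg_all$cv, list(seed = cfg_all$seed)))
  want_occ <- isTRUE(cfg_all$occlusion$edges) ||
    isTRUE(cfg_all$occlusion$regions)
  stage_msg("nested CV: %d reps x %d folds, %d base classifiers per fold",
            plan$outer_reps, plan$outer_folds,
            plan$inner_folds * plan$inner_reps)
  cv <- nested_cv(stacks, dat$labels, plan, model_cfg,
                  keep_models = want_occ)

  paths <- list()
  metrics <- dplyr::bind_rows(
    dplyr::mutate(tidy(cv), set = "per_repetition", .before = 1),
    dplyr::mutate(glance(cv), set = "summary", .before = 1))
  paths$metrics <- file.path(out_dir, "metrics.csv")
  readr::write_csv(metrics, paths$metrics)
  paths$predictions <- file.path(out_dir, "predictions.csv")
  readr::write_csv(cv$predictions, paths$predictions)

  edges <- regions <- NULL
  if (isTRUE(cfg_all$occlusion$edges)) {
    stage_msg("occlusion: edges")
    edges <- edge_importance(cv, stacks)
    paths$edges <- file.path(out_dir, "edge_importance.csv")
    readr::write_csv(edges, paths$edges)
  }
  if (isTRUE(cfg_all$occlusion$regions)) {
    stage_msg("occlusion: regions")
    regions <- region_contribution(cv, stacks)
    paths$regions <- file.path(out_dir, "region_contribution.csv")
    readr::write_csv(regions, paths$regions)
  }

  meta <- list(config = cfg_all,
               config_hash = rlang::hash(cfg_all),
               n_subjects = n, n_rois = N, d = d,
               lam_grid = lam_grid,
               elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  paths$meta <- file.path(out_dir, "run_meta.json")
  jsonlite::write_json(meta, paths$meta, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  stage_msg("done in %.1fs", meta$elapsed_sec)
  invisible(list(cv = cv, edges = edges, regions = regions,
                 paths = paths, config = cfg_all))
}
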