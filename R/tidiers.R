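#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy per-repetition metrics of a cross-validation run
#'
#' @param x an `smfc_cv`.
#' @param ... unused.
#' @return tibble with one row per outer repetition and columns
#'   `repetition`, ACC, SEN, SPE, BAC, AUC, F1, PPV (fractions).
#' @export
tidy.smfc_cv <- function(x, ...) x$per_rep

#' One-row summary of a cross-validation run
#'
#' Mean and standard deviation of every metric across the outer
#' repetitions — the "mean (std)" convention of classification tables.
#'
#' @param x an `smfc_cv`.
#' @param ... unused.
#' @return one-row tibble with `<metric>` means and `<metric>_sd` columns.
#' @export
glance.smfc_cv <- function(x, ...) {
  mets <- dplyr::select(x$per_rep, -"repetition")
  means <- dplyr::summarise(mets, dplyr::across(dplyr::everything(),
                                                ~mean(.x, na.rm = TRUE)))
  sds <- dplyr::summarise(mets, dplyr::across(dplyr::everything(),
                                              ~stats::sd(.x, na.rm = TRUE)))
  names(sds) <- paste0(names(sds), "_sd")
  dplyr::bind_cols(means, sds)
}

#' Training history of a fitted classifier
#'
#' @param x an `smfc_model`.
#' @param ... unused.
#' @return tibble with `epoch` and training `loss`.
#' @export
tidy.smfc_model <- function(x, ...) {
  tibble::tibble(epoch = seq_along(x$history), loss = x$history)
}

#' One-row summary of a fitted classifier
#'
#' @param x an `smfc_model`.
#' @param ... unused.
#' @return tibble with epochs trained, initial/final loss and parameter
#'   count.
#' @export
glance.smfc_model <- function(x, ...) {
  tibble::tibble(
    epochs = length(x$history),
    initial_loss = if (length(x$history)) x$history[1] else NA_real_,
    final_loss = if (length(x$history)) x$history[length(x$history)] else NA_real_,
    n_parameters = sum(vapply(x$params, length, numeric(1))),
    trained = x$trained)
}

stack_to_long <- function(stack) {
  d <- dim(stack$M)[3]
  purrr::map_dfr(seq_len(d), function(k) {
    m <- stack$M[, , k]
    tibble::tibble(
      level = k, lambda = stack$lam_grid[k],
      roi_i = rep(seq_len(nrow(m)), times = ncol(m)),
      roi_j = rep(seq_len(ncol(m)), each = nrow(m)),
      value = as.vector(m))
  })
}

#' Heatmaps of a network stack
#'
#' One tile panel per sparsity level; zero (masked) entries are blank.
#'
#' @param object an `fcn_stack`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.fcn_stack <- function(object, ...) {
  df <- stack_to_long(object)
  df$value[df$value == 0] <- NA
  ggplot2::ggplot(df, ggplot2::aes(x = .data$roi_j, y = .data$roi_i,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~level, labeller = ggplot2::label_both) +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1), na.value = "white") +
    ggplot2::labs(x = "ROI", y = "ROI", fill = "r",
                  title = sprintf("Connectivity stack (%s), subject %s",
                                  object$kind, object$subject_id)) +
    ggplot2::theme_minimal()
}

#' Metric distribution across repetitions
#'
#' @param object an `smfc_cv`.
#' @param ... unused.
#' @return a ggplot of per-repetition metric values.
#' @export
autoplot.smfc_cv <- function(object, ...) {
  df <- tidyr::pivot_longer(object$per_rep, -"repetition",
                            names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$metric, y = 100 * .data$value)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.6) +
    ggplot2::labs(x = NULL, y = "percent",
                  title = "Nested CV metrics across repetitions") +
    ggplot2::theme_minimal()
}

#' Region contribution profile
#'
#' @param object a [region_contribution()] table.
#' @param ... unused.
#' @return a ggplot bar chart of normalized contributions.
#' @export
autoplot.region_contribution <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = factor(.data$roi), y = .data$C)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "ROI", y = "contribution",
                  title = "Occlusion contribution per region") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       size = 6))
}

#' Top connections by occlusion importance
#'
#' @param object an [edge_importance()] table.
#' @param k how many connections to show (default 10).
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.edge_importance <- function(object, k = 10, ...) {
  top <- top_k_report(object, min(k, nrow(object)))
  top$edge <- factor(paste(top$name_i, top$name_j, sep = " - "),
                     levels = rev(paste(top$name_i, top$name_j, sep = " - ")))
  ggplot2::ggplot(top, ggplot2::aes(x = .data$accuracy_drop, y = .data$edge)) +
    ggplot2::geom_segment(ggplot2::aes(x = 0, xend = .data$accuracy_drop,
                                       yend = .data$edge)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "accuracy drop (percentage points)", y = NULL,
                  title = "Most important connections (occlusion)") +
    ggplot2::theme_minimal()
}
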