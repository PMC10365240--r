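#' Subject time-series container
#'
#' A light S3 container for one subject's ROI time series: an L x N numeric
#' matrix (rows = time points, columns = ROIs) plus ROI labels, a subject
#' identifier and a binary diagnostic label.
#'
#' @param values numeric L x N matrix.
#' @param roi_ids character vector of N ROI names (defaults to `ROI1..ROIN`).
#' @param subject_id single string.
#' @param label 0, 1 or NA.
#' @param normalized logical; whether columns are centered and unit-norm.
#'
#' @return An object of class `ts_matrix`.
#' @keywords internal
new_ts_matrix <- function(values, roi_ids = NULL, subject_id = NA_character_,
                          label = NA_integer_, normalized = FALSE) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(roi_ids)) roi_ids <- paste0("ROI", seq_len(ncol(values)))
  stopifnot(length(roi_ids) == ncol(values))
  structure(
    list(values = values, roi_ids = as.character(roi_ids),
         subject_id = as.character(subject_id),
         label = if (is.na(label)) NA_integer_ else as.integer(label),
         normalized = isTRUE(normalized)),
    class = "ts_matrix"
  )
}

#' Normalize ROI time series
#'
#' Centers each ROI's time series to zero mean and scales it to unit
#' Euclidean norm, the convention under which the plain cross-product
#' `t(X) %*% X` of the normalized matrix is exactly the sample Pearson
#' correlation matrix. Constant (zero-variance) columns are rejected,
#' identifying the offending ROI.
#'
#' @param raw numeric L x N matrix (L >= 2), rows = time points.
#' @param roi_ids,subject_id,label metadata forwarded to the container.
#'
#' @return A normalized [ts_matrix][new_ts_matrix] object.
#' @export
#' @examples
#' x <- normalize_series(matrix(rnorm(60), 20, 3))
#' colMeans(x$values)            # ~0
#' colSums(x$values^2)           # all 1
normalize_series <- function(raw, roi_ids = NULL, subject_id = NA_character_,
                             label = NA_integer_) {
  if (!is.matrix(raw)) raw <- as.matrix(raw)
  if (!is.numeric(raw)) rlang::abort("time series must be numeric")
  if (nrow(raw) < 2) rlang::abort("need at least 2 time points (L >= 2)")
  if (anyNA(raw) || any(!is.finite(raw))) {
    bad <- which(!is.finite(raw), arr.ind = TRUE)[1, ]
    rlang::abort(sprintf("non-finite value at time point %d, ROI column %d",
                         bad[1], bad[2]))
  }
  centered <- sweep(raw, 2, colMeans(raw), "-")
  nrms <- sqrt(colSums(centered^2))
  if (any(nrms < .Machine$double.eps * nrow(raw))) {
    bad <- which(nrms < .Machine$double.eps * nrow(raw))
    lab <- if (!is.null(roi_ids)) roi_ids[bad[1]] else paste0("column ", bad[1])
    rlang::abort(sprintf("constant time series (zero variance) in %s%s",
                         lab,
                         if (length(bad) > 1)
                           sprintf(" and %d other column(s)", length(bad) - 1)
                         else ""))
  }
  vals <- sweep(centered, 2, nrms, "/")
  new_ts_matrix(vals, roi_ids = roi_ids, subject_id = subject_id,
                label = label, normalized = TRUE)
}

#' Pearson correlation matrix of a subject
#'
#' Computes the whole-brain N x N Pearson matrix as the cross-product of
#' the normalized time-series matrix. Entries lie in \[-1, 1\] with unit
#' diagonal; tiny floating-point overshoots are clamped.
#'
#' @param ts a normalized [ts_matrix][new_ts_matrix].
#' @return N x N symmetric numeric matrix with `dimnames` set to ROI ids.
#' @export
pearson_matrix <- function(ts) {
  stopifnot(inherits(ts, "ts_matrix"))
  if (!isTRUE(ts$normalized)) {
    rlang::abort("time series must be normalized first (see normalize_series)")
  }
  p <- crossprod(ts$values)
  p <- (p + t(p)) / 2
  p[p > 1] <- 1
  p[p < -1] <- -1
  diag(p) <- 1
  dimnames(p) <- list(ts$roi_ids, ts$roi_ids)
  p
}

#' @export
print.ts_matrix <- function(x, ...) {
  cat(sprintf("<ts_matrix> subject %s: %d time points x %d ROIs%s%s\n",
              x$subject_id, nrow(x$values), ncol(x$values),
              if (!is.na(x$label)) sprintf(", label %d", x$label) else "",
              if (x$normalized) ", normalized" else ""))
  invisible(x)
}

#' Drop initial volumes of a scan
#'
#' Resting-state acquisitions typically discard the first few volumes so
#' that the signal reaches steady state; with 150 acquired volumes and the
#' conventional 10 dropped this leaves L = 140 time points.
#'
#' @param raw numeric matrix, rows = time points.
#' @param n_discard number of leading rows to drop (default 10).
#' @return the trimmed matrix.
#' @export
discard_initial_volumes <- function(raw, n_discard = 10) {
  if (!is.matrix(raw)) raw <- as.matrix(raw)
  stopifnot(n_discard >= 0, n_discard < nrow(raw))
  if (n_discard == 0) return(raw)
  raw[-seq_len(n_discard), , drop = FALSE]
}
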