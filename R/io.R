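#' Read a subject's ROI time series from delimited text
#'
#' Accepts TSV/CSV with rows = time points and columns = ROIs (or the
#' transpose with `orientation = "roi-by-time"`). A header row of ROI
#' names is auto-detected: if the first line contains any token that does
#' not parse as a number it is taken as the header. Ragged rows,
#' non-numeric cells and missing values are rejected with a row/column
#' diagnostic.
#'
#' @param path file path.
#' @param orientation `"time-by-roi"` (default) or `"roi-by-time"`.
#' @param delim field delimiter; guessed from the extension when `NULL`
#'   (`.csv` = comma, otherwise whitespace/tab).
#' @return numeric matrix L x N with `colnames` set when a header exists.
#' @export
read_timeseries <- function(path, orientation = c("time-by-roi", "roi-by-time"),
                            delim = NULL) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) rlang::abort(sprintf("file not found: %s", path))
  if (is.null(delim))
    delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else ""
  first <- readLines(path, n = 1)
  toks <- strsplit(trimws(first),
                   if (delim == "") "[[:space:]]+" else delim)[[1]]
  has_header <- anyNA(suppressWarnings(as.numeric(toks)))
  raw <- utils::read.table(path, header = has_header,
                           sep = if (delim == "") "" else delim,
                           check.names = FALSE)
  for (j in seq_along(raw)) {
    col <- raw[[j]]
    if (!is.numeric(col)) {
      bad <- which(is.na(suppressWarnings(as.numeric(as.character(col)))))[1]
      rlang::abort(sprintf("non-numeric cell at data row %d, column %d of %s",
                           bad, j, path))
    }
  }
  mat <- as.matrix(raw)
  if (anyNA(mat)) {
    bad <- which(is.na(mat), arr.ind = TRUE)[1, ]
    rlang::abort(sprintf("missing value at data row %d, column %d of %s",
                         bad[1], bad[2], path))
  }
  if (orientation == "roi-by-time") {
    nms <- rownames(mat)
    mat <- t(mat)
    colnames(mat) <- nms
  }
  storage.mode(mat) <- "double"
  mat
}

#' Read a cohort manifest
#'
#' A manifest is a CSV/TSV table with columns `subject_id`, `path` and
#' `label` (0/1); relative paths are resolved against the manifest's
#' directory. Subject ids must be unique and both labels must be present.
#'
#' @param path manifest file.
#' @return tibble with resolved `path` column.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) rlang::abort(sprintf("manifest not found: %s", path))
  delim <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  man <- tibble::as_tibble(utils::read.table(path, header = TRUE, sep = delim,
                                             stringsAsFactors = FALSE))
  need <- c("subject_id", "path", "label")
  if (!all(need %in% names(man)))
    rlang::abort(sprintf("manifest must have columns %s",
                         paste(need, collapse = ", ")))
  if (anyDuplicated(man$subject_id))
    rlang::abort("duplicate subject_id in manifest")
  if (!all(man$label %in% c(0, 1)))
    rlang::abort("labels must be 0 or 1")
  if (length(unique(man$label)) < 2)
    rlang::abort("manifest must contain both labels")
  base <- dirname(normalizePath(path))
  man$path <- ifelse(grepl("^(/|[A-Za-z]:)", man$path), man$path,
                     file.path(base, man$path))
  missing <- !file.exists(man$path)
  if (any(missing))
    rlang::abort(sprintf("unresolvable path(s) in manifest: %s",
                         paste(man$subject_id[missing], collapse = ", ")))
  man
}

#' Load a cohort from a manifest
#'
#' @param manifest tibble from [read_manifest()] or a path to one.
#' @param orientation passed to [read_timeseries()].
#' @return list with `cohort` (normalized [ts_matrix][new_ts_matrix]
#'   objects) and `labels`.
#' @export
load_cohort <- function(manifest, orientation = "time-by-roi") {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  cohort <- purrr::map(seq_len(nrow(manifest)), function(i) {
    raw <- read_timeseries(manifest$path[i], orientation = orientation)
    normalize_series(raw, roi_ids = colnames(raw),
                     subject_id = manifest$subject_id[i],
                     label = manifest$label[i])
  })
  list(cohort = cohort, labels = as.integer(manifest$label))
}

#' Write a synthetic cohort to disk in the manifest format
#'
#' One TSV per subject (rows = time points, header = ROI names) plus a
#' `manifest.csv`, i.e. exactly the input format [load_cohort()] reads.
#'
#' @param sim result of [sample_cohort()].
#' @param dir output directory (created if needed).
#' @return invisibly, the manifest path.
#' @export
write_cohort <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- purrr::map(sim$cohort, function(ts) {
    fn <- paste0(ts$subject_id, ".tsv")
    df <- as.data.frame(ts$values)
    names(df) <- ts$roi_ids
    utils::write.table(df, file.path(dir, fn), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    tibble::tibble(subject_id = ts$subject_id, path = fn, label = ts$label)
  })
  man <- dplyr::bind_rows(rows)
  man_path <- file.path(dir, "manifest.csv")
  utils::write.table(man, man_path, sep = ",", row.names = FALSE,
                     quote = FALSE)
  invisible(man_path)
}

#' Write an FCN stack as portable text
#'
#' A directory with `meta.json` (subject id, grid, kind, ROI names) and
#' one CSV per sparsity level; [read_fcn_stack()] round-trips it.
#'
#' @param stack an `fcn_stack`.
#' @param dir output directory.
#' @return invisibly, `dir`.
#' @export
write_fcn_stack <- function(stack, dir) {
  stopifnot(inherits(stack, "fcn_stack"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- list(subject_id = stack$subject_id, label = stack$label,
               lam_grid = stack$lam_grid, kind = stack$kind,
               roi_ids = stack$roi_ids)
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  for (k in seq_along(stack$lam_grid)) {
    utils::write.table(stack$M[, , k],
                       file.path(dir, sprintf("level_%02d.csv", k)),
                       sep = ",", row.names = FALSE, col.names = FALSE)
  }
  invisible(dir)
}

#' @rdname write_fcn_stack
#' @export
read_fcn_stack <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  d <- length(meta$lam_grid)
  mats <- lapply(seq_len(d), function(k)
    as.matrix(utils::read.table(file.path(dir, sprintf("level_%02d.csv", k)),
                                sep = ",")))
  N <- nrow(mats[[1]])
  M <- array(0, c(N, N, d))
  for (k in seq_len(d)) M[, , k] <- mats[[k]]
  lab <- suppressWarnings(as.integer(meta$label))
  if (length(lab) == 0) lab <- NA_integer_
  sid <- meta$subject_id
  if (is.null(sid) || length(sid) == 0) sid <- NA_character_
  new_fcn_stack(M, meta$lam_grid, meta$roi_ids, sid, lab, kind = meta$kind)
}
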