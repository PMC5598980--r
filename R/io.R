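#' Read and write peak lists
#'
#' Peak lists are tibbles with columns `measurement_id`, `rt` (s), `ik0`
#' (Vs/cm2), `intensity`, and optional bounding-box columns `rt_lo`, `rt_hi`,
#' `ik0_lo`, `ik0_hi`. The on-disk form is CSV with those column names
#' (`rt_s`, `ik0_Vs_cm2` for the units-bearing ones).
#'
#' @param path file to read or write.
#' @param peaks a peak-list tibble.
#' @return `read_peaklist()` returns a tibble; `write_peaklist()` returns
#'   `path` invisibly.
#' @export
read_peaklist <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  req <- c("measurement_id", "rt_s", "ik0_Vs_cm2", "intensity")
  if (!all(req %in% names(df))) {
    stop(sprintf("peak list %s is missing columns: %s", path,
                 paste(setdiff(req, names(df)), collapse = ", ")), call. = FALSE)
  }
  out <- tibble::tibble(
    measurement_id = as.character(df$measurement_id),
    rt = df$rt_s, ik0 = df$ik0_Vs_cm2, intensity = df$intensity
  )
  for (col in c("rt_lo", "rt_hi", "ik0_lo", "ik0_hi")) {
    if (col %in% names(df)) out[[col]] <- df[[col]]
  }
  validate_peaklist(out)
}

#' @rdname read_peaklist
#' @export
write_peaklist <- function(peaks, path) {
  validate_peaklist(peaks)
  out <- dplyr::rename(peaks, rt_s = "rt", ik0_Vs_cm2 = "ik0")
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

validate_peaklist <- function(peaks) {
  peaks <- tibble::as_tibble(peaks)
  req <- c("measurement_id", "rt", "ik0", "intensity")
  stopifnot(all(req %in% names(peaks)))
  if (nrow(peaks)) {
    if (anyNA(peaks[req])) stop("peak list contains missing values", call. = FALSE)
    dup <- duplicated(peaks[c("measurement_id", "rt", "ik0")])
    if (any(dup)) stop("duplicate peak position within a measurement", call. = FALSE)
    if (all(c("rt_lo", "rt_hi") %in% names(peaks))) {
      bad <- !is.na(peaks$rt_lo) & !(peaks$rt_lo <= peaks$rt & peaks$rt <= peaks$rt_hi)
      if (any(bad)) stop("peak bbox does not contain peak position", call. = FALSE)
    }
  }
  peaks
}

#' Read and write feature matrices
#'
#' A feature matrix is a wide tibble: one row per measurement with columns
#' `measurement_id`, `label`, then one numeric column per consensus-peak
#' feature. Entries are the intensity assigned to that measurement for that
#' feature, 0 when no peak was found within the assignment radius.
#'
#' @param path file to read or write.
#' @param fm a feature-matrix tibble.
#' @return `read_feature_matrix()` returns a tibble; `write_feature_matrix()`
#'   returns `path` invisibly.
#' @export
read_feature_matrix <- function(path) {
  header <- strsplit(readLines(path, n = 1), ",", fixed = TRUE)[[1]]
  if (anyDuplicated(header)) {
    stop(sprintf("duplicate feature id '%s' in %s",
                 header[duplicated(header)][1], path), call. = FALSE)
  }
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_feature_matrix(df)
}

#' @rdname read_feature_matrix
#' @export
write_feature_matrix <- function(fm, path) {
  validate_feature_matrix(fm)
  readr::write_csv(fm, path, progress = FALSE)
  invisible(path)
}

validate_feature_matrix <- function(fm) {
  fm <- tibble::as_tibble(fm)
  stopifnot(all(c("measurement_id", "label") %in% names(fm)))
  if (anyDuplicated(fm$measurement_id)) {
    stop("duplicate measurement ids in feature matrix", call. = FALSE)
  }
  vals <- feature_values(fm)
  if (ncol(vals) && (!all(is.finite(vals)) || any(vals < 0))) {
    stop("feature values must be finite and >= 0", call. = FALSE)
  }
  fm
}

#' Numeric feature block of a feature-matrix tibble
#'
#' Drops the `measurement_id` and `label` columns and returns the intensity
#' block as a numeric matrix with measurement ids as row names.
#'
#' @param fm a feature-matrix tibble.
#' @return Numeric matrix, n measurements x p features.
#' @export
feature_block <- function(fm) feature_values(fm)

feature_values <- function(fm) {
  cols <- setdiff(names(fm), c("measurement_id", "label"))
  m <- as.matrix(fm[cols])
  if (length(cols)) storage.mode(m) <- "double"
  rownames(m) <- fm$measurement_id
  m
}
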