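#' Construct an MCC-IMS measurement
#'
#' A measurement is one breath sample's dense 2D intensity map: rows follow
#' retention time (the multi-capillary column axis, seconds), columns follow
#' inverse reduced mobility 1/K0 (the ion drift axis, Vs/cm2). All public
#' coordinates in the package are in these physical units; grid indices never
#' leave the internals.
#'
#' @param intensity numeric matrix, `length(rt) x length(ik0)`, finite values.
#' @param rt retention-time axis in seconds, strictly ascending.
#' @param ik0 inverse-reduced-mobility axis in Vs/cm2, strictly ascending.
#' @param sample_id identifier for the measurement.
#' @param label optional class label, `"case"` or `"control"`.
#' @return An object of class `ims_measurement`: a list with fields
#'   `sample_id`, `rt`, `ik0`, `intensity`, `label`.
#' @examples
#' m <- ims_measurement(matrix(0, 4, 3), rt = 1:4, ik0 = c(0.5, 0.6, 0.7), "s1")
#' dim(m$intensity)
#' @export
ims_measurement <- function(intensity, rt, ik0, sample_id = "sample",
                            label = NA_character_) {
  intensity <- as.matrix(intensity)
  storage.mode(intensity) <- "double"
  rt <- as.double(rt)
  ik0 <- as.double(ik0)
  m <- structure(
    list(sample_id = as.character(sample_id), rt = rt, ik0 = ik0,
         intensity = intensity, label = as.character(label)),
    class = "ims_measurement"
  )
  validate_measurement(m)
}

validate_measurement <- function(m) {
  if (length(m$rt) == 0 || length(m$ik0) == 0) {
    stop("zero-sized measurement grids are invalid", call. = FALSE)
  }
  if (!all(is.finite(m$rt)) || !all(is.finite(m$ik0))) {
    stop("measurement axes must be finite", call. = FALSE)
  }
  if (any(diff(m$rt) <= 0)) stop("rt axis must be strictly ascending", call. = FALSE)
  if (any(diff(m$ik0) <= 0)) stop("ik0 axis must be strictly ascending", call. = FALSE)
  if (!identical(dim(m$intensity), c(length(m$rt), length(m$ik0)))) {
    stop(sprintf("intensity shape (%d x %d) does not match axes (%d x %d)",
                 nrow(m$intensity), ncol(m$intensity),
                 length(m$rt), length(m$ik0)), call. = FALSE)
  }
  if (!all(is.finite(m$intensity))) {
    stop("intensity values must all be finite", call. = FALSE)
  }
  if (!is.na(m$label) && !m$label %in% c("case", "control")) {
    stop("label must be 'case', 'control' or NA", call. = FALSE)
  }
  m
}

#' @export
print.ims_measurement <- function(x, ...) {
  cat(sprintf("<ims_measurement> %s: %d rt x %d ik0\n", x$sample_id,
              length(x$rt), length(x$ik0)))
  cat(sprintf("  rt  %.4g..%.4g s | 1/K0 %.4g..%.4g Vs/cm2 | max intensity %.4g\n",
              min(x$rt), max(x$rt), min(x$ik0), max(x$ik0), max(x$intensity)))
  if (!is.na(x$label)) cat(sprintf("  label: %s\n", x$label))
  invisible(x)
}

#' @export
dim.ims_measurement <- function(x) dim(x$intensity)

#' Read a measurement from a headered dense-grid text file
#'
#' The on-disk format is a delimited grid: optional leading `#` metadata lines
#' (`# sample_id: ...`, `# label: ...`), then a header row whose first cell is
#' empty/reserved and whose remaining cells are the 1/K0 axis, then one row
#' per retention time whose first cell is the rt value. Axes stored in
#' descending order are normalised to ascending (with the matrix reordered to
#' match), and a transposed file (rows = 1/K0) is normalised to rows = rt.
#'
#' @param path file to read.
#' @param sep field separator (default comma).
#' @param transpose set `TRUE` when the file stores rows as 1/K0 spectra.
#' @return An [ims_measurement()].
#' @export
read_measurement <- function(path, sep = ",", transpose = FALSE) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (length(lines) < 2) {
    stop(sprintf("malformed measurement file %s: need a header row and at least one data row", path),
         call. = FALSE)
  }
  sample_id <- sub("^#\\s*sample_id:\\s*", "", grep("^#\\s*sample_id:", meta, value = TRUE))
  label <- sub("^#\\s*label:\\s*", "", grep("^#\\s*label:", meta, value = TRUE))
  fields <- strsplit(lines, sep, fixed = TRUE)

  header <- fields[[1]]
  col_axis <- suppressWarnings(as.double(header[-1]))
  if (anyNA(col_axis)) {
    stop(sprintf("malformed header in %s (line 1): non-numeric axis value '%s'",
                 path, header[-1][which(is.na(col_axis))[1]]), call. = FALSE)
  }
  body <- fields[-1]
  ncol_expect <- length(header)
  row_axis <- numeric(length(body))
  mat <- matrix(NA_real_, length(body), length(col_axis))
  for (i in seq_along(body)) {
    row <- body[[i]]
    if (length(row) != ncol_expect) {
      stop(sprintf("malformed row %d in %s: %d fields, expected %d",
                   i + 1L, path, length(row), ncol_expect), call. = FALSE)
    }
    vals <- suppressWarnings(as.double(row))
    if (anyNA(vals)) {
      j <- which(is.na(vals))[1]
      stop(sprintf("parse error in %s at row %d, column %d: non-numeric cell '%s'",
                   path, i, j - 1L, row[j]), call. = FALSE)
    }
    row_axis[i] <- vals[1]
    mat[i, ] <- vals[-1]
  }

  if (transpose) {
    mat <- t(mat)
    tmp <- row_axis; row_axis <- col_axis; col_axis <- tmp
  }
  # normalise to strictly ascending axes
  ord_r <- order(row_axis)
  ord_c <- order(col_axis)
  ims_measurement(mat[ord_r, ord_c, drop = FALSE], rt = row_axis[ord_r],
                  ik0 = col_axis[ord_c],
                  sample_id = if (length(sample_id)) sample_id[1] else
                    tools::file_path_sans_ext(basename(path)),
                  label = if (length(label)) label[1] else NA_character_)
}

#' Write a measurement to the dense-grid text format
#'
#' Round-trips through [read_measurement()] to better than 1e-9 relative
#' precision on axes and intensities.
#'
#' @param m an [ims_measurement()].
#' @param path destination file.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_measurement <- function(m, path, sep = ",") {
  validate_measurement(m)
  con <- tryCatch(file(path, "w"), error = function(e)
    stop(sprintf("cannot write measurement to %s: %s", path, conditionMessage(e)),
         call. = FALSE))
  on.exit(close(con))
  writeLines(sprintf("# sample_id: %s", m$sample_id), con)
  if (!is.na(m$label)) writeLines(sprintf("# label: %s", m$label), con)
  fmt <- function(x) format(x, digits = 17, scientific = TRUE, trim = TRUE)
  writeLines(paste(c("", fmt(m$ik0)), collapse = sep), con)
  body <- cbind(fmt(m$rt), matrix(fmt(m$intensity), nrow(m$intensity)))
  writeLines(apply(body, 1, paste, collapse = sep), con)
  invisible(path)
}

#' Heatmap of a measurement
#'
#' @param object an [ims_measurement()].
#' @param trans transformation applied to intensity for display.
#' @param ... unused.
#' @return A ggplot object: 1/K0 on x, retention time on y.
#' @exportS3Method ggplot2::autoplot
autoplot.ims_measurement <- function(object, trans = sqrt, ...) {
  df <- tidyr::expand_grid(rt = object$rt, ik0 = object$ik0)
  df$intensity <- as.vector(t(object$intensity))
  ggplot2::ggplot(df, ggplot2::aes(.data$ik0, .data$rt,
                                   fill = trans(.data$intensity))) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "intensity") +
    ggplot2::labs(x = "1/K0 [Vs/cm2]", y = "retention time [s]",
                  title = object$sample_id)
}
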