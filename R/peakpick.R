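#' @importFrom rlang .data
NULL

empty_peaklist <- function(id, bbox = FALSE) {
  out <- tibble::tibble(measurement_id = character(), rt = double(),
                        ik0 = double(), intensity = double())
  if (bbox) {
    out$rt_lo <- double(); out$rt_hi <- double()
    out$ik0_lo <- double(); out$ik0_hi <- double()
  }
  out
}

# columns excluded from peak candidacy: the RIP band, if the measurement
# passed through compensate_rip()
rip_mask_cols <- function(m) {
  if (is.null(m$rip_band)) integer(0) else m$rip_band
}

# strict 8-neighbourhood local maxima; returns a logical matrix
strict_local_max <- function(x) {
  nr <- nrow(x); nc <- ncol(x)
  pad <- matrix(-Inf, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- x
  res <- matrix(TRUE, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    res <- res & (x > pad[(2 + dr):(nr + 1 + dr), (2 + dc):(nc + 1 + dc)])
  }
  res
}

# 8-connected components of a logical mask; returns an integer label vector
# over which(mask) cell indices (list: cells = linear indices, comp = labels)
connected_components8 <- function(mask) {
  cells <- which(mask)
  if (!length(cells)) return(list(cells = integer(0), comp = integer(0)))
  nr <- nrow(mask)
  rows <- ((cells - 1L) %% nr) + 1L
  cols <- ((cells - 1L) %/% nr) + 1L
  key <- function(r, co) (co - 1L) * nr + r
  pos <- seq_along(cells)
  edges <- list()
  shifts <- list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))
  for (s in shifts) {
    nb <- match(key(rows + s[1], cols + s[2]), cells)
    ok <- !is.na(nb) & rows + s[1] >= 1L & rows + s[1] <= nr
    edges[[length(edges) + 1L]] <- cbind(pos[ok], nb[ok])
  }
  e <- do.call(rbind, edges)
  g <- igraph::make_empty_graph(n = length(cells), directed = FALSE)
  if (nrow(e)) g <- igraph::add_edges(g, t(e))
  list(cells = cells, comp = igraph::components(g)$membership)
}

cells_to_rowcol <- function(cells, nr) {
  list(row = ((cells - 1L) %% nr) + 1L, col = ((cells - 1L) %/% nr) + 1L)
}

#' Local-maxima (LM) peak picking
#'
#' Flags every cell whose intensity exceeds a threshold and strictly exceeds
#' all eight neighbours (exact-tie plateaus yield no candidate), then joins
#' nearby candidates with the weighted cluster-editing routine also used for
#' cross-measurement clustering: candidate pairs within `join_radius` grid
#' cells (Chebyshev) get positive similarity `join_radius - distance`, and
#' the minimum-cost clique partition groups them. Each resulting peak takes
#' the position and intensity of its highest-intensity member cell.
#'
#' @param m an [ims_measurement()], typically after [compensate_rip()] and
#'   [smooth_savgol()]; the RIP band (if recorded on `m`) is masked from
#'   candidacy.
#' @param threshold intensity threshold in signal units; default: the
#'   [estimate_noise()] level of `m`.
#' @param join_radius joining distance in grid cells (Chebyshev).
#' @return A peak-list tibble.
#' @export
pick_lm <- function(m, threshold = NULL, join_radius = 3) {
  validate_measurement(m)
  if (is.null(threshold)) threshold <- estimate_noise(m)$level
  stopifnot(threshold >= 0)
  cand <- strict_local_max(m$intensity) & (m$intensity > threshold)
  cand[, rip_mask_cols(m)] <- FALSE
  cells <- which(cand)
  if (!length(cells)) return(empty_peaklist(m$sample_id))
  rc <- cells_to_rowcol(cells, nrow(m$intensity))
  cheb <- pmax(abs(outer(rc$row, rc$row, `-`)), abs(outer(rc$col, rc$col, `-`)))
  part <- ce_partition(join_radius - cheb)
  ints <- m$intensity[cells]
  best <- vapply(split(seq_along(cells), part$membership),
                 function(ix) ix[which.max(ints[ix])], integer(1))
  best <- best[order(rc$row[best], rc$col[best])]
  tibble::tibble(measurement_id = m$sample_id, rt = m$rt[rc$row[best]],
                 ik0 = m$ik0[rc$col[best]], intensity = ints[best])
}

#' SGLTR peak picking (Savitzky-Golay Laplace-operator thresholding regions)
#'
#' Computes the negated-Laplacian curvature response of the matrix with
#' Savitzky-Golay second-derivative filters ([laplacian_response()]), then
#' takes the 8-connected components of the cells whose response exceeds the
#' response's own noise level and whose intensity exceeds the intensity
#' noise level. Each region becomes one peak at its maximum-intensity cell,
#' with the region bounding box attached.
#'
#' @inheritParams pick_lm
#' @param window,order Savitzky-Golay filter parameters.
#' @param noise_k threshold factor for both noise levels.
#' @param floor lower bound applied to both thresholds, in the respective
#'   units; useful on noise-free synthetic data where the estimated level
#'   degenerates to zero.
#' @param min_region smallest accepted region size in cells; single-cell
#'   blips are not credible 2D peaks, so regions below this size are
#'   discarded.
#' @return A peak-list tibble with bbox columns.
#' @export
pick_sgltr <- function(m, window = 9, order = 2, noise_k = 3, floor = 0,
                       min_region = 2) {
  validate_measurement(m)
  resp <- laplacian_response(m, window, order)$intensity
  lev_r <- max(estimate_noise(resp, noise_k)$level, floor)
  lev_i <- max(estimate_noise(m, noise_k)$level, floor)
  mask <- resp > lev_r & m$intensity > lev_i
  mask[, rip_mask_cols(m)] <- FALSE
  cc <- connected_components8(mask)
  if (!length(cc$cells)) return(empty_peaklist(m$sample_id, bbox = TRUE))
  rc <- cells_to_rowcol(cc$cells, nrow(m$intensity))
  ints <- m$intensity[cc$cells]
  regions <- split(seq_along(cc$cells), cc$comp)
  regions <- regions[lengths(regions) >= min_region]
  if (!length(regions)) return(empty_peaklist(m$sample_id, bbox = TRUE))
  purrr::map_dfr(regions, function(ix) {
    apex <- ix[which.max(ints[ix])]
    tibble::tibble(
      measurement_id = m$sample_id,
      rt = m$rt[rc$row[apex]], ik0 = m$ik0[rc$col[apex]],
      intensity = ints[apex],
      rt_lo = m$rt[min(rc$row[ix])], rt_hi = m$rt[max(rc$row[ix])],
      ik0_lo = m$ik0[min(rc$col[ix])], ik0_hi = m$ik0[max(rc$col[ix])])
  }) |> dplyr::arrange(.data$rt, .data$ik0)
}

#' PDSA peak picking (peak detection by slope analysis)
#'
#' Processes each drift spectrum (one retention time, one matrix row) on its
#' own: sliding windows of `segment_window` cells are scored by their
#' intensity sum; a window is a segment when its score is a strict local
#' maximum over one-cell shifts and exceeds `segment_window` times the noise
#' level; among overlapping segments within a row only the highest-scoring
#' survives. Segments in adjacent rows whose drift intervals overlap by at
#' least `min_overlap_fraction` of the window are chained, and each chain
#' yields one peak at its maximum-intensity cell with the union bounding
#' box.
#'
#' @inheritParams pick_sgltr
#' @param segment_window sliding-window length in cells.
#' @param min_overlap_fraction minimum fractional drift-interval overlap for
#'   chaining segments across adjacent retention times, in `[0, 1]`.
#' @return A peak-list tibble with bbox columns.
#' @export
pick_pdsa <- function(m, segment_window = 5, noise_k = 3,
                      min_overlap_fraction = 0.5, floor = 0) {
  validate_measurement(m)
  w <- segment_window
  nc <- ncol(m$intensity)
  if (w > nc) stop("segment_window exceeds spectrum length", call. = FALSE)
  stopifnot(min_overlap_fraction >= 0, min_overlap_fraction <= 1)
  level <- max(estimate_noise(m, noise_k)$level, floor)
  masked <- rip_mask_cols(m)

  cs <- cbind(0, t(apply(m$intensity, 1, cumsum)))
  starts <- seq_len(nc - w + 1L)
  score <- cs[, starts + w, drop = FALSE] - cs[, starts, drop = FALSE]

  segs <- purrr::map_dfr(seq_len(nrow(score)), function(i) {
    s <- score[i, ]
    left <- c(-Inf, s[-length(s)]); right <- c(s[-1], -Inf)
    ok <- s > left & s > right & s > w * level
    if (length(masked)) {
      hit <- vapply(starts, function(j) any(j:(j + w - 1L) %in% masked), logical(1))
      ok <- ok & !hit
    }
    j <- which(ok)
    if (!length(j)) return(NULL)
    # overlapping segments within a row: keep the best scorer greedily
    keep <- integer(0)
    for (cand in j[order(-s[j])]) {
      if (!any(abs(keep - cand) < w)) keep <- c(keep, cand)
    }
    tibble::tibble(row = i, start = sort(keep))
  })
  if (!nrow(segs)) return(empty_peaklist(m$sample_id, bbox = TRUE))

  # chain segments across adjacent retention times by drift-interval overlap
  n <- nrow(segs)
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (n > 1) {
    pairs <- which(outer(segs$row, segs$row, function(a, b) b - a == 1L) &
                     outer(segs$start, segs$start,
                           function(a, b) (w - abs(a - b)) / w >= min_overlap_fraction),
                   arr.ind = TRUE)
    if (nrow(pairs)) g <- igraph::add_edges(g, t(pairs))
  }
  comp <- igraph::components(g)$membership
  purrr::map_dfr(split(seq_len(n), comp), function(ix) {
    sub <- segs[ix, ]
    cols_lo <- min(sub$start); cols_hi <- max(sub$start) + w - 1L
    block <- m$intensity[sub$row, cols_lo:cols_hi, drop = FALSE]
    apex <- which(block == max(block), arr.ind = TRUE)[1, ]
    tibble::tibble(
      measurement_id = m$sample_id,
      rt = m$rt[sub$row[apex[1]]], ik0 = m$ik0[cols_lo + apex[2] - 1L],
      intensity = max(block),
      rt_lo = m$rt[min(sub$row)], rt_hi = m$rt[max(sub$row)],
      ik0_lo = m$ik0[cols_lo], ik0_hi = m$ik0[cols_hi])
  }) |> dplyr::arrange(.data$rt, .data$ik0)
}

#' Preprocess and pick peaks for a batch of measurements
#'
#' Convenience wrapper running the standard chain RIP compensation ->
#' Savitzky-Golay smoothing -> one picker over a list of measurements,
#' returning a single combined peak-list tibble.
#'
#' @param measurements list of [ims_measurement()] objects.
#' @param method `"lm"`, `"sgltr"` or `"pdsa"`.
#' @param rip enable RIP compensation.
#' @param smooth_window,smooth_order smoothing parameters (`smooth_window =
#'   0` disables smoothing).
#' @param ... passed to the picker.
#' @return A peak-list tibble over all measurements.
#' @export
pick_peaks <- function(measurements, method = c("sgltr", "lm", "pdsa"),
                       rip = TRUE, smooth_window = 9, smooth_order = 2, ...) {
  method <- match.arg(method)
  picker <- switch(method, lm = pick_lm, sgltr = pick_sgltr, pdsa = pick_pdsa)
  purrr::map_dfr(measurements, function(m) {
    if (rip) m <- compensate_rip(m)
    if (smooth_window >= 3) {
      sm <- smooth_savgol(m, smooth_window, smooth_order)
      sm$rip_band <- m$rip_band
      m <- sm
    }
    picker(m, ...)
  })
}
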