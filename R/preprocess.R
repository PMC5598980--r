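#' Robust noise level of a measurement
#'
#' Estimates the background signal level of a 2D intensity matrix as
#' median + k * MAD (MAD scaled by 1.4826 for consistency with the normal
#' standard deviation). Most of an MCC-IMS matrix is background, so the
#' median/MAD pair is a robust location/scale estimate that a handful of
#' analyte peaks cannot shift.
#'
#' @param m an [ims_measurement()], or a bare numeric matrix.
#' @param k threshold factor (dimensionless, > 0); default 3 (the usual
#'   three-sigma rule).
#' @return An object of class `ims_noise`: list with `center`, `spread`,
#'   `k`, and `level = center + k * spread`.
#' @export
estimate_noise <- function(m, k = 3) {
  stopifnot(k > 0)
  x <- if (inherits(m, "ims_measurement")) m$intensity else m
  center <- stats::median(x)
  spread <- stats::mad(x, center = center)
  structure(list(center = center, spread = spread, k = k,
                 level = center + k * spread),
            class = "ims_noise")
}

#' @export
print.ims_noise <- function(x, ...) {
  cat(sprintf("<ims_noise> center %.4g, spread %.4g, level (k=%g) %.4g\n",
              x$center, x$spread, x$k, x$level))
  invisible(x)
}

#' Compensate the reactant ion peak (RIP)
#'
#' The RIP is a high-intensity artifact band from the ionised carrier gas; it
#' sits at a fixed drift position (1/K0) across all retention times. A RIP
#' is called present when the largest column-wise median intensity dominates
#' the typical column median by at least `dominance` (analyte peaks are
#' localised in retention time and barely move a column median, while the
#' RIP spans the whole column). Its band is then the contiguous run of
#' columns around that maximum whose medians exceed `band_fraction` of it;
#' the small default captures the band's full cross-profile tails, which
#' otherwise survive as intense retention-invariant stripes. Within the band
#' the column-wise 25th percentile (a robust per-column baseline across
#' retention time) is subtracted and the result clamped at zero; columns
#' outside the band are untouched, so analyte peaks away from the RIP are
#' preserved exactly.
#'
#' @param m an [ims_measurement()].
#' @param band_fraction fraction of the maximal column median down to which
#'   the contiguous band extends (default 0.02).
#' @param dominance minimal ratio of the maximal column median to the median
#'   column median for a RIP to be declared at all (default 5).
#' @return A new measurement with the same axes; the detected band column
#'   indices are attached as field `rip_band` (integer vector, possibly
#'   empty) and are masked from peak candidacy by the pickers.
#' @export
compensate_rip <- function(m, band_fraction = 0.02, dominance = 5) {
  validate_measurement(m)
  stopifnot(band_fraction > 0, band_fraction <= 1, dominance >= 1)
  med <- apply(m$intensity, 2, stats::median)
  out <- m
  peak_col <- which.max(med)
  if (med[peak_col] <= 0 ||
      med[peak_col] < dominance * max(stats::median(med), 0)) {
    out$rip_band <- integer(0)                  # no dominant band present
    return(out)
  }
  in_band <- med > band_fraction * med[peak_col]
  # contiguous run containing the maximum
  lo <- peak_col; while (lo > 1 && in_band[lo - 1]) lo <- lo - 1
  hi <- peak_col; while (hi < length(med) && in_band[hi + 1]) hi <- hi + 1
  band <- lo:hi
  baseline <- apply(m$intensity[, band, drop = FALSE], 2, stats::quantile,
                    probs = 0.25, names = FALSE)
  out$intensity[, band] <- pmax(
    sweep(m$intensity[, band, drop = FALSE], 2, baseline), 0)
  out$rip_band <- band
  out
}

# Savitzky-Golay convolution kernel: least-squares fit of a polynomial of
# degree `order` on the window -h..h (unit cell spacing), evaluated as the
# `deriv`-th derivative at the centre. Exact for polynomials up to `order`.
sg_kernel <- function(window, order, deriv = 0) {
  if (window %% 2 != 1 || window < 3) {
    stop("Savitzky-Golay window must be odd and >= 3", call. = FALSE)
  }
  if (order >= window) stop("polynomial order must be < window", call. = FALSE)
  if (deriv > order) stop("derivative order exceeds polynomial order", call. = FALSE)
  h <- (window - 1) / 2
  x <- -h:h
  X <- outer(x, 0:order, `^`)
  # row deriv+1 of (X'X)^{-1} X' gives the deriv-th polynomial coefficient
  coef <- solve(crossprod(X), t(X))[deriv + 1, ]
  coef * factorial(deriv)
}

# apply a 1D kernel along matrix rows (margin = 1: down the rt axis) or
# columns, with nearest-edge replication at the borders
apply_kernel <- function(x, kernel, margin) {
  h <- (length(kernel) - 1) / 2
  n <- dim(x)[margin]
  idx_pad <- c(rep(1L, h), seq_len(n), rep(n, h))
  out <- matrix(0, nrow(x), ncol(x))
  for (j in seq_along(kernel)) {
    sl <- idx_pad[j:(j + n - 1)]
    out <- out + kernel[j] * (if (margin == 1) x[sl, , drop = FALSE]
                              else x[, sl, drop = FALSE])
  }
  out
}

#' Separable 2D Savitzky-Golay smoothing
#'
#' Applies a Savitzky-Golay (local polynomial least squares) smoothing kernel
#' along the retention-time axis and then along the 1/K0 axis. The filter is
#' linear, preserves constants exactly, and reproduces any polynomial surface
#' of degree at most `order` exactly on interior cells. Borders use
#' nearest-edge replication.
#'
#' @param m an [ims_measurement()].
#' @param window odd kernel width in grid cells, >= 3.
#' @param order polynomial degree, < window.
#' @return A smoothed measurement (axes unchanged; `rip_band` carried over).
#' @export
smooth_savgol <- function(m, window = 9, order = 2) {
  validate_measurement(m)
  k <- sg_kernel(window, order, deriv = 0)
  out <- m
  out$intensity <- apply_kernel(apply_kernel(m$intensity, k, 1), k, 2)
  out
}

#' Negated-Laplacian curvature response
#'
#' The response driving SGLTR peak picking: minus the sum of the unmixed
#' second derivatives along retention time and along 1/K0, each estimated by
#' a Savitzky-Golay second-derivative filter on the cell grid (units:
#' intensity per cell^2). A peak apex has strongly negative second
#' derivatives in both directions, so the response is large and positive
#' there.
#'
#' @inheritParams smooth_savgol
#' @return A measurement whose `intensity` holds the curvature response
#'   (may be negative).
#' @export
laplacian_response <- function(m, window = 9, order = 2) {
  validate_measurement(m)
  if (order < 2) stop("curvature response needs polynomial order >= 2", call. = FALSE)
  k2 <- sg_kernel(window, order, deriv = 2)
  out <- m
  out$intensity <- -(apply_kernel(m$intensity, k2, 1) +
                       apply_kernel(m$intensity, k2, 2))
  out
}

#' Hard-threshold denoising
#'
#' Sets every cell strictly below `level` to zero, leaving the rest
#' untouched.
#'
#' @param m an [ims_measurement()].
#' @param level threshold in signal units, >= 0.
#' @return The thresholded measurement.
#' @export
threshold_denoise <- function(m, level) {
  validate_measurement(m)
  stopifnot(level >= 0)
  m$intensity[m$intensity < level] <- 0
  m
}
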