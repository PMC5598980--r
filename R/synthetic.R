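#' Specification of a synthetic two-class MCC-IMS cohort
#'
#' Defines the study conditions a generated cohort emulates: two groups of
#' breath measurements on a shared grid, a reactant-ion-peak band, a set of
#' true analyte peaks (some class-differential) whose realised positions
#' jitter across measurements and which drop out of individual measurements
#' with some probability, lognormal intensities, and additive detector
#' noise clamped at zero.
#'
#' Defaults give a desk-scale cohort of 30 cases + 30 controls on a
#' 600 x 400 grid (retention 0-300 s, 1/K0 0.4-1.0 Vs/cm2) with 20 shared +
#' 5 differential peaks (per-measurement peak counts of this order match
#' routinely reported MCC-IMS numbers), a twofold case/control intensity
#' ratio on differential peaks, 10% dropout and peak amplitudes around 20x
#' the noise standard deviation.
#'
#' @param n_case,n_control group sizes.
#' @param grid list `n_rt`, `n_ik0`, `rt_range` (s), `ik0_range` (Vs/cm2).
#' @param n_shared_peaks,n_diff_peaks counts of non-differential and
#'   class-differential true peaks.
#' @param amplitude_lognormal list `mu`, `sigma` of log peak amplitude
#'   (signal units).
#' @param effect_size multiplicative intensity fold-change of differential
#'   peaks in cases.
#' @param jitter list `sd_ik0` (Vs/cm2), `sd_rt` (s): positional noise of a
#'   peak across measurements.
#' @param dropout probability that a true peak is absent from a
#'   measurement.
#' @param peak_shape list `sd_ik0`, `sd_rt`, `rt_tailing` (s; exponential
#'   tail constant of the retention profile, 0 = pure Gaussian).
#' @param rip list `column_fraction` (band width as a fraction of the 1/K0
#'   axis; the band is centred at 12% of the axis, near the low-mobility
#'   end where the reactant ion peak physically sits) and `amplitude`.
#' @param noise_sd additive Gaussian noise standard deviation.
#' @param min_sep minimum normalised separation (default [peak_scaling()])
#'   enforced between true peak positions.
#' @param seed integer seed; the cohort is a deterministic function of the
#'   spec.
#' @return An object of class `ims_cohort_spec`.
#' @export
cohort_spec <- function(n_case = 30, n_control = 30,
                        grid = list(n_rt = 600, n_ik0 = 400,
                                    rt_range = c(0, 300),
                                    ik0_range = c(0.4, 1.0)),
                        n_shared_peaks = 20, n_diff_peaks = 5,
                        amplitude_lognormal = list(mu = log(20), sigma = 0.4),
                        effect_size = 2,
                        jitter = list(sd_ik0 = 0.001, sd_rt = 1),
                        dropout = 0.1,
                        peak_shape = list(sd_ik0 = 0.005, sd_rt = 2.5,
                                          rt_tailing = 0),
                        rip = list(column_fraction = 0.06, amplitude = 150),
                        noise_sd = 1, min_sep = 8, seed = 1) {
  stopifnot(n_case >= 1, n_control >= 1, dropout >= 0, dropout <= 1,
            effect_size > 0, jitter$sd_ik0 > 0, jitter$sd_rt > 0,
            peak_shape$sd_ik0 > 0, peak_shape$sd_rt > 0,
            peak_shape$rt_tailing >= 0, noise_sd >= 0,
            rip$column_fraction >= 0, rip$column_fraction < 1)
  structure(as.list(environment()), class = "ims_cohort_spec")
}

# exponentially modified Gaussian retention profile, normalised to apex 1
emg_profile <- function(t, mu, sigma, tau) {
  if (tau <= 0) return(exp(-0.5 * ((t - mu) / sigma)^2))
  z <- (sigma / tau - (t - mu) / sigma) / sqrt(2)
  v <- exp(sigma^2 / (2 * tau^2) - (t - mu) / tau) * 2 * stats::pnorm(-z * sqrt(2))
  v[!is.finite(v)] <- 0
  if (max(v) > 0) v / max(v) else v
}

#' Generate a synthetic two-class cohort with ground truth
#'
#' Draws true peak positions uniformly over the usable grid area (away from
#' the RIP band and the borders, with a minimum pairwise separation), then
#' renders each measurement as RIP band + present peaks (2D Gaussian,
#' optionally tailed in retention time) at jittered positions + clamped
#' Gaussian noise. Differential peaks have their intensity multiplied by
#' `effect_size` in cases. Output is bitwise-deterministic given the spec's
#' seed.
#'
#' @param spec an [cohort_spec()].
#' @return An object of class `ims_cohort`: list with `measurements` (named
#'   list of [ims_measurement()]), `labels` (tibble `measurement_id`,
#'   `label`), and `truth` (list of `features` — true positions and
#'   differential flags — and `realized` — per-measurement presence,
#'   position and amplitude of every feature).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "ims_cohort_spec"))
  withr::with_seed(spec$seed, generate_cohort_impl(spec))
}

generate_cohort_impl <- function(spec) {
  g <- spec$grid
  rt <- seq(g$rt_range[1], g$rt_range[2], length.out = g$n_rt)
  ik0 <- seq(g$ik0_range[1], g$ik0_range[2], length.out = g$n_ik0)
  cell_rt <- diff(rt[1:2]); cell_ik0 <- diff(ik0[1:2])

  # RIP band geometry (columns), centred at 12% of the ik0 axis
  rip_cols <- integer(0); rip_profile <- NULL
  if (spec$rip$column_fraction > 0 && spec$rip$amplitude > 0) {
    width <- max(3L, round(spec$rip$column_fraction * g$n_ik0))
    center <- round(0.12 * g$n_ik0)
    rip_cols <- max(1L, center - width %/% 2):min(g$n_ik0, center + width %/% 2)
    rip_profile <- spec$rip$amplitude *
      exp(-0.5 * ((rip_cols - center) / (width / 4))^2)
  }

  # true feature positions: uniform with rejection to keep min separation
  n_feat <- spec$n_shared_peaks + spec$n_diff_peaks
  margin_rt <- 5 * spec$peak_shape$sd_rt
  margin_ik0 <- 5 * spec$peak_shape$sd_ik0
  ik0_lo <- if (length(rip_cols)) ik0[max(rip_cols)] + 4 * margin_ik0
            else min(ik0) + margin_ik0
  sc <- peak_scaling()
  pos <- matrix(NA_real_, 0, 2)
  tries <- 0L
  while (nrow(pos) < n_feat && tries < 5000L) {
    tries <- tries + 1L
    cand <- c(stats::runif(1, ik0_lo, max(ik0) - margin_ik0),
              stats::runif(1, min(rt) + margin_rt, max(rt) - margin_rt))
    if (nrow(pos)) {
      d <- peak_dist_matrix(
        tibble::tibble(ik0 = c(pos[, 1], cand[1]), rt = c(pos[, 2], cand[2])),
        sc)[nrow(pos) + 1L, seq_len(nrow(pos))]
      if (min(d) < spec$min_sep) next
    }
    pos <- rbind(pos, cand)
  }
  if (nrow(pos) < n_feat) {
    warning("could not place all true peaks at the requested separation; cohort is denser than specified")
    while (nrow(pos) < n_feat) {
      pos <- rbind(pos, c(stats::runif(1, ik0_lo, max(ik0) - margin_ik0),
                          stats::runif(1, min(rt) + margin_rt, max(rt) - margin_rt)))
    }
  }
  if (n_feat >= 2) {
    dcell <- pmax(abs(outer(pos[, 1], pos[, 1], `-`)) / cell_ik0,
                  abs(outer(pos[, 2], pos[, 2], `-`)) / cell_rt)
    if (min(dcell[upper.tri(dcell)]) < 3) {
      warning("true peaks closer than 3 grid cells; pickers cannot resolve them")
    }
  }
  features <- tibble::tibble(
    feature_id = sprintf("T%03d", seq_len(n_feat)),
    ik0 = pos[, 1], rt = pos[, 2],
    differential = seq_len(n_feat) %in% sample.int(n_feat, spec$n_diff_peaks))

  n <- spec$n_case + spec$n_control
  labels <- tibble::tibble(
    measurement_id = sprintf("M%03d", seq_len(n)),
    label = rep(c("case", "control"), c(spec$n_case, spec$n_control)))

  measurements <- vector("list", n)
  realized <- vector("list", n)
  for (i in seq_len(n)) {
    mat <- if (spec$noise_sd > 0) {
      pmax(matrix(stats::rnorm(g$n_rt * g$n_ik0, 0, spec$noise_sd),
                  g$n_rt, g$n_ik0), 0)
    } else matrix(0, g$n_rt, g$n_ik0)
    if (length(rip_cols)) {
      mat[, rip_cols] <- mat[, rip_cols] +
        matrix(rip_profile, g$n_rt, length(rip_cols), byrow = TRUE)
    }
    present <- stats::runif(n_feat) >= spec$dropout
    jit_ik0 <- features$ik0 + stats::rnorm(n_feat, 0, spec$jitter$sd_ik0)
    jit_rt <- features$rt + stats::rnorm(n_feat, 0, spec$jitter$sd_rt)
    log_amp <- spec$amplitude_lognormal$mu +
      log(spec$effect_size) * (features$differential & labels$label[i] == "case")
    amp <- exp(stats::rnorm(n_feat, log_amp, spec$amplitude_lognormal$sigma))
    for (f in which(present)) {
      sd_r <- spec$peak_shape$sd_rt; sd_d <- spec$peak_shape$sd_ik0
      tau <- spec$peak_shape$rt_tailing
      rows <- which(rt >= jit_rt[f] - 4.5 * sd_r &
                      rt <= jit_rt[f] + 4.5 * sd_r + 8 * tau)
      cols <- which(ik0 >= jit_ik0[f] - 4.5 * sd_d &
                      ik0 <= jit_ik0[f] + 4.5 * sd_d)
      if (!length(rows) || !length(cols)) next
      prof_rt <- emg_profile(rt[rows], jit_rt[f], sd_r, tau)
      prof_ik0 <- exp(-0.5 * ((ik0[cols] - jit_ik0[f]) / sd_d)^2)
      mat[rows, cols] <- mat[rows, cols] + amp[f] * (prof_rt %o% prof_ik0)
    }
    measurements[[i]] <- ims_measurement(mat, rt, ik0,
                                         sample_id = labels$measurement_id[i],
                                         label = labels$label[i])
    realized[[i]] <- tibble::tibble(
      measurement_id = labels$measurement_id[i],
      feature_id = features$feature_id, present = present,
      ik0 = jit_ik0, rt = jit_rt, amplitude = amp)
  }
  names(measurements) <- labels$measurement_id
  structure(list(measurements = measurements, labels = labels,
                 truth = list(features = features,
                              realized = dplyr::bind_rows(realized)),
                 spec = spec),
            class = "ims_cohort")
}

#' @export
print.ims_cohort <- function(x, ...) {
  cat(sprintf("<ims_cohort> %d case + %d control measurements, %d true peaks (%d differential)\n",
              sum(x$labels$label == "case"), sum(x$labels$label == "control"),
              nrow(x$truth$features), sum(x$truth$features$differential)))
  m <- x$measurements[[1]]
  cat(sprintf("  grid %d rt x %d ik0\n", length(m$rt), length(m$ik0)))
  invisible(x)
}

#' Match detections against ground truth
#'
#' Greedy one-to-one matching of detected positions to true positions by
#' ascending normalised distance, accepting pairs within `radius`. Recall =
#' matched / truth, precision = matched / detected; an empty detection set
#' reports precision 1 with `zero_support = TRUE`. The position RMSE is
#' over matched pairs, in normalised distance units.
#'
#' @param detected an `ims_clusters` object (its consensus peaks are
#'   matched), or any tibble with `rt`, `ik0` columns.
#' @param truth the `features` tibble of a cohort's ground truth, an
#'   `ims_cohort`, or any tibble with `rt`, `ik0` columns.
#' @param radius maximum normalised match distance (> 0).
#' @param scaling an [peak_scaling()].
#' @return One-row tibble: `recall`, `precision`, `rmse`, `n_matched`,
#'   `n_truth`, `n_detected`, `zero_support`.
#' @export
truth_match <- function(detected, truth, radius = 1, scaling = peak_scaling()) {
  stopifnot(radius > 0)
  det <- if (inherits(detected, "ims_clusters")) detected$consensus
         else tibble::as_tibble(detected)
  tru <- if (inherits(truth, "ims_cohort")) truth$truth$features
         else tibble::as_tibble(truth)
  n_d <- nrow(det); n_t <- nrow(tru)
  if (n_d == 0) {
    return(tibble::tibble(recall = 0, precision = 1, rmse = NA_real_,
                          n_matched = 0L, n_truth = n_t, n_detected = 0L,
                          zero_support = TRUE))
  }
  both <- dplyr::bind_rows(det[c("rt", "ik0")], tru[c("rt", "ik0")])
  D <- peak_dist_matrix(both, scaling)[seq_len(n_d), n_d + seq_len(n_t),
                                       drop = FALSE]
  ord <- order(D)
  used_d <- logical(n_d); used_t <- logical(n_t)
  matched <- numeric(0)
  for (o in ord) {
    if (D[o] > radius) break
    i <- ((o - 1) %% n_d) + 1; j <- ((o - 1) %/% n_d) + 1
    if (used_d[i] || used_t[j]) next
    used_d[i] <- TRUE; used_t[j] <- TRUE
    matched <- c(matched, D[o])
  }
  k <- length(matched)
  tibble::tibble(recall = k / n_t, precision = k / n_d,
                 rmse = if (k) sqrt(mean(matched^2)) else NA_real_,
                 n_matched = k, n_truth = n_t, n_detected = n_d,
                 zero_support = FALSE)
}

#' Write a cohort to a directory of delimited text files
#'
#' One measurement grid file per sample plus `labels.csv` and `truth.csv`.
#'
#' @param cohort an `ims_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "ims_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (m in cohort$measurements) {
    write_measurement(m, file.path(dir, paste0(m$sample_id, ".csv")))
  }
  readr::write_csv(cohort$labels, file.path(dir, "labels.csv"), progress = FALSE)
  readr::write_csv(cohort$truth$features, file.path(dir, "truth.csv"),
                   progress = FALSE)
  invisible(dir)
}
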