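#' Tolerance scaling for peak distances
#'
#' Peaks from different measurements are compared in a normalised coordinate
#' system: the 1/K0 separation is divided by `tol_ik0` and the retention-time
#' separation by `tol_rt_abs + tol_rt_rel * mean(rt)` (retention-time spread
#' grows along the column, hence the relative term). The normalised distance
#' between two peaks u, v is
#' `sqrt((d_ik0/tol_ik0)^2 + (d_rt/(tol_rt_abs + tol_rt_rel*(rt_u+rt_v)/2))^2)`;
#' a distance of 1 means "one tolerance ellipse apart".
#'
#' @param tol_ik0 1/K0 tolerance in Vs/cm2 (> 0).
#' @param tol_rt_abs absolute retention-time tolerance in seconds (> 0).
#' @param tol_rt_rel relative retention-time tolerance (fraction, >= 0).
#' @return An object of class `ims_scaling`.
#' @export
peak_scaling <- function(tol_ik0 = 0.003, tol_rt_abs = 3, tol_rt_rel = 0.01) {
  stopifnot(tol_ik0 > 0, tol_rt_abs > 0, tol_rt_rel >= 0)
  structure(list(tol_ik0 = tol_ik0, tol_rt_abs = tol_rt_abs,
                 tol_rt_rel = tol_rt_rel),
            class = "ims_scaling")
}

#' Normalised pairwise distance matrix between peaks
#'
#' @param peaks tibble with columns `ik0`, `rt`.
#' @param scaling an [peak_scaling()] object.
#' @return Symmetric numeric matrix of normalised distances.
#' @export
peak_dist_matrix <- function(peaks, scaling = peak_scaling()) {
  stopifnot(inherits(scaling, "ims_scaling"))
  d_ik0 <- outer(peaks$ik0, peaks$ik0, `-`) / scaling$tol_ik0
  mean_rt <- outer(peaks$rt, peaks$rt, `+`) / 2
  d_rt <- outer(peaks$rt, peaks$rt, `-`) /
    (scaling$tol_rt_abs + scaling$tol_rt_rel * mean_rt)
  sqrt(d_ik0^2 + d_rt^2)
}
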