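#' Build the classification feature matrix
#'
#' Turns consensus peaks plus per-measurement peak lists into the
#' measurements x features intensity table used for classification. The
#' intensity of consensus peak j for measurement i is taken from the peak of
#' measurement i closest (normalised distance, see [peak_scaling()]) to the
#' consensus position, provided that distance is at most `assign_radius`;
#' when no peak lies within the radius the entry is 0 (no detectable analyte
#' signal). A peak may serve several consensus peaks only by being the
#' closest to each.
#'
#' @param clusters an `ims_clusters` object, or a consensus tibble with
#'   columns `feature_id`, `rt`, `ik0`.
#' @param peaks combined peak-list tibble over all measurements (a
#'   measurement with no detected peaks simply has no rows and gets an
#'   all-zero row).
#' @param labels tibble with columns `measurement_id`, `label`; defines the
#'   row set and order of the output.
#' @param assign_radius maximum normalised distance for intensity
#'   assignment (default 1: the tolerance ellipse).
#' @param scaling an [peak_scaling()].
#' @return A feature-matrix tibble: `measurement_id`, `label`, then one
#'   column per consensus peak.
#' @export
build_feature_matrix <- function(clusters, peaks, labels, assign_radius = 1,
                                 scaling = peak_scaling()) {
  consensus <- if (inherits(clusters, "ims_clusters")) clusters$consensus
               else tibble::as_tibble(clusters)
  stopifnot(all(c("feature_id", "rt", "ik0") %in% names(consensus)),
            assign_radius > 0)
  if (!nrow(consensus)) stop("no consensus peaks to build features from", call. = FALSE)
  if (anyDuplicated(consensus$feature_id)) {
    stop("duplicate feature ids in consensus set", call. = FALSE)
  }
  labels <- tibble::as_tibble(labels)
  stopifnot(all(c("measurement_id", "label") %in% names(labels)))
  if (anyDuplicated(labels$measurement_id)) {
    stop("duplicate measurement ids in labels", call. = FALSE)
  }
  peaks <- validate_peaklist(peaks)

  p <- nrow(consensus)
  vals <- matrix(0, nrow(labels), p,
                 dimnames = list(NULL, consensus$feature_id))
  split_peaks <- split(peaks, peaks$measurement_id)
  for (i in seq_len(nrow(labels))) {
    pk <- split_peaks[[labels$measurement_id[i]]]
    if (is.null(pk) || !nrow(pk)) next
    both <- dplyr::bind_rows(pk[c("rt", "ik0")], consensus[c("rt", "ik0")])
    D <- peak_dist_matrix(both, scaling)[seq_len(nrow(pk)),
                                         nrow(pk) + seq_len(p), drop = FALSE]
    nearest <- apply(D, 2, which.min)
    dist_min <- D[cbind(nearest, seq_len(p))]
    hit <- dist_min <= assign_radius
    vals[i, hit] <- pk$intensity[nearest[hit]]
  }
  dplyr::bind_cols(labels[c("measurement_id", "label")],
                   tibble::as_tibble(vals))
}
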