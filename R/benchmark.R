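picker_fun_name <- function(picker) {
  key <- tolower(picker)
  if (!key %in% c("lm", "sgltr", "pdsa")) {
    stop(sprintf("peak picker '%s' is declared in the registry but not implemented here",
                 picker), call. = FALSE)
  }
  key
}

clusterer_fun_name <- function(clusterer) {
  key <- tolower(clusterer)
  if (!key %in% c("gs", "dbscan", "ce", "em")) {
    stop(sprintf("peak clusterer '%s' is declared in the registry but not implemented here",
                 clusterer), call. = FALSE)
  }
  key
}

#' Run one full pipeline on a cohort
#'
#' Chains preprocessing + peak picking over all measurements, peak
#' clustering, feature-matrix construction, and repeated nested
#' cross-validated classification.
#'
#' @param cohort an `ims_cohort`, or a list with elements `measurements`
#'   (named list of [ims_measurement()]) and `labels` (tibble).
#' @param picker `"LM"`, `"SGLTR"` or `"PDSA"` (case-insensitive).
#' @param clusterer `"GS"`, `"DBSCAN"`, `"CE"` or `"EM"`.
#' @param classifier classifier name, see [classifier_spec()].
#' @param plan an [cv_plan()].
#' @param picker_args,cluster_args extra arguments for the picking and
#'   clustering stages.
#' @param assign_radius,scaling feature-assignment parameters, see
#'   [build_feature_matrix()].
#' @return A list of class `ims_pipeline_result`: `cv` (an `ims_cv`),
#'   `clusters`, `peaks`, `features`, and the pipeline description.
#' @export
run_pipeline <- function(cohort, picker = "SGLTR", clusterer = "DBSCAN",
                         classifier = "rf", plan = cv_plan(),
                         picker_args = list(), cluster_args = list(),
                         assign_radius = 1, scaling = peak_scaling()) {
  peaks <- do.call(pick_peaks, c(list(cohort$measurements,
                                      method = picker_fun_name(picker)),
                                 picker_args))
  clusters <- do.call(cluster_peaks, c(list(peaks,
                                            method = clusterer_fun_name(clusterer)),
                                       cluster_args))
  fm <- build_feature_matrix(clusters, peaks, cohort$labels,
                             assign_radius = assign_radius, scaling = scaling)
  cv <- run_cv(fm, classifier_spec(classifier), plan)
  structure(list(pipeline = paste(toupper(picker), toupper(clusterer),
                                  classifier, sep = "+"),
                 cv = cv, clusters = clusters, peaks = peaks, features = fm),
            class = "ims_pipeline_result")
}

#' @export
print.ims_pipeline_result <- function(x, ...) {
  cat(sprintf("<ims_pipeline_result> %s\n", x$pipeline))
  cat(sprintf("  %d peaks -> %d consensus features; median AUC %.3f\n",
              nrow(x$peaks), nrow(x$clusters$consensus), x$cv$median_auc))
  invisible(x)
}

#' Benchmark pipelines across datasets with rank-sum comparison
#'
#' Runs every requested pipeline on every dataset and assembles the
#' rank-sum report ([rank_sum_table()]): per dataset, pipelines are ranked
#' by median AUC and the ranks summed.
#'
#' @param datasets named list of cohorts (see [run_pipeline()]).
#' @param pipelines tibble with columns `picker`, `clusterer`,
#'   `classifier`; default: all implemented pipelines of [ims_registry()].
#' @param plan an [cv_plan()].
#' @param ... passed on to [run_pipeline()].
#' @return A list of class `ims_benchmark`: `medians` (long tibble),
#'   `table` (the rank-sum report).
#' @export
run_benchmark <- function(datasets, pipelines = NULL, plan = cv_plan(), ...) {
  if (is.null(pipelines)) pipelines <- list_pipelines()
  stopifnot(length(names(datasets)) == length(datasets))
  rows <- list()
  for (ds in names(datasets)) {
    for (i in seq_len(nrow(pipelines))) {
      res <- run_pipeline(datasets[[ds]], pipelines$picker[i],
                          pipelines$clusterer[i], pipelines$classifier[i],
                          plan = plan, ...)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        pipeline = res$pipeline, dataset = ds,
        median_auc = res$cv$median_auc)
    }
  }
  medians <- dplyr::bind_rows(rows)
  structure(list(medians = medians, table = rank_sum_table(medians)),
            class = "ims_benchmark")
}

#' @export
print.ims_benchmark <- function(x, ...) {
  cat("<ims_benchmark>\n")
  print(x$table)
  invisible(x)
}
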