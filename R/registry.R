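#' The benchmarked method registry
#'
#' Declares the design space of the benchmark: six peak pickers (LM, PME,
#' PDSA, SGLTR, OPME, and VisualNow's automated picker VNa), five clustering
#' methods combinable with pickers (GS, DBSCAN, CE, EM, VNa), the combined
#' manual VisualNow procedure VNm (picking and clustering in one
#' inseparable step), and six classifiers. Feasibility rules: VNa
#' clustering only accepts VNa-picked peaks, and VNm cannot be mixed with
#' any automated step. Methods backed by unavailable software or models
#' published elsewhere (PME, OPME, both VisualNow entries) are declared but
#' not implemented, so the enumeration still spans the full design space.
#'
#' @return A list with tibbles `pickers`, `clusterers`, `combined`,
#'   `classifiers` and the feasibility predicate `feasible(picker,
#'   clusterer)`.
#' @export
ims_registry <- function() {
  list(
    pickers = tibble::tibble(
      name = c("LM", "PME", "PDSA", "SGLTR", "OPME", "VNa"),
      automated = TRUE,
      implemented = c(TRUE, FALSE, TRUE, TRUE, FALSE, FALSE)),
    clusterers = tibble::tibble(
      name = c("GS", "DBSCAN", "CE", "EM", "VNa"),
      automated = TRUE,
      implemented = c(TRUE, TRUE, TRUE, TRUE, FALSE)),
    combined = tibble::tibble(
      name = "VNm", automated = FALSE, implemented = FALSE),
    classifiers = tibble::tibble(
      name = c("svm_lin", "svm_rbf", "knn", "ct", "gbm", "rf"),
      implemented = TRUE),
    feasible = function(picker, clusterer) clusterer != "VNa" | picker == "VNa"
  )
}

known_methods <- c("LM", "PME", "PDSA", "SGLTR", "OPME", "VNa", "VNm",
                   "GS", "DBSCAN", "CE", "EM",
                   "svm_lin", "svm_rbf", "knn", "ct", "gbm", "rf")

#' Enumerate the pipeline design space
#'
#' Counts the feasible (picker, clusterer) combinations and full
#' (picker, clusterer, classifier) pipelines implied by a method registry
#' and its feasibility rules, overall and restricted to fully automated
#' methods.
#'
#' @param registry a registry as returned by [ims_registry()].
#' @return One-row tibble with `picker_clusterer_combos`,
#'   `automated_combos`, `pipelines`, `automated_pipelines`.
#' @export
enumerate_design <- function(registry = ims_registry()) {
  nm <- c(registry$pickers$name, registry$clusterers$name,
          registry$combined$name, registry$classifiers$name)
  bad <- setdiff(nm, known_methods)
  if (length(bad)) {
    stop(sprintf("unknown method name: %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  combos <- tidyr::expand_grid(picker = registry$pickers$name,
                               clusterer = registry$clusterers$name) |>
    dplyr::filter(registry$feasible(.data$picker, .data$clusterer))
  combos$automated <-
    registry$pickers$automated[match(combos$picker, registry$pickers$name)] &
    registry$clusterers$automated[match(combos$clusterer, registry$clusterers$name)]
  if (nrow(registry$combined)) {
    combos <- dplyr::bind_rows(combos, tibble::tibble(
      picker = registry$combined$name, clusterer = registry$combined$name,
      automated = registry$combined$automated))
  }
  n_clf <- nrow(registry$classifiers)
  tibble::tibble(
    picker_clusterer_combos = nrow(combos),
    automated_combos = sum(combos$automated),
    pipelines = nrow(combos) * n_clf,
    automated_pipelines = sum(combos$automated) * n_clf)
}

#' List concrete pipelines from a registry
#'
#' @param registry a registry as returned by [ims_registry()].
#' @param implemented_only drop pipelines containing a declared-but-
#'   unimplemented method.
#' @return Tibble with columns `picker`, `clusterer`, `classifier`,
#'   `pipeline` (a readable id).
#' @export
list_pipelines <- function(registry = ims_registry(), implemented_only = TRUE) {
  combos <- tidyr::expand_grid(picker = registry$pickers$name,
                               clusterer = registry$clusterers$name) |>
    dplyr::filter(registry$feasible(.data$picker, .data$clusterer))
  if (nrow(registry$combined)) {
    combos <- dplyr::bind_rows(combos, tibble::tibble(
      picker = registry$combined$name, clusterer = registry$combined$name))
  }
  out <- tidyr::expand_grid(combos, classifier = registry$classifiers$name)
  if (implemented_only) {
    impl <- c(registry$pickers$name[registry$pickers$implemented],
              registry$combined$name[registry$combined$implemented])
    impl_cl <- c(registry$clusterers$name[registry$clusterers$implemented],
                 registry$combined$name[registry$combined$implemented])
    out <- dplyr::filter(out, .data$picker %in% impl,
                         .data$clusterer %in% impl_cl,
                         .data$classifier %in%
                           registry$classifiers$name[registry$classifiers$implemented])
  }
  out$pipeline <- paste(out$picker, out$clusterer, out$classifier, sep = "+")
  out
}
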