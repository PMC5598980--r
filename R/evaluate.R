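#' Stratified k-fold assignment
#'
#' Splits sample indices into `k` folds whose sizes differ by at most one
#' and whose per-class counts differ from exact proportionality by at most
#' one, so every fold mirrors the cohort's case/control balance. Within
#' each class, samples are shuffled and dealt into near-equal chunks; the
#' leftover samples of each class go to the currently smallest folds, which
#' keeps the overall fold sizes balanced.
#'
#' @param labels class labels (factor or character), length n.
#' @param k number of folds; every class must have at least `k` members.
#' @param seed optional integer; when given, fold assignment is a
#'   deterministic function of it (the surrounding RNG state is untouched).
#' @return Integer vector of length n with fold ids in `1..k`.
#' @export
stratified_folds <- function(labels, k = 10, seed = NULL) {
  labels <- as.factor(labels)
  n <- length(labels)
  counts_cl <- table(labels)
  if (any(counts_cl < k)) {
    stop(sprintf("class '%s' has %d members, fewer than k = %d folds",
                 names(counts_cl)[which.min(counts_cl)], min(counts_cl), k),
         call. = FALSE)
  }
  run <- function() {
    fold <- integer(n)
    totals <- integer(k)
    for (cl in levels(labels)) {
      idx <- sample(which(labels == cl))
      m <- length(idx)
      base <- m %/% k; rem <- m %% k
      sizes <- rep(base, k)
      if (rem > 0) {
        extra <- order(totals, seq_len(k))[seq_len(rem)]
        sizes[extra] <- base + 1L
      }
      fold[idx] <- rep(seq_len(k), times = sizes)
      totals <- totals + sizes
    }
    fold
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Area under the ROC curve (Mann-Whitney form)
#'
#' The probability that a randomly chosen case scores above a randomly
#' chosen control, with ties counting one half:
#' `(#concordant + 0.5 * #tied) / (n_case * n_control)`. Computed via
#' midranks, and therefore invariant under any strictly monotone transform
#' of the scores.
#'
#' @param scores numeric case-class scores.
#' @param labels class labels; `"case"`/`1`/`TRUE` is the positive class.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores, labels) {
  pos <- as_case(labels)
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("AUC needs both classes present", call. = FALSE)
  stopifnot(length(scores) == length(labels), all(is.finite(scores)))
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

as_case <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.numeric(labels)) return(labels == 1)
  as.character(labels) == "case"
}

#' Cross-validation plan
#'
#' @param k_folds folds per CV run (default 10).
#' @param repetitions independent repetitions of the whole CV (default 50;
#'   medians across repetitions are the reported statistic).
#' @param seed base seed; repetition r uses `seed + r`.
#' @return An object of class `ims_cv_plan`.
#' @export
cv_plan <- function(k_folds = 10, repetitions = 50, seed = 1) {
  stopifnot(k_folds >= 2, repetitions >= 1)
  structure(list(k_folds = as.integer(k_folds),
                 repetitions = as.integer(repetitions),
                 seed = as.integer(seed), stratified = TRUE),
            class = "ims_cv_plan")
}

#' Repeated stratified (nested) cross-validated AUC
#'
#' Runs `repetitions` independent stratified `k_folds`-fold CVs. In each
#' repetition, every outer fold is held out once; when the classifier has a
#' tuning grid, an inner stratified 10-fold CV on the outer training set
#' picks the grid point with the best mean inner AUC, and the model is
#' refitted with it on the full outer training set. Held-out case-class
#' scores are pooled over the k outer folds and give one AUC per
#' repetition.
#'
#' @param fm feature-matrix tibble (see [build_feature_matrix()]).
#' @param clf an [classifier_spec()].
#' @param plan an [cv_plan()].
#' @param row_hook optional function called as `row_hook(rep, fold, purpose,
#'   rows)` with the sample rows used for `"train"`/`"tune"`/`"test"` in
#'   each outer fold; used to audit that tuning never touches test rows.
#' @return An object of class `ims_cv` with fields `auc_per_rep`,
#'   `median_auc`, `classifier`, `plan`, `chosen_params`.
#' @export
run_cv <- function(fm, clf = classifier_spec("rf"), plan = cv_plan(),
                   row_hook = NULL) {
  fm <- validate_feature_matrix(fm)
  X <- feature_values(fm)
  if (!ncol(X)) stop("feature matrix has no feature columns", call. = FALSE)
  y <- factor(fm$label, levels = c("control", "case"))
  if (anyNA(y)) stop("labels must be 'case' or 'control'", call. = FALSE)
  if (nlevels(droplevels(y)) < 2) stop("both classes must be present", call. = FALSE)
  grid <- grid_rows(clf$tuning_grid)

  aucs <- numeric(plan$repetitions)
  chosen <- list()
  for (r in seq_len(plan$repetitions)) {
    withr::with_seed(plan$seed + r, {
      fold <- stratified_folds(y, plan$k_folds)
      scores <- numeric(length(y))
      for (f in seq_len(plan$k_folds)) {
        te <- which(fold == f); tr <- which(fold != f)
        if (length(unique(y[tr])) < 2) {
          stop(sprintf("outer training set of fold %d (repetition %d) has a single class",
                       f, r), call. = FALSE)
        }
        params <- grid[[1]]
        if (length(grid) > 1) {
          if (!is.null(row_hook)) row_hook(r, f, "tune", tr)
          params <- tune_inner(X[tr, , drop = FALSE], y[tr], clf$name, grid)
        }
        if (!is.null(row_hook)) {
          row_hook(r, f, "train", tr); row_hook(r, f, "test", te)
        }
        scores[te] <- fit_score(clf$name, params, X[tr, , drop = FALSE], y[tr],
                                X[te, , drop = FALSE])
        if (length(params)) {
          chosen[[length(chosen) + 1L]] <-
            tibble::tibble(rep = r, fold = f, !!!params)
        }
      }
      aucs[r] <- auc(scores, y)
    })
  }
  structure(list(auc_per_rep = aucs, median_auc = stats::median(aucs),
                 classifier = clf$name, plan = plan,
                 chosen_params = dplyr::bind_rows(chosen)),
            class = "ims_cv")
}

# inner 10-fold tuning: best mean AUC over inner test folds
tune_inner <- function(X, y, name, grid, k_inner = 10) {
  k_inner <- min(k_inner, min(table(y)))
  fold <- stratified_folds(y, k_inner)
  mean_auc <- vapply(grid, function(params) {
    fold_auc <- vapply(seq_len(k_inner), function(f) {
      te <- which(fold == f); tr <- which(fold != f)
      if (length(unique(y[te])) < 2 || length(unique(y[tr])) < 2) return(NA_real_)
      s <- fit_score(name, params, X[tr, , drop = FALSE], y[tr],
                     X[te, , drop = FALSE])
      auc(s, y[te])
    }, numeric(1))
    mean(fold_auc, na.rm = TRUE)
  }, numeric(1))
  grid[[which.max(mean_auc)]]
}

#' @export
print.ims_cv <- function(x, ...) {
  cat(sprintf("<ims_cv> %s: median AUC %.3f over %d x %d-fold CV\n",
              x$classifier, x$median_auc, x$plan$repetitions, x$plan$k_folds))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.ims_cv <- function(x, ...) {
  tibble::tibble(rep = seq_along(x$auc_per_rep), auc = x$auc_per_rep)
}

#' @exportS3Method generics::glance
glance.ims_cv <- function(x, ...) {
  tibble::tibble(classifier = x$classifier, k_folds = x$plan$k_folds,
                 repetitions = x$plan$repetitions,
                 median_auc = x$median_auc,
                 iqr_auc = stats::IQR(x$auc_per_rep))
}

#' @exportS3Method ggplot2::autoplot
autoplot.ims_cv <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = "", y = .data$auc)) +
    ggplot2::geom_boxplot(width = 0.3) +
    ggplot2::geom_jitter(width = 0.08, alpha = 0.4) +
    ggplot2::labs(x = object$classifier, y = "AUC per CV repetition",
                  title = sprintf("median AUC %.3f", object$median_auc))
}

#' Rank-sum comparison of pipelines across datasets
#'
#' For each dataset, pipelines are ranked by median AUC (rank 1 = best;
#' competition ranking, tied values share the minimum rank). Each
#' pipeline's ranks are summed across datasets; the report is sorted by
#' rank sum ascending and also carries the arithmetic mean of the
#' per-dataset median AUCs.
#'
#' @param medians long tibble with columns `pipeline`, `dataset`,
#'   `median_auc`; every pipeline must have a value for every dataset.
#' @return Tibble: `pipeline`, `mean_auc`, one `rank_<dataset>` column per
#'   dataset, `rank_sum`, sorted by `rank_sum`.
#' @export
rank_sum_table <- function(medians) {
  medians <- tibble::as_tibble(medians)
  stopifnot(all(c("pipeline", "dataset", "median_auc") %in% names(medians)))
  full <- tidyr::expand_grid(pipeline = unique(medians$pipeline),
                             dataset = unique(medians$dataset))
  miss <- dplyr::anti_join(full, medians, by = c("pipeline", "dataset"))
  if (nrow(miss)) {
    stop(sprintf("missing median AUC for pipeline '%s' on dataset '%s'",
                 miss$pipeline[1], miss$dataset[1]), call. = FALSE)
  }
  if (nrow(medians) > nrow(full)) {
    stop("duplicate pipeline/dataset entries", call. = FALSE)
  }
  ranked <- medians |>
    dplyr::group_by(.data$dataset) |>
    dplyr::mutate(rank = dplyr::min_rank(dplyr::desc(.data$median_auc))) |>
    dplyr::ungroup()
  wide <- ranked |>
    dplyr::select("pipeline", "dataset", "rank") |>
    tidyr::pivot_wider(names_from = "dataset", values_from = "rank",
                       names_prefix = "rank_")
  summary <- ranked |>
    dplyr::group_by(.data$pipeline) |>
    dplyr::summarise(mean_auc = mean(.data$median_auc),
                     rank_sum = sum(.data$rank), .groups = "drop")
  dplyr::left_join(summary, wide, by = "pipeline") |>
    dplyr::relocate("rank_sum", .after = dplyr::last_col()) |>
    dplyr::arrange(.data$rank_sum, dplyr::desc(.data$mean_auc))
}

#' Mean rank sum of a clustering method across classifiers
#'
#' For one picker/clusterer combination, its ranks among the competing
#' clustering methods under each of the classification algorithms are
#' summed and divided by the minimum achievable rank sum (the number of
#' classifiers, i.e. all ranks equal 1). A value of 1 means the combination
#' wins under every classifier; the maximum is the number of competing
#' clustering methods.
#'
#' @param ranks integer ranks, one per classifier (>= 1).
#' @param n_classifiers number of classifiers (default `length(ranks)`).
#' @return The normalised mean rank sum.
#' @export
mean_rank_sum <- function(ranks, n_classifiers = length(ranks)) {
  stopifnot(length(ranks) == n_classifiers, all(ranks >= 1))
  sum(ranks) / n_classifiers
}
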