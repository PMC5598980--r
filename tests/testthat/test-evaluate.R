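# a quickly separable feature matrix: one feature equals the label + noise
separable_fm <- function(n_case = 10, n_control = 10, noise = 0.01, seed = 1,
                         p_extra = 3) {
  withr::with_seed(seed, {
    lab <- rep(c("case", "control"), c(n_case, n_control))
    n <- length(lab)
    tibble::tibble(measurement_id = sprintf("M%03d", seq_len(n)), label = lab,
                   signal = (lab == "case") * 10 + abs(rnorm(n, 0, noise))) |>
      dplyr::bind_cols(tibble::as_tibble(
        matrix(abs(rnorm(n * p_extra)), n,
               dimnames = list(NULL, sprintf("junk%d", seq_len(p_extra))))))
  })
}

test_that("stratified folds respect cohort proportions at clinical sizes", {
  labels <- rep(c("case", "control"), c(92, 35))
  fold <- stratified_folds(labels, k = 10, seed = 7)
  sizes <- table(fold)
  expect_true(all(sizes %in% 12:13))
  per_class <- table(labels, fold)
  expect_true(all(per_class["case", ] %in% 9:10))
  expect_true(all(per_class["control", ] %in% 3:4))
})

test_that("stratified folds are exact on a balanced 20-sample cohort", {
  labels <- rep(c("case", "control"), 10)
  fold <- stratified_folds(labels, k = 10, seed = 3)
  tab <- table(labels, fold)
  expect_true(all(tab == 1))
})

test_that("fold assignment is a deterministic function of the seed", {
  labels <- rep(c("case", "control"), c(30, 25))
  expect_identical(stratified_folds(labels, 10, seed = 5),
                   stratified_folds(labels, 10, seed = 5))
  differs <- vapply(1:20, function(s) {
    !identical(stratified_folds(labels, 10, seed = s),
               stratified_folds(labels, 10, seed = s + 1000))
  }, logical(1))
  expect_gte(mean(differs), 0.95)
  expect_error(stratified_folds(rep(c("case", "control"), c(50, 5)), k = 10),
               "fewer than k")
})

test_that("AUC matches the Mann-Whitney definition, ties and all", {
  expect_equal(auc(c(5, 6, 1, 2), c("case", "case", "control", "control")), 1)
  expect_equal(auc(rep(3, 6), rep(c("case", "control"), 3)), 0.5)
  # 2 concordant of 4 pairs
  expect_equal(auc(c(0.9, 0.7, 0.4, 0.3), c(1, 0, 0, 1)), 0.5)
  expect_error(auc(1:3, c("case", "case", "case")), "both classes")

  # cross-check against an independent implementation on random data
  for (s in 1:10) {
    withr::with_seed(s, {
      sc <- round(rnorm(40), 1)             # rounded to force ties
      lb <- sample(c("case", "control"), 40, replace = TRUE,
                   prob = c(0.6, 0.4))
    })
    if (length(unique(lb)) < 2) next
    ref <- suppressMessages(as.numeric(pROC::auc(
      pROC::roc(lb, sc, levels = c("control", "case"), direction = "<"))))
    expect_equal(auc(sc, lb), ref, tolerance = 1e-12)
  }
})

test_that("AUC is invariant under strictly monotone score transforms", {
  withr::with_seed(2, {
    sc <- rnorm(60); lb <- rep(c("case", "control"), 30)
  })
  base <- auc(sc, lb)
  expect_equal(auc(exp(sc), lb), base)
  expect_equal(auc(5 * sc - 3, lb), base)
  expect_equal(auc(atan(sc), lb), base)
})

test_that("run_cv returns one pooled AUC per repetition and perfect AUC when separable", {
  fm <- separable_fm()
  cv <- run_cv(fm, classifier_spec("rf"), cv_plan(repetitions = 4, seed = 11))
  expect_length(cv$auc_per_rep, 4)
  expect_equal(cv$median_auc, 1.0)
  expect_equal(glance(cv)$median_auc, 1.0)
  expect_equal(nrow(tidy(cv)), 4)
})

test_that("nested tuning selects parameters without touching outer test rows", {
  fm <- separable_fm(n_case = 15, n_control = 15, seed = 4)
  log <- list()
  hook <- function(rep, fold, purpose, rows) {
    log[[length(log) + 1L]] <<- list(rep = rep, fold = fold,
                                     purpose = purpose, rows = rows)
  }
  cv <- run_cv(fm, classifier_spec("ct"), cv_plan(repetitions = 2, seed = 9),
               row_hook = hook)
  df <- dplyr::bind_rows(lapply(log, function(e)
    tibble::tibble(rep = e$rep, fold = e$fold, purpose = e$purpose,
                   rows = list(e$rows))))
  for (key in unique(paste(df$rep, df$fold))) {
    sub <- df[paste(df$rep, df$fold) == key, ]
    test_rows <- unlist(sub$rows[sub$purpose == "test"])
    other <- unlist(sub$rows[sub$purpose != "test"])
    expect_length(intersect(test_rows, other), 0)
  }
  expect_true(all(c("rep", "fold", "cp") %in% names(cv$chosen_params)))
  expect_true(all(cv$chosen_params$cp %in% c(0.001, 0.01, 0.1)))
})

test_that("run_cv rejects degenerate inputs", {
  fm <- separable_fm(n_case = 12, n_control = 12)
  fm$label <- "case"
  expect_error(run_cv(fm, classifier_spec("rf")), "both classes")
})

test_that("rank sums reproduce the published top-pipeline arithmetic", {
  # construct 20 pipelines whose per-dataset orderings put the pipeline of
  # interest at ranks 12, 3 and 1; its rank sum must come out as 16
  withr::with_seed(6, {
    pipes <- c("SGLTR+DBSCAN+RF", sprintf("P%02d", 1:19))
    mk <- function(rank_target) {
      auc <- rep(NA_real_, 20)
      auc[1] <- 1 - rank_target / 100
      others <- setdiff(seq_len(20), 1)
      above <- sample(others, rank_target - 1)
      auc[above] <- 1 - (seq_len(rank_target - 1)) / 200
      rest <- setdiff(others, above)
      auc[rest] <- auc[1] - seq_along(rest) / 50
      auc
    }
    medians <- dplyr::bind_rows(lapply(
      c(D1 = 12, D2 = 3, D3 = 1),
      function(r) tibble::tibble(pipeline = pipes, median_auc = mk(r))),
      .id = "dataset")
  })
  tab <- rank_sum_table(medians)
  row <- tab[tab$pipeline == "SGLTR+DBSCAN+RF", ]
  expect_equal(unlist(row[c("rank_D1", "rank_D2", "rank_D3")],
                      use.names = FALSE), c(12, 3, 1))
  expect_equal(row$rank_sum, 16)
  expect_setequal(tab$pipeline, pipes)
  expect_true(all(diff(tab$rank_sum) >= 0))
})

test_that("tied AUCs share the minimum rank and missing cells error", {
  medians <- tidyr::expand_grid(pipeline = c("A", "B", "C"),
                                dataset = c("D1", "D2")) |>
    dplyr::mutate(median_auc = c(0.9, 0.8, 0.9, 0.8, 0.8, 0.7))
  tab <- rank_sum_table(medians)
  expect_equal(sort(tab$rank_D1), c(1, 1, 3))
  expect_error(rank_sum_table(medians[-1, ]), "missing median AUC.*'A'")
})

test_that("a pipeline ranked first everywhere attains the minimum rank sum", {
  medians <- tidyr::expand_grid(pipeline = c("best", "mid", "worst"),
                                dataset = c("D1", "D2", "D3")) |>
    dplyr::mutate(median_auc = rep(c(0.95, 0.85, 0.75), each = 3))
  tab <- rank_sum_table(medians)
  expect_equal(tab$rank_sum[tab$pipeline == "best"], 3)
})

test_that("mean rank sum normalises by the number of classifiers", {
  expect_equal(mean_rank_sum(rep(1, 6)), 1)
  expect_equal(mean_rank_sum(c(1, 2, 1, 2, 1, 2)), 1.5)
  ranks <- c(4, 4, 4, 4, 4, 4)     # worst case with four clustering methods
  expect_lte(mean_rank_sum(ranks), 4)
  expect_gte(mean_rank_sum(ranks), 1)
})

test_that("design enumeration matches the declared registry and its rules", {
  counts <- enumerate_design()
  expect_equal(counts$picker_clusterer_combos, 26)
  expect_equal(counts$automated_combos, 25)
  expect_equal(counts$pipelines, 156)
  expect_equal(counts$automated_pipelines, 150)

  tiny <- list(
    pickers = tibble::tibble(name = "LM", automated = TRUE, implemented = TRUE),
    clusterers = tibble::tibble(name = "GS", automated = TRUE, implemented = TRUE),
    combined = tibble::tibble(name = character(), automated = logical(),
                              implemented = logical()),
    classifiers = tibble::tibble(name = "rf", implemented = TRUE),
    feasible = function(picker, clusterer) TRUE)
  expect_equal(enumerate_design(tiny)$pipelines, 1)

  bad <- tiny; bad$pickers$name <- "MYSTERY"
  expect_error(enumerate_design(bad), "unknown method")
})

test_that("unimplemented registry methods error cleanly from the pipeline runner", {
  co <- list(measurements = list(), labels = tibble::tibble())
  expect_error(run_pipeline(co, picker = "PME"), "not implemented")
  expect_error(run_pipeline(co, picker = "SGLTR", clusterer = "VNa"),
               "not implemented")
})
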