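small_spec <- function(seed = 5, ...) {
  cohort_spec(n_case = 4, n_control = 4,
              grid = list(n_rt = 120, n_ik0 = 90, rt_range = c(0, 120),
                          ik0_range = c(0.4, 1.0)),
              n_shared_peaks = 6, n_diff_peaks = 2, seed = seed, ...)
}

test_that("the generator is bitwise-deterministic given the seed", {
  a <- generate_cohort(small_spec())
  b <- generate_cohort(small_spec())
  expect_identical(a$labels, b$labels)
  expect_identical(a$truth, b$truth)
  expect_identical(a$measurements[["M003"]]$intensity,
                   b$measurements[["M003"]]$intensity)
  c <- generate_cohort(cohort_spec(n_case = 4, n_control = 4,
                                   grid = small_spec()$grid,
                                   n_shared_peaks = 6, n_diff_peaks = 2,
                                   seed = 6))
  expect_false(identical(a$measurements[["M003"]]$intensity,
                         c$measurements[["M003"]]$intensity))
})

test_that("noise-free, dropout-free cohorts expose every true apex to LM", {
  co <- generate_cohort(small_spec(noise_sd = 0, dropout = 0))
  n_true <- nrow(co$truth$features)
  for (m in co$measurements) {
    pk <- pick_lm(m, threshold = 0.05)
    expect_equal(nrow(pk), n_true)
    hit <- truth_match(pk, co$truth$realized[
      co$truth$realized$measurement_id == m$sample_id, ], radius = 2)
    expect_equal(hit$recall, 1)
    expect_equal(hit$precision, 1)
  }
})

test_that("realized truth is consistent with its invariants", {
  co <- generate_cohort(small_spec())
  real <- co$truth$realized
  m <- co$measurements[[1]]
  expect_true(all(real$rt > min(m$rt) & real$rt < max(m$rt)))
  expect_true(all(real$ik0 > min(m$ik0) & real$ik0 < max(m$ik0)))
  expect_equal(nrow(real), nrow(co$labels) * nrow(co$truth$features))
  expect_true(all(real$amplitude > 0))
  # dropout rate plausibly near its parameter (10%)
  expect_lt(abs(mean(!real$present) - 0.1), 0.12)
})

test_that("without differential peaks the class intensity laws coincide", {
  ok <- 0
  for (s in 1:12) {
    # coarse display grid: positions may sit closer than 3 cells, which is
    # irrelevant here because only the realized amplitudes are compared
    co <- suppressWarnings(generate_cohort(cohort_spec(
      n_case = 10, n_control = 10,
      grid = list(n_rt = 40, n_ik0 = 40, rt_range = c(0, 40),
                  ik0_range = c(0.4, 1.0)),
      n_shared_peaks = 8, n_diff_peaks = 0, rip = list(column_fraction = 0,
                                                       amplitude = 0),
      seed = 100 + s)))
    real <- dplyr::left_join(co$truth$realized, co$labels, by = "measurement_id")
    p <- stats::ks.test(real$amplitude[real$label == "case"],
                        real$amplitude[real$label == "control"])$p.value
    if (p > 0.01) ok <- ok + 1
  }
  expect_gte(ok, 10)
})

test_that("differential peaks carry the case/control fold change", {
  co <- generate_cohort(small_spec(effect_size = 3, seed = 8))
  real <- dplyr::left_join(co$truth$realized, co$labels, by = "measurement_id") |>
    dplyr::left_join(co$truth$features[c("feature_id", "differential")],
                     by = "feature_id")
  ratio <- real |>
    dplyr::filter(.data$differential) |>
    dplyr::group_by(.data$label) |>
    dplyr::summarise(m = mean(log(.data$amplitude)), .groups = "drop")
  fold <- exp(diff(range(ratio$m)))
  expect_gt(fold, 1.8)
  expect_lt(fold, 5)
})

test_that("overcrowded specs warn about unresolvable peak spacing", {
  expect_warning(
    generate_cohort(cohort_spec(
      n_case = 1, n_control = 1,
      grid = list(n_rt = 15, n_ik0 = 15, rt_range = c(0, 15),
                  ik0_range = c(0.4, 0.55)),
      n_shared_peaks = 25, n_diff_peaks = 0, min_sep = 0.01,
      peak_shape = list(sd_ik0 = 0.004, sd_rt = 0.5, rt_tailing = 0),
      seed = 2)),
    "3 grid cells|separation")
})

test_that("truth matching implements greedy one-to-one assignment", {
  truth <- tibble::tibble(rt = c(50, 100), ik0 = c(0.6, 0.8))
  exact <- truth_match(truth, truth)
  expect_equal(exact$recall, 1)
  expect_equal(exact$precision, 1)
  expect_equal(exact$rmse, 0)

  none <- truth_match(truth[0, ], truth)
  expect_equal(none$recall, 0)
  expect_equal(none$precision, 1)
  expect_true(none$zero_support)

  jit <- truth
  jit$rt <- jit$rt + c(1, -1)
  jm <- truth_match(jit, truth, radius = 1)
  expect_equal(jm$n_matched, 2L)
  expect_lte(jm$rmse, 1)

  # a single detection cannot match two truths
  dm <- truth_match(truth[1, ], truth, radius = 100)
  expect_equal(dm$n_matched, 1L)
  expect_equal(dm$recall, 0.5)
})

test_that("retention-time tailing skews the peak profile forward", {
  co_sym <- generate_cohort(small_spec(noise_sd = 0, dropout = 0))
  co_tail <- generate_cohort(small_spec(
    noise_sd = 0, dropout = 0,
    peak_shape = list(sd_ik0 = 0.005, sd_rt = 2.5, rt_tailing = 4)))
  m1 <- co_sym$measurements[[1]]$intensity
  m2 <- co_tail$measurements[[1]]$intensity
  # center of mass along rt moves to later times under tailing
  com <- function(mat) sum(seq_len(nrow(mat)) * rowSums(mat)) / sum(mat)
  expect_gt(com(m2), com(m1))
})

test_that("cohorts round-trip through a directory of text files", {
  co <- generate_cohort(small_spec())
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  expect_true(file.exists(file.path(dir, "labels.csv")))
  back <- read_measurement(file.path(dir, "M002.csv"))
  expect_equal(back$intensity, co$measurements[["M002"]]$intensity,
               tolerance = 1e-12)
  expect_equal(back$label, co$measurements[["M002"]]$label)
})
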