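coincident_peaks <- function(n, rt = 50, ik0 = 0.7) {
  tibble::tibble(measurement_id = sprintf("M%02d", seq_len(n)),
                 rt = rt, ik0 = ik0, intensity = seq_len(n))
}

test_that("grid squares keep dense cells and report member-average positions", {
  res <- cluster_grid_squares(coincident_peaks(5), min_count = 3)
  expect_equal(nrow(res$consensus), 1)
  expect_equal(res$consensus$rt, 50)
  expect_equal(res$consensus$ik0, 0.7)
  expect_equal(res$consensus$support, 5L)

  expect_equal(nrow(cluster_grid_squares(coincident_peaks(5), min_count = 6)$consensus), 0)
})

test_that("grid-squares binning respects cell boundaries", {
  # cells of width 0.01 anchored at the leftmost peak: 3 left + 2 right
  pk <- tibble::tibble(
    measurement_id = sprintf("M%02d", 1:5),
    rt = rep(10, 5),
    ik0 = c(0.700, 0.703, 0.706, 0.712, 0.715),
    intensity = 1:5)
  res <- cluster_grid_squares(pk, cell_ik0 = 0.01, cell_rt = 5, min_count = 3)
  expect_equal(nrow(res$consensus), 1)
  expect_equal(res$consensus$support, 3L)
  expect_equal(res$consensus$ik0, mean(c(0.700, 0.703, 0.706)))
  expect_equal(sum(is.na(res$assignment$feature_id)), 2)
})

test_that("DBSCAN separates well-spaced groups and flags isolated points as noise", {
  sc <- peak_scaling()
  withr::with_seed(21, {
    g1 <- tibble::tibble(measurement_id = sprintf("M%02d", 1:5),
                         rt = 50 + rnorm(5, 0, 0.3), ik0 = 0.60 + rnorm(5, 0, 3e-4),
                         intensity = 1)
    g2 <- tibble::tibble(measurement_id = sprintf("M%02d", 1:5),
                         rt = 150 + rnorm(5, 0, 0.3), ik0 = 0.90 + rnorm(5, 0, 3e-4),
                         intensity = 1)
  })
  res <- cluster_dbscan(dplyr::bind_rows(g1, g2), eps = 1, min_pts = 3, scaling = sc)
  expect_equal(nrow(res$consensus), 2)
  cons <- dplyr::arrange(res$consensus, rt)
  expect_lt(abs(cons$rt[1] - mean(g1$rt)), 1)
  expect_lt(abs(cons$ik0[2] - mean(g2$ik0)), 0.003)

  iso <- random_peakset(8, seed = 5)   # spread over the whole plane
  res2 <- cluster_dbscan(iso, eps = 0.01, min_pts = 2)
  expect_equal(nrow(res2$consensus), 0)
  expect_true(all(is.na(res2$assignment$feature_id)))
})

test_that("DBSCAN partitions match the brute-force density-reachability closure", {
  for (s in 1:10) {
    pk <- random_peakset(sample(5:20, 1), seed = 300 + s,
                         rt_range = c(20, 60), ik0_range = c(0.6, 0.68))
    eps <- runif(1, 0.5, 3); mp <- sample(2:4, 1)
    got <- cluster_dbscan(pk, eps, mp)
    want <- oracle_dbscan(pk, eps, mp)
    got_m <- match(got$assignment$feature_id, got$consensus$feature_id)
    expect_identical(canonical_partition(got_m), canonical_partition(want))
  }
})

test_that("cluster editing solves the 3-point instance to the enumerated optimum", {
  sc <- peak_scaling(tol_ik0 = 0.01, tol_rt_abs = 5, tol_rt_rel = 0)
  pk <- tibble::tibble(measurement_id = c("A", "B", "C"),
                       rt = c(50, 50, 50), ik0 = c(0.700, 0.7005, 0.75),
                       intensity = 1)
  res <- cluster_editing(pk, sim_threshold = 1, scaling = sc)
  expect_equal(nrow(res$consensus), 2)
  fid <- res$assignment$feature_id[order(res$assignment$measurement_id)]
  expect_equal(fid[1], fid[2])
  expect_false(fid[3] == fid[1])

  W <- 1 - peak_dist_matrix(pk, sc)
  expect_equal(res$cost, oracle_ce_min_cost(W), tolerance = 1e-12)
})

test_that("cluster editing leaves far-apart peaks as singletons at zero cost", {
  pk <- random_peakset(6, seed = 9)
  res <- cluster_editing(pk, sim_threshold = 0.05)
  expect_equal(nrow(res$consensus), 6)
  expect_equal(res$cost, 0)
})

test_that("EM keeps a lone peak fixed and recovers two clouds", {
  one <- tibble::tibble(measurement_id = "M1", rt = 77.5, ik0 = 0.654,
                        intensity = 3)
  res <- cluster_em(one, sigma_ik0 = 0.003, sigma_rt = 3)
  expect_equal(nrow(res$consensus), 1)
  expect_equal(res$consensus$rt, 77.5, tolerance = 1e-9)
  expect_equal(res$consensus$ik0, 0.654, tolerance = 1e-9)

  hits <- 0
  for (s in 1:20) {
    sig_d <- 0.003; sig_r <- 3
    withr::with_seed(700 + s, {
      pk <- tibble::tibble(
        measurement_id = sprintf("M%02d", rep(1:30, 2)),
        rt = c(rnorm(30, 100 - 5 * sig_r, sig_r), rnorm(30, 100 + 5 * sig_r, sig_r)),
        ik0 = c(rnorm(30, 0.70 - 5 * sig_d, sig_d), rnorm(30, 0.70 + 5 * sig_d, sig_d)),
        intensity = 1)
    })
    res <- cluster_em(pk, sig_d, sig_r)
    if (nrow(res$consensus) == 2) {
      cons <- dplyr::arrange(res$consensus, rt)
      tol_r <- 3 * sig_r / sqrt(30); tol_d <- 3 * sig_d / sqrt(30)
      if (abs(cons$rt[1] - (100 - 5 * sig_r)) < tol_r &&
          abs(cons$rt[2] - (100 + 5 * sig_r)) < tol_r &&
          abs(cons$ik0[1] - (0.70 - 5 * sig_d)) < tol_d &&
          abs(cons$ik0[2] - (0.70 + 5 * sig_d)) < tol_d) hits <- hits + 1
    }
  }
  expect_gte(hits, 18)
})

test_that("EM merging collapses an overseeded mixture and log-likelihood is monotone", {
  withr::with_seed(31, {
    pk <- tibble::tibble(
      measurement_id = sprintf("M%02d", rep(1:25, 2)),
      rt = c(rnorm(25, 80, 3), rnorm(25, 130, 3)),
      ik0 = c(rnorm(25, 0.62, 0.003), rnorm(25, 0.85, 0.003)),
      intensity = 1)
  })
  # tiny init cells seed many components (close to one per peak)
  res <- cluster_em(pk, sigma_ik0 = 0.003, sigma_rt = 3)
  expect_equal(nrow(res$consensus), 2)
  tr <- res$params$trace
  between_merges <- which(!tr$merged[-nrow(tr)])
  if (length(between_merges)) {
    expect_true(all(diff(tr$loglik)[between_merges] > -1e-6))
  }
})

test_that("clusterings are invariant to peak-list order", {
  pk <- random_peakset(30, seed = 55, rt_range = c(20, 120),
                       ik0_range = c(0.55, 0.8))
  shuf <- withr::with_seed(8, pk[sample.int(nrow(pk)), ])
  for (fun in list(function(p) cluster_grid_squares(p, min_count = 1),
                   function(p) cluster_dbscan(p, eps = 1.5, min_pts = 2),
                   function(p) cluster_editing(p, sim_threshold = 1.5),
                   function(p) cluster_em(p))) {
    a <- fun(pk)$consensus; b <- fun(shuf)$consensus
    expect_equal(nrow(a), nrow(b))
    expect_lt(max(abs(a$rt - b$rt)), 1e-9)
    expect_lt(max(abs(a$ik0 - b$ik0)), 1e-9)
  }
})

test_that("DBSCAN and CE cluster structure is scale-consistent", {
  pk <- random_peakset(20, seed = 77, rt_range = c(40, 80),
                       ik0_range = c(0.6, 0.7))
  sc1 <- peak_scaling(tol_ik0 = 0.003, tol_rt_abs = 3, tol_rt_rel = 0)
  fac <- 4
  pk2 <- pk
  pk2$rt <- 40 + (pk$rt - 40) * fac
  pk2$ik0 <- 0.6 + (pk$ik0 - 0.6) * fac
  sc2 <- peak_scaling(tol_ik0 = 0.003 * fac, tol_rt_abs = 3 * fac, tol_rt_rel = 0)
  for (pair in list(
    list(cluster_dbscan(pk, 1.2, 2, sc1), cluster_dbscan(pk2, 1.2, 2, sc2)),
    list(cluster_editing(pk, 1.2, sc1), cluster_editing(pk2, 1.2, sc2)))) {
    a <- match(pair[[1]]$assignment$feature_id, pair[[1]]$consensus$feature_id)
    b <- match(pair[[2]]$assignment$feature_id, pair[[2]]$consensus$feature_id)
    expect_identical(canonical_partition(a), canonical_partition(b))
  }
})

test_that("cluster assignments partition the non-noise peaks", {
  pk <- random_peakset(40, seed = 13, rt_range = c(20, 200),
                       ik0_range = c(0.5, 0.95))
  for (res in list(cluster_grid_squares(pk, min_count = 2),
                   cluster_dbscan(pk, 1, 2), cluster_editing(pk, 1),
                   cluster_em(pk))) {
    expect_equal(nrow(res$assignment), nrow(pk))
    assigned <- res$assignment$feature_id[!is.na(res$assignment$feature_id)]
    expect_true(all(assigned %in% res$consensus$feature_id))
    supp <- table(assigned)
    expect_equal(sort(as.integer(supp[res$consensus$feature_id])),
                 sort(res$consensus$support))
  }
})
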