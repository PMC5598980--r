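# Fixture builders, written independently of the package's synthetic module
# so picker/cluster tests do not lean on the code they exercise.

# measurement with truncation-free 2D Gaussian bumps rendered over the whole
# grid; centers is a tibble/data.frame with rt, ik0, amp
gauss_measurement <- function(centers, n_rt = 60, n_ik0 = 50,
                              rt_range = c(0, 60), ik0_range = c(0.5, 1.0),
                              sd_rt = 2, sd_ik0 = 0.01, noise_sd = 0,
                              seed = NULL, id = "fix") {
  build <- function() {
    rt <- seq(rt_range[1], rt_range[2], length.out = n_rt)
    ik0 <- seq(ik0_range[1], ik0_range[2], length.out = n_ik0)
    mat <- matrix(0, n_rt, n_ik0)
    for (i in seq_len(nrow(centers))) {
      mat <- mat + centers$amp[i] *
        exp(-0.5 * ((rt - centers$rt[i]) / sd_rt)^2) %o%
        exp(-0.5 * ((ik0 - centers$ik0[i]) / sd_ik0)^2)
    }
    if (noise_sd > 0) {
      mat <- mat + matrix(rnorm(n_rt * n_ik0, 0, noise_sd), n_rt, n_ik0)
    }
    ims_measurement(mat, rt, ik0, sample_id = id)
  }
  if (is.null(seed)) build() else withr::with_seed(seed, build())
}

# random valid measurement for IO round-trip property tests
random_measurement <- function(seed) {
  withr::with_seed(seed, {
    n_rt <- sample(2:12, 1); n_ik0 <- sample(2:12, 1)
    ims_measurement(matrix(runif(n_rt * n_ik0, 0, 1e3), n_rt, n_ik0),
                    rt = sort(runif(n_rt, 0, 500)),
                    ik0 = sort(runif(n_ik0, 0.3, 1.2)),
                    sample_id = sprintf("r%03d", seed),
                    label = sample(c("case", "control", NA), 1))
  })
}

# random peak set spread over the plane, in one or several measurements
random_peakset <- function(n, seed, n_measurements = 3,
                           rt_range = c(10, 200), ik0_range = c(0.45, 1.0)) {
  withr::with_seed(seed, tibble::tibble(
    measurement_id = sprintf("M%02d", sample.int(n_measurements, n, replace = TRUE)),
    rt = runif(n, rt_range[1], rt_range[2]),
    ik0 = runif(n, ik0_range[1], ik0_range[2]),
    intensity = runif(n, 1, 100)))
}
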