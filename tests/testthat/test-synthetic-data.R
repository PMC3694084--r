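test_that("generation is seed-deterministic and noise-free at infinite SNR", {
  s <- two_source_spec()
  L <- lead_field(4, 2, seed = 1)
  th <- prior_mean_theta(s)
  d1 <- simulate_erp(s, th, L, snr = 10, seed = 5, grid = fast_grid)
  d2 <- simulate_erp(s, th, L, snr = 10, seed = 5, grid = fast_grid)
  expect_equal(d1$y, d2$y)
  d3 <- simulate_erp(s, th, L, snr = 10, seed = 6, grid = fast_grid)
  expect_gt(max(abs(d1$y[[1]] - d3$y[[1]])), 0)
  clean <- simulate_erp(s, th, L, snr = Inf, seed = 5, grid = fast_grid)
  h <- predict_response(s, th, L, stimulus_input(), fast_grid)
  expect_equal(clean$y[[1]], h[[1]])
})

test_that("the default grid covers 0-900 ms at 250 Hz", {
  s <- two_source_spec()
  d <- simulate_erp(s, prior_mean_theta(s), lead_field(4, 2, seed = 1),
                    input = stimulus_input(amplitude = 5), snr = 10, seed = 1)
  expect_equal(length(d$times), 0.9 * 250 + 1)
  expect_equal(d$srate, 250)
  expect_equal(range(d$times), c(0, 900))
})

test_that("noise calibration reproduces the requested trial-averaged SNR", {
  s <- two_source_spec()
  L <- lead_field(4, 2, seed = 1)
  th <- prior_mean_theta(s)
  inp <- stimulus_input(amplitude = 5)
  h <- predict_response(s, th, L, inp, fast_grid)
  peak <- max(h[[1]]^2)
  noise_pow <- vapply(1:200, function(k) {
    d <- simulate_erp(s, th, L, inp, snr = 10, seed = k, grid = fast_grid)
    mean((d$y[[1]] - h[[1]])^2)
  }, numeric(1))
  expect_lt(abs(peak / mean(noise_pow) / 10 - 1), 0.1)
})

test_that("epoch concatenation tiles and truncates exactly", {
  s <- two_source_spec()
  d <- simulate_erp(s, prior_mean_theta(s), lead_field(4, 2, seed = 1),
                    input = stimulus_input(amplitude = 5),
                    snr = 10, seed = 2, grid = seq(0, 198, by = 2))
  L0 <- length(d$times)          # 100 samples
  expect_equal(extend_data_length(d, L0)$y, d$y)
  d2 <- extend_data_length(d, 250)        # 2.5 epochs
  expect_equal(ncol(d2$y[[1]]), 250L)
  expect_equal(d2$y[[1]][, 201:250], d$y[[1]][, 1:50])
  d3 <- extend_data_length(d, 2000)
  k <- c(0L, 123L, 999L, 1999L)
  expect_equal(d3$y[[1]][, k + 1L], d3$y[[1]][, (k %% L0) + 1L])
  expect_equal(length(d3$times), 2000L)
  expect_equal(diff(d3$times)[1], 2)
})

test_that("complexity scaling reaches requested parameter counts exactly", {
  base <- model_spec(5, F_mask = (row(diag(5)) == col(diag(5)) + 1),
                     B_mask = (col(diag(5)) == row(diag(5)) + 1),
                     U_mask = c(TRUE, rep(FALSE, 4)))
  N0 <- n_parameters(base)
  expect_identical(scale_model_complexity(base, N0), base)
  for (N in c(46L, 64L, 111L, 128L, 256L)) {
    sc <- scale_model_complexity(base, N)
    expect_equal(n_parameters(sc), N)
    # the Jacobian task count tracks the complexity
    expect_length(make_jacobian_tasks(prior_mean_theta(sc)), N)
  }
  expect_error(scale_model_complexity(base, N0 - 1), "below the base")
  # a fully connected 5-source model enumerates all extrinsic entries
  full <- scale_model_complexity(base, 3L * 20L + 1L)
  expect_true(all(full$F_mask[row(diag(5)) != col(diag(5))]))
})

test_that("datasets round-trip through the TSV + JSON container", {
  s <- two_source_spec(M_mask = matrix(c(0, 1, 0, 0), 2, 2),
                       conditions = c("standard", "deviant"))
  th <- prior_mean_theta(s) + 0.1
  d <- simulate_erp(s, th, lead_field(4, 2, seed = 3),
                    input = stimulus_input(amplitude = 5),
                    snr = 10, seed = 9, grid = fast_grid)
  stem <- file.path(withr::local_tempdir(), "ds")
  write_dataset(d, stem)
  d2 <- read_dataset(stem)
  expect_equal(d2$y$standard, d$y$standard, tolerance = 1e-12)
  expect_equal(d2$y$deviant, d$y$deviant, tolerance = 1e-12)
  expect_equal(d2$conditions, d$conditions)
  expect_equal(d2$ground_truth$theta, d$ground_truth$theta)
  expect_equal(d2$ground_truth$spec, d$ground_truth$spec)
})
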