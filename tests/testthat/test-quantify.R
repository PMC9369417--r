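test_that("filters fire exactly as printed", {
  f_ok <- mock_fit(free_s = 4.0, chi2 = 1e-2)
  f_s <- mock_fit(free_s = 0.05)
  f_chi <- mock_fit(chi2 = 1e-5)
  f_s_hi <- mock_fit(free_s = 15.5)
  out <- apply_filters(list(f_ok, f_s, f_chi, f_s_hi))
  expect_length(out$kept, 1)
  expect_equal(out$reasons,
               c("structural_parameter_out_of_range", "chi2_rule",
                 "structural_parameter_out_of_range"))
  # exclusion accounting: kept + discarded = input, one reason per discard
  expect_equal(length(out$kept) + length(out$discarded), 4)
  expect_equal(length(out$reasons), length(out$discarded))

  # boundary behaviour: chi2 exactly at the threshold is kept (rule is <)
  expect_length(apply_filters(list(mock_fit(chi2 = 1e-4)))$kept, 1)
  # configurable direction: exclude_large discards big chi2 instead
  out2 <- apply_filters(list(f_ok, mock_fit(chi2 = 10)),
                        chi2_threshold = 1, chi2_rule = "exclude_large")
  expect_equal(out2$reasons, "chi2_rule")
  # empty input -> empty output
  expect_length(apply_filters(list())$kept, 0)
})

test_that("per-cell averaging enforces the minimum repetition rule", {
  fits6 <- lapply(1:6, function(i) mock_fit(n = 20 + i))
  # 10x10s scheme: minimum 5 valid repetitions
  m6 <- summarize_cell(fits6, scheme = "10x10s", cell_id = "c1")
  expect_false(m6$excluded)
  expect_equal(m6$n, mean(21:26))
  m4 <- summarize_cell(fits6[1:4], scheme = "10x10s", cell_id = "c1")
  expect_true(m4$excluded)
  expect_equal(m4$exclusion_reason, "insufficient_repetitions")
  # 5x5s scheme: minimum 3
  m3 <- summarize_cell(fits6[1:3], scheme = "5x5s", cell_id = "c1")
  expect_false(m3$excluded)
  m2 <- summarize_cell(fits6[1:2], scheme = "5x5s", cell_id = "c1")
  expect_true(m2$excluded)
})

test_that("identical repetitions average to themselves with derived fields", {
  f <- mock_fit(n = 20, tau1 = 987.8e-6, tau2 = 8e-2, f1 = 0.6, cpm = 5)
  m <- summarize_cell(rep(list(f), 5), scheme = "5x5s",
                      optics = optics_spec(w0 = 0.22), cell_id = "c1")
  expect_equal(m$n, 20)
  expect_equal(m$cpm, 5)
  expect_equal(m$d1, 0.22^2 / (4 * 987.8e-6))
  expect_equal(m$d2, 0.22^2 / (4 * 8e-2))
  expect_equal(m$fraction_slow, 0.4)
  expect_equal(m$per_cell_copies, 20 * 82 / 0.57)
  # fast constant is D1 by construction
  expect_gt(m$d1, m$d2)
})

test_that("diffusion constant conversion is exact", {
  # unit case: w0 = 1 um, tau = 0.25 s -> 1 um^2/s
  expect_equal(diffusion_constant(0.25, w0 = 1), 1)
  # the calibrated-waist value that corresponds to the published fast rate
  expect_equal(diffusion_constant(987.8e-6, w0 = 0.22), 12.25, tolerance = 1e-4)
  # scaling law: doubling w0 quadruples D
  expect_equal(diffusion_constant(0.1, w0 = 2), 4 * diffusion_constant(0.1, w0 = 1))
  # round trip: D * tau = w0^2 / 4 exactly
  tau <- 3.7e-3
  expect_equal(diffusion_constant(tau, 0.22) * tau, 0.22^2 / 4)
  expect_error(diffusion_constant(-1, 0.22), "positive")
})

test_that("per-cell copies scale linearly by the volume ratio", {
  expect_equal(per_cell_copies(0), 0)
  expect_equal(per_cell_copies(1), 82 / 0.57)
  expect_equal(per_cell_copies(1), 143.86, tolerance = 1e-4)
  expect_equal(per_cell_copies(25.19), 25.19 * 82 / 0.57)
  expect_equal(per_cell_copies(25.19), 3623.8, tolerance = 1e-4)
  # exact linearity
  x <- c(0.5, 2, 10)
  expect_equal(per_cell_copies(x), x * per_cell_copies(1))
  expect_error(per_cell_copies(1, confocal_volume = 0), "positive")
})

test_that("median_ci gives exact medians and seed-stable bootstrap CIs", {
  out <- median_ci(1:11, seed = 1)
  expect_equal(out$median, 6)
  # degenerate sample: CI collapses to the constant
  cc <- median_ci(rep(3.5, 10), seed = 1)
  expect_equal(c(cc$lower, cc$upper), c(3.5, 3.5))
  x <- rnorm(20)
  expect_identical(median_ci(x, seed = 9, n_boot = 500),
                   median_ci(x, seed = 9, n_boot = 500))
  expect_error(median_ci(c(1, 2)), "at least 3")
})

test_that("bootstrap CI covers the true median at nominal-ish rate", {
  # coverage simulation, scaled down (60 trials, n_boot 1000): a 95% CI
  # for the median of 200 log-normal draws must cover the true median in
  # at least 90% of trials
  true_med <- exp(0)
  set.seed(77)
  cover <- replicate(60, {
    x <- rlnorm(200, 0, 0.5)
    ci <- median_ci(x, n_boot = 1000, seed = sample.int(1e6, 1))
    ci$lower <= true_med && true_med <= ci$upper
  })
  expect_gte(mean(cover), 0.90)
})
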