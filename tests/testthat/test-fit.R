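test_that("noise-free two-component curves are recovered to < 1e-4", {
  p <- fcs_params(n = 18, triplet_fraction = 0.12, triplet_time = 25e-6,
                  f1 = 0.6, tau1 = 9e-4, tau2 = 7e-2, s = 4)
  cv <- generate_curve(p, noise_scale = 0)
  f <- fit_curve(cv, components = 2, fix_s = 4)
  expect_lt(abs(f$params$n / p$n - 1), 1e-4)
  expect_lt(abs(f$params$f1 - p$f1), 1e-4)
  expect_lt(abs(f$params$tau1 / p$tau1 - 1), 1e-4)
  expect_lt(abs(f$params$tau2 / p$tau2 - 1), 1e-4)
  expect_lt(abs(f$params$triplet_fraction - p$triplet_fraction), 1e-4)
  expect_lt(f$chi2, 1e-12)
})

test_that("model nesting: 2-component fit of 1-component data keeps N", {
  p <- fcs_params(n = 14, tau1 = 2e-3, s = 4)
  cv <- generate_curve(p, noise_scale = 0)
  f1c <- fit_curve(cv, components = 1, fix_s = 4, triplet = FALSE)
  expect_lt(abs(f1c$params$n / 14 - 1), 1e-6)
  expect_lt(abs(f1c$params$tau1 / 2e-3 - 1), 1e-6)
  f2c <- fit_curve(cv, components = 2, fix_s = 4, triplet = FALSE)
  # fractions are degenerate but total N is preserved
  expect_lt(abs(f2c$params$n / 14 - 1), 1e-3)
})

test_that("degenerate curves are flagged no_correlation", {
  lags <- make_lag_grid(1e-6, 1, 60)
  flat0 <- fcs_curve(lags, rep(0, 60))
  expect_equal(fit_curve(flat0)$qc_flags, "no_correlation")
  expect_null(fit_curve(flat0)$params)
  # pure noise around zero
  set.seed(8)
  noise <- fcs_curve(lags, rnorm(60, 0, 0.01))
  expect_true("no_correlation" %in% fit_curve(noise)$qc_flags)
})

test_that("fitted components are relabelled fast-first", {
  p <- fcs_params(n = 10, f1 = 0.35, tau1 = 5e-2, tau2 = 4e-4, s = 4)
  cv <- generate_curve(p, noise_scale = 0)
  f <- fit_curve(cv, fix_s = 4, triplet = FALSE)
  expect_lt(f$params$tau1, f$params$tau2)
  # matches the relabelled truth: fast tau 4e-4 with fraction 0.65
  expect_equal(f$params$tau1, 4e-4, tolerance = 1e-3)
  expect_equal(f$params$f1, 0.65, tolerance = 1e-3)
})

test_that("CPM is the curve mean rate over fitted N", {
  p <- fcs_params(n = 20, tau1 = 1e-3, s = 4)
  cv <- generate_curve(p, noise_scale = 0, mean_rate = 100)
  f <- fit_curve(cv, components = 1, fix_s = 4, triplet = FALSE)
  expect_equal(f$cpm, 100 / f$params$n, tolerance = 1e-9)
  expect_equal(f$cpm, 5, tolerance = 1e-4)
})

test_that("two-stage fit prescreens the free structural parameter", {
  set.seed(21)
  # curves generated with S = 4 pass the prescreen and recover parameters
  p <- params_fis1_het(n = 20)
  s_est <- numeric(10)
  for (i in 1:10) {
    f <- two_stage_fit(noisy_curve(p))
    s_est[i] <- f$free_s_estimate
    expect_false("structural_parameter_out_of_range" %in% f$qc_flags)
    expect_equal(f$params$s, 4)
    expect_equal(f$params$n, 20, tolerance = 0.1)
  }
  expect_true(all(s_est >= 0.1 & s_est <= 15))

  # a curve generated with a pathological S yields an out-of-range free-S
  # estimate and is flagged for exclusion
  p_bad <- fcs_params(n = 20, f1 = 0.6, tau1 = 9e-4, tau2 = 7e-2, s = 0.05)
  f_bad <- two_stage_fit(generate_curve(p_bad, noise_scale = 0))
  expect_true(f_bad$free_s_estimate < 0.1 || f_bad$free_s_estimate > 15)
  expect_true("structural_parameter_out_of_range" %in% f_bad$qc_flags)
  expect_length(apply_filters(list(f_bad))$kept, 0)

  # stage-2 refit of an exact S = 4 curve equals a direct fixed-S fit
  cv <- generate_curve(p, noise_scale = 0)
  f2 <- two_stage_fit(cv)
  fd <- fit_curve(cv, fix_s = 4)
  expect_equal(f2$params$n, fd$params$n, tolerance = 1e-8)
  expect_equal(f2$params$tau1, fd$params$tau1, tolerance = 1e-6)
})

test_that("parameter recovery at 1% signal noise meets stated tolerances", {
  # two parameter sets spanning the published regimes; 40 noisy curves
  # each (scaled down from 100 for runtime; median errors are stable)
  regimes <- list(
    fcs_params(n = 10, triplet_fraction = 0.15, triplet_time = 20e-6,
               f1 = 0.6, tau1 = tau_from_d(13), tau2 = tau_from_d(0.2), s = 4),
    fcs_params(n = 30, triplet_fraction = 0.15, triplet_time = 20e-6,
               f1 = 0.4, tau1 = tau_from_d(9), tau2 = tau_from_d(0.1), s = 4)
  )
  set.seed(31)
  for (p in regimes) {
    res <- t(replicate(40, {
      f <- fit_curve(noisy_curve(p), fix_s = 4)
      c(n = abs(f$params$n / p$n - 1),
        t1 = abs(f$params$tau1 / p$tau1 - 1),
        t2 = abs(f$params$tau2 / p$tau2 - 1),
        fs = abs((1 - f$params$f1) - (1 - p$f1)))
    }))
    expect_lt(median(res[, "n"]), 0.05)
    expect_lt(median(res[, "t1"]), 0.15)
    expect_lt(median(res[, "t2"]), 0.15)
    expect_lt(median(res[, "fs"]), 0.05)
  }
})

test_that("fit_curve validates its preconditions", {
  expect_error(fit_curve(fcs_curve(c(1e-3, 2e-3), c(0.1, 0.05))),
               "at least 10 lags")
})
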