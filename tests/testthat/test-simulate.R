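test_that("zero brightness and zero background give an all-zero trace", {
  cfg <- sim_config(species_spec(10, 1, brightness = 0),
                    triplet = triplet_spec(0), mean_molecules_in_cv = 5,
                    bin_width = 1e-4, duration = 0.1, repetitions = 2)
  trs <- simulate_trace(cfg, seed = 1)
  expect_length(trs, 2)
  for (tr in trs) expect_equal(tr$counts, rep(0, 1000))
})

test_that("an immobile molecule at the focus emits at its peak brightness", {
  # MDF at the origin is 1, so the mean count rate converges to q
  q <- 10
  cfg <- sim_config(species_spec(0, 1, brightness = q),
                    triplet = triplet_spec(0), mean_molecules_in_cv = 1e-9,
                    bin_width = 1e-3, duration = 10, repetitions = 1,
                    origin_start = TRUE)
  tr <- simulate_trace(cfg, seed = 2)[[1]]
  expect_equal(trace_mean_rate(tr), q, tolerance = 0.02)
})

test_that("time-average occupancy of the effective volume matches target", {
  # direct occupancy oracle: count molecules inside an ellipsoid of
  # effective-volume size along the trajectory; the mean must sit within
  # 3 block-estimated standard errors of the configured 10
  cfg <- sim_config(species_spec(10, 1, brightness = 10),
                    triplet = triplet_spec(0), mean_molecules_in_cv = 10,
                    bin_width = 2e-5, duration = 1, repetitions = 1)
  tr <- simulate_trace(cfg, seed = 3, track_occupancy = TRUE)[[1]]
  occ <- tr$occupancy
  blocks <- colMeans(matrix(occ, ncol = 20))
  se <- sd(blocks) / sqrt(20)
  expect_lt(abs(mean(occ) - 10), 3 * se + 1e-9)
  # mean count rate = brightness x occupancy x MDF volume ratio 2^(-3/2)
  expected_rate <- 10 * mean(occ) * 2^(-1.5)
  expect_equal(trace_mean_rate(tr), expected_rate, tolerance = 0.05)
})

test_that("simulation is reproducible for a fixed seed", {
  # triplet blinking on: the 2 us default binning resolves tau_T = 20 us
  cfg <- sim_config(species_spec(5, 1, brightness = 15),
                    mean_molecules_in_cv = 8,
                    bin_width = 2e-6, duration = 0.02, repetitions = 2)
  a <- simulate_trace(cfg, seed = 99)
  b <- simulate_trace(cfg, seed = 99)
  expect_equal(a[[1]]$counts, b[[1]]$counts)
  expect_equal(a[[2]]$counts, b[[2]]$counts)
  # ground truth is retained on every trace
  expect_equal(a[[1]]$ground_truth$mean_molecules_in_cv, 8)
})

test_that("config validation enforces physical preconditions", {
  sp <- species_spec(10, 1, 10)
  expect_error(sim_config(sp, timestep = 1e-3, bin_width = 1e-4),
               "timestep")
  expect_error(sim_config(sp, box_size = c(0.5, 0.5, 0.5)), "box too small")
  expect_error(sim_config(list(species_spec(10, 0.5, 10),
                               species_spec(1, 0.2, 10))),
               "fractions must sum to 1")
  # triplet slower than the fastest diffusion time is rejected
  expect_error(sim_config(sp, triplet = triplet_spec(0.2, 5e-3)),
               "triplet relaxation")
})

test_that("autocorrelating and fitting a simulated trace recovers D and N", {
  # scaled-down version of the physics-recovery property (3 seeds rather
  # than 20, 10 s of total trace per seed at 50 us bins) to stay inside
  # the test-time budget; median relative errors must be within 15%
  d_true <- 2; n_true <- 10
  tau_true <- tau_from_d(d_true)
  errs <- t(sapply(1:3, function(s) {
    cfg <- sim_config(species_spec(d_true, 1, brightness = 30),
                      triplet = triplet_spec(0), mean_molecules_in_cv = n_true,
                      bin_width = 5e-5, duration = 2, repetitions = 5)
    trs <- simulate_trace(cfg, seed = 100 + s)
    curves <- lapply(trs, autocorrelate_multitau, max_lag = 0.2)
    avg <- average_curves(curves)
    f <- fit_curve(avg, components = 1, fix_s = 4, triplet = FALSE)
    c(n = abs(f$params$n / n_true - 1),
      d = abs(tau_true / f$params$tau1 - 1))
  }))
  expect_lt(median(errs[, "n"]), 0.15)
  expect_lt(median(errs[, "d"]), 0.15)
})

test_that("generate_curve honours its noise contract", {
  p <- params_fis1_het()
  lags <- make_lag_grid(1e-6, 1, 80)
  # zero noise reproduces the closed form exactly
  cv0 <- generate_curve(p, lags, noise_scale = 0)
  expect_equal(cv0$g, fcs_model_g(lags, p))
  # noise-free curves are strictly decreasing for valid offset-0 parameters
  expect_true(all(diff(cv0$g) < 0))
  # G at the smallest lag -> 1/N as lag -> 0 (triplet-free)
  p10 <- fcs_params(n = 10, tau1 = 1e-3, s = 4)
  cvn <- generate_curve(p10, make_lag_grid(1e-9, 1, 50))
  expect_equal(cvn$g[1], 0.1, tolerance = 1e-4)
  # seeded noise is reproducible, and the two noise models scale as stated
  c1 <- generate_curve(p, lags, noise_scale = 0.01, seed = 5)
  c2 <- generate_curve(p, lags, noise_scale = 0.01, seed = 5)
  expect_equal(c1$g, c2$g)
  expect_error(generate_curve(p, lags, noise_scale = -1), "non-negative")
  set.seed(1)
  g0 <- fcs_model_g(lags, p)
  resid_sb <- replicate(50, generate_curve(p, lags, 0.05)$g - g0)
  resid_pr <- replicate(50, generate_curve(
    p, lags, 0.05, noise_model = "proportional")$g - g0)
  expect_equal(apply(resid_sb, 1, sd), 0.05 * (1 + g0), tolerance = 0.35)
  expect_equal(apply(resid_pr, 1, sd), 0.05 * g0, tolerance = 0.35)
})
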