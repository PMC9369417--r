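# shared fixtures, built in code

w0_cal <- 0.22  # calibrated lateral beam waist, um

tau_from_d <- function(d, w0 = w0_cal) w0^2 / (4 * d)

# the FIS1 GFP/+ glucose mobility regime: fast 12.25 um^2/s (59.6% fast),
# slow taken at the glycerol slow-rate scale
params_fis1_het <- function(n = 20, triplet = 0.15) {
  fcs_params(n = n, triplet_fraction = triplet, triplet_time = 20e-6,
             f1 = 0.596, tau1 = tau_from_d(12.25), tau2 = tau_from_d(0.15),
             s = 4)
}

# small deterministic photon trace for correlator tests
random_trace <- function(n_bins = 2000, bin_width = 1e-5, lambda = 3) {
  fcs_trace(stats::rpois(n_bins, lambda), bin_width)
}

# curves with 1%-of-signal noise, the mobility-recovery regime
noisy_curve <- function(params, noise = 0.01, mean_rate = NA_real_) {
  generate_curve(params, noise_scale = noise, mean_rate = mean_rate,
                 noise_model = "proportional")
}

# a minimal fcs_fit-like object for filter/averaging tests
mock_fit <- function(n = 20, chi2 = 1e-2, free_s = 4, flags = character(0),
                     tau1 = 1e-3, tau2 = 8e-2, f1 = 0.6, cpm = 5,
                     cell_id = "c1") {
  structure(list(
    params = fcs_params(n = n, triplet_fraction = 0.1, triplet_time = 2e-5,
                        f1 = f1, tau1 = tau1, tau2 = tau2, s = 4),
    chi2 = chi2, cpm = cpm, qc_flags = flags, converged = TRUE,
    free_s_estimate = free_s, mean_rate = cpm * n, n_lags = 100,
    components = 2, cell_id = cell_id
  ), class = "fcs_fit")
}
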