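#' Diffusing species specification
#'
#' @param diffusion_coefficient Diffusion coefficient in um^2/s (> 0; 0 is
#'   allowed only for deliberately immobile validation molecules).
#' @param fraction Fraction of the molecule pool in this species, in `[0, 1]`.
#' @param brightness Peak per-molecule brightness in kHz at the centre of the
#'   detection volume (>= 0).
#' @return A `species_spec` list.
#' @export
species_spec <- function(diffusion_coefficient, fraction = 1, brightness = 10) {
  stopifnot(is.finite(diffusion_coefficient), diffusion_coefficient >= 0)
  stopifnot(fraction >= 0, fraction <= 1)
  stopifnot(brightness >= 0)
  structure(list(diffusion_coefficient = diffusion_coefficient,
                 fraction = fraction, brightness = brightness),
            class = "species_spec")
}

#' Confocal optics specification
#'
#' @param w0 Lateral beam waist in um (calibrated value 0.22 um).
#' @param structural_parameter Axial-to-lateral aspect ratio S = z0/w0
#'   (instrument convention 4).
#' @param confocal_volume Calibration constant for per-cell copy-number
#'   scaling, in femtolitres (default 0.57 fl).
#' @return An `optics_spec` list.
#' @export
optics_spec <- function(w0 = 0.22, structural_parameter = 4,
                        confocal_volume = 0.57) {
  stopifnot(w0 > 0, structural_parameter >= 1, confocal_volume > 0)
  structure(list(w0 = w0, structural_parameter = structural_parameter,
                 confocal_volume = confocal_volume),
            class = "optics_spec")
}

#' Effective (correlation) volume of a 3D Gaussian observation profile
#'
#' `V_eff = pi^{3/2} S w0^3` in um^3 (= fl); the molecule number N reported
#' by the FCS amplitude equals concentration times this volume.
#'
#' @param optics An [optics_spec].
#' @return Volume in femtolitres.
#' @export
effective_volume <- function(optics) {
  stopifnot(inherits(optics, "optics_spec"))
  pi^1.5 * optics$structural_parameter * optics$w0^3
}

#' Triplet (dark-state) specification
#'
#' @param dark_fraction Equilibrium dark-state probability T in `[0, 1)`.
#' @param relaxation_time Triplet relaxation time tau_T in seconds.
#' @return A `triplet_spec` list.
#' @export
triplet_spec <- function(dark_fraction = 0.15, relaxation_time = 20e-6) {
  stopifnot(dark_fraction >= 0, dark_fraction < 1)
  stopifnot(relaxation_time > 0)
  structure(list(dark_fraction = dark_fraction,
                 relaxation_time = relaxation_time),
            class = "triplet_spec")
}

#' Trace-level simulation configuration
#'
#' Describes one cell's acquisition: the molecule pool, optics, triplet
#' kinetics, occupancy, binning and repetition scheme for Brownian-dynamics
#' photon-trace simulation.
#'
#' The instrument bins at 200 ns; simulating 5e7 bins per 10 s repetition is
#' not desk-scale, so the default bin width is 2 us, which still resolves
#' triplet relaxation times >= 10 us and all diffusion times of interest.
#'
#' @param species List of [species_spec]; fractions must sum to 1.
#' @param optics An [optics_spec].
#' @param triplet A [triplet_spec] (use `dark_fraction = 0` to disable).
#' @param mean_molecules_in_cv Expected molecule number in the effective
#'   volume [effective_volume].
#' @param bin_width Bin width in seconds (default 2e-6).
#' @param duration Seconds per repetition (acquisition scheme: 10 s x 10
#'   repetitions, or 5 s x 5).
#' @param repetitions Number of repetitions.
#' @param background_rate Uncorrelated background in kHz.
#' @param box_size Full box edge lengths in um (length 1 or 3); defaults to
#'   the minimum allowed `6 w0` laterally and `6 S w0` axially.
#' @param timestep Propagation timestep in seconds; must divide `bin_width`
#'   (default equal to it).
#' @param origin_start Start all molecules at the beam centre (validation
#'   hook for pinned-molecule checks); default FALSE (uniform in the box).
#' @return A `sim_config` list.
#' @export
sim_config <- function(species, optics = optics_spec(),
                       triplet = triplet_spec(),
                       mean_molecules_in_cv = 10,
                       bin_width = 2e-6, duration = 10, repetitions = 10,
                       background_rate = 0, box_size = NULL,
                       timestep = bin_width, origin_start = FALSE) {
  if (inherits(species, "species_spec")) species <- list(species)
  stopifnot(length(species) >= 1L,
            all(vapply(species, inherits, logical(1), "species_spec")))
  fr <- vapply(species, `[[`, numeric(1), "fraction")
  if (abs(sum(fr) - 1) > 1e-8) stop("species fractions must sum to 1")
  stopifnot(inherits(optics, "optics_spec"), inherits(triplet, "triplet_spec"))
  stopifnot(mean_molecules_in_cv > 0, bin_width > 0, duration > 0,
            repetitions >= 1, background_rate >= 0)
  n_bins <- duration / bin_width
  if (abs(n_bins - round(n_bins)) > 1e-6)
    stop("duration must be an integer number of bins")
  if (timestep > bin_width + 1e-15)
    stop("timestep must not exceed bin_width")
  spb <- bin_width / timestep
  if (abs(spb - round(spb)) > 1e-6)
    stop("bin_width must be an integer multiple of timestep")
  min_xy <- 6 * optics$w0
  min_z <- 6 * optics$structural_parameter * optics$w0
  if (is.null(box_size)) box_size <- c(min_xy, min_xy, min_z)
  if (length(box_size) == 1L) box_size <- rep(box_size, 3L)
  if (box_size[1] < min_xy - 1e-9 || box_size[2] < min_xy - 1e-9 ||
      box_size[3] < min_z - 1e-9)
    stop("box too small: need >= 6 w0 laterally and >= 6 S w0 axially")
  ds <- vapply(species, `[[`, numeric(1), "diffusion_coefficient")
  if (triplet$dark_fraction > 0 && any(ds > 0)) {
    tau_d_min <- optics$w0^2 / (4 * max(ds[ds > 0]))
    if (triplet$relaxation_time >= tau_d_min)
      stop("triplet relaxation time must be shorter than the smallest diffusion time")
  }
  structure(list(
    species = species, optics = optics, triplet = triplet,
    mean_molecules_in_cv = mean_molecules_in_cv,
    bin_width = bin_width, duration = duration, repetitions = repetitions,
    background_rate = background_rate, box_size = box_size,
    timestep = timestep, origin_start = origin_start
  ), class = "sim_config")
}

#' Simulate photon-count traces by Brownian dynamics
#'
#' Propagates point emitters through a periodic box, evaluates the 3D
#' Gaussian detection profile at each position, applies per-molecule triplet
#' blinking, and draws Poisson photon counts per bin. The number of
#' simulated molecules is chosen so that the expected occupancy of the
#' effective volume equals `mean_molecules_in_cv`.
#'
#' @param config A [sim_config].
#' @param seed Integer RNG seed (reproducible for a fixed seed).
#' @param track_occupancy Also record the per-bin molecule count inside an
#'   ellipsoid of effective-volume size (direct occupancy oracle).
#' @return List of [fcs_trace] objects, one per repetition. When
#'   `track_occupancy = TRUE` each trace carries an `occupancy` vector.
#' @export
simulate_trace <- function(config, seed = 1L, track_occupancy = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(as.integer(seed))
  v_eff <- effective_volume(config$optics)
  v_box <- prod(config$box_size)
  n_mol <- max(1L, round(config$mean_molecules_in_cv * v_box / v_eff))
  fr <- vapply(config$species, `[[`, numeric(1), "fraction")
  # assign molecules to species by largest-remainder rounding of n_mol * f
  n_per <- floor(n_mol * fr)
  rem <- n_mol - sum(n_per)
  if (rem > 0) {
    idx <- order(n_mol * fr - n_per, decreasing = TRUE)
    n_per[idx[seq_len(rem)]] <- n_per[idx[seq_len(rem)]] + 1L
  }
  diff_coef <- rep(vapply(config$species, `[[`, numeric(1),
                          "diffusion_coefficient"), times = n_per)
  bright <- rep(vapply(config$species, `[[`, numeric(1), "brightness"),
                times = n_per)
  n_bins <- round(config$duration / config$bin_width)
  spb <- round(config$bin_width / config$timestep)
  gt <- list(
    mean_molecules_in_cv = config$mean_molecules_in_cv,
    n_simulated = n_mol, species = config$species,
    triplet = config$triplet, optics = config$optics
  )
  lapply(seq_len(config$repetitions), function(rep_i) {
    res <- .sim_trace_cpp(
      n_bins = n_bins, steps_per_bin = spb, dt = config$timestep,
      diff_coef = diff_coef, brightness = bright,
      w0 = config$optics$w0, s_param = config$optics$structural_parameter,
      box = config$box_size, background_khz = config$background_rate,
      triplet_T = config$triplet$dark_fraction,
      triplet_tau = config$triplet$relaxation_time,
      origin_start = config$origin_start,
      track_occupancy = track_occupancy
    )
    tr <- fcs_trace(res$counts, config$bin_width, repetition_id = rep_i,
                    ground_truth = gt)
    if (track_occupancy) tr$occupancy <- res$occupancy
    tr
  })
}

#' Generate a synthetic correlation curve from model parameters
#'
#' Evaluates the closed-form model on a lag grid and adds zero-mean
#' Gaussian noise. Two noise models are available:
#' \describe{
#'   \item{`"scaled_baseline"`}{sd = `noise_scale * (1 + g(tau))` — noise
#'     proportional to the displayed (baseline-1) amplitude, i.e. an
#'     absolute noise floor of about `noise_scale` on g. At typical
#'     amplitudes (1/N ~ 0.05) this floor dominates the correlation decay;
#'     it emulates number/brightness recovery conditions.}
#'   \item{`"proportional"`}{sd = `noise_scale * g(tau)` — noise
#'     proportional to the correlation signal itself, the regime in which
#'     diffusion times and fractions are recoverable (see the methods
#'     vignette).}
#' }
#'
#' @param params An [fcs_params] ground-truth parameter set.
#' @param lag_grid Strictly increasing positive lags in seconds
#'   (default [make_lag_grid]).
#' @param noise_scale Relative noise level (>= 0); 0 returns the exact model.
#' @param mean_rate Mean count rate in kHz to store on the curve (e.g.
#'   brightness x N); used downstream for CPM.
#' @param seed Optional integer seed for reproducible noise.
#' @param noise_model `"scaled_baseline"` (default) or `"proportional"`.
#' @return An [fcs_curve] whose `meta$ground_truth` holds `params`.
#' @export
generate_curve <- function(params, lag_grid = make_lag_grid(),
                           noise_scale = 0, mean_rate = NA_real_,
                           seed = NULL,
                           noise_model = c("scaled_baseline", "proportional")) {
  stopifnot(inherits(params, "fcs_params"))
  stopifnot(all(lag_grid > 0), !is.unsorted(lag_grid, strictly = TRUE))
  noise_model <- match.arg(noise_model)
  if (noise_scale < 0) stop("noise_scale must be non-negative")
  if (!is.null(seed)) set.seed(as.integer(seed))
  g0 <- fcs_model_g(lag_grid, params)
  sd <- if (noise_model == "scaled_baseline") noise_scale * (1 + g0)
        else noise_scale * g0
  g <- if (noise_scale > 0)
    g0 + stats::rnorm(length(g0), 0, sd) else g0
  fcs_curve(lag_grid, g, mean_rate = mean_rate,
            meta = list(method = "synthetic", noise_scale = noise_scale,
                        noise_model = noise_model, ground_truth = params))
}
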