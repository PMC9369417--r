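# Nonlinear least-squares fitting of the 1/2-component 3D diffusion +
# triplet model. Scale parameters (N, tau_T, tau_i, S) are fitted on a log
# scale; fractions, triplet fraction and offset on a linear scale, all under
# box constraints via nlminb.

# fast unvalidated model evaluation used inside the optimiser loop
.model_g_raw <- function(lag, n, trip_t, tau_t, f1, tau1, tau2, s, offset,
                         two_cpt) {
  cpt <- function(tau_d)
    1 / ((1 + lag / tau_d) * sqrt(1 + lag / (s^2 * tau_d)))
  d <- if (two_cpt) f1 * cpt(tau1) + (1 - f1) * cpt(tau2) else cpt(tau1)
  tr <- if (trip_t > 0) 1 + trip_t / (1 - trip_t) * exp(-lag / tau_t) else 1
  offset + (1 / n) * tr * d
}

# data-driven deterministic starting values: N from the short-lag
# amplitude, diffusion times from where the running-median-smoothed curve
# falls to 75% / 25% of that amplitude. Smoothing keeps per-point noise
# from triggering the decay thresholds at spuriously early lags.
.fit_init <- function(lags, g, two_cpt) {
  k <- min(length(g), 9L)
  if (k %% 2L == 0L) k <- k - 1L
  gs <- if (k >= 3L) stats::runmed(g, k, endrule = "median") else g
  g1 <- mean(gs[seq_len(min(8L, length(gs)))])
  n0 <- if (is.finite(g1) && g1 > 1e-6) 1 / g1 else 10
  n0 <- min(max(n0, 1e-2), 1e4)
  decay_lag <- function(frac) {
    idx <- which(gs <= frac * g1)
    if (length(idx) == 0L) return(stats::median(lags))
    lags[idx[1L]]
  }
  if (two_cpt) {
    t1 <- decay_lag(0.75)
    t2 <- decay_lag(0.25)
    if (t2 <= t1) t2 <- t1 * 10
    list(n0 = n0, tau1 = t1, tau2 = t2)
  } else {
    list(n0 = n0, tau1 = decay_lag(0.5), tau2 = NA_real_)
  }
}

#' Fit an FCS model to a correlation curve
#'
#' Weighted nonlinear least squares of the closed-form model [fcs_model_g]
#' against a measured or synthetic curve. Components are relabelled after
#' the fit so that `tau1 < tau2` (fast component first). The reduced
#' chi-squared is the weighted residual sum of squares divided by the
#' residual degrees of freedom; with unit weights (no per-lag scatter
#' available) this is essentially the mean squared residual, the scale on
#' which the chi-squared QC rule operates.
#'
#' @param curve An [fcs_curve].
#' @param components 1 or 2 diffusing components.
#' @param fix_s Fix the structural parameter at this value (e.g. 4); `NULL`
#'   leaves it free.
#' @param triplet Include the triplet term (default TRUE). Disable for
#'   triplet-free synthetic data.
#' @param weights Optional per-lag weights (e.g. `1/sigma^2`); default unit.
#' @param fit_offset Fit a baseline offset (default TRUE).
#' @return An `fcs_fit` object: fitted [fcs_params] in `$params`, plus
#'   `chi2`, `cpm` (kHz, mean rate / N), `qc_flags`, `converged`,
#'   `free_s_estimate` (NA unless S was free), `mean_rate`, `n_lags`.
#' @export
fit_curve <- function(curve, components = 2, fix_s = NULL, triplet = TRUE,
                      weights = NULL, fit_offset = TRUE) {
  stopifnot(inherits(curve, "fcs_curve"))
  components <- as.integer(components)
  stopifnot(components %in% c(1L, 2L))
  lags <- curve$lags
  g <- curve$g
  if (length(lags) < 10L) stop("curve must have at least 10 lags")
  w <- if (is.null(weights)) rep(1, length(g)) else weights
  stopifnot(length(w) == length(g), all(w > 0))

  flags <- character(0)
  # flat-curve screen: nothing to fit if the short-lag amplitude is within
  # the noise floor of its own estimate. Per-point noise comes from first
  # differences; the floor is the standard error of the leading-lag mean.
  sigma_pt <- stats::mad(diff(g)) / sqrt(2)
  k_lead <- min(length(g), max(8L, ceiling(length(g) * 0.1)))
  amp_est <- mean(g[seq_len(k_lead)])
  noise_floor <- sigma_pt / sqrt(k_lead)
  if (isTRUE(curve$meta$zero_mean) || max(g) <= 0 ||
      amp_est < 10 * noise_floor) {
    return(structure(list(
      params = NULL, chi2 = NA_real_, cpm = NA_real_,
      qc_flags = "no_correlation", converged = FALSE,
      free_s_estimate = NA_real_, mean_rate = curve$mean_rate,
      n_lags = length(lags), components = components
    ), class = "fcs_fit"))
  }

  two_cpt <- components == 2L
  init <- .fit_init(lags, g, two_cpt)
  free_s <- is.null(fix_s)

  # parameter vector layout (transformed space)
  nm <- c("log_n",
          if (triplet) c("trip_t", "log_tau_t"),
          if (two_cpt) "f1",
          "log_tau1",
          if (two_cpt) "log_tau2",
          if (free_s) "log_s",
          if (fit_offset) "offset")
  start <- c(log(init$n0),
             if (triplet) c(0.1, log(20e-6)),
             if (two_cpt) 0.5,
             log(init$tau1),
             if (two_cpt) log(init$tau2),
             if (free_s) log(4),
             if (fit_offset) 0)
  lower <- c(log(1e-3),
             if (triplet) c(0, log(1e-6)),
             if (two_cpt) 0,
             log(1e-6),
             if (two_cpt) log(1e-6),
             if (free_s) log(0.01),
             if (fit_offset) -1)
  upper <- c(log(1e4),
             if (triplet) c(0.8, log(1e-4)),
             if (two_cpt) 1,
             log(1),
             if (two_cpt) log(1),
             if (free_s) log(100),
             if (fit_offset) 1)
  names(start) <- names(lower) <- names(upper) <- nm

  unpack <- function(th) {
    list(
      n = exp(th[["log_n"]]),
      trip_t = if (triplet) th[["trip_t"]] else 0,
      tau_t = if (triplet) exp(th[["log_tau_t"]]) else 20e-6,
      f1 = if (two_cpt) th[["f1"]] else 1,
      tau1 = exp(th[["log_tau1"]]),
      tau2 = if (two_cpt) exp(th[["log_tau2"]]) else NA_real_,
      s = if (free_s) exp(th[["log_s"]]) else fix_s,
      offset = if (fit_offset) th[["offset"]] else 0
    )
  }
  obj <- function(th) {
    p <- unpack(th)
    r <- .model_g_raw(lags, p$n, p$trip_t, p$tau_t, p$f1, p$tau1,
                      if (two_cpt) p$tau2 else p$tau1, p$s, p$offset,
                      two_cpt) - g
    sum(w * r * r)
  }

  res <- tryCatch(
    stats::nlminb(start, obj, lower = lower, upper = upper,
                  control = list(iter.max = 800, eval.max = 1600,
                                 rel.tol = 1e-14, x.tol = 1e-12)),
    error = function(e) NULL)
  # polish from the first solution; helps exact round-trips on noise-free data
  if (!is.null(res)) {
    res2 <- tryCatch(
      stats::nlminb(res$par, obj, lower = lower, upper = upper,
                    control = list(iter.max = 400, eval.max = 800,
                                   rel.tol = 1e-15, x.tol = 1e-14)),
      error = function(e) NULL)
    if (!is.null(res2) && res2$objective <= res$objective) res <- res2
  }
  if (is.null(res) || !is.finite(res$objective)) {
    return(structure(list(
      params = NULL, chi2 = NA_real_, cpm = NA_real_,
      qc_flags = "fit_failed", converged = FALSE,
      free_s_estimate = NA_real_, mean_rate = curve$mean_rate,
      n_lags = length(lags), components = components
    ), class = "fcs_fit"))
  }

  p <- unpack(res$par)
  # relabel so component 1 is the fast one
  if (two_cpt && p$tau1 > p$tau2) {
    tmp <- p$tau1; p$tau1 <- p$tau2; p$tau2 <- tmp
    p$f1 <- 1 - p$f1
  }
  n_free <- length(start)
  dof <- max(1L, length(g) - n_free)
  chi2 <- res$objective / dof
  params <- fcs_params(n = p$n, triplet_fraction = p$trip_t,
                       triplet_time = p$tau_t, f1 = p$f1,
                       tau1 = p$tau1, tau2 = p$tau2, s = p$s,
                       offset = p$offset)
  # any finite optimum is reported; nlminb convergence codes other than 0
  # (e.g. "false convergence") still mark usable minima after the polish
  # pass, so only a non-finite objective or an optimiser error fails a fit
  converged <- TRUE
  structure(list(
    params = params, chi2 = chi2,
    cpm = if (is.na(curve$mean_rate)) NA_real_ else curve$mean_rate / p$n,
    qc_flags = flags, converged = converged,
    free_s_estimate = if (free_s) p$s else NA_real_,
    mean_rate = curve$mean_rate, n_lags = length(lags),
    components = components
  ), class = "fcs_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.fcs_fit <- function(x, ...) {
  if (is.null(x$params)) {
    cat("FCS fit: no parameters (flags:",
        paste(x$qc_flags, collapse = ", "), ")\n")
    return(invisible(x))
  }
  p <- x$params
  cat(sprintf("FCS fit (%d-component): N = %.3f, chi2 = %.3g\n",
              x$components, p$n, x$chi2))
  if (!is.na(p$tau2))
    cat(sprintf("  f_fast = %.3f, tau1 = %.4g us, tau2 = %.4g us\n",
                p$f1, p$tau1 * 1e6, p$tau2 * 1e6))
  if (!is.na(x$free_s_estimate))
    cat(sprintf("  free S estimate = %.3g\n", x$free_s_estimate))
  if (!is.na(x$cpm)) cat(sprintf("  CPM = %.3f kHz\n", x$cpm))
  if (length(x$qc_flags)) cat("  flags:", paste(x$qc_flags, collapse = ", "), "\n")
  invisible(x)
}

#' Two-stage fit with free then fixed structural parameter
#'
#' Stage 1 fits the model with the structural parameter S free and records
#' the estimate; curves whose free-S estimate falls outside `s_bounds`
#' (default `[0.1, 15]`) are flagged `structural_parameter_out_of_range`
#' for downstream exclusion. Stage 2 refits with S fixed (default 4) and
#' provides the reported parameters.
#'
#' @param curve An [fcs_curve].
#' @param components 1 or 2 diffusing components (default 2).
#' @param triplet Include the triplet term.
#' @param fix_s Stage-2 fixed structural parameter (default 4).
#' @param s_bounds Acceptance interval for the stage-1 free-S estimate.
#' @param ... Passed to [fit_curve].
#' @return An `fcs_fit` from stage 2, carrying `free_s_estimate`, combined
#'   `qc_flags`, and the full stage-1 fit in `$stage1`.
#' @export
two_stage_fit <- function(curve, components = 2, triplet = TRUE, fix_s = 4,
                          s_bounds = c(0.1, 15), ...) {
  stage1 <- fit_curve(curve, components = components, fix_s = NULL,
                      triplet = triplet, ...)
  flags <- character(0)
  s_est <- stage1$free_s_estimate
  if ("no_correlation" %in% stage1$qc_flags) {
    stage1$stage1 <- NULL
    return(stage1)
  }
  if (is.na(s_est) || s_est < s_bounds[1] || s_est > s_bounds[2])
    flags <- c(flags, "structural_parameter_out_of_range")
  stage2 <- fit_curve(curve, components = components, fix_s = fix_s,
                      triplet = triplet, ...)
  stage2$free_s_estimate <- s_est
  stage2$qc_flags <- unique(c(stage2$qc_flags, flags))
  stage2$stage1 <- stage1
  stage2
}
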