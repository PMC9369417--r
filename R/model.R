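#' FCS model parameter set
#'
#' Bundles the parameters of the one- or two-component 3D free-diffusion
#' autocorrelation model with an optional triplet (dark-state) term.
#'
#' @param n Mean number of molecules in the effective confocal volume (> 0).
#' @param triplet_fraction Equilibrium dark-state fraction T in `[0, 1)`.
#' @param triplet_time Triplet relaxation time in seconds (> 0).
#' @param f1 Fraction of molecules in the first (fast) diffusing component,
#'   in `[0, 1]`. The second component carries `1 - f1`.
#' @param tau1,tau2 Characteristic diffusion times in seconds. For a
#'   one-component model leave `tau2 = NA` and `f1 = 1`.
#' @param s Structural parameter, the axial-to-lateral aspect ratio
#'   `z0 / w0` of the confocal volume.
#' @param offset Baseline offset added to the correlation.
#'
#' @return An object of class `fcs_params` (a named list).
#' @examples
#' p <- fcs_params(n = 20, f1 = 0.6, tau1 = 1e-3, tau2 = 8e-2)
#' fcs_model_g(c(1e-6, 1e-3, 1), p)
#' @export
fcs_params <- function(n, triplet_fraction = 0, triplet_time = 20e-6,
                       f1 = 1, tau1 = 1e-3, tau2 = NA_real_,
                       s = 4, offset = 0) {
  stopifnot(is.numeric(n), length(n) == 1L, is.finite(n), n > 0)
  stopifnot(triplet_fraction >= 0, triplet_fraction < 1)
  stopifnot(triplet_time > 0)
  stopifnot(f1 >= 0, f1 <= 1)
  stopifnot(tau1 > 0)
  if (!is.na(tau2)) stopifnot(tau2 > 0)
  stopifnot(s > 0)
  p <- list(
    n = as.numeric(n),
    triplet_fraction = as.numeric(triplet_fraction),
    triplet_time = as.numeric(triplet_time),
    f1 = as.numeric(f1),
    tau1 = as.numeric(tau1),
    tau2 = as.numeric(tau2),
    s = as.numeric(s),
    offset = as.numeric(offset)
  )
  class(p) <- "fcs_params"
  p
}

#' @export
print.fcs_params <- function(x, ...) {
  cat("FCS model parameters\n")
  cat(sprintf("  N = %.4g  (amplitude 1/N = %.4g)\n", x$n, 1 / x$n))
  if (x$triplet_fraction > 0)
    cat(sprintf("  triplet: T = %.3g, tau_T = %.3g us\n",
                x$triplet_fraction, x$triplet_time * 1e6))
  if (is.na(x$tau2)) {
    cat(sprintf("  one component: tau = %.4g us\n", x$tau1 * 1e6))
  } else {
    cat(sprintf("  two components: f1 = %.3f, tau1 = %.4g us, tau2 = %.4g us\n",
                x$f1, x$tau1 * 1e6, x$tau2 * 1e6))
  }
  cat(sprintf("  S = %.3g, offset = %.3g\n", x$s, x$offset))
  invisible(x)
}

#' Closed-form FCS autocorrelation model
#'
#' Evaluates the fluctuation autocorrelation of free 3D diffusion through a
#' 3D Gaussian observation volume, with up to two diffusing components and a
#' triplet blinking term:
#' \deqn{g(\tau) = \mathrm{offset} + \frac{1}{N}
#'   \left[1 + \frac{T}{1-T} e^{-\tau/\tau_T}\right]
#'   \sum_i f_i \left(1 + \tau/\tau_i\right)^{-1}
#'   \left(1 + \tau/(S^2 \tau_i)\right)^{-1/2}}
#' The baseline convention is 0 at long lags (offset aside); the
#' display amplitude used in instrument software is `1 + g`.
#'
#' @param lag Lag times in seconds (vector, >= 0).
#' @param params An [fcs_params] object.
#' @return Numeric vector of g values, one per lag.
#' @export
fcs_model_g <- function(lag, params) {
  stopifnot(inherits(params, "fcs_params"))
  stopifnot(all(lag >= 0))
  one_cpt <- function(tau_d) {
    1 / ((1 + lag / tau_d) * sqrt(1 + lag / (params$s^2 * tau_d)))
  }
  diff_part <- if (is.na(params$tau2)) {
    one_cpt(params$tau1)
  } else {
    params$f1 * one_cpt(params$tau1) + (1 - params$f1) * one_cpt(params$tau2)
  }
  tt <- params$triplet_fraction
  trip <- if (tt > 0) {
    1 + tt / (1 - tt) * exp(-lag / params$triplet_time)
  } else 1
  params$offset + (1 / params$n) * trip * diff_part
}

#' Logarithmically spaced lag grid
#'
#' @param min_lag,max_lag Grid end points in seconds.
#' @param n Number of lags.
#' @return Strictly increasing numeric vector of lags.
#' @export
make_lag_grid <- function(min_lag = 1e-6, max_lag = 1, n = 160) {
  stopifnot(min_lag > 0, max_lag > min_lag, n >= 2)
  exp(seq(log(min_lag), log(max_lag), length.out = n))
}
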