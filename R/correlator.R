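#' Photon count trace
#'
#' One repetition of a fluorescence fluctuation recording: photon counts in
#' consecutive time bins.
#'
#' @param counts Non-negative integer photon counts per bin.
#' @param bin_width Bin width in seconds.
#' @param repetition_id,cell_id,group Optional provenance labels.
#' @param ground_truth Optional list of generating parameters (kept so that
#'   downstream recovery can be audited).
#' @return An `fcs_trace` object.
#' @export
fcs_trace <- function(counts, bin_width, repetition_id = 1L,
                      cell_id = NA_character_, group = NA_character_,
                      ground_truth = NULL) {
  stopifnot(is.numeric(counts), length(counts) >= 1L)
  stopifnot(all(counts >= 0), all(counts == round(counts)))
  stopifnot(is.numeric(bin_width), bin_width > 0)
  structure(list(
    counts = as.numeric(counts),
    bin_width = bin_width,
    duration = length(counts) * bin_width,
    repetition_id = repetition_id,
    cell_id = cell_id,
    group = group,
    ground_truth = ground_truth
  ), class = "fcs_trace")
}

#' @export
print.fcs_trace <- function(x, ...) {
  cat(sprintf(
    "FCS photon trace: %d bins x %.3g us = %.4g s, mean rate %.3f kHz\n",
    length(x$counts), x$bin_width * 1e6, x$duration, trace_mean_rate(x)))
  invisible(x)
}

#' Mean count rate of a trace in kHz
#' @param trace An [fcs_trace].
#' @return Mean photon count rate in kHz.
#' @export
trace_mean_rate <- function(trace) {
  stopifnot(inherits(trace, "fcs_trace"))
  mean(trace$counts) / trace$bin_width / 1000
}

#' Autocorrelation curve container
#'
#' @param lags Lag times in seconds, strictly increasing and positive.
#' @param g Fluctuation autocorrelation values (baseline-0 convention).
#' @param mean_rate Mean count rate in kHz.
#' @param n_effective Number of averaged products per lag (optional).
#' @param meta Optional list of provenance metadata. A `zero_mean` flag marks
#'   curves from all-zero traces whose correlation is undefined.
#' @return An `fcs_curve` object.
#' @export
fcs_curve <- function(lags, g, mean_rate = NA_real_, n_effective = NULL,
                      meta = list()) {
  stopifnot(is.numeric(lags), is.numeric(g), length(lags) == length(g))
  stopifnot(all(lags > 0), !is.unsorted(lags, strictly = TRUE))
  stopifnot(all(is.finite(g)))
  if (!is.na(mean_rate)) stopifnot(mean_rate >= 0)
  structure(list(
    lags = as.numeric(lags), g = as.numeric(g),
    mean_rate = mean_rate, n_effective = n_effective, meta = meta
  ), class = "fcs_curve")
}

#' @export
print.fcs_curve <- function(x, ...) {
  cat(sprintf(
    "FCS curve: %d lags [%.3g, %.3g] s, g(min lag) = %.4g, mean rate %.3g kHz\n",
    length(x$lags), min(x$lags), max(x$lags), x$g[1], x$mean_rate))
  invisible(x)
}

#' Remove the initial non-correlated period from a trace
#'
#' The first ~0.5 s of each confocal recording is dominated by uncorrelated
#' background and is dropped before correlation analysis.
#'
#' @param trace An [fcs_trace].
#' @param skip Seconds to drop from the start (default 0.5).
#' @return The trimmed [fcs_trace].
#' @export
trim_trace <- function(trace, skip = 0.5) {
  stopifnot(inherits(trace, "fcs_trace"))
  stopifnot(is.numeric(skip), skip >= 0)
  if (skip >= trace$duration)
    stop("`skip` must be smaller than the trace duration")
  n_drop <- round(skip / trace$bin_width)
  if (n_drop == 0L) return(trace)
  out <- trace
  out$counts <- trace$counts[-seq_len(n_drop)]
  out$duration <- length(out$counts) * trace$bin_width
  out
}

# Symmetric per-lag normalisation: products of the two overlapping segments
# are normalised by the product of the segment means, which suppresses bias
# from slow drift relative to a single global-mean normalisation.
.g_at_lags <- function(x, lags_bins, symmetric = TRUE) {
  n <- length(x)
  gm <- mean(x)
  vapply(lags_bins, function(k) {
    a <- x[seq_len(n - k)]
    b <- x[seq.int(k + 1L, n)]
    if (symmetric) {
      ma <- mean(a); mb <- mean(b)
      if (ma == 0 || mb == 0) return(0)
      mean(a * b) / (ma * mb) - 1
    } else {
      if (gm == 0) return(0)
      mean(a * b) / gm^2 - 1
    }
  }, numeric(1))
}

#' Direct (brute-force) autocorrelation at every integer-bin lag
#'
#' Reference correlator used as the oracle for the multi-tau implementation:
#' `g(tau) = <dF(t) dF(t+tau)> / <F>^2`, evaluated at every integer-bin lag
#' up to `max_lag`.
#'
#' @param trace An [fcs_trace] with at least 2 bins.
#' @param max_lag Maximum lag in seconds; must be below half the duration.
#' @param symmetric Use per-lag segment means for normalisation (default)
#'   rather than the global mean.
#' @return An [fcs_curve]. An all-zero trace yields g = 0 everywhere with
#'   `meta$zero_mean = TRUE` and a warning.
#' @export
autocorrelate_direct <- function(trace, max_lag = NULL, symmetric = TRUE) {
  stopifnot(inherits(trace, "fcs_trace"))
  n <- length(trace$counts)
  stopifnot(n >= 2L)
  if (is.null(max_lag)) max_lag <- trace$duration / 4
  if (max_lag >= trace$duration / 2)
    stop("`max_lag` must be below half the trace duration")
  kmax <- max(1L, floor(max_lag / trace$bin_width))
  kmax <- min(kmax, n - 2L)
  lags_bins <- seq_len(kmax)
  zero_mean <- mean(trace$counts) == 0
  if (zero_mean) {
    warning("all-zero trace: correlation undefined, returning g = 0")
    g <- rep(0, kmax)
  } else {
    g <- .g_at_lags(trace$counts, lags_bins, symmetric)
  }
  fcs_curve(
    lags = lags_bins * trace$bin_width, g = g,
    mean_rate = trace_mean_rate(trace),
    n_effective = n - lags_bins,
    meta = list(method = "direct", zero_mean = zero_mean,
                cell_id = trace$cell_id, repetition_id = trace$repetition_id,
                group = trace$group)
  )
}

#' Multi-tau autocorrelation on a quasi-logarithmic lag grid
#'
#' Computes the first `m` integer-bin lags at full resolution, then halves
#' the time resolution (pairwise binning) and computes lags `m/2+1 ... m` of
#' the coarsened signal per stage, spanning microseconds to seconds
#' efficiently. Normalisation matches [autocorrelate_direct]; the stage-0
#' lags of both agree exactly.
#'
#' @param trace An [fcs_trace] with at least `2 m` bins.
#' @param m Channels per stage (default 16, the common hardware convention).
#' @param max_lag Optional maximum lag in seconds (default duration / 4).
#' @param symmetric Normalisation convention, as in [autocorrelate_direct].
#' @return An [fcs_curve] with quasi-log-spaced lags.
#' @export
autocorrelate_multitau <- function(trace, m = 16L, max_lag = NULL,
                                   symmetric = TRUE) {
  stopifnot(inherits(trace, "fcs_trace"))
  m <- as.integer(m)
  stopifnot(m >= 2L, m %% 2L == 0L)
  n <- length(trace$counts)
  if (n < 2L * m) stop("trace shorter than 2 m bins")
  if (is.null(max_lag)) max_lag <- trace$duration / 4
  zero_mean <- mean(trace$counts) == 0
  if (zero_mean) warning("all-zero trace: correlation undefined, returning g = 0")

  x <- trace$counts
  dt <- trace$bin_width
  lags <- numeric(0)
  g <- numeric(0)
  neff <- integer(0)
  stage <- 0L
  repeat {
    lag_bins <- if (stage == 0L) seq_len(m) else seq.int(m %/% 2L + 1L, m)
    lag_s <- lag_bins * dt
    lag_bins <- lag_bins[lag_s <= max_lag & lag_bins <= length(x) - 2L]
    if (length(lag_bins) == 0L) break
    gs <- if (zero_mean) rep(0, length(lag_bins)) else
      .g_at_lags(x, lag_bins, symmetric)
    lags <- c(lags, lag_bins * dt)
    g <- c(g, gs)
    neff <- c(neff, length(x) - lag_bins)
    # coarsen by 2 for the next stage
    nn <- length(x) %/% 2L
    if (nn < m + 2L) break
    x <- (x[seq.int(1L, 2L * nn, by = 2L)] + x[seq.int(2L, 2L * nn, by = 2L)]) / 2
    dt <- dt * 2
    stage <- stage + 1L
    if (m * dt > 2 * max_lag && stage > 1L) break
  }
  ord <- order(lags)
  fcs_curve(
    lags = lags[ord], g = g[ord],
    mean_rate = trace_mean_rate(trace),
    n_effective = neff[ord],
    meta = list(method = "multitau", m = m, zero_mean = zero_mean,
                cell_id = trace$cell_id, repetition_id = trace$repetition_id,
                group = trace$group)
  )
}

#' Pointwise average of correlation curves on a shared lag grid
#'
#' @param curves List of [fcs_curve] objects with identical lag grids.
#' @return An [fcs_curve] with the mean g and mean count rate.
#' @export
average_curves <- function(curves) {
  stopifnot(is.list(curves), length(curves) >= 1L)
  stopifnot(all(vapply(curves, inherits, logical(1), "fcs_curve")))
  lags <- curves[[1L]]$lags
  for (cv in curves[-1L]) {
    if (length(cv$lags) != length(lags) ||
        max(abs(cv$lags - lags)) > 1e-12 * max(lags))
      stop("curves must share an identical lag grid")
  }
  gmat <- vapply(curves, function(cv) cv$g, numeric(length(lags)))
  gmat <- matrix(gmat, nrow = length(lags))
  rates <- vapply(curves, function(cv) cv$mean_rate, numeric(1))
  fcs_curve(
    lags = lags, g = rowMeans(gmat),
    mean_rate = mean(rates),
    meta = list(method = "average", n_curves = length(curves))
  )
}
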