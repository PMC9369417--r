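# Rank-normalisation coupling of whole-cell intensity distributions to FCS
# molecule-number distributions (Q-Q matching), without re-implementing any
# image segmentation.

#' Map a sample onto a reference distribution by rank normalisation
#'
#' Each sample value is replaced by the reference empirical quantile at the
#' sample value's own (mid-)rank, using plotting positions `(k - 0.5) / n`
#' and linear interpolation between reference order statistics (quantile
#' type 5). The mapping is monotone, so sample ordering (and any Spearman
#' correlation with the original values) is preserved exactly; applying it
#' with the sample as its own reference returns the sample unchanged.
#'
#' @param sample Numeric vector to rescale (>= 2 values).
#' @param reference Numeric vector providing the target distribution
#'   (>= 2 values). A single-element sample maps to the reference median.
#' @return Numeric vector, same length and order as `sample`.
#' @export
rank_normalize <- function(sample, reference) {
  sample <- sample[!is.na(sample)]
  reference <- reference[!is.na(reference)]
  if (length(sample) < 1L || length(reference) < 2L)
    stop("sample must be non-empty and reference have >= 2 values")
  if (length(sample) == 1L)
    return(stats::median(reference))
  p <- (rank(sample, ties.method = "average") - 0.5) / length(sample)
  stats::quantile(reference, probs = p, type = 5, names = FALSE)
}

#' Paired quantiles for a Q-Q comparison of two samples
#'
#' @param a,b Numeric vectors (each >= 2 values).
#' @param n_quantiles Number of probability points, spread evenly over
#'   1%...99% (default 99).
#' @return data.frame with columns `prob`, `q_a`, `q_b`.
#' @export
qq_pairs <- function(a, b, n_quantiles = 99) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2L || length(b) < 2L) stop("each input needs >= 2 values")
  stopifnot(n_quantiles >= 1)
  probs <- seq(0.01, 0.99, length.out = n_quantiles)
  data.frame(
    prob = probs,
    q_a = stats::quantile(a, probs, type = 5, names = FALSE),
    q_b = stats::quantile(b, probs, type = 5, names = FALSE)
  )
}
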