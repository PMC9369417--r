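# Population-level statistical layer: two-sample tests, normality screen and
# the CPM-vs-amplitude regression check.

.test_report <- function(test, statistic, p_value, n, direction = NA_character_,
                         flags = character(0)) {
  structure(list(test = test, statistic = statistic, p_value = p_value,
                 n = n, direction = direction, flags = flags),
            class = "fcs_test")
}

#' @export
print.fcs_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, two-tailed p = %.4g (n = %s)\n",
              x$test, x$statistic, x$p_value, paste(x$n, collapse = ", ")))
  if (!is.na(x$direction)) cat("  direction:", x$direction, "\n")
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Mann-Whitney U test (two-tailed)
#'
#' Rank-sum test for a location shift between two independent samples.
#' When both groups have at most 8 observations and there are no ties the
#' two-tailed p-value is exact, computed by complete enumeration of all
#' rank assignments; otherwise the normal approximation with mid-rank tie
#' correction and continuity correction is used.
#'
#' @param a,b Numeric vectors (each non-empty).
#' @return An `fcs_test` report with the U statistic of group `a`.
#' @export
mann_whitney <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  n1 <- length(a); n2 <- length(b)
  if (n1 < 1L || n2 < 1L) stop("both groups must be non-empty")
  pooled <- c(a, b)
  r <- rank(pooled)
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  has_ties <- anyDuplicated(pooled) > 0L
  if (!has_ties && n1 <= 8L && n2 <= 8L) {
    # exact: enumerate all C(n1+n2, n1) assignments of ranks to group a
    combs <- utils::combn(n1 + n2, n1)
    us <- colSums(combs) - n1 * (n1 + 1) / 2
    mu <- n1 * n2 / 2
    p <- mean(abs(us - mu) >= abs(u - mu) - 1e-9)
  } else {
    mu <- n1 * n2 / 2
    nn <- n1 + n2
    tie_tab <- table(pooled)
    tie_corr <- sum(tie_tab^3 - tie_tab) / (nn * (nn - 1))
    sigma2 <- n1 * n2 / 12 * ((nn + 1) - tie_corr)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- max(0, abs(u - mu) - 0.5) / sqrt(sigma2)
      p <- 2 * stats::pnorm(z, lower.tail = FALSE)
    }
  }
  dir <- if (u > n1 * n2 / 2) "a > b" else if (u < n1 * n2 / 2) "a < b" else "none"
  .test_report("Mann-Whitney U", u, min(p, 1), c(n1, n2), dir)
}

#' D'Agostino-Pearson omnibus K2 normality test
#'
#' Combines transformed skewness and kurtosis z-scores into
#' `K2 = Z1^2 + Z2^2`, referred to a chi-squared distribution with 2 df.
#' Requires n >= 20 (the transformation's validity domain); smaller samples
#' are returned with an `insufficient_n` flag and no p-value.
#'
#' @param values Numeric vector.
#' @return An `fcs_test` report with statistic K2.
#' @export
dagostino_k2 <- function(values) {
  x <- values[!is.na(values)]
  n <- length(x)
  if (stats::sd(x) == 0) stop("constant input: normality test undefined")
  if (n < 20L)
    return(.test_report("D'Agostino-Pearson K2", NA_real_, NA_real_, n,
                        flags = "insufficient_n"))
  m <- mean(x)
  m2 <- mean((x - m)^2); m3 <- mean((x - m)^3); m4 <- mean((x - m)^4)
  b1 <- m3 / m2^1.5
  b2 <- m4 / m2^2
  # skewness z (D'Agostino 1970)
  y <- b1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(log(sqrt(w2)))
  alpha <- sqrt(2 / (w2 - 1))
  z1 <- delta * log(y / alpha + sqrt((y / alpha)^2 + 1))
  # kurtosis z (Anscombe & Glynn 1983)
  eb2 <- 3 * (n - 1) / (n + 1)
  vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (b2 - eb2) / sqrt(vb2)
  sqrtb1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  aa <- 6 + 8 / sqrtb1 * (2 / sqrtb1 + sqrt(1 + 4 / sqrtb1^2))
  z2 <- ((1 - 2 / (9 * aa)) -
           ((1 - 2 / aa) / (1 + xk * sqrt(2 / (aa - 4))))^(1 / 3)) *
    sqrt(9 * aa / 2)
  k2 <- z1^2 + z2^2
  p <- stats::pchisq(k2, df = 2, lower.tail = FALSE)
  .test_report("D'Agostino-Pearson K2", k2, p, n)
}

#' Ordinary least-squares regression with R-squared
#'
#' Used to monitor the relation between CPM and amplitude measurements; a
#' comparable R-squared across strains indicates the molecule-number
#' comparison is free of brightness artefacts.
#'
#' @param x,y Numeric vectors of equal length (n >= 3).
#' @return List (class `fcs_regression`) with `slope`, `intercept`,
#'   `r_squared`, `n`.
#' @export
linreg_r2 <- function(x, y) {
  keep <- !(is.na(x) | is.na(y))
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L || length(y) != n) stop("need >= 3 paired values")
  if (stats::sd(x) == 0) stop("zero variance in x")
  fit <- stats::lm.fit(cbind(1, x), y)
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  structure(list(slope = unname(fit$coefficients[2]),
                 intercept = unname(fit$coefficients[1]),
                 r_squared = r2, n = n),
            class = "fcs_regression")
}

#' @export
print.fcs_regression <- function(x, ...) {
  cat(sprintf("OLS: y = %.4g x + %.4g, R^2 = %.3f (n = %d)\n",
              x$slope, x$intercept, x$r_squared, x$n))
  invisible(x)
}

#' Unpaired (Welch) t-test, two-tailed
#'
#' Parametric comparison used for normally distributed mean measurements
#' (e.g. per-cell diffusion coefficients). The unequal-variance Welch form
#' is used.
#'
#' @param a,b Numeric vectors (each >= 2 values).
#' @return An `fcs_test` report.
#' @export
unpaired_t <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2L || length(b) < 2L) stop("each group needs >= 2 values")
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    p <- if (mean(a) == mean(b)) 1 else 0
    return(.test_report("Welch t", if (p == 1) 0 else Inf, p,
                        c(length(a), length(b)),
                        if (mean(a) > mean(b)) "a > b"
                        else if (mean(a) < mean(b)) "a < b" else "none"))
  }
  ht <- stats::t.test(a, b, var.equal = FALSE)
  dir <- if (mean(a) > mean(b)) "a > b" else if (mean(a) < mean(b)) "a < b" else "none"
  .test_report("Welch t", unname(ht$statistic), ht$p.value,
               c(length(a), length(b)), dir)
}
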