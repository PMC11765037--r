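#' D'Agostino-Pearson omnibus normality test
#'
#' Combines the sample-size-corrected skewness and kurtosis z-scores into
#' the K-squared statistic, referred to a chi-squared distribution with two
#' degrees of freedom. Requires n >= 8; below that the kurtosis
#' transformation is undefined.
#'
#' @param x numeric sample.
#' @return list with \code{statistic} (K2), \code{p.value}, \code{z_skew},
#'   \code{z_kurt}, \code{n}.
#' @references D'Agostino, Belanger & D'Agostino Jr (1990), Am. Stat. 44.
#' @export
dagostino_pearson <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 8L) stop("D'Agostino-Pearson test requires n >= 8")
  m <- mean(x)
  m2 <- mean((x - m)^2)
  m3 <- mean((x - m)^3)
  m4 <- mean((x - m)^4)
  g1 <- m3 / m2^1.5
  b2 <- m4 / m2^2

  # skewness: D'Agostino (1970) transformation
  y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(log(sqrt(w2)))
  alpha <- sqrt(2 / (w2 - 1))
  z1 <- delta * log(y / alpha + sqrt((y / alpha)^2 + 1))

  # kurtosis: Anscombe & Glynn (1983) transformation
  eb2 <- 3 * (n - 1) / (n + 1)
  vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xx <- (b2 - eb2) / sqrt(vb2)
  sqrtb1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  a <- 6 + 8 / sqrtb1 * (2 / sqrtb1 + sqrt(1 + 4 / sqrtb1^2))
  z2 <- ((1 - 2 / (9 * a)) -
           ((1 - 2 / a) / (1 + xx * sqrt(2 / (a - 4))))^(1 / 3)) /
    sqrt(2 / (9 * a))

  k2 <- z1^2 + z2^2
  list(statistic = k2, p.value = stats::pchisq(k2, df = 2, lower.tail = FALSE),
       z_skew = z1, z_kurt = z2, n = n)
}

#' Normality-gated two-sample comparison
#'
#' The comparison rule used for section statistics: both samples are tested
#' for normality with the D'Agostino-Pearson omnibus test at \code{alpha};
#' when both pass, a two-tailed Student's t-test is used, otherwise a
#' two-sided Mann-Whitney U test. Samples too small for the normality test
#' (n < 8) are routed to the Mann-Whitney branch.
#'
#' @param a,b numeric samples (e.g. per-patient mean JSD values of one
#'   section under two conditions).
#' @param alpha significance level for both the normality gate and the
#'   final significance flag.
#' @return list of class \code{section_test}: \code{test_used} ("t" or
#'   "mann-whitney"), \code{p_value}, \code{significant}, \code{n_a},
#'   \code{n_b}, \code{normality_p} (length-2, NA when skipped).
#' @export
compare_sections <- function(a, b, alpha = 0.05) {
  a <- a[is.finite(a)]
  b <- b[is.finite(b)]
  if (length(a) < 3L || length(b) < 3L)
    stop("need at least 3 values per group")
  norm_p <- c(NA_real_, NA_real_)
  normal <- FALSE
  if (length(a) >= 8L && length(b) >= 8L) {
    norm_p <- c(dagostino_pearson(a)$p.value, dagostino_pearson(b)$p.value)
    normal <- all(norm_p > alpha)
  }
  if (normal) {
    ht <- stats::t.test(a, b, var.equal = TRUE)
    test_used <- "t"
  } else {
    ht <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE))
    test_used <- "mann-whitney"
  }
  structure(list(test_used = test_used, p_value = ht$p.value,
                 significant = ht$p.value < alpha,
                 n_a = length(a), n_b = length(b),
                 normality_p = norm_p),
            class = "section_test")
}

#' @export
print.section_test <- function(x, ...) {
  cat(sprintf("%s test: p = %.4g%s (n = %d vs %d)\n",
              if (x$test_used == "t") "Student's t" else "Mann-Whitney U",
              x$p_value, if (x$significant) " *" else "", x$n_a, x$n_b))
  invisible(x)
}
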