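#' Generate f^(-k) power-law noise
#'
#' Spectral synthesis: the discrete Fourier transform of white Gaussian
#' noise is shaped by \eqn{f^{-k/2}} (so the power spectrum follows
#' \eqn{f^{-k}}), the DC bin is zeroed, and the inverse transform is taken.
#' The output is standardized to zero mean and unit variance. \code{k = 0}
#' is white noise, \code{k = 2} Brownian-like noise.
#'
#' @param k spectral exponent (the study range is 0 to 3; values outside
#'   trigger a warning).
#' @param n series length (a power of 2 is fastest).
#' @param seed optional integer seed; when given, the series is a pure
#'   function of \code{(k, n, seed)}.
#' @return numeric series of length \code{n}.
#' @examples
#' x <- generate_knoise(2, 4096, seed = 1)
#' @export
generate_knoise <- function(k, n, seed = NULL) {
  if (k < 0 || k > 3) warning("k outside the calibrated range [0, 3]")
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(n)
  w <- stats::rnorm(n)
  X <- stats::fft(w)
  # symmetric frequency magnitudes: bin j corresponds to f = min(j, n-j)/n
  j <- 0:(n - 1L)
  f <- pmin(j, n - j) / n
  shape <- c(0, f[-1L]^(-k / 2)) # DC removed
  y <- Re(stats::fft(X * shape, inverse = TRUE)) / n
  (y - mean(y)) / stats::sd(y)
}

#' Log-log periodogram slope
#'
#' Ordinary least-squares slope of log power versus log frequency over the
#' positive-frequency periodogram; for \eqn{f^{-k}} noise the slope
#' estimates \eqn{-k}.
#'
#' @param x numeric series.
#' @return slope estimate.
#' @export
periodogram_slope <- function(x) {
  n <- length(x)
  P <- Mod(stats::fft(x))^2 / n
  j <- seq_len(n %/% 2 - 1L) # positive frequencies, DC and Nyquist excluded
  lf <- log(j / n)
  lp <- log(P[j + 1L])
  keep <- is.finite(lp)
  stats::coef(stats::lm(lp[keep] ~ lf[keep]))[[2L]]
}

#' H x C plane landmarks of k-noises
#'
#' Locates \eqn{f^{-k}} stochastic processes in the entropy-complexity
#' plane by Monte-Carlo: for each exponent, \code{n_realizations} series are
#' synthesized, ordinal PDFs estimated, and the mean \eqn{(H, C)} position
#' recorded. These landmarks anchor the interpretation of empirical
#' trajectories: white noise (k = 0) sits at \eqn{H \approx 1, C \approx 0}
#' and increasing \eqn{k} moves down in entropy along the stochastic arc.
#'
#' @param k_values spectral exponents (the study uses 2, 2.5 and 3 as plane
#'   references, within the range 0 to 3).
#' @param D,tau ordinal embedding parameters.
#' @param n series length per realization.
#' @param n_realizations Monte-Carlo realizations per exponent.
#' @param seed integer seed for reproducibility.
#' @return data.frame of class \code{knoise_landmarks}: columns \code{k},
#'   \code{H}, \code{C}, \code{Q}, plus attributes \code{n},
#'   \code{n_realizations}, \code{seed}.
#' @export
knoise_landmarks <- function(k_values = c(0, 1, 2, 2.5, 3), D = 4L, tau = 2L,
                             n = 2^15, n_realizations = 10L, seed = 1L) {
  rows <- lapply(k_values, function(k) {
    hc <- vapply(seq_len(n_realizations), function(i) {
      x <- generate_knoise(k, n, seed = seed + 7919L * i + round(1000 * k))
      p <- ordinal_pdf(x, D, tau, warn_short = FALSE)
      s <- statistical_complexity(p)
      c(s$H, s$C, s$Q)
    }, numeric(3))
    data.frame(k = k, H = mean(hc[1L, ]), C = mean(hc[2L, ]),
               Q = mean(hc[3L, ]))
  })
  out <- do.call(rbind, rows)
  attr(out, "n") <- n
  attr(out, "n_realizations") <- n_realizations
  attr(out, "seed") <- seed
  class(out) <- c("knoise_landmarks", "data.frame")
  out
}
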