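#' Ordinal (Bandt-Pompe) pattern encoding of a time series
#'
#' Assigns each length-\code{D}, delay-\code{tau} subsequence of \code{x} the
#' index of its ordinal pattern, i.e. the rank ordering of its values.
#' Amplitudes are discarded; only the relative ordering within each window
#' matters, which makes the encoding invariant under monotone rescaling.
#'
#' Patterns are indexed by the position of the window's rank word in the
#' reverse-lexicographic ordering of the permutations of \code{1:D}. For
#' \code{D = 3} the six patterns are, in index order,
#' (321), (312), (231), (213), (132), (123): the fully descending window is
#' type 1 and the fully ascending window is type \code{D!}. Ties are broken
#' by temporal order (the earlier sample receives the lower rank).
#'
#' @param x numeric series.
#' @param D embedding dimension (window length), an integer >= 2.
#' @param tau embedding delay in samples, an integer >= 1.
#' @return integer vector of pattern indices in \code{1:factorial(D)}, one per
#'   window, of length \code{length(x) - (D - 1) * tau}.
#' @seealso [ordinal_pdf()], [ordinal_patterns()]
#' @examples
#' ordinal_encode(c(1, 2, 5, 4, 3, 5), D = 3, tau = 1) # 6 5 1 4
#' @export
ordinal_encode <- function(x, D = 4L, tau = 2L) {
  x <- as.numeric(x)
  if (length(x) == 0L || anyNA(x) || any(!is.finite(x)))
    stop("series must be non-empty and contain only finite values")
  D <- as.integer(D)
  tau <- as.integer(tau)
  if (is.na(D) || D < 2L) stop("D must be an integer >= 2")
  if (is.na(tau) || tau < 1L) stop("tau must be an integer >= 1")
  span <- (D - 1L) * tau
  K <- length(x) - span
  if (K < 1L)
    stop(sprintf("series of length %d too short for one window at D=%d, tau=%d (needs >= %d samples)",
                 length(x), D, tau, span + 1L))

  # window matrix W[k, d] = x[k + (d-1) tau]
  W <- matrix(0, K, D)
  for (d in seq_len(D)) W[, d] <- x[seq.int(1L + (d - 1L) * tau, length.out = K)]

  # rank word per window; ties broken by temporal order (earlier = lower rank)
  r <- matrix(1L, K, D)
  for (d in seq_len(D)) {
    for (e in seq_len(D)) {
      if (e == d) next
      r[, d] <- r[, d] + (W[, e] < W[, d] | (W[, e] == W[, d] & e < d))
    }
  }

  # lexicographic rank of the rank word via its Lehmer code, then reverse
  fct <- factorial(D - seq_len(D)) # (D-1)!, (D-2)!, ..., 0!
  lex <- rep.int(1, K)
  for (i in seq_len(D - 1L)) {
    ci <- rep.int(0L, K)
    for (j in seq.int(i + 1L, D)) ci <- ci + (r[, j] < r[, i])
    lex <- lex + ci * fct[i]
  }
  as.integer(factorial(D) + 1 - lex)
}

#' Ordinal pattern labels in index order
#'
#' @param D embedding dimension.
#' @return character vector of length \code{factorial(D)}: the rank word of
#'   each pattern index, e.g. \code{"321"} for the descending type 1 at D = 3.
#' @export
ordinal_patterns <- function(D = 4L) {
  D <- as.integer(D)
  if (D < 2L) stop("D must be >= 2")
  perms <- function(v) {
    if (length(v) == 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
    }
    out
  }
  labs <- vapply(perms(seq_len(D)), paste, character(1), collapse = "")
  rev(labs) # lexicographic list reversed -> reverse-lexicographic index order
}

#' Estimate the Bandt-Pompe ordinal probability distribution
#'
#' Counts the ordinal patterns of all \code{length(x) - (D-1) tau} windows and
#' normalizes by the number of windows, so the probabilities always sum to 1
#' for any delay.
#'
#' @inheritParams ordinal_encode
#' @param warn_short warn when the number of windows is small relative to the
#'   alphabet size \code{D!} (fewer than 5 windows per pattern), in which case
#'   the estimated distribution is unreliable.
#' @return an object of class \code{ordinal_pdf}: list with \code{probs}
#'   (length \code{D!}), \code{D}, \code{tau}, \code{n_windows}.
#' @examples
#' p <- ordinal_pdf(rnorm(1000), D = 4, tau = 2)
#' sum(p$probs)
#' @export
ordinal_pdf <- function(x, D = 4L, tau = 2L, warn_short = TRUE) {
  idx <- ordinal_encode(x, D, tau)
  L <- factorial(as.integer(D))
  K <- length(idx)
  if (warn_short && K < 5L * L)
    warning(sprintf("only %d windows for %d patterns; ordinal PDF estimate is unreliable (series should be much longer than D!)",
                    K, L))
  new_ordinal_pdf(tabulate(idx, nbins = L) / K, D = as.integer(D),
                  tau = as.integer(tau), n_windows = K)
}

#' Construct an ordinal_pdf from probabilities
#'
#' Low-level constructor used when a distribution arises from something other
#' than direct counting (e.g. the mean control PDF).
#'
#' @param probs numeric probability vector of length \code{D!}.
#' @param D,tau embedding parameters the distribution refers to.
#' @param n_windows number of windows behind the estimate (informational).
#' @return \code{ordinal_pdf} object.
#' @export
new_ordinal_pdf <- function(probs, D, tau, n_windows = NA_integer_) {
  probs <- as.numeric(probs)
  D <- as.integer(D)
  if (length(probs) != factorial(D))
    stop(sprintf("probs must have length D! = %d", factorial(D)))
  if (any(probs < -1e-12) || abs(sum(probs) - 1) > 1e-8)
    stop("probs must be non-negative and sum to 1")
  structure(list(probs = pmax(probs, 0), D = D, tau = as.integer(tau),
                 n_windows = n_windows),
            class = "ordinal_pdf")
}

#' @export
print.ordinal_pdf <- function(x, ...) {
  cat(sprintf("Ordinal pattern PDF: D = %d, tau = %d (%d patterns), %s windows\n",
              x$D, x$tau, length(x$probs),
              ifelse(is.na(x$n_windows), "?", format(x$n_windows))))
  top <- order(x$probs, decreasing = TRUE)[seq_len(min(5L, length(x$probs)))]
  labs <- ordinal_patterns(x$D)
  cat("Top patterns:\n")
  for (i in top)
    cat(sprintf("  %2d (%s): %.4f\n", i, labs[i], x$probs[i]))
  invisible(x)
}

#' @export
as.data.frame.ordinal_pdf <- function(x, ...) {
  data.frame(pattern = seq_along(x$probs),
             label = ordinal_patterns(x$D),
             probability = x$probs)
}

.probs <- function(p) {
  if (inherits(p, "ordinal_pdf")) p$probs
  else if (is.numeric(p)) p
  else stop("expected an ordinal_pdf or a numeric probability vector")
}

#' Shannon entropy of a probability distribution (nats)
#'
#' \eqn{S = -\sum_j p_j \ln p_j} with the convention \eqn{0 \ln 0 = 0}.
#'
#' @param p an \code{ordinal_pdf} or numeric probability vector.
#' @return entropy in nats, in \eqn{[0, \ln L]}.
#' @export
shannon_entropy <- function(p) {
  p <- .probs(p)
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Normalized Shannon entropy
#'
#' \eqn{H = S / \ln L}: 0 for a degenerate distribution, 1 for the uniform.
#'
#' @inheritParams shannon_entropy
#' @return value in \eqn{[0, 1]}.
#' @export
normalized_entropy <- function(p) {
  p <- .probs(p)
  shannon_entropy(p) / log(length(p))
}

#' Jensen-Shannon divergence between two distributions
#'
#' \eqn{D_{JS}[p, q] = S[(p+q)/2] - S[p]/2 - S[q]/2} (nats). Symmetric,
#' non-negative, zero iff \eqn{p = q}; its square root is a metric.
#'
#' @param p,q \code{ordinal_pdf} objects or probability vectors over the same
#'   alphabet.
#' @return divergence in \eqn{[0, \ln 2]}.
#' @export
jensen_shannon <- function(p, q) {
  p <- .probs(p)
  q <- .probs(q)
  if (length(p) != length(q))
    stop(sprintf("distributions have different alphabet sizes (%d vs %d)",
                 length(p), length(q)))
  d <- shannon_entropy((p + q) / 2) - shannon_entropy(p) / 2 - shannon_entropy(q) / 2
  max(d, 0) # clamp tiny negative rounding
}

# JSD between a degenerate distribution and the uniform over L symbols:
# the maximum of DJS(., uniform) over the simplex. Closed form used for the
# disequilibrium normalization constant Q0 = 1 / max DJS.
.jsd_max <- function(L) {
  # mixture m = (delta + uniform)/2 has one entry (L+1)/(2L), L-1 entries 1/(2L)
  sm <- -((L + 1) / (2 * L)) * log((L + 1) / (2 * L)) +
    ((L - 1) / (2 * L)) * log(2 * L)
  sm - log(L) / 2
}

#' Disequilibrium of a distribution
#'
#' Normalized Jensen-Shannon distance from \code{p} to the uniform
#' distribution: \eqn{Q = Q_0 D_{JS}[p, p_e]}, with \eqn{Q_0} the inverse of
#' the maximal possible distance (attained by a degenerate distribution), so
#' \eqn{Q \in [0, 1]}, 0 iff uniform, 1 iff degenerate.
#'
#' @inheritParams shannon_entropy
#' @return value in \eqn{[0, 1]}.
#' @export
disequilibrium <- function(p) {
  p <- .probs(p)
  L <- length(p)
  jensen_shannon(p, rep.int(1 / L, L)) / .jsd_max(L)
}

#' Entropy, disequilibrium and statistical complexity of a distribution
#'
#' Computes the coordinates of \code{p} in the entropy-complexity causal
#' plane: normalized entropy \eqn{H}, disequilibrium \eqn{Q}, and statistical
#' complexity \eqn{C = H Q}. \eqn{C} vanishes both for fully ordered
#' (degenerate) and fully random (uniform) distributions and is maximal at
#' intermediate entropy, making the pair \eqn{(H, C)} a two-dimensional
#' signature of the underlying dynamics.
#'
#' @inheritParams shannon_entropy
#' @return object of class \code{hc_point}: list with numeric \code{H},
#'   \code{C}, \code{Q}.
#' @examples
#' statistical_complexity(rep(1/24, 24)) # H = 1, C = 0
#' @export
statistical_complexity <- function(p) {
  p <- .probs(p)
  H <- normalized_entropy(p)
  Q <- disequilibrium(p)
  structure(list(H = H, C = H * Q, Q = Q), class = "hc_point")
}

#' @export
print.hc_point <- function(x, ...) {
  cat(sprintf("HxC point: H = %.4f, C = %.4f (Q = %.4f)\n", x$H, x$C, x$Q))
  invisible(x)
}

#' @export
as.data.frame.hc_point <- function(x, ...) {
  data.frame(H = x$H, C = x$C, Q = x$Q)
}

#' Serialize an ordinal PDF to CSV
#'
#' Writes columns \code{pattern}, \code{label}, \code{probability}.
#'
#' @param p \code{ordinal_pdf}.
#' @param file path.
#' @export
write_ordinal_pdf <- function(p, file) {
  stopifnot(inherits(p, "ordinal_pdf"))
  utils::write.csv(as.data.frame(p), file, row.names = FALSE)
  invisible(file)
}
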