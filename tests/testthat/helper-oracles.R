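# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's vectorized code paths.

# all permutations of 1:D in reverse-lexicographic order, as rank words
perms_revlex <- function(D) {
  rec <- function(v) {
    if (length(v) == 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) for (r in rec(v[-i])) out <- c(out, list(c(v[i], r)))
    out
  }
  rev(rec(seq_len(D)))
}

# naive per-window pattern typing: explicit rank word, looked up in the
# enumeration table
naive_encode <- function(x, D, tau) {
  K <- length(x) - (D - 1) * tau
  tab <- vapply(perms_revlex(D), paste, character(1), collapse = "-")
  vapply(seq_len(K), function(k) {
    w <- x[k + (0:(D - 1)) * tau]
    r <- rank(w, ties.method = "first")
    match(paste(r, collapse = "-"), tab)
  }, integer(1))
}

naive_pdf <- function(x, D, tau) {
  idx <- naive_encode(x, D, tau)
  tabulate(idx, nbins = factorial(D)) / length(idx)
}

# random probability vectors (Dirichlet via gamma)
rdirichlet <- function(n, L, alpha = 1) {
  a <- matrix(stats::rgamma(n * L, alpha), n, L)
  a / rowSums(a)
}

# direct entropy/JSD evaluation, independent of the package implementation
direct_entropy <- function(p) {
  q <- p[p > 0]
  -sum(q * log(q))
}

direct_jsd <- function(p, q) {
  direct_entropy((p + q) / 2) - direct_entropy(p) / 2 - direct_entropy(q) / 2
}

# simple synthetic test record: regular Gaussian-bump beats on 8 leads
# (independent of the package generator) with known R times
simple_beats_record <- function(dur_s = 20, fs = 1000, rr_s = 0.8,
                                noise = 0, seed = 1) {
  set.seed(seed)
  n <- dur_s * fs
  t <- seq_len(n) / fs
  r_times <- seq(0.5, dur_s - 0.5, by = rr_s)
  # constant baseline dipole so the modulus baseline sits away from zero
  xyz <- matrix(rep(c(150, 100, 80), each = n), n, 3)
  for (r in r_times) {
    for (ax in 1:3) {
      amp <- c(800, 1100, 350)[ax]
      xyz[, ax] <- xyz[, ax] + amp * exp(-0.5 * ((t - r) / 0.011)^2) +
        0.25 * amp * exp(-0.5 * ((t - r - 0.18) / 0.05)^2)
    }
  }
  K <- kors_matrix()
  W <- t(K) %*% solve(K %*% t(K))
  leads <- xyz %*% t(W)
  if (noise > 0) leads <- leads + matrix(rnorm(n * 8, sd = noise), n, 8)
  list(record = ecg_record(leads, colnames(K), fs),
       r_samples = round(r_times * fs))
}
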