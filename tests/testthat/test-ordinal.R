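test_that("ordinal encoding reproduces the canonical worked example", {
  x <- c(1, 2, 5, 4, 3, 5)
  types <- ordinal_encode(x, D = 3, tau = 1)
  expect_identical(types[1:3], c(6L, 5L, 1L))
  expect_length(types, 4L)
  # pattern labels: descending first, ascending last
  expect_identical(ordinal_patterns(3),
                   c("321", "312", "231", "213", "132", "123"))
})

test_that("monotone series map to the extreme patterns and reverse under time reversal", {
  x <- seq_len(100)
  expect_true(all(ordinal_encode(x, 4, 2) == factorial(4)))
  expect_length(ordinal_encode(x, 4, 2), 94L)
  expect_true(all(ordinal_encode(rev(x), 4, 2) == 1L))
  expect_true(all(ordinal_encode(cumsum(abs(rnorm(50)) + 0.01), 3, 1) == 6L))
})

test_that("encoding is invariant under positive affine transforms", {
  set.seed(11)
  for (i in 1:20) {
    x <- rnorm(60)
    D <- sample(2:4, 1)
    tau <- sample(1:3, 1)
    a <- runif(1, 0.1, 10)
    b <- rnorm(1, sd = 5)
    expect_identical(ordinal_encode(a * x + b, D, tau),
                     ordinal_encode(x, D, tau))
  }
})

test_that("ties are broken by temporal order", {
  # constant series: every window gets the ascending pattern (earlier = lower)
  expect_true(all(ordinal_encode(rep(2, 10), 3, 1) == 6L))
  # a tie inside a window: (5, 5, 1) ranks as (1, 2, ...) for the tied pair
  expect_identical(ordinal_encode(c(5, 5, 1), 3, 1),
                   ordinal_encode(c(5, 5.001, 1), 3, 1))
})

test_that("encoding rejects degenerate inputs", {
  expect_error(ordinal_encode(c(1, 2), 3, 1), "too short")
  expect_error(ordinal_encode(c(1, NA, 3, 4), 3, 1), "finite")
  expect_error(ordinal_encode(c(1, Inf, 3, 4), 3, 1), "finite")
  expect_error(ordinal_encode(1:10, 1, 1), "D must be")
  expect_error(ordinal_encode(1:10, 3, 0), "tau must be")
})

test_that("estimated PDF matches hand enumeration of the worked example", {
  p <- suppressWarnings(ordinal_pdf(c(1, 2, 5, 4, 3, 5), 3, 1))
  # 4 windows: (1,2,5)->6, (2,5,4)->5, (5,4,3)->1, (4,3,5)->4
  expect_equal(p$probs, c(0.25, 0, 0, 0.25, 0.25, 0.25))
  expect_identical(p$n_windows, 4L)
  expect_equal(sum(p$probs), 1)
})

test_that("estimated PDF agrees with brute-force enumeration on short series", {
  set.seed(7)
  for (i in 1:60) {
    n <- sample(5:12, 1)
    D <- sample(2:3, 1)
    tau <- sample(1:2, 1)
    if (n <= (D - 1) * tau) next
    # integer-valued series so that ties occur
    x <- sample(1:4, n, replace = TRUE)
    expect_equal(suppressWarnings(ordinal_pdf(x, D, tau))$probs,
                 naive_pdf(x, D, tau))
  }
  # exhaustive: every series of length 6 over alphabet {1,2,3}, D = 3, tau = 1
  grid <- expand.grid(rep(list(1:3), 6))
  for (r in seq_len(nrow(grid))) {
    x <- as.numeric(grid[r, ])
    expect_equal(suppressWarnings(ordinal_pdf(x, 3, 1))$probs,
                 naive_pdf(x, 3, 1))
  }
})

test_that("iid series yield a near-uniform ordinal PDF", {
  set.seed(123)
  p <- ordinal_pdf(runif(2^16), 4, 2)
  expect_true(all(abs(p$probs - 1 / 24) < 0.01))
  expect_identical(p$n_windows, 65530L)
})

test_that("a short series triggers the reliability warning", {
  expect_warning(ordinal_pdf(rnorm(30), 4, 2), "unreliable")
})

test_that("Shannon entropy limits and values are exact", {
  expect_equal(shannon_entropy(rep(1 / 24, 24)), log(24))
  expect_equal(shannon_entropy(c(1, rep(0, 23))), 0)
  expect_equal(shannon_entropy(c(0.5, 0.5, rep(0, 22))), log(2))
  expect_equal(normalized_entropy(rep(1 / 24, 24)), 1)
  expect_equal(normalized_entropy(c(1, rep(0, 23))), 0)
  expect_equal(normalized_entropy(c(0.5, 0.5, rep(0, 22))), log(2) / log(24),
               tolerance = 1e-12)
})

test_that("Jensen-Shannon divergence is a squared metric with known extremes", {
  expect_equal(jensen_shannon(rep(1 / 6, 6), rep(1 / 6, 6)), 0)
  d1 <- c(1, rep(0, 5)); d2 <- c(0, 1, rep(0, 4))
  expect_equal(jensen_shannon(d1, d2), log(2))
  expect_error(jensen_shannon(rep(1 / 6, 6), rep(1 / 24, 24)), "alphabet")
  set.seed(21)
  for (i in 1:100) {
    p <- rdirichlet(1, 6)[1, ]; q <- rdirichlet(1, 6)[1, ]; r <- rdirichlet(1, 6)[1, ]
    expect_gte(jensen_shannon(p, q), 0)
    expect_equal(jensen_shannon(p, q), jensen_shannon(q, p), tolerance = 1e-12)
    # sqrt(JSD) satisfies the triangle inequality
    expect_lte(sqrt(jensen_shannon(p, r)),
               sqrt(jensen_shannon(p, q)) + sqrt(jensen_shannon(q, r)) + 1e-12)
  }
  # agrees with a direct independent evaluation
  set.seed(22)
  p <- rdirichlet(1, 24)[1, ]; q <- rdirichlet(1, 24)[1, ]
  expect_equal(jensen_shannon(p, q), direct_jsd(p, q), tolerance = 1e-12)
})

test_that("disequilibrium is 0 at uniform, 1 at degenerate, monotone in mixing", {
  L <- 24
  expect_equal(disequilibrium(rep(1 / L, L)), 0)
  expect_equal(disequilibrium(c(1, rep(0, L - 1))), 1)
  lam <- seq(0, 1, by = 0.05)
  qv <- vapply(lam, function(l)
    disequilibrium(l * c(1, rep(0, L - 1)) + (1 - l) * rep(1 / L, L)),
    numeric(1))
  expect_true(all(diff(qv) > 0))
  expect_equal(qv[1], 0)
  expect_equal(qv[length(qv)], 1)
})

test_that("the degenerate distribution maximizes distance to uniform (L = 6)", {
  L <- 6
  u <- rep(1 / L, L)
  target <- jensen_shannon(c(1, rep(0, L - 1)), u)
  # numerical maximization over the simplex from several starts
  set.seed(5)
  best <- 0
  for (s in 1:6) {
    o <- optim(rnorm(L), function(th) {
      p <- exp(th - max(th)); p <- p / sum(p)
      -jensen_shannon(p, u)
    }, method = "BFGS", control = list(maxit = 400))
    best <- max(best, -o$value)
  }
  # plus dense random sampling biased towards the simplex corners
  samp <- rdirichlet(20000, L, alpha = 0.05)
  best <- max(best, apply(samp, 1, function(p) jensen_shannon(p, u)))
  expect_lte(best, target + 1e-9)
  expect_gte(best, target - 1e-3) # the optimizer does reach the corner
})

test_that("statistical complexity composes entropy and disequilibrium", {
  s <- statistical_complexity(rep(1 / 24, 24))
  expect_equal(s$H, 1); expect_equal(s$C, 0)
  s <- statistical_complexity(c(1, rep(0, 23)))
  expect_equal(s$H, 0); expect_equal(s$C, 0)
  # equal mixture: C equals the product of independently evaluated H and Q
  L <- 24
  p <- 0.5 * c(1, rep(0, L - 1)) + 0.5 * rep(1 / L, L)
  s <- statistical_complexity(p)
  H_direct <- direct_entropy(p) / log(L)
  Q_direct <- direct_jsd(p, rep(1 / L, L)) /
    direct_jsd(c(1, rep(0, L - 1)), rep(1 / L, L))
  expect_equal(s$C, H_direct * Q_direct, tolerance = 1e-12)
  expect_equal(s$C, s$H * s$Q, tolerance = 1e-12)
})

test_that("ordinal PDFs serialize to CSV and back", {
  p <- ordinal_pdf(rnorm(500), 3, 1)
  f <- withr::local_tempfile(fileext = ".csv")
  write_ordinal_pdf(p, f)
  d <- read.csv(f)
  expect_equal(d$probability, p$probs)
  expect_equal(d$label[1], 321L) # numeric-looking label round-trips as int
})
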