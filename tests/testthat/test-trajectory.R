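# minimal hand-built beat_set / phase_series constructors for unit tests
fake_beat_set <- function(windows, t_s, fs = 1000) {
  n <- nrow(windows)
  structure(list(windows = windows, r_samples = round(t_s * fs),
                 q_onsets = rep(NA_integer_, n), fs = fs, pre = 256,
                 series = numeric(0), annotations = NULL, id = NULL,
                 accepted = rep(TRUE, n), xcorr = rep(1, n),
                 shift = rep(0L, n), rms_pre_q = rep(0, n),
                 record_excluded = FALSE, n_dropped_edge = 0L),
            class = "beat_set")
}

fake_series <- function(H, C = H * 0.1, jsd = rep(0.1, length(H)),
                        t = seq_along(H) - 1, phase = "occlusion",
                        duration = max(t) + 1) {
  structure(list(phase = phase, beat_times = t,
                 pdfs = matrix(1 / 24, length(H), 24), H = H, C = C,
                 Q = ifelse(H > 0, C / H, 0), jsd = jsd, D = 4L, tau = 2L,
                 duration = duration),
            class = "phase_series")
}

fake_traj <- function(H, C, n_beats = rep(1, length(H)), width = 30) {
  structure(data.frame(window_center = (seq_along(H) - 0.5) * width,
                       H = H, C = C, Q = ifelse(H > 0, C / H, 0),
                       jsd = NA_real_, n_beats = n_beats),
            width = width, phase = "occlusion",
            class = c("hc_trajectory", "data.frame"))
}

test_that("per-beat quantifiers match an independent recomputation", {
  set.seed(51)
  W <- rbind(rnorm(512), cumsum(rnorm(512)), sin(1:512 / 20) + rnorm(512, sd = 0.1))
  bs <- fake_beat_set(W, t_s = c(1, 2, 3))
  ps <- per_beat_quantifiers(bs, "control", 0, 10)
  expect_length(ps$H, 3L)
  for (i in 1:3) {
    p_naive <- naive_pdf(W[i, ], 4, 2)
    expect_equal(ps$pdfs[i, ], p_naive)
    expect_equal(ps$H[i], direct_entropy(p_naive) / log(24), tolerance = 1e-12)
  }
  # 512-sample window at D=4, tau=2 -> 506 pattern windows
  p <- ordinal_pdf(W[1, ], 4, 2, warn_short = FALSE)
  expect_identical(p$n_windows, 506L)
})

test_that("a constant-voltage beat is fully ordered under the tie rule", {
  bs <- fake_beat_set(rbind(rep(5, 512), rnorm(512)), t_s = c(1, 2))
  ps <- per_beat_quantifiers(bs, "control", 0, 10)
  expect_equal(ps$H[1], 0)
  expect_equal(ps$C[1], 0)
  expect_equal(ps$pdfs[1, 24], 1) # all windows typed as the ascending pattern
})

test_that("mean control PDF averages beat PDFs and is the JSD reference", {
  # identical beats: mean equals each; JSD to reference is 0
  p0 <- c(0.5, 0.3, 0.2, rep(0, 21))
  pm <- matrix(rep(p0, 4), 4, byrow = TRUE)
  mc <- mean_control_pdf(pm)
  expect_equal(mc$probs, p0)
  # two degenerate beats at patterns 1 and 2
  mc2 <- mean_control_pdf(rbind(c(1, rep(0, 23)), c(0, 1, rep(0, 22))))
  expect_equal(mc2$probs, c(0.5, 0.5, rep(0, 22)))
  # the mean is a better JSD centroid than any single beat or the uniform
  set.seed(52)
  pm <- rdirichlet(100, 24, alpha = 2)
  mc3 <- mean_control_pdf(pm)
  expect_equal(sum(mc3$probs), 1, tolerance = 1e-12)
  mean_jsd_to <- function(q) mean(apply(pm, 1, function(p) jensen_shannon(p, q)))
  at_mean <- mean_jsd_to(mc3$probs)
  expect_lt(at_mean, mean_jsd_to(rep(1 / 24, 24)))
  for (i in sample(100, 10)) expect_lt(at_mean, mean_jsd_to(pm[i, ]))
})

test_that("per-beat JSD to the reference behaves as a divergence", {
  set.seed(53)
  W <- matrix(rnorm(512 * 5), 5)
  bs <- fake_beat_set(W, t_s = 1:5)
  ps <- per_beat_quantifiers(bs, "control", 0, 10)
  mc <- mean_control_pdf(ps)
  ps <- jsd_to_reference(ps, mc)
  expect_true(all(ps$jsd >= 0))
  # a beat whose PDF equals the reference has JSD 0
  ps1 <- fake_series(H = 1)
  ps1$pdfs[1, ] <- mc$probs
  ps1 <- jsd_to_reference(ps1, mc)
  expect_equal(ps1$jsd[1], 0)
})

test_that("window averaging tiles the phase and flags empty windows", {
  # identical quantifiers: every window mean equals that value
  ps <- fake_series(H = rep(0.8, 60), C = rep(0.15, 60),
                    t = seq(0, 59.5, length.out = 60), duration = 60)
  tr <- window_average(ps, 30)
  expect_identical(nrow(tr), 2L)
  expect_equal(tr$H, c(0.8, 0.8))
  expect_equal(tr$C, c(0.15, 0.15))
  expect_equal(tr$window_center, c(15, 45))
  # one beat per window: trajectory equals beat values
  ps2 <- fake_series(H = c(0.7, 0.8, 0.9), t = c(5, 35, 65), duration = 90)
  tr2 <- window_average(ps2, 30)
  expect_equal(tr2$H, c(0.7, 0.8, 0.9))
  expect_equal(tr2$n_beats, c(1, 1, 1))
  # an empty window stays NA, not interpolated
  ps3 <- fake_series(H = c(0.7, 0.9), t = c(5, 65), duration = 90)
  tr3 <- window_average(ps3, 30)
  expect_true(is.na(tr3$H[2]))
  expect_equal(tr3$n_beats[2], 0)
})

test_that("window means track a linear trend at the window midpoints", {
  tt <- seq(0, 120, by = 0.8)
  ps <- fake_series(H = 0.9 - 0.001 * tt, t = tt, duration = 120)
  tr <- window_average(ps, 30)
  expect_equal(tr$H, 0.9 - 0.001 * tr$window_center, tolerance = 1e-3)
})

test_that("incomplete final windows follow the half-full rule", {
  tt <- seq(0, 70, by = 1) # 70 s phase at 30 s windows: 2 full + 10 s stub
  ps <- fake_series(H = rep(0.8, length(tt)), t = tt, duration = 70.9)
  expect_identical(nrow(window_average(ps, 30)), 2L)
  ps2 <- fake_series(H = rep(0.8, length(tt)), t = tt, duration = 80)
  expect_identical(nrow(window_average(ps2, 30)), 3L) # 20 s stub >= half
})

test_that("delta metrics reproduce the endpoint arithmetic", {
  tr <- fake_traj(H = c(0.87, 0.8, 0.76), C = c(0.12, 0.15, 0.18))
  d <- delta_metrics(tr)
  expect_equal(d$delta_H, (0.76 - 0.87) / 0.87, tolerance = 1e-12)
  expect_equal(d$delta_C, 0.5, tolerance = 1e-12)
  # constant trajectory: both deltas zero
  d0 <- delta_metrics(fake_traj(H = c(0.8, 0.8), C = c(0.1, 0.1)))
  expect_equal(d0$delta_H, 0)
  expect_equal(d0$delta_C, 0)
  # endpoints are the first/last NON-EMPTY windows
  tr2 <- fake_traj(H = c(NA, 0.9, 0.6, NA), C = c(NA, 0.1, 0.2, NA),
                   n_beats = c(0, 2, 2, 0))
  d2 <- delta_metrics(tr2)
  expect_equal(d2$H_initial, 0.9)
  expect_equal(d2$H_final, 0.6)
  expect_error(delta_metrics(fake_traj(H = 0.8, C = 0.1)), "at least 2")
})

test_that("control sections partition time and average correctly", {
  # uniform control JSD: every section mean equals it
  ps <- fake_series(H = rep(0.8, 100), jsd = rep(0.04, 100),
                    t = seq(0, 239, length.out = 100), duration = 240,
                    phase = "control")
  s <- control_sections(ps, 8) # 4 min at 30 s windows -> 8 sections
  expect_length(s, 8L)
  expect_equal(s, rep(0.04, 8))
  # brute-force partition agreement on irregular data
  set.seed(54)
  tt <- sort(runif(200, 0, 240))
  jj <- runif(200)
  ps2 <- fake_series(H = rep(0.8, 200), jsd = jj, t = tt, duration = 240,
                     phase = "control")
  s2 <- control_sections(ps2, 8)
  for (k in 1:8) {
    sel <- tt >= (k - 1) * 30 & tt < k * 30
    expect_equal(s2[k], mean(jj[sel]))
  }
})

test_that("the control region box spans the window means", {
  tr1 <- fake_traj(H = c(0.84, 0.85), C = c(0.13, 0.14))
  cr1 <- control_region(tr1)
  expect_equal(cr1$H_range, c(0.84, 0.85))
  expect_equal(cr1$C_range, c(0.13, 0.14))
  # single point: degenerate box
  cr0 <- control_region(fake_traj(H = 0.85, C = 0.135))
  expect_equal(diff(cr0$H_range), 0)
  # list of trajectories pools the windows
  cr2 <- control_region(list(tr1, fake_traj(H = 0.86, C = 0.12)))
  expect_equal(cr2$H_range, c(0.84, 0.86))
  expect_equal(cr2$C_range, c(0.12, 0.14))
})
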