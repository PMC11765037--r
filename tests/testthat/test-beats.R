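test_that("R-wave detection recovers known beat times on clean and noisy records", {
  sb <- simple_beats_record(dur_s = 20, rr_s = 1.0, noise = 8, seed = 2)
  r <- detect_r_waves(sb$record$signals[, "II"], 1000)
  # every true beat recovered within +/- 10 ms, no spurious detections
  expect_identical(length(r), length(sb$r_samples))
  expect_true(all(abs(r - sb$r_samples) <= 10))
  expect_length(attr(r, "rr_flagged"), 0L)
})

test_that("detection rate tracks the true heart rate", {
  for (rr in c(1.0, 60 / 90)) {
    sb <- simple_beats_record(dur_s = 30, rr_s = rr, noise = 5, seed = 3)
    r <- detect_r_waves(sb$record$signals[, "II"], 1000)
    rate <- 60 / (mean(diff(r)) / 1000)
    expect_lt(abs(rate - 60 / rr) / (60 / rr), 0.02)
  }
})

test_that("flat or empty signals yield no beats, with a warning", {
  expect_warning(r <- detect_r_waves(rep(0, 5000), 1000), "no beats|flat")
  expect_length(r, 0L)
  expect_error(detect_r_waves(rep(0, 100), 1000), "at least 2 s")
})

test_that("window extraction follows the half-open centring convention", {
  m <- vm_series(seq_len(3000), fs = 1000) # values = sample index
  bs <- extract_windows(m, c(1000, 2000))
  expect_identical(dim(bs$windows), c(2L, 512L))
  # R at sample 1000 covers samples [744, 1256): values 744..1255
  expect_equal(bs$windows[1, ], as.numeric(744:1255))
  expect_equal(bs$windows[1, 257], 1000) # R sample sits at position pre+1
  # beats too close to an edge are dropped with a log message
  expect_message(bs2 <- extract_windows(m, c(100, 1500, 2900)), "dropped")
  expect_identical(nrow(bs2$windows), 1L)
  expect_identical(bs2$n_dropped_edge, 2L)
})

test_that("the median template ignores outlier beats", {
  set.seed(4)
  beat <- sin(seq(0, 2 * pi, length.out = 64))
  w <- matrix(rep(beat, 10), 10, byrow = TRUE)
  expect_equal(build_template(w), beat)
  w[10, ] <- beat + 50 # one ectopic-like outlier
  expect_equal(build_template(w), beat)
  # symmetric perturbation pairs cancel in the median
  wp <- rbind(beat, beat + 0.3, beat - 0.3)
  expect_equal(build_template(wp), beat)
  expect_error(build_template(w[1:2, ]), "at least 3")
})

test_that("template acceptance is exact for identical beats and finds known lags", {
  fs <- 1000
  # a long series with a recurring smooth beat every second
  t <- seq_len(10 * fs) / fs
  series <- numeric(length(t))
  r_true <- seq(500, 9500, by = 1000)
  for (r in r_true) series <- series + exp(-0.5 * ((seq_along(t) - r) / 15)^2)
  m <- vm_series(series * 100, fs)
  # report one fiducial 8 ms early, so its window content is template
  # delayed by 8 ms
  r_rep <- r_true; r_rep[4] <- r_true[4] - 8
  bs <- accept_beats(extract_windows(m, r_rep))
  expect_true(all(bs$accepted))
  expect_true(all(bs$xcorr > 0.999))
  expect_identical(bs$shift[4], -8L)
  expect_true(all(bs$shift[-4] == 0L))
  # jitter correction recentres the late beat
  expect_equal(bs$r_samples[4], r_true[4])
  expect_identical(nrow(bs$windows), length(r_true))
})

test_that("white-noise windows are rejected at the 0.75 threshold", {
  fs <- 1000
  t_idx <- seq_len(30 * fs)
  series <- numeric(length(t_idx))
  r_true <- seq(500, 29500, by = 1000)
  for (r in r_true) series <- series + 800 * exp(-0.5 * ((t_idx - r) / 12)^2)
  set.seed(10)
  rejected <- 0L
  n_draws <- 100L
  for (i in seq_len(n_draws)) {
    s2 <- series
    k <- sample(3:28, 1)
    lo <- r_true[k] - 256
    s2[lo:(lo + 511)] <- abs(rnorm(512, sd = 200)) # replace one beat by noise
    bs <- accept_beats(extract_windows(vm_series(s2, fs), r_true),
                       threshold = 0.75)
    if (!bs$accepted[k]) rejected <- rejected + 1L
    expect_true(all(bs$accepted[-k]))
  }
  expect_gte(rejected, n_draws - 1L)
})

test_that("acceptance decisions are scale-invariant", {
  sb <- simple_beats_record(dur_s = 15, noise = 10, seed = 6)
  pp <- preprocess_record(sb$record)
  bs1 <- accept_beats(extract_windows(pp$modulus, sb$r_samples))
  m3 <- pp$modulus; m3$values <- 3 * m3$values
  bs3 <- accept_beats(extract_windows(m3, sb$r_samples))
  expect_identical(bs1$accepted, bs3$accepted)
  expect_identical(bs1$shift, bs3$shift)
})

test_that("the pre-Q RMS gate passes clean records and excludes noisy ones", {
  sb <- simple_beats_record(dur_s = 15, noise = 0, seed = 7)
  pp <- preprocess_record(sb$record)
  q <- sb$r_samples - 45
  bs <- extract_windows(pp$modulus, sb$r_samples, q_onsets = q)
  bs <- accept_beats(bs)
  clean <- rms_noise_gate(bs, limit = 20)
  expect_false(clean$record_excluded)
  expect_true(all(clean$rms_pre_q < 5, na.rm = TRUE))
  # inject 30 uV broadband noise on the orthogonal leads: the modulus
  # residual trips the 20 uV gate
  set.seed(11)
  xyz <- pp$xyz
  xyz$signals <- xyz$signals + matrix(rnorm(length(xyz$signals), sd = 30),
                                      nrow(xyz$signals))
  noisy <- vector_modulus(xyz)
  bsn <- accept_beats(extract_windows(noisy, sb$r_samples, q_onsets = q))
  gated <- rms_noise_gate(bsn, limit = 20)
  expect_true(gated$record_excluded)
  # an infinite limit never excludes
  expect_false(rms_noise_gate(bsn, limit = Inf)$record_excluded)
  expect_error(rms_noise_gate(extract_windows(pp$modulus, sb$r_samples)),
               "Q onsets")
})

test_that("the full segmentation chain accepts nearly all true beats and no extras", {
  spec <- cohort_spec(n_patients = 1, arteries = "LAD", control_s = 40)
  p <- generate_patient(spec, 1, seed = 5)
  pp <- preprocess_record(p$control)
  bs <- segment_beats(pp$modulus, pp$leads$signals[, "II"])
  truth <- p$truth$control
  # >= 95% of true beats recovered within 10 ms among accepted windows
  hits <- vapply(truth$r_sample, function(r)
    any(abs(bs$r_samples[bs$accepted] - r) <= 10), logical(1))
  expect_gte(mean(hits), 0.95)
  # no spurious windows: every accepted window matches a true beat
  spurious <- vapply(bs$r_samples[bs$accepted], function(r)
    !any(abs(truth$r_sample - r) <= 15), logical(1))
  expect_identical(sum(spurious), 0L)
  expect_false(bs$record_excluded)
  qc <- beat_qc(bs)
  expect_identical(nrow(qc), nrow(bs$windows))
  expect_true(all(c("xcorr", "shift_ms", "rms_pre_q", "accepted") %in% names(qc)))
})
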