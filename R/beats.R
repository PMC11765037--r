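#' R-wave detection on lead II
#'
#' Built-in QRS detector: band-pass 5-25 Hz (3rd-order Butterworth,
#' forward-backward), squared derivative, 120 ms moving-window integration,
#' adaptive threshold with a 250 ms refractory period, and peak refinement on
#' the band-passed signal. It is a deliberately simple stand-in for full
#' wavelet-based ECG delineation and is intended for clean or synthetic
#' records; externally supplied R times (sidecar annotations) bypass it.
#'
#' @param lead_ii numeric voltage series of lead II (microvolts).
#' @param fs sampling rate (Hz).
#' @param threshold_frac adaptive threshold as a fraction of the 99th
#'   percentile of the integrated detection function.
#' @param refractory_ms minimum separation between detections.
#' @return strictly increasing integer sample indices of R peaks, with
#'   attribute \code{rr_flagged}: indices of inter-beat intervals outside
#'   the physiological 0.3-2.0 s range.
#' @export
detect_r_waves <- function(lead_ii, fs, threshold_frac = 0.3,
                           refractory_ms = 250) {
  x <- as.numeric(lead_ii)
  if (length(x) < 2 * fs) stop("need at least 2 s of signal")
  if (all(abs(x - x[1]) < .Machine$double.eps * 100)) {
    warning("flat signal: no beats found")
    return(structure(integer(0), rr_flagged = integer(0)))
  }
  bf <- signal::butter(3, c(5, 25) / (fs / 2), type = "pass")
  xb <- signal::filtfilt(bf, x)
  d <- c(0, diff(xb)) * fs / 1000 # uV per ms
  e <- d^2
  w <- max(1L, round(0.120 * fs))
  integ <- stats::filter(e, rep(1 / w, w), sides = 2)
  integ[is.na(integ)] <- 0
  thr <- threshold_frac * stats::quantile(integ, 0.99, names = FALSE)
  if (thr <= 0) {
    warning("no beats found")
    return(structure(integer(0), rr_flagged = integer(0)))
  }
  above <- integ > thr
  # rising edges of supra-threshold bursts
  starts <- which(diff(c(FALSE, above)) == 1)
  refr <- round(refractory_ms / 1000 * fs)
  half <- round(0.075 * fs)
  n <- length(x)
  peaks <- integer(0)
  last <- -refr
  for (s in starts) {
    if (s - last < refr) next
    lo <- max(1L, s - half)
    hi <- min(n, s + half)
    p <- lo + which.max(abs(xb[lo:hi])) - 1L
    if (length(peaks) && p - peaks[length(peaks)] < refr) next
    peaks <- c(peaks, p)
    last <- p
  }
  if (!length(peaks)) warning("no beats found")
  rr <- diff(peaks) / fs
  structure(as.integer(peaks),
            rr_flagged = which(rr < 0.3 | rr > 2.0))
}

#' Q-onset estimation before each R wave
#'
#' Locates the Q onset as the first sample before the R peak where the
#' band-passed slope magnitude falls below 5 percent of the R upstroke
#' slope, capped at 80 ms before R. Used to place the pre-Q noise-gate
#' segment and the baseline-spline knots.
#'
#' @param lead_ii lead II voltage series (microvolts).
#' @param r_samples R-peak sample indices.
#' @param fs sampling rate (Hz).
#' @param max_before_ms search cap before R.
#' @param slope_frac slope threshold as a fraction of the peak slope.
#' @return integer Q-onset sample indices (same length as \code{r_samples}).
#' @export
find_q_onsets <- function(lead_ii, r_samples, fs, max_before_ms = 80,
                          slope_frac = 0.05) {
  x <- as.numeric(lead_ii)
  bf <- signal::butter(3, c(5, 25) / (fs / 2), type = "pass")
  xb <- signal::filtfilt(bf, x)
  sl <- abs(c(0, diff(xb)))
  cap <- round(max_before_ms / 1000 * fs)
  vapply(as.integer(r_samples), function(r) {
    lo <- max(2L, r - cap)
    if (lo >= r) return(lo)
    seg <- sl[lo:r]
    thr <- slope_frac * max(seg)
    below <- which(seg < thr)
    if (!length(below)) return(lo)
    # last sub-threshold sample before the upstroke
    as.integer(lo + below[length(below)] - 1L)
  }, integer(1))
}

#' Extract fixed-length beat windows from the vector modulus
#'
#' Cuts one 512 ms window per R wave from the modulus series: half the
#' window length before the R sample and half at-and-after it (half-open
#' convention). Beats whose window would cross a record edge are dropped.
#'
#' @param modulus \code{vm_series}.
#' @param r_samples R-peak sample indices (on the same time base).
#' @param window_ms window length in ms.
#' @param q_onsets optional Q-onset sample indices matching
#'   \code{r_samples}.
#' @return object of class \code{beat_set}: windows matrix (one row per
#'   beat), kept \code{r_samples}, \code{q_onsets}, \code{fs}, the source
#'   series, and QC fields filled by [accept_beats()] / [rms_noise_gate()].
#' @export
extract_windows <- function(modulus, r_samples, window_ms = 512,
                            q_onsets = NULL) {
  stopifnot(inherits(modulus, "vm_series"))
  fs <- modulus$fs
  wlen <- round(window_ms / 1000 * fs)
  pre <- wlen %/% 2L
  n <- length(modulus$values)
  r_samples <- as.integer(r_samples)
  keep <- r_samples - pre >= 1L & r_samples + (wlen - pre) - 1L <= n
  n_dropped <- sum(!keep)
  if (n_dropped)
    message(sprintf("%d beat(s) dropped: window crosses a record edge", n_dropped))
  r <- r_samples[keep]
  q <- if (is.null(q_onsets)) rep(NA_integer_, length(r))
       else as.integer(q_onsets)[keep]
  win <- matrix(0, length(r), wlen)
  for (i in seq_along(r))
    win[i, ] <- modulus$values[(r[i] - pre):(r[i] + wlen - pre - 1L)]
  structure(list(windows = win, r_samples = r, q_onsets = q, fs = fs,
                 pre = pre, series = modulus$values,
                 annotations = modulus$annotations, id = modulus$id,
                 accepted = rep(NA, length(r)),
                 xcorr = rep(NA_real_, length(r)),
                 shift = rep(NA_integer_, length(r)),
                 rms_pre_q = rep(NA_real_, length(r)),
                 record_excluded = NA, n_dropped_edge = n_dropped),
            class = "beat_set")
}

#' @export
print.beat_set <- function(x, ...) {
  cat(sprintf("Beat set%s: %d beats (%d-sample windows at %g Hz)\n",
              if (is.null(x$id)) "" else paste0(" '", x$id, "'"),
              nrow(x$windows), ncol(x$windows), x$fs))
  if (!all(is.na(x$accepted)))
    cat(sprintf("  accepted %d / %d (template correlation)\n",
                sum(x$accepted, na.rm = TRUE), nrow(x$windows)))
  if (!is.na(x$record_excluded))
    cat(sprintf("  record %s by the pre-Q RMS noise gate\n",
                if (x$record_excluded) "EXCLUDED" else "passes"))
  invisible(x)
}

#' Median beat template
#'
#' Samplewise median across candidate beat windows. The median (rather than
#' the mean) keeps occasional ectopic or noisy beats from contaminating the
#' template.
#'
#' @param beats \code{beat_set} or a windows matrix (one row per beat).
#' @return numeric template window.
#' @export
build_template <- function(beats) {
  w <- if (inherits(beats, "beat_set")) beats$windows else as.matrix(beats)
  if (nrow(w) < 3L) stop("need at least 3 candidate beats for a template")
  apply(w, 2L, stats::median)
}

#' Template-based beat acceptance with jitter correction
#'
#' Computes, for every beat, the maximum normalized cross-correlation with
#' the template over lags within \code{max_shift_ms}. Beats exceeding
#' \code{threshold} are accepted and realigned to the best lag by an
#' integer-sample shift (the window is re-cut from the source series);
#' others are rejected. Normalized correlation makes the decision invariant
#' to overall amplitude scaling.
#'
#' @param beats \code{beat_set}.
#' @param template template window (defaults to [build_template()] on all
#'   beats).
#' @param threshold acceptance threshold on the correlation coefficient.
#' @param max_shift_ms jitter search half-range in ms.
#' @return \code{beat_set} with \code{accepted}, \code{xcorr}, \code{shift}
#'   (in samples; negative when the beat arrived late) filled in and
#'   accepted windows realigned.
#' @export
accept_beats <- function(beats, template = NULL, threshold = 0.75,
                         max_shift_ms = 50) {
  stopifnot(inherits(beats, "beat_set"))
  if (is.null(template)) template <- build_template(beats)
  wlen <- ncol(beats$windows)
  stopifnot(length(template) == wlen)
  maxlag <- round(max_shift_ms / 1000 * beats$fs)
  lags <- -maxlag:maxlag
  n <- nrow(beats$windows)
  nsrc <- length(beats$series)
  for (i in seq_len(n)) {
    w <- beats$windows[i, ]
    cc <- vapply(lags, function(l) {
      if (l >= 0) {
        a <- template[seq_len(wlen - l)]
        b <- w[(1 + l):wlen]
      } else {
        a <- template[(1 - l):wlen]
        b <- w[seq_len(wlen + l)]
      }
      if (stats::sd(a) == 0 || stats::sd(b) == 0) return(-Inf)
      stats::cor(a, b)
    }, numeric(1))
    best <- which.max(cc)
    beats$xcorr[i] <- cc[best]
    l <- lags[best]
    beats$shift[i] <- -l
    beats$accepted[i] <- is.finite(cc[best]) && cc[best] > threshold
    if (beats$accepted[i] && l != 0L) {
      # re-cut the window around the jitter-corrected R position
      r2 <- beats$r_samples[i] + l
      lo <- r2 - beats$pre
      hi <- r2 + wlen - beats$pre - 1L
      if (lo >= 1L && hi <= nsrc) {
        beats$windows[i, ] <- beats$series[lo:hi]
        beats$r_samples[i] <- r2
      }
    }
  }
  beats
}

#' Pre-Q RMS noise gate
#'
#' Measures, per beat, the RMS of the high-pass residual (2nd-order
#' Butterworth, 40 Hz cut-off) of the modulus over the 20 ms segment ending
#' at the Q onset — an isoelectric stretch where any power is noise. The
#' whole record is excluded when the median per-beat RMS exceeds
#' \code{limit}; per-beat values are kept for diagnostics.
#'
#' @param beats \code{beat_set} with \code{q_onsets} available.
#' @param pre_q_ms segment length before the Q point (ms).
#' @param limit record-exclusion limit in microvolts.
#' @param hp_cutoff high-pass cut-off (Hz) for the noise residual.
#' @return \code{beat_set} with \code{rms_pre_q} and \code{record_excluded}
#'   filled in.
#' @export
rms_noise_gate <- function(beats, pre_q_ms = 20, limit = 20, hp_cutoff = 40) {
  stopifnot(inherits(beats, "beat_set"))
  if (all(is.na(beats$q_onsets)))
    stop("Q onsets required for the noise gate (run find_q_onsets or supply annotations)")
  fs <- beats$fs
  bf <- signal::butter(2, hp_cutoff / (fs / 2), type = "high")
  resid <- signal::filtfilt(bf, beats$series)
  seg <- round(pre_q_ms / 1000 * fs)
  beats$rms_pre_q <- vapply(beats$q_onsets, function(q) {
    if (is.na(q)) return(NA_real_)
    lo <- max(1L, q - seg)
    if (lo >= q) return(NA_real_)
    sqrt(mean(resid[lo:(q - 1L)]^2))
  }, numeric(1))
  med <- stats::median(beats$rms_pre_q, na.rm = TRUE)
  beats$record_excluded <- is.finite(med) && med > limit
  beats
}

#' Beat-level quality-control table
#'
#' @param beats \code{beat_set}.
#' @return data.frame with one row per beat: index, R sample, template
#'   correlation, applied shift (ms), pre-Q RMS (microvolts), accepted flag.
#' @export
beat_qc <- function(beats) {
  stopifnot(inherits(beats, "beat_set"))
  data.frame(beat = seq_len(nrow(beats$windows)),
             r_sample = beats$r_samples,
             xcorr = beats$xcorr,
             shift_ms = beats$shift / beats$fs * 1000,
             rms_pre_q = beats$rms_pre_q,
             accepted = beats$accepted)
}

#' Full beat segmentation chain for one record
#'
#' Detects R waves on lead II (or uses annotation-supplied R/Q samples),
#' estimates Q onsets, cuts 512 ms modulus windows, builds the median
#' template, applies the correlation acceptance gate with jitter correction
#' and the pre-Q RMS noise gate.
#'
#' @param modulus \code{vm_series} of the record.
#' @param lead_ii lead II voltage series used for detection.
#' @param r_samples,q_samples optional externally supplied fiducials
#'   (1-based sample indices); when given, detection is bypassed.
#' @param window_ms beat window length (ms).
#' @param xcorr_threshold template-correlation acceptance threshold.
#' @param pre_q_ms,rms_limit noise-gate parameters.
#' @return \code{beat_set}, fully annotated.
#' @export
segment_beats <- function(modulus, lead_ii, r_samples = NULL,
                          q_samples = NULL, window_ms = 512,
                          xcorr_threshold = 0.75, pre_q_ms = 20,
                          rms_limit = 20) {
  fs <- modulus$fs
  if (is.null(r_samples)) {
    r_samples <- detect_r_waves(lead_ii, fs)
    if (!length(r_samples)) {
      bs <- extract_windows(modulus, integer(0))
      bs$record_excluded <- FALSE
      return(bs)
    }
  }
  if (is.null(q_samples)) q_samples <- find_q_onsets(lead_ii, r_samples, fs)
  bs <- extract_windows(modulus, r_samples, window_ms, q_onsets = q_samples)
  if (nrow(bs$windows) >= 3L) {
    bs <- accept_beats(bs, threshold = xcorr_threshold)
  } else {
    bs$accepted <- rep(FALSE, nrow(bs$windows))
  }
  rms_noise_gate(bs, pre_q_ms = pre_q_ms, limit = rms_limit)
}
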