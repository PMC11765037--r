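#' Per-beat ordinal quantifiers of a record phase
#'
#' For each accepted beat whose R time falls in \code{[t_start, t_end)},
#' estimates the ordinal PDF of its modulus window and computes the
#' normalized entropy, disequilibrium and statistical complexity, plus —
#' when a reference distribution is given — the Jensen-Shannon divergence
#' to it. A 512-sample window at the default D = 4, tau = 2 yields 506
#' pattern windows per beat.
#'
#' @param beats \code{beat_set} (accepted flags set).
#' @param phase phase label: \code{"control"}, \code{"occlusion"} or
#'   \code{"recovery"}.
#' @param t_start,t_end phase bounds in seconds on the record time base.
#' @param D,tau ordinal embedding parameters.
#' @param reference optional \code{ordinal_pdf} (the Mean Control PDF) for
#'   per-beat JSD.
#' @return object of class \code{phase_series}: \code{phase},
#'   \code{beat_times} (seconds from phase start), \code{pdfs} (beats x D!
#'   matrix), \code{H}, \code{C}, \code{Q}, \code{jsd}, \code{D},
#'   \code{tau}, \code{duration}.
#' @export
per_beat_quantifiers <- function(beats, phase = "control", t_start = 0,
                                 t_end = Inf, D = 4L, tau = 2L,
                                 reference = NULL) {
  stopifnot(inherits(beats, "beat_set"))
  tb <- beats$r_samples / beats$fs
  acc <- beats$accepted
  acc[is.na(acc)] <- FALSE
  keep <- which(acc & tb >= t_start & tb < t_end)
  L <- factorial(as.integer(D))
  n <- length(keep)
  pdfs <- matrix(0, n, L)
  H <- C <- Q <- numeric(n)
  for (j in seq_len(n)) {
    p <- ordinal_pdf(beats$windows[keep[j], ], D, tau, warn_short = FALSE)
    pdfs[j, ] <- p$probs
    s <- statistical_complexity(p)
    H[j] <- s$H; C[j] <- s$C; Q[j] <- s$Q
  }
  out <- structure(list(phase = phase,
                        beat_times = tb[keep] - t_start,
                        pdfs = pdfs, H = H, C = C, Q = Q,
                        jsd = rep(NA_real_, n),
                        D = as.integer(D), tau = as.integer(tau),
                        duration = if (is.finite(t_end)) t_end - t_start
                                   else if (n) max(tb[keep] - t_start) else 0),
                   class = "phase_series")
  if (!is.null(reference)) out <- jsd_to_reference(out, reference)
  out
}

#' @export
print.phase_series <- function(x, ...) {
  cat(sprintf("Phase series '%s': %d beats over %.1f s (D = %d, tau = %d)\n",
              x$phase, length(x$H), x$duration, x$D, x$tau))
  if (length(x$H))
    cat(sprintf("  mean H = %.3f, mean C = %.3f%s\n", mean(x$H), mean(x$C),
                if (all(is.na(x$jsd))) "" else
                  sprintf(", mean JSD to reference = %.4f", mean(x$jsd))))
  invisible(x)
}

#' Mean control PDF of a patient
#'
#' Componentwise arithmetic mean of the per-beat ordinal PDFs of the
#' control phase, renormalized to guard against rounding. This is the
#' per-patient reference distribution against which all occlusion,
#' recovery and control beats are measured by JSD.
#'
#' @param control \code{phase_series} of control beats (or a beats x L
#'   probability matrix).
#' @return \code{ordinal_pdf}.
#' @export
mean_control_pdf <- function(control) {
  pm <- if (inherits(control, "phase_series")) control$pdfs else as.matrix(control)
  if (nrow(pm) < 1L) stop("need at least one accepted control beat")
  p <- colMeans(pm)
  p <- p / sum(p)
  D <- if (inherits(control, "phase_series")) control$D
       else { d <- 2L; while (factorial(d) < ncol(pm)) d <- d + 1L; d }
  new_ordinal_pdf(p, D = D,
                  tau = if (inherits(control, "phase_series")) control$tau else NA_integer_,
                  n_windows = nrow(pm))
}

#' Fill per-beat JSD to a reference distribution
#'
#' @param series \code{phase_series}.
#' @param reference \code{ordinal_pdf} (Mean Control PDF).
#' @return \code{phase_series} with \code{jsd} populated.
#' @export
jsd_to_reference <- function(series, reference) {
  stopifnot(inherits(series, "phase_series"))
  ref <- .probs(reference)
  if (length(ref) != ncol(series$pdfs))
    stop("reference alphabet size does not match the series")
  series$jsd <- apply(series$pdfs, 1L, function(p) jensen_shannon(p, ref))
  if (!length(series$H)) series$jsd <- numeric(0)
  series
}

#' Windowed trajectory of per-beat quantifiers
#'
#' Averages the per-beat quantifiers in consecutive time windows tiling the
#' phase (30 s windows during occlusion and 15 s during recovery are the
#' study defaults). Windows without beats are kept as NA rows, never
#' interpolated. An incomplete final window is included when at least half
#' of its span lies inside the phase, otherwise dropped.
#'
#' @param series \code{phase_series}.
#' @param width window width in seconds.
#' @param duration phase duration (defaults to the recorded phase
#'   duration).
#' @return object of class \code{hc_trajectory}: data.frame with columns
#'   \code{window_center}, \code{H}, \code{C}, \code{Q}, \code{jsd},
#'   \code{n_beats}; attributes \code{width} and \code{phase}.
#' @export
window_average <- function(series, width, duration = series$duration) {
  stopifnot(inherits(series, "phase_series"), width > 0)
  if (!is.finite(duration) || duration <= 0)
    duration <- if (length(series$beat_times)) max(series$beat_times) else width
  n_full <- floor(duration / width)
  rem <- duration - n_full * width
  n_win <- n_full + (rem >= width / 2)
  n_win <- max(n_win, 1L)
  idx <- pmin(floor(series$beat_times / width) + 1L, n_win)
  agg <- function(v) vapply(seq_len(n_win), function(w) {
    sel <- idx == w & series$beat_times < n_win * width
    if (any(sel)) mean(v[sel]) else NA_real_
  }, numeric(1))
  out <- data.frame(window_center = (seq_len(n_win) - 0.5) * width,
                    H = agg(series$H), C = agg(series$C), Q = agg(series$Q),
                    jsd = agg(series$jsd),
                    n_beats = vapply(seq_len(n_win), function(w)
                      sum(idx == w & series$beat_times < n_win * width),
                      numeric(1)))
  structure(out, width = width, phase = series$phase,
            class = c("hc_trajectory", "data.frame"))
}

#' Relative endpoint changes of a trajectory
#'
#' \eqn{\delta X = (X_{final} - X_{initial}) / X_{initial}} for the
#' entropy and complexity of the first and last non-empty windows, the
#' signed relative change over a phase.
#'
#' @param traj \code{hc_trajectory}.
#' @return list of class \code{delta_metrics}: \code{delta_H},
#'   \code{delta_C}, plus the endpoint values.
#' @examples
#' # endpoint arithmetic: 0.87 -> 0.76 is a 12.6% entropy drop
#' @export
delta_metrics <- function(traj) {
  stopifnot(inherits(traj, "hc_trajectory"))
  ok <- which(traj$n_beats > 0 & is.finite(traj$H))
  if (length(ok) < 2L) stop("need at least 2 non-empty windows for deltas")
  i <- ok[1L]; f <- ok[length(ok)]
  structure(list(delta_H = (traj$H[f] - traj$H[i]) / traj$H[i],
                 delta_C = (traj$C[f] - traj$C[i]) / traj$C[i],
                 H_initial = traj$H[i], H_final = traj$H[f],
                 C_initial = traj$C[i], C_final = traj$C[f]),
            class = "delta_metrics")
}

#' @export
print.delta_metrics <- function(x, ...) {
  cat(sprintf("deltaH = %+.1f%% (%.3f -> %.3f), deltaC = %+.1f%% (%.3f -> %.3f)\n",
              100 * x$delta_H, x$H_initial, x$H_final,
              100 * x$delta_C, x$C_initial, x$C_final))
  invisible(x)
}

#' Section means of the control JSD
#'
#' Splits the control beats into \code{n_sections} contiguous
#' equal-duration sections and averages the per-beat JSD within each, so
#' control sections can be compared one-to-one against occlusion or
#' recovery windows (a patient with 4 min of occlusion at 30 s windows
#' contributes 8 occlusion windows and 8 control sections).
#'
#' @param control \code{phase_series} with \code{jsd} filled.
#' @param n_sections number of sections (>= 1).
#' @param duration control duration (defaults to the recorded one).
#' @return numeric vector of per-section mean JSDs (NA for empty
#'   sections).
#' @export
control_sections <- function(control, n_sections, duration = control$duration) {
  stopifnot(inherits(control, "phase_series"), n_sections >= 1L)
  if (all(is.na(control$jsd))) stop("control JSD not computed; call jsd_to_reference first")
  if (!is.finite(duration) || duration <= 0)
    duration <- max(control$beat_times)
  width <- duration / n_sections
  idx <- pmin(floor(control$beat_times / width) + 1L, n_sections)
  vapply(seq_len(n_sections), function(s) {
    sel <- idx == s
    if (any(sel)) mean(control$jsd[sel]) else NA_real_
  }, numeric(1))
}

#' Control region of the entropy-complexity plane
#'
#' Bounding box of the control window means across patients; in stable
#' controls this box is small (the study reports roughly H 0.84-0.86 by
#' C 0.13-0.14) and sits near the f^(-2.5) noise landmark.
#'
#' @param trajectories a single \code{hc_trajectory} or a list of them
#'   (one per patient).
#' @return list of class \code{control_region}: \code{H_range},
#'   \code{C_range}, \code{n_windows}.
#' @export
control_region <- function(trajectories) {
  if (inherits(trajectories, "hc_trajectory"))
    trajectories <- list(trajectories)
  H <- unlist(lapply(trajectories, function(t) t$H[t$n_beats > 0]))
  C <- unlist(lapply(trajectories, function(t) t$C[t$n_beats > 0]))
  H <- H[is.finite(H)]; C <- C[is.finite(C)]
  if (!length(H)) stop("no non-empty control windows")
  structure(list(H_range = range(H), C_range = range(C),
                 n_windows = length(H)),
            class = "control_region")
}

#' @export
print.control_region <- function(x, ...) {
  cat(sprintf("Control region: H %.3f-%.3f x C %.3f-%.3f (%d windows)\n",
              x$H_range[1], x$H_range[2], x$C_range[1], x$C_range[2],
              x$n_windows))
  invisible(x)
}
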