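# Synthetic phase-structured ECG cohort generator.
#
# The beat model is plumbing for exercising the analysis chain, not a
# physiological simulation: each beat is a sum of Gaussian-shaped
# P/Q/R/S/T components on an orthogonal XYZ dipole, projected to the eight
# standard leads through a right-inverse of the Kors matrix so that the
# Kors transform recovers the dipole exactly. Two qualitative ischaemia
# profiles are provided: an "LAD-like" profile that grows a broad
# monophasic ST-T component (the ECG deforming towards an action-potential
# -like waveform), and an "RCA-like" profile that adds beat-to-beat
# irregularity confined to the ST-T segment.

# base dipole components: center (ms relative to R), width (ms),
# amplitude on X, Y, Z (uV)
.beat_components <- function(st_amp = 0) {
  comps <- rbind(
    P = c(-180, 22,   40,   55,   18),
    Q = c(-28,   8,  -90, -130,  -45),
    R = c(0,    11,  850, 1150,  380),
    S = c(32,    9, -190, -280,  -95),
    T = c(185,  55,  170,  240,   80))
  if (st_amp > 0) {
    # broad ST-T merge component: raises the ST segment into a single
    # smooth repolarization wave
    comps <- rbind(comps,
                   ST = c(110, 85, 520 * st_amp, 700 * st_amp, 230 * st_amp))
  }
  colnames(comps) <- c("center", "width", "ax", "ay", "az")
  comps
}

# right-inverse of the Kors matrix: 8x3 weights W with K %*% W = I3
.kors_rinv <- function() {
  K <- kors_matrix()
  t(K) %*% solve(K %*% t(K))
}

# evaluate the XYZ dipole of one beat on a time grid (ms relative to R)
.dipole <- function(t_ms, comps) {
  out <- matrix(0, length(t_ms), 3L)
  for (i in seq_len(nrow(comps))) {
    g <- exp(-0.5 * ((t_ms - comps[i, "center"]) / comps[i, "width"])^2)
    out <- out + outer(g, comps[i, c("ax", "ay", "az")])
  }
  out
}

# random ST-T irregularity: broadband micro-fluctuation confined to the
# repolarization segment by a smooth envelope, fresh for every beat (uses
# the current RNG stream). Fine-scale roughness is what raises the ordinal
# entropy of a beat at millisecond delays; smooth morphology changes only
# add order.
.stt_fluctuation <- function(t_ms, sigma) {
  n <- length(t_ms)
  if (sigma <= 0) return(matrix(0, n, 3L))
  env <- exp(-0.5 * ((t_ms - 170) / 80)^2)
  matrix(stats::rnorm(3L * n, sd = sigma), n, 3L) * env
}

#' Generate one synthetic 8-lead ECG beat
#'
#' Evaluates the Gaussian-component beat model for a single beat and
#' projects it onto the eight standard leads (I, II, V1-V6) with
#' Kors-consistent weights. Ground-truth fiducials are returned with the
#' signal.
#'
#' @param morph list of morphology parameters: \code{st_amp} (0-1,
#'   LAD-like monophasic ST-T deformation) and \code{stt_sigma}
#'   (microvolts, RCA-like beat-to-beat ST-T irregularity).
#' @param fs sampling rate, >= 250 Hz.
#' @param pre_ms,post_ms segment extent around the R peak.
#' @param seed optional seed (the ST-T fluctuation is random).
#' @return list: \code{leads} (samples x 8 matrix, microvolts),
#'   \code{lead_names}, \code{fs}, \code{r_index} and \code{q_index}
#'   (1-based ground-truth sample indices of the R peak and Q onset).
#' @export
generate_synthetic_beat <- function(morph = list(st_amp = 0, stt_sigma = 0),
                                    fs = 1000, pre_ms = 350, post_ms = 450,
                                    seed = NULL) {
  if (fs < 250) stop("fs must be >= 250 Hz")
  if (!is.null(seed)) set.seed(seed)
  st_amp <- if (is.null(morph$st_amp)) 0 else morph$st_amp
  stt_sigma <- if (is.null(morph$stt_sigma)) 0 else morph$stt_sigma
  t_ms <- seq(-pre_ms, post_ms, by = 1000 / fs)
  d <- .dipole(t_ms, .beat_components(st_amp)) +
    .stt_fluctuation(t_ms, stt_sigma)
  leads <- d %*% t(.kors_rinv())
  colnames(leads) <- colnames(kors_matrix())
  list(leads = leads, lead_names = colnames(leads), fs = fs,
       r_index = which.min(abs(t_ms)),
       q_index = which.min(abs(t_ms + 45)))
}

#' Synthetic cohort specification
#'
#' Defines the study conditions emulated by the generator: a cohort of
#' patients each contributing a five-minute control record and a PTCA
#' record with an occlusion phase (balloon inflation to deflation, duration
#' drawn around 4 min 6 s with a 90 s standard deviation) and a recovery
#' phase (mean about 3.7 min). Nine patients follow the LAD-like occlusion
#' profile and fifteen the RCA-like profile by default.
#'
#' @param n_patients cohort size.
#' @param arteries per-patient profile labels, \code{"LAD"} or \code{"RCA"}.
#' @param control_s control-record duration (seconds).
#' @param occlusion_mean_s,occlusion_sd_s occlusion duration distribution.
#' @param recovery_mean_s,recovery_sd_s recovery duration distribution.
#' @param heart_rate_bpm mean heart rate; per-patient rates vary around it.
#' @param noise_rms broadband additive noise RMS per lead (microvolts).
#' @param wander_amplitude baseline respiratory wander amplitude
#'   (microvolts, about 0.25 Hz).
#' @param st_max peak LAD-like ST-T deformation (0-1 scale).
#' @param stt_sigma_max peak RCA-like ST-T irregularity (microvolts).
#' @param quantum amplitude resolution (microvolts) applied to the output.
#' @return list of class \code{cohort_spec}.
#' @export
cohort_spec <- function(n_patients = 24L,
                        arteries = rep(c("LAD", "RCA"), c(9L, 15L)),
                        control_s = 300,
                        occlusion_mean_s = 246, occlusion_sd_s = 90,
                        recovery_mean_s = 222, recovery_sd_s = 60,
                        heart_rate_bpm = 70,
                        noise_rms = 4,
                        wander_amplitude = 60,
                        st_max = 1.0,
                        stt_sigma_max = 12,
                        quantum = 0.6) {
  n_patients <- as.integer(n_patients)
  if (length(arteries) == 2L && n_patients != 2L && is.null(names(arteries)))
    arteries <- rep(arteries, length.out = n_patients)
  if (length(arteries) != n_patients)
    stop("arteries must give one profile per patient")
  if (!all(arteries %in% c("LAD", "RCA")))
    stop("arteries must be 'LAD' or 'RCA'")
  structure(list(n_patients = n_patients, arteries = arteries,
                 control_s = control_s,
                 occlusion_mean_s = occlusion_mean_s,
                 occlusion_sd_s = occlusion_sd_s,
                 recovery_mean_s = recovery_mean_s,
                 recovery_sd_s = recovery_sd_s,
                 heart_rate_bpm = heart_rate_bpm,
                 noise_rms = noise_rms,
                 wander_amplitude = wander_amplitude,
                 st_max = st_max, stt_sigma_max = stt_sigma_max,
                 quantum = quantum),
            class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf("Synthetic cohort spec: %d patients (%d LAD-like, %d RCA-like)\n",
              x$n_patients, sum(x$arteries == "LAD"), sum(x$arteries == "RCA")))
  cat(sprintf("  control %g s; occlusion %g +/- %g s; recovery %g +/- %g s\n",
              x$control_s, x$occlusion_mean_s, x$occlusion_sd_s,
              x$recovery_mean_s, x$recovery_sd_s))
  cat(sprintf("  noise %g uV RMS, wander %g uV, st_max %g, stt_sigma_max %g uV\n",
              x$noise_rms, x$wander_amplitude, x$st_max, x$stt_sigma_max))
  invisible(x)
}

# morphology profile at time t (seconds) within a phase.
# Occlusion: LAD ramps the ST-T merge amplitude linearly to st_max;
# RCA stays quiescent for the first half, then ramps ST-T irregularity.
# Recovery (both profiles): starts from a regularized reperfusion state
# (moderate ST-T merge, no irregularity) that decays exponentially back
# towards the control morphology.
.morph_at <- function(artery, phase, t, duration, spec) {
  if (phase == "control") return(list(st_amp = 0, stt_sigma = 0))
  if (phase == "occlusion") {
    frac <- min(1, max(0, t / duration))
    if (artery == "LAD")
      return(list(st_amp = spec$st_max * frac, stt_sigma = 0))
    # RCA-like: quiescent for the first half of the occlusion, then the
    # ST-T irregularity ramps up over the second half
    on <- (t - duration / 2) / (duration / 2)
    return(list(st_amp = 0,
                stt_sigma = spec$stt_sigma_max * min(1, max(0, on))))
  }
  # recovery
  a0 <- if (artery == "LAD") 0.65 * spec$st_max else 0.35 * spec$st_max
  list(st_amp = a0 * exp(-t / max(1e-9, duration / 2.5)), stt_sigma = 0)
}

# generate one continuous multi-phase record; phases is a data.frame with
# columns phase, duration. Uses the current RNG stream.
.generate_record <- function(spec, artery, phases, fs = 1000, id = NULL) {
  rr_mean <- 60 / spec$hr_bpm
  total <- sum(phases$duration)
  n <- round(total * fs)
  leads <- matrix(0, n, 8L)
  W <- .kors_rinv()
  pre_ms <- 350; post_ms <- 450
  t_rel <- seq(-pre_ms, post_ms, by = 1000 / fs)
  nseg <- length(t_rel)

  truth <- list()
  phase_start <- 0
  for (ph in seq_len(nrow(phases))) {
    phase <- phases$phase[ph]
    dur <- phases$duration[ph]
    t_beat <- phase_start + rr_mean * 0.6 # settle-in before first beat
    while (t_beat < phase_start + dur - post_ms / 1000) {
      m <- .morph_at(artery, phase, t_beat - phase_start, dur, spec)
      comps <- .beat_components(m$st_amp)
      d <- .dipole(t_rel, comps) + .stt_fluctuation(t_rel, m$stt_sigma)
      seg <- d %*% t(W)
      r_idx <- round(t_beat * fs)
      lo <- r_idx - round(pre_ms / 1000 * fs)
      sel <- seq.int(lo, length.out = nseg)
      ok <- sel >= 1L & sel <= n
      leads[sel[ok], ] <- leads[sel[ok], ] + seg[ok, ]
      truth[[length(truth) + 1L]] <-
        data.frame(phase = phase, t_r = t_beat, r_sample = r_idx,
                   q_sample = r_idx - round(0.045 * fs),
                   st_amp = m$st_amp, stt_sigma = m$stt_sigma)
      t_beat <- t_beat + rr_mean + stats::rnorm(1, sd = 0.012)
    }
    phase_start <- phase_start + dur
  }

  # baseline wander (respiratory band) + broadband noise + quantization
  tt <- seq_len(n) / fs
  if (spec$wander_amplitude > 0) {
    wander <- spec$wander_amplitude *
      (sin(2 * pi * 0.25 * tt + stats::runif(1, 0, 2 * pi)) +
         0.5 * sin(2 * pi * 0.09 * tt + stats::runif(1, 0, 2 * pi)))
    wcoef <- stats::rnorm(8L, 1, 0.15)
    leads <- leads + outer(wander, wcoef)
  }
  if (spec$noise_rms > 0)
    leads <- leads + matrix(stats::rnorm(n * 8L, sd = spec$noise_rms), n, 8L)
  if (spec$quantum > 0)
    leads <- round(leads / spec$quantum) * spec$quantum

  truth <- do.call(rbind, truth)
  total <- n / fs # realized duration after rounding to whole samples
  ann <- if (identical(phases$phase, "control")) {
    list(control = c(0, total), end = total)
  } else {
    list(inflation = phases$duration[1L],
         deflation = phases$duration[1L] + phases$duration[2L],
         end = total)
  }
  list(record = ecg_record(leads, colnames(kors_matrix()), fs,
                           annotations = ann, id = id),
       truth = truth)
}

#' Generate a synthetic PTCA cohort
#'
#' Produces, for every patient, a control record and a PTCA record (a short
#' pre-inflation lead-in, the occlusion phase, and the recovery phase) with
#' sidecar-style annotations and per-beat ground truth (true R and Q-onset
#' samples, phase labels and morphology trajectory). All randomness flows
#' from \code{seed}.
#'
#' @param spec \code{cohort_spec}.
#' @param seed integer seed.
#' @param patients optional subset of patient indices to generate (the
#'   per-patient random streams are unchanged, so patient 7 of a subset is
#'   identical to patient 7 of the full cohort).
#' @return list of class \code{synthetic_cohort}; each element has
#'   \code{id}, \code{artery}, \code{control} / \code{ptca}
#'   (\code{ecg_record}), \code{truth} (list of per-beat ground-truth
#'   tables), and \code{durations}.
#' @export
generate_cohort <- function(spec = cohort_spec(), seed = 1L,
                            patients = seq_len(spec$n_patients)) {
  stopifnot(inherits(spec, "cohort_spec"))
  out <- vector("list", length(patients))
  for (j in seq_along(patients)) {
    i <- patients[j]
    out[[j]] <- generate_patient(spec, i, seed)
  }
  names(out) <- vapply(out, `[[`, character(1), "id")
  structure(out, class = "synthetic_cohort", seed = seed, spec = spec)
}

#' Generate one patient of a synthetic cohort
#'
#' @inheritParams generate_cohort
#' @param i patient index within the cohort.
#' @return one patient element as described in [generate_cohort()].
#' @export
generate_patient <- function(spec, i, seed = 1L) {
  stopifnot(inherits(spec, "cohort_spec"), i >= 1L, i <= spec$n_patients)
  set.seed((seed * 1000L + i) %% .Machine$integer.max)
  artery <- spec$arteries[i]
  hr <- min(95, max(50, stats::rnorm(1, spec$heart_rate_bpm, 7)))
  occ <- min(420, max(150, stats::rnorm(1, spec$occlusion_mean_s,
                                        spec$occlusion_sd_s)))
  rec <- min(400, max(90, stats::rnorm(1, spec$recovery_mean_s,
                                       spec$recovery_sd_s)))
  pspec <- spec
  pspec$hr_bpm <- hr
  id <- sprintf("P%02d_%s", i, artery)
  ctrl <- .generate_record(pspec, artery,
                           data.frame(phase = "control",
                                      duration = spec$control_s),
                           id = paste0(id, "_control"))
  ptca <- .generate_record(pspec, artery,
                           data.frame(phase = c("lead_in", "occlusion",
                                                "recovery"),
                                      duration = c(10, occ, rec)),
                           id = paste0(id, "_ptca"))
  list(id = id, artery = artery, heart_rate = hr,
       control = ctrl$record, ptca = ptca$record,
       truth = list(control = ctrl$truth, ptca = ptca$truth),
       durations = c(control = spec$control_s, occlusion = occ,
                     recovery = rec))
}

#' Write a synthetic cohort to disk
#'
#' Writes, per patient, the control and PTCA records as CSV (the same
#' dialect [read_ecg_csv()] consumes), sidecar annotation JSONs, and
#' ground-truth CSVs.
#'
#' @param cohort \code{synthetic_cohort}.
#' @param dir output directory (created if missing).
#' @return the directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (p in cohort) {
    write_ecg_csv(p$control, file.path(dir, paste0(p$id, "_control.csv")))
    write_ecg_csv(p$ptca, file.path(dir, paste0(p$id, "_ptca.csv")))
    utils::write.csv(p$truth$control,
                     file.path(dir, paste0(p$id, "_control_truth.csv")),
                     row.names = FALSE)
    utils::write.csv(p$truth$ptca,
                     file.path(dir, paste0(p$id, "_ptca_truth.csv")),
                     row.names = FALSE)
  }
  invisible(dir)
}
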