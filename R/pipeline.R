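#' Analysis run configuration
#'
#' Bundles every tunable of the processing chain with the study defaults:
#' ordinal embedding D = 4, tau = 2 (24 pattern symbols); 512 ms beat
#' windows; 75 percent template-correlation acceptance; 20 microvolt pre-Q
#' RMS record gate over 20 ms; 30 s occlusion and 15 s recovery averaging
#' windows; 60 Hz mains notch; significance level 0.05.
#'
#' @param D,tau ordinal embedding dimension and delay.
#' @param window_ms beat window length (ms).
#' @param xcorr_threshold template-correlation acceptance threshold.
#' @param rms_limit record-exclusion RMS limit (microvolts).
#' @param pre_q_ms pre-Q noise-gate segment (ms).
#' @param occlusion_window_s,recovery_window_s trajectory window widths (s).
#' @param control_window_s control trajectory window width (s).
#' @param line_freq mains frequency (Hz).
#' @param alpha significance level.
#' @param seed integer seed for every stochastic step downstream.
#' @return list of class \code{run_config} with a \code{hash} attribute
#'   that changes iff any parameter changes.
#' @export
run_config <- function(D = 4L, tau = 2L, window_ms = 512,
                       xcorr_threshold = 0.75, rms_limit = 20,
                       pre_q_ms = 20, occlusion_window_s = 30,
                       recovery_window_s = 15, control_window_s = 30,
                       line_freq = 60, alpha = 0.05, seed = 1L) {
  cfg <- list(D = as.integer(D), tau = as.integer(tau),
              window_ms = window_ms, xcorr_threshold = xcorr_threshold,
              rms_limit = rms_limit, pre_q_ms = pre_q_ms,
              occlusion_window_s = occlusion_window_s,
              recovery_window_s = recovery_window_s,
              control_window_s = control_window_s,
              line_freq = line_freq, alpha = alpha, seed = as.integer(seed))
  structure(cfg, hash = config_hash(cfg), class = "run_config")
}

#' Configuration hash
#'
#' FNV-1a hash of the deparsed parameter list; reports carry it so any
#' parameter override is visible in the outputs.
#'
#' @param cfg \code{run_config} or plain list.
#' @return 8-hex-digit character hash.
#' @export
config_hash <- function(cfg) {
  s <- paste(names(cfg), vapply(cfg, function(v) paste(format(v, digits = 15),
                                                       collapse = ","),
                                character(1)),
             sep = "=", collapse = ";")
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

#' @export
print.run_config <- function(x, ...) {
  cat(sprintf("Run config [%s]: D=%d tau=%d, window %g ms, xcorr>%.2f, RMS limit %g uV,\n",
              attr(x, "hash"), x$D, x$tau, x$window_ms, x$xcorr_threshold,
              x$rms_limit))
  cat(sprintf("  windows occlusion %g s / recovery %g s, notch %g Hz, alpha %g, seed %d\n",
              x$occlusion_window_s, x$recovery_window_s, x$line_freq,
              x$alpha, x$seed))
  invisible(x)
}

# preprocess one raw 8-lead record and segment its beats; fiducials from
# sidecar annotations (r_samples/q_samples, 0-based) are honoured.
.process_record <- function(record, config) {
  ann <- record$annotations
  rec <- notch_filter(record, config$line_freq)
  ii <- rec$signals[, match("ii", tolower(rec$leads))]
  r <- if (!is.null(ann$r_samples)) as.integer(ann$r_samples) + 1L
       else detect_r_waves(ii, rec$fs)
  q <- if (!is.null(ann$q_samples)) as.integer(ann$q_samples) + 1L
       else if (length(r)) find_q_onsets(ii, r, rec$fs) else integer(0)
  # baseline knots: midpoint of the 20 ms isoelectric segment before Q
  knots <- q - round(config$pre_q_ms / 2 / 1000 * rec$fs)
  knots <- knots[knots >= 1]
  if (length(knots) >= 4L) rec <- remove_baseline(rec, knots)
  m <- vector_modulus(kors_transform(rec))
  bs <- if (length(r)) {
    b <- extract_windows(m, r, config$window_ms, q_onsets = q)
    if (nrow(b$windows) >= 3L) b <- accept_beats(b, threshold = config$xcorr_threshold)
    else b$accepted <- rep(FALSE, nrow(b$windows))
    rms_noise_gate(b, pre_q_ms = config$pre_q_ms, limit = config$rms_limit)
  } else {
    b <- extract_windows(m, integer(0))
    b$record_excluded <- FALSE
    b
  }
  bs
}

#' Analyse one patient (control record + PTCA record)
#'
#' Runs the full chain for a single patient: preprocessing and beat QC on
#' both records, Mean Control PDF, per-beat quantifiers and JSD for the
#' control, occlusion and recovery phases, windowed trajectories, and
#' endpoint delta metrics.
#'
#' @param control \code{ecg_record} of the control session.
#' @param ptca \code{ecg_record} of the PTCA session, annotated with
#'   \code{inflation}, \code{deflation} and \code{end} times.
#' @param config \code{run_config}.
#' @param id patient identifier.
#' @param artery optional occlusion-site label carried into reports.
#' @return list of class \code{patient_analysis}; \code{excluded} is TRUE
#'   when either record fails the RMS noise gate (quantifiers are then not
#'   computed).
#' @export
analyze_patient <- function(control, ptca, config = run_config(),
                            id = NULL, artery = NA_character_) {
  if (is.null(id)) id <- if (!is.null(control$id)) control$id else "patient"
  bs_ctrl <- .process_record(control, config)
  bs_ptca <- .process_record(ptca, config)
  excluded <- isTRUE(bs_ctrl$record_excluded) || isTRUE(bs_ptca$record_excluded)
  exclusion_reason <- if (excluded)
    sprintf("pre-Q RMS noise gate (> %g uV)", config$rms_limit) else NA_character_

  out <- list(id = id, artery = artery, excluded = excluded,
              exclusion_reason = exclusion_reason,
              qc = list(control = beat_qc(bs_ctrl), ptca = beat_qc(bs_ptca)))
  if (excluded) return(structure(out, class = "patient_analysis"))

  ann_c <- control$annotations
  cw <- if (!is.null(ann_c$control)) ann_c$control
        else c(0, length(bs_ctrl$series) / bs_ctrl$fs)
  ctrl <- per_beat_quantifiers(bs_ctrl, "control", cw[1], cw[2],
                               D = config$D, tau = config$tau)
  if (!length(ctrl$H)) {
    out$excluded <- TRUE
    out$exclusion_reason <- "no accepted control beats"
    return(structure(out, class = "patient_analysis"))
  }
  mcp <- mean_control_pdf(ctrl)
  ctrl <- jsd_to_reference(ctrl, mcp)

  ann <- ptca$annotations
  if (is.null(ann$inflation) || is.null(ann$deflation))
    stop("PTCA record needs inflation/deflation annotations")
  t_end <- if (!is.null(ann$end)) ann$end else length(bs_ptca$series) / bs_ptca$fs
  occ <- per_beat_quantifiers(bs_ptca, "occlusion", ann$inflation,
                              ann$deflation, config$D, config$tau, mcp)
  rec <- per_beat_quantifiers(bs_ptca, "recovery", ann$deflation, t_end,
                              config$D, config$tau, mcp)

  traj <- list(control = window_average(ctrl, config$control_window_s),
               occlusion = window_average(occ, config$occlusion_window_s),
               recovery = window_average(rec, config$recovery_window_s))
  deltas <- list(
    occlusion = tryCatch(delta_metrics(traj$occlusion), error = function(e) NULL),
    recovery = tryCatch(delta_metrics(traj$recovery), error = function(e) NULL))

  n_occ <- sum(traj$occlusion$n_beats > 0)
  n_rec <- sum(traj$recovery$n_beats > 0)
  sections <- list(
    occlusion_control = if (n_occ) control_sections(ctrl, nrow(traj$occlusion)) else numeric(0),
    recovery_control = if (n_rec) control_sections(ctrl, nrow(traj$recovery)) else numeric(0))

  out <- c(out, list(mean_control_pdf = mcp,
                     phases = list(control = ctrl, occlusion = occ,
                                   recovery = rec),
                     trajectories = traj, deltas = deltas,
                     control_sections = sections))
  structure(out, class = "patient_analysis")
}

#' @export
print.patient_analysis <- function(x, ...) {
  cat(sprintf("Patient %s (%s)%s\n", x$id, x$artery,
              if (x$excluded) paste0(" - EXCLUDED: ", x$exclusion_reason) else ""))
  if (!x$excluded) {
    for (ph in names(x$phases))
      cat(sprintf("  %-9s: %3d beats, mean H %.3f, mean C %.3f\n", ph,
                  length(x$phases[[ph]]$H), mean(x$phases[[ph]]$H),
                  mean(x$phases[[ph]]$C)))
    if (!is.null(x$deltas$occlusion))
      cat("  occlusion "); print(x$deltas$occlusion)
  }
  invisible(x)
}

#' Run the full study over a cohort
#'
#' Orchestrates the complete replication: per-patient analysis
#' ([analyze_patient()]), cross-patient control region, per-section JSD
#' statistics (occlusion vs control and recovery vs control), delta
#' summaries by occlusion site, k-noise plane landmarks, and (optionally)
#' CSV/JSON reports under an output directory with a manifest.
#'
#' Patients whose records fail the noise gate are excluded and logged,
#' never silently dropped.
#'
#' @param x a \code{cohort_spec} (records are generated patient by patient
#'   and discarded after analysis, keeping memory flat) or a list of
#'   patients, each a list with \code{control} and \code{ptca}
#'   \code{ecg_record}s and optional \code{id} / \code{artery}.
#' @param config \code{run_config}; its \code{seed} drives cohort
#'   generation and the landmark Monte-Carlo.
#' @param output_dir optional report directory.
#' @param landmarks compute k-noise plane landmarks.
#' @return object of class \code{hc_study}.
#' @export
run_study <- function(x, config = run_config(), output_dir = NULL,
                      landmarks = TRUE) {
  if (inherits(x, "cohort_spec")) {
    n <- x$n_patients
    get_patient <- function(i) generate_patient(x, i, seed = config$seed)
    input_desc <- sprintf("synthetic cohort (n=%d, seed=%d)", n, config$seed)
  } else if (is.list(x) && length(x)) {
    n <- length(x)
    get_patient <- function(i) x[[i]]
    input_desc <- sprintf("%d supplied patient record pairs", n)
  } else stop("no records to analyse")

  patients <- vector("list", n)
  for (i in seq_len(n)) {
    p <- get_patient(i)
    pid <- if (!is.null(p$id)) p$id else sprintf("P%02d", i)
    art <- if (!is.null(p$artery)) p$artery else NA_character_
    patients[[i]] <- analyze_patient(p$control, p$ptca, config,
                                     id = pid, artery = art)
  }
  names(patients) <- vapply(patients, `[[`, character(1), "id")
  ok <- !vapply(patients, `[[`, logical(1), "excluded")

  ctrl_region <- if (any(ok))
    control_region(lapply(patients[ok], function(p) p$trajectories$control))
  else NULL

  sec_tests <- list(
    occlusion = .section_tests(patients[ok], "occlusion", config$alpha),
    recovery = .section_tests(patients[ok], "recovery", config$alpha))

  lms <- if (landmarks)
    knoise_landmarks(c(0, 1, 2, 2.5, 3), D = config$D, tau = config$tau,
                     seed = config$seed)
  else NULL
  env <- complexity_envelope(factorial(config$D))

  study <- structure(list(patients = patients, config = config,
                          control_region = ctrl_region,
                          section_tests = sec_tests,
                          landmarks = lms, envelope = env,
                          input = input_desc,
                          n_excluded = sum(!ok)),
                     class = "hc_study")
  if (!is.null(output_dir)) write_study(study, output_dir)
  study
}

# per-section unpaired comparisons across patients: phase window mean JSD
# vs the matching control section mean
.section_tests <- function(patients, phase, alpha) {
  if (!length(patients)) return(NULL)
  n_sec <- max(vapply(patients, function(p) nrow(p$trajectories[[phase]]),
                      numeric(1)), 0)
  if (n_sec < 1) return(NULL)
  rows <- list()
  for (s in seq_len(n_sec)) {
    a <- vapply(patients, function(p) {
      tr <- p$trajectories[[phase]]
      if (s <= nrow(tr) && tr$n_beats[s] > 0) tr$jsd[s] else NA_real_
    }, numeric(1))
    b <- vapply(patients, function(p) {
      cs <- p$control_sections[[paste0(phase, "_control")]]
      if (s <= length(cs)) cs[s] else NA_real_
    }, numeric(1))
    a <- a[is.finite(a)]; b <- b[is.finite(b)]
    if (length(a) >= 3L && length(b) >= 3L) {
      ht <- compare_sections(a, b, alpha)
      rows[[s]] <- data.frame(section = s, n_phase = ht$n_a,
                              n_control = ht$n_b,
                              mean_phase = mean(a), mean_control = mean(b),
                              test_used = ht$test_used,
                              p_value = ht$p_value,
                              significant = ht$significant)
    }
  }
  if (!length(rows)) return(NULL)
  do.call(rbind, rows)
}

#' Per-patient delta table of a study
#'
#' @param study \code{hc_study}.
#' @return data.frame: patient, artery, phase, delta_H, delta_C and the
#'   endpoint values.
#' @export
delta_table <- function(study) {
  stopifnot(inherits(study, "hc_study"))
  rows <- list()
  for (p in study$patients) {
    if (p$excluded) next
    for (ph in c("occlusion", "recovery")) {
      d <- p$deltas[[ph]]
      if (is.null(d)) next
      rows[[length(rows) + 1L]] <-
        data.frame(patient = p$id, artery = p$artery, phase = ph,
                   delta_H = d$delta_H, delta_C = d$delta_C,
                   H_initial = d$H_initial, H_final = d$H_final,
                   C_initial = d$C_initial, C_final = d$C_final)
    }
  }
  if (!length(rows)) return(NULL)
  do.call(rbind, rows)
}

#' Per-window trajectory table of a study
#'
#' @param study \code{hc_study}.
#' @return data.frame: patient, artery, phase, window_center, H, C, Q,
#'   jsd, n_beats.
#' @export
trajectory_table <- function(study) {
  stopifnot(inherits(study, "hc_study"))
  rows <- list()
  for (p in study$patients) {
    if (p$excluded) next
    for (ph in names(p$trajectories)) {
      tr <- p$trajectories[[ph]]
      rows[[length(rows) + 1L]] <-
        data.frame(patient = p$id, artery = p$artery, phase = ph,
                   as.data.frame(tr))
    }
  }
  do.call(rbind, rows)
}

#' Write study reports
#'
#' Emits the report bundle: per-window trajectories, per-patient deltas,
#' per-section statistics, beat-level QC, plane data (envelope + k-noise
#' landmarks), a JSON summary and a manifest carrying the configuration
#' hash and seed.
#'
#' @param study \code{hc_study}.
#' @param dir output directory (created if missing).
#' @return the directory, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "hc_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(d, f) if (!is.null(d)) utils::write.csv(d, file.path(dir, f),
                                                        row.names = FALSE)
  w(trajectory_table(study), "trajectories.csv")
  w(delta_table(study), "deltas.csv")
  w(study$section_tests$occlusion, "sections_occlusion.csv")
  w(study$section_tests$recovery, "sections_recovery.csv")
  qc <- do.call(rbind, lapply(study$patients, function(p) {
    rbind(data.frame(patient = p$id, record = "control", p$qc$control),
          data.frame(patient = p$id, record = "ptca", p$qc$ptca))
  }))
  w(qc, "beat_qc.csv")
  excl <- do.call(rbind, lapply(study$patients, function(p)
    data.frame(patient = p$id, excluded = p$excluded,
               reason = p$exclusion_reason)))
  w(excl, "record_qc.csv")
  env <- study$envelope
  w(data.frame(H = env$H, Cmin = env$Cmin, Cmax = env$Cmax), "envelope.csv")
  if (!is.null(study$landmarks)) w(as.data.frame(study$landmarks),
                                   "knoise_landmarks.csv")
  sm <- summary(study)
  jsonlite::write_json(list(
    control_region = if (!is.null(study$control_region))
      list(H = study$control_region$H_range, C = study$control_region$C_range),
    deltas = sm$delta_summary,
    significant_sections = sm$significant_sections,
    n_excluded = study$n_excluded), file.path(dir, "summary.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "rows")
  jsonlite::write_json(list(
    input = study$input,
    config = unclass(study$config),
    config_hash = attr(study$config, "hash"),
    seed = study$config$seed,
    package_version = as.character(utils::packageVersion("ecgcomplexity")),
    r_version = R.version.string,
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
    file.path(dir, "manifest.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' @export
print.hc_study <- function(x, ...) {
  cat(sprintf("HxC study of %s: %d patients (%d excluded by QC)\n",
              x$input, length(x$patients), x$n_excluded))
  if (!is.null(x$control_region)) print(x$control_region)
  invisible(x)
}

#' Summarize a study
#'
#' @param object \code{hc_study}.
#' @param ... unused.
#' @return list of class \code{summary.hc_study}: per-site/phase mean
#'   delta table, control region, landmark table, significant-section
#'   counts.
#' @export
summary.hc_study <- function(object, ...) {
  dt <- delta_table(object)
  ds <- if (!is.null(dt)) {
    agg <- stats::aggregate(cbind(delta_H, delta_C) ~ artery + phase,
                            data = dt, FUN = mean)
    agg[order(agg$artery, agg$phase), ]
  } else NULL
  sig <- lapply(object$section_tests, function(st)
    if (is.null(st)) c(significant = 0L, tested = 0L)
    else c(significant = sum(st$significant), tested = nrow(st)))
  structure(list(input = object$input,
                 n_patients = length(object$patients),
                 n_excluded = object$n_excluded,
                 delta_summary = ds,
                 control_region = object$control_region,
                 landmarks = object$landmarks,
                 significant_sections = sig),
            class = "summary.hc_study")
}

#' @export
print.summary.hc_study <- function(x, ...) {
  cat(sprintf("HxC study summary - %s (%d patients, %d excluded)\n",
              x$input, x$n_patients, x$n_excluded))
  if (!is.null(x$control_region)) print(x$control_region)
  if (!is.null(x$delta_summary)) {
    cat("\nMean relative endpoint changes by occlusion site:\n")
    d <- x$delta_summary
    for (i in seq_len(nrow(d)))
      cat(sprintf("  %-4s %-9s deltaH %+6.1f%%  deltaC %+6.1f%%\n",
                  d$artery[i], d$phase[i], 100 * d$delta_H[i],
                  100 * d$delta_C[i]))
  }
  for (ph in names(x$significant_sections)) {
    s <- x$significant_sections[[ph]]
    cat(sprintf("\n%s vs control: %d of %d sections significant", ph,
                s["significant"], s["tested"]))
  }
  cat("\n")
  if (!is.null(x$landmarks)) {
    cat("\nk-noise landmarks (H, C):\n")
    lm <- x$landmarks
    for (i in seq_len(nrow(lm)))
      cat(sprintf("  k = %-3g H %.3f  C %.3f\n", lm$k[i], lm$H[i], lm$C[i]))
  }
  invisible(x)
}

#' Plot a study in the entropy-complexity plane
#'
#' Draws the Cmin/Cmax envelope, the control-region box, the k-noise
#' landmarks and the per-patient occlusion and recovery window means.
#'
#' @param x \code{hc_study}.
#' @param phases which phases to draw.
#' @param ... passed to the envelope plot.
#' @export
plot.hc_study <- function(x, phases = c("occlusion", "recovery"), ...) {
  plot(x$envelope, ...)
  if (!is.null(x$control_region)) {
    cr <- x$control_region
    graphics::rect(cr$H_range[1], cr$C_range[1], cr$H_range[2],
                   cr$C_range[2], border = "black", lwd = 2)
  }
  cols <- c(occlusion = "red", recovery = "blue", control = "grey40")
  for (p in x$patients) {
    if (p$excluded) next
    for (ph in phases) {
      tr <- p$trajectories[[ph]]
      sel <- tr$n_beats > 0
      graphics::points(tr$H[sel], tr$C[sel], col = cols[[ph]], pch = 20,
                       cex = 0.6)
    }
  }
  if (!is.null(x$landmarks))
    graphics::points(x$landmarks$H, x$landmarks$C, pch = 4, cex = 1.2,
                     col = "darkgreen")
  invisible(x)
}
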