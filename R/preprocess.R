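#' Power-line notch filter
#'
#' Removes mains interference with a 2nd-order Butterworth band-stop filter
#' (default -3 dB edges at \code{line_freq} +/- 1 Hz), applied
#' forward-backward for zero phase distortion, independently per lead.
#'
#' @param record \code{ecg_record}.
#' @param line_freq mains frequency in Hz (60 for the North-American grid,
#'   50 elsewhere).
#' @param width half-width of the stop band in Hz.
#' @return filtered \code{ecg_record} of identical dimensions.
#' @export
notch_filter <- function(record, line_freq = 60, width = 1) {
  stopifnot(inherits(record, "ecg_record"))
  fs <- record$fs
  if (fs <= 2 * line_freq)
    stop(sprintf("sampling rate %g Hz too low to notch %g Hz", fs, line_freq))
  bf <- signal::butter(2, c(line_freq - width, line_freq + width) / (fs / 2),
                       type = "stop")
  out <- record
  out$signals <- apply(record$signals, 2L, function(v)
    signal::filtfilt(bf, v))
  colnames(out$signals) <- record$leads
  out
}

#' Baseline-wander removal by cubic-spline subtraction
#'
#' Estimates the baseline at per-beat fiducial points (the isoelectric PR
#' segment before each QRS) as the median voltage in a short window around
#' each knot, interpolates a natural cubic spline through these estimates,
#' and subtracts it per lead. This attenuates respiratory wander and slow
#' electrode-impedance drift while leaving beat morphology intact.
#'
#' @param record \code{ecg_record}.
#' @param knots strictly increasing fiducial sample indices (>= 4).
#' @param est_ms width in ms of the median window around each knot used for
#'   the local baseline estimate.
#' @return corrected \code{ecg_record}.
#' @export
remove_baseline <- function(record, knots, est_ms = 20) {
  stopifnot(inherits(record, "ecg_record"))
  knots <- as.integer(knots)
  if (length(knots) < 4L) stop("baseline correction needs at least 4 knots")
  if (any(diff(knots) <= 0)) stop("knots must be strictly increasing")
  n <- nrow(record$signals)
  if (knots[1L] < 1L || knots[length(knots)] > n)
    stop("knots fall outside the record")
  half <- max(1L, round(est_ms / 2 * record$fs / 1000))
  out <- record
  tall <- seq_len(n)
  for (j in seq_along(record$leads)) {
    v <- record$signals[, j]
    est <- vapply(knots, function(k)
      stats::median(v[max(1L, k - half):min(n, k + half)]), numeric(1))
    base <- stats::spline(knots, est, xout = tall, method = "natural")$y
    out$signals[, j] <- v - base
  }
  out
}

#' Kors regression matrix (8 leads to orthogonal XYZ)
#'
#' The published 3 x 8 regression matrix mapping the eight independent
#' standard leads (I, II, V1-V6) to the orthogonal vectorcardiographic
#' X, Y, Z leads. Coefficients from Kors et al., the standard regression
#' reconstruction of the Frank leads.
#'
#' @return 3 x 8 numeric matrix with dimnames.
#' @export
kors_matrix <- function() {
  m <- rbind(
    X = c(I =  0.38, II = -0.07, V1 = -0.13, V2 =  0.05, V3 = -0.01,
          V4 =  0.14, V5 =  0.06, V6 =  0.54),
    Y = c(I = -0.07, II =  0.93, V1 =  0.06, V2 = -0.02, V3 = -0.05,
          V4 =  0.06, V5 = -0.17, V6 =  0.13),
    Z = c(I =  0.11, II = -0.23, V1 = -0.43, V2 = -0.06, V3 = -0.14,
          V4 = -0.20, V5 = -0.11, V6 =  0.31))
  m
}

#' Kors transform to orthogonal XYZ leads
#'
#' Applies the Kors regression matrix samplewise to an 8-lead record
#' (leads I, II, V1-V6; lead-name matching is case-insensitive).
#'
#' @param record \code{ecg_record} containing the eight independent leads.
#' @return \code{ecg_record} with leads X, Y, Z.
#' @export
kors_transform <- function(record) {
  stopifnot(inherits(record, "ecg_record"))
  km <- kors_matrix()
  want <- colnames(km)
  pos <- match(tolower(want), tolower(record$leads))
  if (anyNA(pos))
    stop("missing lead(s) for Kors transform: ",
         paste(want[is.na(pos)], collapse = ", "))
  xyz <- record$signals[, pos, drop = FALSE] %*% t(km)
  ecg_record(xyz, c("X", "Y", "Z"), record$fs,
             annotations = record$annotations, id = record$id)
}

#' ECG vector modulus
#'
#' Samplewise Euclidean magnitude of the orthogonal leads,
#' \eqn{M_t = \sqrt{X_t^2 + Y_t^2 + Z_t^2}}. The modulus condenses the
#' spatio-temporal cardiac vector loop into a single non-negative series and
#' is invariant under any rotation of the XYZ frame.
#'
#' @param record \code{ecg_record} with leads X, Y, Z.
#' @return \code{vm_series}.
#' @export
vector_modulus <- function(record) {
  stopifnot(inherits(record, "ecg_record"))
  pos <- match(c("x", "y", "z"), tolower(record$leads))
  if (anyNA(pos))
    stop("vector modulus requires leads X, Y, Z (run kors_transform first)")
  m <- sqrt(rowSums(record$signals[, pos, drop = FALSE]^2))
  vm_series(m, record$fs, annotations = record$annotations, id = record$id)
}

#' Standard preprocessing chain for an 8-lead record
#'
#' Notch filter, optional spline baseline correction (when beat fiducials
#' are available), Kors transform, vector modulus — in that order.
#'
#' @param record 8-lead \code{ecg_record}.
#' @param line_freq mains frequency (Hz).
#' @param baseline_knots optional fiducial sample indices for
#'   [remove_baseline()]; skipped when \code{NULL}.
#' @return list with the preprocessed \code{ecg_record} (\code{leads}),
#'   the XYZ record (\code{xyz}) and the \code{vm_series} (\code{modulus}).
#' @export
preprocess_record <- function(record, line_freq = 60, baseline_knots = NULL) {
  rec <- notch_filter(record, line_freq)
  if (!is.null(baseline_knots) && length(baseline_knots) >= 4L)
    rec <- remove_baseline(rec, baseline_knots)
  xyz <- kors_transform(rec)
  list(leads = rec, xyz = xyz, modulus = vector_modulus(xyz))
}
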