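#' Multi-lead ECG record
#'
#' Container for a uniformly sampled multi-lead voltage record with optional
#' procedure-phase annotations. Voltages are carried in microvolts throughout
#' the package; convert on ingest if your source uses millivolts.
#'
#' @param signals numeric matrix, one column per lead (microvolts).
#' @param leads character vector of lead names (e.g. \code{"I"}, \code{"II"},
#'   \code{"V1"}..\code{"V6"}, or \code{"X"}, \code{"Y"}, \code{"Z"}).
#' @param fs sampling rate in Hz.
#' @param annotations optional list of phase marks in seconds:
#'   \code{control = c(t0, t1)}, \code{inflation}, \code{deflation},
#'   \code{end}. Balloon inflation starts the occlusion phase; deflation
#'   starts the reperfusion (recovery) phase.
#' @param id optional record identifier.
#' @return object of class \code{ecg_record}.
#' @export
ecg_record <- function(signals, leads, fs, annotations = NULL, id = NULL) {
  signals <- as.matrix(signals)
  if (!is.numeric(signals)) stop("signals must be numeric")
  leads <- as.character(leads)
  if (length(leads) != ncol(signals))
    stop("one lead name per signal column required")
  if (anyDuplicated(leads)) stop("duplicate lead names")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) stop("fs must be a positive scalar (Hz)")
  colnames(signals) <- leads
  dur <- nrow(signals) / fs
  if (!is.null(annotations)) {
    annotations <- validate_annotations(annotations, dur)
  }
  structure(list(signals = signals, leads = leads, fs = fs,
                 annotations = annotations, id = id),
            class = "ecg_record")
}

validate_annotations <- function(ann, duration) {
  ann <- as.list(ann)
  tvals <- unlist(ann[names(ann) %in% c("control", "inflation", "deflation", "end")])
  if (any(tvals < 0) || any(tvals > duration + 1e-9))
    stop("annotation times fall outside the record")
  if (!is.null(ann$inflation) && !is.null(ann$deflation) &&
      ann$inflation >= ann$deflation)
    stop("inflation time must precede deflation time")
  if (!is.null(ann$control) && length(ann$control) != 2L)
    stop("control annotation must be a (start, end) pair")
  ann
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("Multi-lead ECG record%s: %d leads (%s), %.1f s at %g Hz\n",
              if (is.null(x$id)) "" else paste0(" '", x$id, "'"),
              length(x$leads), paste(x$leads, collapse = ", "),
              nrow(x$signals) / x$fs, x$fs))
  if (!is.null(x$annotations)) {
    a <- x$annotations
    if (!is.null(a$inflation))
      cat(sprintf("  balloon inflation %.1f s, deflation %.1f s\n",
                  a$inflation, a$deflation))
    if (!is.null(a$control))
      cat(sprintf("  control %.1f-%.1f s\n", a$control[1], a$control[2]))
  }
  invisible(x)
}

#' Vector-modulus series of an orthogonal-lead ECG
#'
#' @param values non-negative magnitude series (microvolts).
#' @param fs sampling rate (Hz).
#' @param annotations inherited phase marks (seconds).
#' @param id record identifier.
#' @return object of class \code{vm_series}.
#' @export
vm_series <- function(values, fs, annotations = NULL, id = NULL) {
  values <- as.numeric(values)
  if (any(values < 0)) stop("vector modulus must be non-negative")
  structure(list(values = values, fs = fs, annotations = annotations, id = id),
            class = "vm_series")
}

#' @export
print.vm_series <- function(x, ...) {
  cat(sprintf("ECG vector-modulus series%s: %.1f s at %g Hz, range %.1f-%.1f uV\n",
              if (is.null(x$id)) "" else paste0(" '", x$id, "'"),
              length(x$values) / x$fs, x$fs, min(x$values), max(x$values)))
  invisible(x)
}

#' Read a multi-lead ECG record from CSV
#'
#' Expects a header row of column names, a first column of time in seconds
#' and one column per lead in microvolts. Phase annotations can be supplied
#' through a sidecar JSON file (see [read_annotations_json()]).
#'
#' @param file CSV path.
#' @param annotations optional path to a sidecar annotation JSON, or an
#'   annotation list.
#' @param id record identifier (defaults to the file name).
#' @return \code{ecg_record}.
#' @export
read_ecg_csv <- function(file, annotations = NULL, id = NULL) {
  d <- utils::read.csv(file, check.names = FALSE)
  if (ncol(d) < 2L) stop("expected a time column plus at least one lead")
  tm <- d[[1L]]
  dt <- diff(tm)
  if (any(dt <= 0) || (max(dt) - min(dt)) > 1e-6 * stats::median(dt) + 1e-9)
    stop("time column must be uniformly increasing")
  fs <- 1 / stats::median(dt)
  if (is.character(annotations)) annotations <- read_annotations_json(annotations)
  ecg_record(as.matrix(d[-1L]), names(d)[-1L], fs = fs,
             annotations = annotations,
             id = if (is.null(id)) basename(file) else id)
}

#' Write a multi-lead ECG record to CSV
#'
#' Inverse of [read_ecg_csv()]; annotations, if any, go to a sidecar JSON
#' next to the CSV (same path with extension \code{.json}).
#'
#' @param record \code{ecg_record}.
#' @param file CSV path.
#' @param digits number of significant digits for voltages.
#' @return the CSV path, invisibly.
#' @export
write_ecg_csv <- function(record, file, digits = 6L) {
  stopifnot(inherits(record, "ecg_record"))
  tm <- (seq_len(nrow(record$signals)) - 1L) / record$fs
  d <- data.frame(time = tm, signif(record$signals, digits),
                  check.names = FALSE)
  utils::write.csv(d, file, row.names = FALSE)
  if (!is.null(record$annotations))
    write_annotations_json(record$annotations, sub("\\.csv$", ".json", file))
  invisible(file)
}

#' Read phase annotations from a sidecar JSON file
#'
#' The JSON object may carry \code{control} (a two-element array of seconds),
#' \code{inflation}, \code{deflation}, \code{end} (seconds), and optionally
#' \code{r_samples} / \code{q_samples} (0-based sample indices) to bypass the
#' built-in beat detector.
#'
#' @param file JSON path.
#' @return annotation list.
#' @export
read_annotations_json <- function(file) {
  jsonlite::read_json(file, simplifyVector = TRUE)
}

#' Write phase annotations to a sidecar JSON file
#'
#' @param annotations annotation list (see [read_annotations_json()]).
#' @param file JSON path.
#' @export
write_annotations_json <- function(annotations, file) {
  jsonlite::write_json(annotations, file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}
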