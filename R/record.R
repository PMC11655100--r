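#' Construct a 12-lead ECG record
#'
#' The package's core container: a 12 x N signal matrix in millivolts with
#' sampling rate and (optional) diagnostic label. Leads are always stored in
#' the standard order returned by [standard_leads()].
#'
#' @param record_id Character scalar identifying the record.
#' @param signals Numeric matrix, 12 rows (leads) x N columns (samples), mV.
#'   Row names, if present, must be the standard lead names (any order; rows
#'   are reordered).
#' @param fs Sampling rate in Hz.
#' @param label One of `"control"`, `"lvh"`, `"unknown"`.
#' @return An object of class `ecg_record`.
#' @export
ecg_record <- function(record_id, signals, fs, label = "unknown") {
  if (!is.matrix(signals) || nrow(signals) != 12L)
    stop("signals must be a 12 x N matrix (one row per lead)")
  leads <- standard_leads()
  if (!is.null(rownames(signals))) {
    if (!setequal(rownames(signals), leads))
      stop("signal row names must be exactly the 12 standard lead names")
    signals <- signals[leads, , drop = FALSE]
  } else {
    rownames(signals) <- leads
  }
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("fs must be a positive scalar (Hz)")
  if (any(!is.finite(signals)))
    stop("all signal samples must be finite")
  label <- match.arg(label, c("control", "lvh", "unknown"))
  structure(
    list(record_id = as.character(record_id), signals = signals,
         fs = fs, lead_names = leads, label = label),
    class = "ecg_record")
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record %s: 12 leads x %d samples @ %g Hz, label=%s>\n",
              x$record_id, ncol(x$signals), x$fs, x$label))
  invisible(x)
}

# Landmarks of one beat in temporal order. R is mandatory for a counted
# beat; all others may be absent (NA).
fiducial_landmarks <- function() {
  c("P_on", "P_peak", "P_off", "QRS_on", "Q", "R", "S", "J",
    "T_on", "T_peak", "T_off")
}

#' Construct a fiducial map
#'
#' One row per (lead, beat) with 1-based sample indices of the wave
#' landmarks (NA = absent) and the per-beat isoelectric baseline in mV.
#' Present indices within a beat must be strictly increasing in the order
#' P_on, P_peak, P_off, QRS_on, Q, R, S, J, T_on, T_peak, T_off.
#'
#' @param df Data frame with columns `lead`, `beat`, the eleven landmark
#'   columns and `baseline_mv`.
#' @param n_samples Record length used for bounds checking (optional).
#' @return The validated data frame with class `fiducial_map`.
#' @export
fiducial_map <- function(df, n_samples = NULL) {
  need <- c("lead", "beat", fiducial_landmarks(), "baseline_mv")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("fiducial map missing columns: ", paste(miss, collapse = ", "))
  df <- as.data.frame(df)[, need]
  validate_fiducials(df, n_samples = n_samples)
  class(df) <- c("fiducial_map", "data.frame")
  df
}

#' Check fiducial-map invariants
#'
#' Asserts that R is present for every beat, that present landmark indices
#' are strictly increasing within each beat, and that indices fall inside
#' the record.
#'
#' @param fid A fiducial map (data frame).
#' @param n_samples Optional record length for bounds checking.
#' @return Invisibly `TRUE`; stops on violation.
#' @export
validate_fiducials <- function(fid, n_samples = NULL) {
  lm <- fiducial_landmarks()
  idx <- as.matrix(fid[, lm])
  if (any(is.na(idx[, "R"]))) stop("R landmark must be present for every beat")
  if (!is.null(n_samples)) {
    rng <- range(idx, na.rm = TRUE)
    if (rng[1] < 1 || rng[2] > n_samples)
      stop("fiducial indices outside record bounds")
  }
  ok <- apply(idx, 1L, function(v) {
    v <- v[!is.na(v)]
    length(v) < 2L || all(diff(v) > 0)
  })
  if (!all(ok))
    stop("fiducial landmarks not strictly increasing within beat(s): ",
         paste(which(!ok), collapse = ", "))
  invisible(TRUE)
}
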