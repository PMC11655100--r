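#' Names of the 19 morphological features (without lead suffix)
#'
#' Six fiducial amplitudes, two amplitude ratios, eight intervals, two
#' T-wave slopes and the negative-QRS percentage.
#'
#' @return Character vector of length 19.
#' @export
morph_feature_names <- function() {
  c("P_amp", "Q_amp", "R_amp", "S_amp", "J_amp", "T_amp",
    "R_over_P", "R_over_T",
    "PR_int", "PS_int", "PT_int", "QT_int", "QRS_dur", "RS_int",
    "ToT_int", "TTe_int",
    "T_slope_asc", "T_slope_des", "QRS_neg_pct")
}

#' Extract the 19 morphological features of one lead
#'
#' Per QC-passing beat, signed amplitudes are measured relative to the beat
#' baseline at P, Q, R, S, J and T; intervals are measured between
#' landmarks (PR = P onset to QRS onset, PS = P onset to S, PT = P onset to
#' T offset, QT = QRS onset to T offset, QRS = QRS onset to J, RS = R to S,
#' ToT = T onset to T peak, TTe = T peak to T offset) and converted to ms;
#' T slopes are two-point secants from T onset to peak (ascending) and peak
#' to offset (descending) in mV/s; the negative-QRS percentage is 100 times
#' the fraction of samples in \[QRS onset, J) strictly below baseline.
#' Every quantity is the median across beats; amplitude ratios R/P and R/T
#' are formed from the median amplitudes (denominators below 0.01 mV in
#' magnitude give a missing value). A missing landmark yields a missing
#' feature, never zero.
#'
#' @param record An [ecg_record].
#' @param fiducials A [fiducial_map].
#' @param lead Lead name.
#' @param beats Optional beat numbers to use (e.g. the QC-retained beats);
#'   default all delineated beats of the lead.
#' @return Named numeric vector of length 19 (see [morph_feature_names()]).
#' @export
extract_lead_features <- function(record, fiducials, lead, beats = NULL) {
  fd <- fiducials[fiducials$lead == lead, ]
  if (!is.null(beats)) fd <- fd[fd$beat %in% beats, ]
  out <- stats::setNames(rep(NA_real_, 19L), morph_feature_names())
  if (!nrow(fd)) return(out)
  x <- record$signals[lead, ]
  fs <- record$fs

  amp_at <- function(idx) ifelse(is.na(idx), NA_real_, x[idx] - fd$baseline_mv)
  med <- function(v) if (all(is.na(v))) NA_real_ else stats::median(v, na.rm = TRUE)

  amps <- list(P = amp_at(fd$P_peak), Q = amp_at(fd$Q), R = amp_at(fd$R),
               S = amp_at(fd$S), J = amp_at(fd$J), T = amp_at(fd$T_peak))
  out[c("P_amp", "Q_amp", "R_amp", "S_amp", "J_amp", "T_amp")] <-
    vapply(amps, med, 0)

  ratio <- function(num, den) {
    if (is.na(num) || is.na(den) || abs(den) < 0.01) NA_real_ else num / den
  }
  out["R_over_P"] <- ratio(out[["R_amp"]], out[["P_amp"]])
  out["R_over_T"] <- ratio(out[["R_amp"]], out[["T_amp"]])

  iv <- function(a, b) med((b - a) / fs * 1000)
  out["PR_int"] <- iv(fd$P_on, fd$QRS_on)
  out["PS_int"] <- iv(fd$P_on, fd$S)
  out["PT_int"] <- iv(fd$P_on, fd$T_off)
  out["QT_int"] <- iv(fd$QRS_on, fd$T_off)
  out["QRS_dur"] <- iv(fd$QRS_on, fd$J)
  out["RS_int"] <- iv(fd$R, fd$S)
  out["ToT_int"] <- iv(fd$T_on, fd$T_peak)
  out["TTe_int"] <- iv(fd$T_peak, fd$T_off)

  slope <- function(i0, i1) {
    ifelse(is.na(i0) | is.na(i1) | i1 == i0, NA_real_,
           (x[i1] - x[i0]) / ((i1 - i0) / fs))
  }
  out["T_slope_asc"] <- med(slope(fd$T_on, fd$T_peak))
  out["T_slope_des"] <- med(slope(fd$T_peak, fd$T_off))

  negp <- mapply(function(on, j, b) {
    if (is.na(on) || is.na(j) || j <= on) return(NA_real_)
    100 * mean(x[on:(j - 1L)] < b)
  }, fd$QRS_on, fd$J, fd$baseline_mv)
  out["QRS_neg_pct"] <- med(negp)
  out
}

#' Assemble the full named feature row of one record
#'
#' Concatenates 19 morphological features for each of the 12 leads, the
#' four Hermite coefficients plus fit RMSE for each lead, and the single
#' lead-independent V-index: 19x12 + 5x12 + 1 = 289 named values. Names
#' follow the `<feature>_<lead>` convention (`R_amp_V1`, `herm_c1_V2`,
#' `T_slope_des_aVR`, ...) plus `v_index`.
#'
#' @param morph Named list (per lead) of 19-feature vectors.
#' @param hermite Named list (per lead) of [hermite_fit] objects (or NULL
#'   entries).
#' @param v_index Scalar V-index (ms) or NA.
#' @return Named numeric vector of length 289.
#' @export
assemble_feature_vector <- function(morph, hermite, v_index = NA_real_) {
  leads <- standard_leads()
  out <- numeric(0)
  for (ld in leads) {
    m <- if (!is.null(morph[[ld]])) morph[[ld]] else
      stats::setNames(rep(NA_real_, 19L), morph_feature_names())
    names(m) <- paste0(morph_feature_names(), "_", ld)
    out <- c(out, m)
  }
  for (ld in leads) {
    h <- hermite[[ld]]
    v <- if (is.null(h)) rep(NA_real_, 5L) else c(h$coeffs[1:4], h$rmse)
    names(v) <- paste0(c(paste0("herm_c", 1:4), "herm_rmse"), "_", ld)
    out <- c(out, v)
  }
  out <- c(out, v_index = as.numeric(v_index))
  if (anyDuplicated(names(out))) stop("feature name collision")
  out
}
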