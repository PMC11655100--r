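#' Convert an amplitude from mV to mm of standard ECG paper
#'
#' Clinical voltage criteria are stated in millimeters at the standard
#' calibration of 10 mm/mV.
#'
#' @param amp_mv Amplitude in mV.
#' @return Amplitude in mm.
#' @export
to_millimeters <- function(amp_mv) 10 * amp_mv

#' Names of the 22 clinical LVH voltage criteria
#' @return Character vector of the criterion abbreviations.
#' @export
criteria_names <- function() {
  vapply(criteria_definitions(), `[[`, "", "abbrev")
}

#' The five criteria with the best standalone discrimination
#'
#' Used as the default "any-of" combination rule.
#' @return Character vector of five criterion abbreviations.
#' @export
top_five_criteria <- function() {
  c("Siegel", "McPhie", "Sokolow-Lyon1", "Grant2", "Romhilt1")
}

# Each definition: abbrev, threshold, units and a function of the
# magnitude-lookup `g(wave, lead)` (mm) plus QRS duration (ms).
# Wave symbols denote |median amplitude| in mm at 10 mm/mV: the criteria
# are positive voltage sums, so depths (Q, S) enter as magnitudes.
criteria_definitions <- function() {
  limb <- .limb_leads(); prec <- .precordial_leads()
  tlv <- function(g) sum(vapply(standard_leads(),
                                function(ld) g("R", ld) + g("S", ld), 0))
  list(
    list(abbrev = "Lewis", threshold = 16,
         lhs = function(g, qrs) (g("R", "I") - g("S", "I")) +
                                (g("S", "III") - g("R", "III"))),
    list(abbrev = "Gubner1", threshold = 25,
         lhs = function(g, qrs) g("R", "I") - g("S", "III")),
    list(abbrev = "Gubner2", threshold = 15,
         lhs = function(g, qrs) g("R", "I")),
    list(abbrev = "Sokolow-Lyon1", threshold = 11,
         lhs = function(g, qrs) g("R", "aVL")),
    list(abbrev = "Goldberger", threshold = 20,
         lhs = function(g, qrs) g("R", "aVF")),
    list(abbrev = "Schack", threshold = 19,
         lhs = function(g, qrs) max(g("Q", "aVR"), g("S", "aVR"))),
    list(abbrev = "Romhilt1", threshold = 19,
         lhs = function(g, qrs) max(vapply(limb,
           function(ld) g("R", ld) + g("S", ld), 0))),
    list(abbrev = "Wilson1", threshold = 23,
         lhs = function(g, qrs) g("S", "V1")),
    list(abbrev = "Mazzoleni", threshold = 25,
         lhs = function(g, qrs) g("S", "V2")),
    list(abbrev = "Sokolow-Lyon2", threshold = 35,
         lhs = function(g, qrs) g("S", "V1") + g("R", "V5")),
    list(abbrev = "Romhilt2", threshold = 45,
         lhs = function(g, qrs) g("S", "V2") + max(g("R", "V5"), g("R", "V6"))),
    list(abbrev = "Murphy", threshold = 35,
         lhs = function(g, qrs) max(g("S", "V1"), g("S", "V2")) +
                                max(g("R", "V5"), g("R", "V6"))),
    list(abbrev = "Grant1", threshold = 40,
         lhs = function(g, qrs) max(g("S", "V1"), g("S", "V2")) + g("R", "V6")),
    list(abbrev = "Grant2", threshold = 35,
         lhs = function(g, qrs) max(vapply(prec,
           function(ld) g("R", ld) + g("S", ld), 0))),
    list(abbrev = "Holt", threshold = 1.0,
         lhs = function(g, qrs) {
           num <- g("R", "V5"); d <- g("R", "V6")
           if (is.na(d) || is.na(num)) return(NA_real_)
           if (d == 0) { if (num == 0) 0 else Inf } else num / d
         }),
    list(abbrev = "McPhie", threshold = 26,
         lhs = function(g, qrs) max(vapply(prec, function(ld) g("R", ld), 0))),
    list(abbrev = "Wolff", threshold = 45,
         lhs = function(g, qrs) g("S", "V2") + max(g("R", "V4"), g("R", "V5"))),
    list(abbrev = "Wilson2", threshold = 33,
         lhs = function(g, qrs) g("R", "V5")),
    list(abbrev = "Wilson3", threshold = 25,
         lhs = function(g, qrs) g("R", "V6")),
    list(abbrev = "Siegel", threshold = 175,
         lhs = function(g, qrs) tlv(g)),
    list(abbrev = "Molloy1", threshold = 2436,
         lhs = function(g, qrs) (g("R", "aVL") + g("S", "V3")) * qrs),
    list(abbrev = "Molloy2", threshold = 2436,
         lhs = function(g, qrs) tlv(g) * qrs))
}

#' Evaluate the 22 clinical LVH voltage criteria
#'
#' Takes a record's assembled feature row (or any named vector holding the
#' per-lead median amplitudes in mV) and evaluates each criterion exactly
#' as codified: wave symbols denote amplitude magnitudes in mm (10 mm/mV),
#' "any lead" clauses take the maximum over the named leads, total 12-lead
#' voltage is the sum of |R| + |S| over all leads, and the two product
#' criteria multiply by the QRS duration in ms. Inequalities are strict; a
#' missing operand makes the criterion result missing, not negative.
#'
#' @param features Named numeric vector with `R_amp_<lead>`, `S_amp_<lead>`,
#'   `Q_amp_<lead>` entries in mV (as produced by
#'   [assemble_feature_vector()]).
#' @param qrs_duration_ms Record-level QRS duration in ms; default the
#'   median of the available `QRS_dur_<lead>` entries.
#' @return Object of class `criteria_report`: data frame with columns
#'   `criterion`, `lhs`, `threshold`, `positive` (logical, NA when
#'   unevaluable).
#' @export
evaluate_criteria <- function(features, qrs_duration_ms = NULL) {
  if (is.data.frame(features)) features <- unlist(features[1, , drop = TRUE])
  g <- function(wave, lead) {
    v <- features[[paste0(wave, "_amp_", lead)]]
    if (is.null(v)) return(NA_real_)
    to_millimeters(abs(as.numeric(v)))
  }
  if (is.null(qrs_duration_ms)) {
    qd <- features[grep("^QRS_dur_", names(features))]
    qrs_duration_ms <- if (length(qd)) stats::median(as.numeric(qd), na.rm = TRUE)
                       else NA_real_
  }
  defs <- criteria_definitions()
  lhs <- vapply(defs, function(d) {
    v <- tryCatch(d$lhs(g, qrs_duration_ms), error = function(e) NA_real_)
    if (is.null(v) || !length(v)) NA_real_ else as.numeric(v)
  }, 0)
  thr <- vapply(defs, `[[`, 0, "threshold")
  rep <- data.frame(criterion = vapply(defs, `[[`, "", "abbrev"),
                    lhs = lhs, threshold = thr,
                    positive = lhs > thr)
  class(rep) <- c("criteria_report", "data.frame")
  rep
}

#' Any-of combination of criteria
#'
#' TRUE iff at least one of the named criteria is positive; missing
#' criterion results count as negative. An empty name list is vacuously
#' FALSE.
#'
#' @param report A [evaluate_criteria()] report.
#' @param names Criterion abbreviations to combine (default the top five).
#' @return Logical scalar.
#' @export
combine_any <- function(report, names = top_five_criteria()) {
  if (!length(names)) return(FALSE)
  unknown <- setdiff(names, report$criterion)
  if (length(unknown)) stop("unknown criteria: ", paste(unknown, collapse = ", "))
  pos <- report$positive[match(names, report$criterion)]
  any(pos %in% TRUE)
}

#' Evaluate the criteria battery on a feature matrix
#'
#' One row per record with each criterion's positivity (0/1, NA when
#' unevaluable) plus the `combo_top5` any-of combination.
#'
#' @param fm Feature matrix data frame (see [extract_features()]).
#' @return Data frame with `record_id`, `label`, one column per criterion
#'   and `combo_top5`.
#' @export
criteria_table <- function(fm) {
  featcols <- setdiff(names(fm), c("record_id", "label"))
  out <- lapply(seq_len(nrow(fm)), function(i) {
    row <- unlist(fm[i, featcols, drop = TRUE])
    rep <- evaluate_criteria(row)
    vals <- as.integer(rep$positive)
    names(vals) <- rep$criterion
    c(vals, combo_top5 = as.integer(combine_any(rep)))
  })
  res <- as.data.frame(do.call(rbind, out), check.names = FALSE)
  cbind(record_id = fm$record_id, label = fm$label, res)
}
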