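#' Extract the full 289-value feature row of one record
#'
#' Runs the whole single-record pipeline: R-peak detection on lead II,
#' per-lead wave delineation, beat-quality-controlled template building,
#' the 19 morphological features per lead, the 4-term Hermite QRS
#' decomposition per lead, and the record-level V-index.
#'
#' @param record An [ecg_record].
#' @param fiducials Optional precomputed [fiducial_map] (e.g. from an
#'   external delineator); default: built-in delineation.
#' @param min_beats,min_corr Beat-quality-control parameters, see
#'   [build_templates()].
#' @return List with `features` (named numeric vector of 289 values, or
#'   `NULL`), `excluded` (logical) and `reason` (string, NA when kept).
#' @export
extract_record_features <- function(record, fiducials = NULL,
                                    min_beats = 5, min_corr = 0.90) {
  fail <- function(reason) list(features = NULL, excluded = TRUE, reason = reason)
  fiducials <- tryCatch({
    if (is.null(fiducials)) delineate_waves(record) else fiducials
  }, error = function(e) NULL)
  if (is.null(fiducials)) return(fail("delineation_failed"))
  tm <- build_templates(record, fiducials, min_beats, min_corr)
  if (tm$excluded) return(fail(tm$reason))
  morph <- list()
  for (ld in record$lead_names) {
    morph[[ld]] <- extract_lead_features(record, fiducials, ld,
                                         beats = tm$templates[[ld]]$beats_used)
  }
  herm <- fit_qrs_all_leads(tm$templates)
  vix <- tryCatch(v_index_record(tm$templates)$v_index,
                  error = function(e) NA_real_)
  list(features = assemble_feature_vector(morph, herm, vix),
       excluded = FALSE, reason = NA_character_)
}

#' Extract a feature matrix from a list of records
#'
#' Applies [extract_record_features()] to every record; records failing
#' quality control are excluded with a reason code (available as the
#' `exclusions` attribute of the result).
#'
#' @param records List of [ecg_record] objects.
#' @param labels Optional label vector overriding the records' own labels.
#' @param fiducials Optional list of precomputed fiducial maps.
#' @param min_beats,min_corr Beat-quality-control parameters.
#' @param verbose Print progress every 50 records.
#' @return Data frame (`record_id`, `label`, 289 feature columns) with an
#'   `exclusions` attribute (data frame `record_id`, `reason`).
#' @export
extract_features <- function(records, labels = NULL, fiducials = NULL,
                             min_beats = 5, min_corr = 0.90, verbose = FALSE) {
  rows <- list(); ids <- character(0); labs <- character(0)
  excl <- list()
  for (i in seq_along(records)) {
    rec <- records[[i]]
    fid_i <- if (is.null(fiducials)) NULL else fiducials[[i]]
    fv <- extract_record_features(rec, fid_i, min_beats, min_corr)
    if (fv$excluded) {
      excl[[length(excl) + 1L]] <- data.frame(record_id = rec$record_id,
                                              reason = fv$reason)
    } else {
      rows[[length(rows) + 1L]] <- fv$features
      ids <- c(ids, rec$record_id)
      labs <- c(labs, if (is.null(labels)) rec$label else labels[i])
    }
    if (verbose && i %% 50 == 0) message("processed ", i, "/", length(records))
  }
  if (!length(rows)) stop("all records were excluded by quality control")
  fm <- as.data.frame(do.call(rbind, rows), check.names = FALSE)
  fm <- cbind(record_id = ids, label = labs, fm)
  attr(fm, "exclusions") <- if (length(excl)) do.call(rbind, excl) else
    data.frame(record_id = character(0), reason = character(0))
  fm
}

#' Save / load a trained model or ensemble
#'
#' Models are serialized with a format-version header alongside the
#' feature list, thresholds and all training seeds, so a stored ensemble
#' reproduces its predictions exactly.
#'
#' @param model A `trained_model` or `ensemble_model`.
#' @param path File path.
#' @return `load_model` returns the model object.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "trained_model") || inherits(model, "ensemble_model"))
  saveRDS(list(format_version = 1L, package = "ecglvh", model = model), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  if (!is.list(obj) || is.null(obj$format_version))
    stop("not an ecglvh model file")
  if (obj$format_version > 1L)
    stop("model file format version ", obj$format_version, " not supported")
  obj$model
}
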