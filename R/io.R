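#' Write an ECG record as a WFDB header/signal pair
#'
#' Writes the PhysioNet WFDB dialect used by the large public 12-lead ECG
#' collections: a `.hea` text header plus a format-16 `.dat` signal file
#' (interleaved little-endian 16-bit integers). Samples are quantized with
#' the given gain (ADU per mV).
#'
#' @param record An [ecg_record].
#' @param dir Output directory.
#' @param gain ADC gain in units per mV (default 1000).
#' @return Invisibly, the path of the header file.
#' @export
write_wfdb_record <- function(record, dir, gain = 1000) {
  stopifnot(inherits(record, "ecg_record"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  id <- record$record_id
  dat <- paste0(id, ".dat")
  n <- ncol(record$signals)
  adc <- round(record$signals * gain)
  adc <- pmin(pmax(adc, -32768), 32767)
  hdr <- c(sprintf("%s 12 %g %d", id, record$fs, n),
           sprintf("%s 16 %g/mV 16 0 %d 0 0 %s",
                   dat, gain, as.integer(adc[, 1]), rownames(adc)))
  writeLines(hdr, file.path(dir, paste0(id, ".hea")))
  con <- file(file.path(dir, dat), "wb")
  on.exit(close(con))
  writeBin(as.integer(as.vector(adc)), con, size = 2L, endian = "little")
  invisible(file.path(dir, paste0(id, ".hea")))
}

# Parse a WFDB signal-spec gain token like "1000", "1000/mV", "1000(0)/uV".
parse_gain <- function(tok) {
  units <- "mV"
  if (grepl("/", tok, fixed = TRUE)) {
    parts <- strsplit(tok, "/", fixed = TRUE)[[1]]
    tok <- parts[1]; units <- parts[2]
  }
  baseline <- 0
  if (grepl("(", tok, fixed = TRUE)) {
    baseline <- as.numeric(sub("^.*\\(([-0-9.]+)\\).*$", "\\1", tok))
    tok <- sub("\\(.*$", "", tok)
  }
  gain <- as.numeric(tok)
  if (is.na(gain) || gain == 0) gain <- 200  # WFDB default gain
  scale <- switch(units,
                  mV = 1, mv = 1,
                  uV = 1000, uv = 1000, "µV" = 1000,
                  V = 0.001,
                  stop("signal units not convertible to mV: ", units))
  list(gain = gain, baseline = baseline, to_mv = 1 / (gain * scale))
}

#' Read a 12-lead WFDB record
#'
#' Reads a header/signal pair in WFDB format 16, converts samples to mV
#' using each signal's gain/units, and reorders leads into the standard
#' order. The lead name is taken from the description field (last token of
#' each signal line).
#'
#' @param path Path to the `.hea` file (or record name without extension).
#' @param label Optional label to attach (`"control"`, `"lvh"`, `"unknown"`).
#' @return An [ecg_record].
#' @export
read_wfdb_record <- function(path, label = "unknown") {
  if (!grepl("\\.hea$", path)) path <- paste0(path, ".hea")
  if (!file.exists(path)) stop("header file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^#", lines)]
  top <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  id <- top[1]
  n_sig <- as.integer(top[2])
  fs <- as.numeric(top[3])
  n <- as.integer(top[4])
  if (is.na(n_sig) || n_sig < 1) stop("malformed WFDB header")
  spec <- lapply(lines[1 + seq_len(n_sig)], function(l) {
    tok <- strsplit(trimws(l), "\\s+")[[1]]
    if (length(tok) < 2) stop("malformed signal line in header")
    fmt <- sub("x.*$", "", tok[2])
    if (fmt != "16") stop("only WFDB format 16 is supported (got ", tok[2], ")")
    g <- if (length(tok) >= 3) parse_gain(tok[3]) else parse_gain("200")
    desc <- if (length(tok) >= 9) tok[length(tok)] else NA_character_
    list(file = tok[1], g = g, lead = desc)
  })
  files <- unique(vapply(spec, `[[`, "", "file"))
  if (length(files) != 1)
    stop("multi-file WFDB records are not supported")
  datp <- file.path(dirname(path), files)
  raw <- readBin(datp, integer(), n = n_sig * n, size = 2L,
                 endian = "little", signed = TRUE)
  if (length(raw) < n_sig * n) stop("signal file shorter than header declares")
  m <- matrix(as.numeric(raw), nrow = n_sig)
  leads <- vapply(spec, `[[`, "", "lead")
  if (anyDuplicated(leads)) stop("duplicated lead names in record")
  missing <- setdiff(standard_leads(), leads)
  if (length(missing))
    stop("record is missing lead(s): ", paste(missing, collapse = ", "))
  sig <- matrix(0, nrow = 12L, ncol = n, dimnames = list(standard_leads(), NULL))
  for (i in seq_len(n_sig)) {
    if (!(leads[i] %in% standard_leads())) next
    sig[leads[i], ] <- (m[i, ] - spec[[i]]$g$baseline) * spec[[i]]$g$to_mv
  }
  ecg_record(id, sig, fs, label)
}

#' Load diagnostic labels from an annotation file
#'
#' Maps record identifiers to `control`/`lvh`. Records annotated with the
#' LVH code map to `lvh` (LVH dominates when both codes are present);
#' records annotated NORM only map to `control`; all other records are
#' dropped.
#'
#' Dialects:
#' \describe{
#'   \item{`plain_csv`}{CSV with columns `record_id,label` where label is
#'     already `control`/`lvh`.}
#'   \item{`ptbxl_scp`}{CSV with columns `ecg_id` (or `record_id`) and
#'     `scp_codes` holding a python-dict-like string of SCP codes; `'LVH'`
#'     and `'NORM'` keys are matched.}
#'   \item{`challenge_snomed`}{CSV with columns `record_id` and `dx_codes`
#'     (comma-separated SNOMED CT codes); code 164873001 marks LVH and
#'     426783006 (sinus rhythm / normal) marks controls.}
#' }
#'
#' @param path CSV file path.
#' @param dialect One of `"plain_csv"`, `"ptbxl_scp"`, `"challenge_snomed"`.
#' @param lvh_code,norm_code SNOMED codes used by the challenge dialect.
#' @return Named character vector: `record_id -> "control"/"lvh"`.
#' @export
load_labels <- function(path, dialect = c("plain_csv", "ptbxl_scp", "challenge_snomed"),
                        lvh_code = "164873001", norm_code = "426783006") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("label file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  if (dialect == "plain_csv") {
    if (!all(c("record_id", "label") %in% names(df)))
      stop("plain_csv labels need columns record_id,label")
    keep <- df$label %in% c("control", "lvh")
    return(stats::setNames(df$label[keep], df$record_id[keep]))
  }
  if (dialect == "ptbxl_scp") {
    idcol <- if ("ecg_id" %in% names(df)) "ecg_id" else "record_id"
    if (!all(c(idcol, "scp_codes") %in% names(df)))
      stop("ptbxl_scp labels need columns ecg_id/record_id and scp_codes")
    has_lvh <- grepl("'LVH'", df$scp_codes, fixed = TRUE)
    has_norm <- grepl("'NORM'", df$scp_codes, fixed = TRUE)
  } else {
    if (!all(c("record_id", "dx_codes") %in% names(df)))
      stop("challenge_snomed labels need columns record_id,dx_codes")
    idcol <- "record_id"
    codes <- strsplit(df$dx_codes, "[,;]\\s*")
    has_lvh <- vapply(codes, function(x) lvh_code %in% trimws(x), FALSE)
    has_norm <- vapply(codes, function(x) norm_code %in% trimws(x), FALSE)
  }
  lab <- ifelse(has_lvh, "lvh", ifelse(has_norm, "control", NA))
  keep <- !is.na(lab)
  stats::setNames(lab[keep], df[[idcol]][keep])
}

#' Write / read a feature matrix as CSV
#'
#' The on-disk contract is a CSV with header `record_id,label,<features...>`;
#' missing values are empty fields. Reading a file with a duplicated
#' `record_id` is an error.
#'
#' @param fm Data frame with columns `record_id`, `label` and numeric
#'   feature columns.
#' @param path CSV file path.
#' @return `read_feature_matrix` returns the data frame;
#'   `write_feature_matrix` returns the path invisibly.
#' @export
write_feature_matrix <- function(fm, path) {
  stopifnot(all(c("record_id", "label") %in% names(fm)))
  utils::write.csv(fm, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("record_id", "label") %in% names(df)))
    stop("feature CSV must have record_id and label columns")
  if (anyDuplicated(df$record_id))
    stop("duplicated record_id in feature CSV")
  df$record_id <- as.character(df$record_id)
  df$label <- as.character(df$label)
  for (j in setdiff(names(df), c("record_id", "label")))
    df[[j]] <- as.numeric(df[[j]])
  df
}

#' Export / import fiducial maps as CSV
#'
#' Long format `record_id,lead,beat,landmark,sample_index` (1-based sample
#' indices), so an external delineator's output can be substituted for the
#' built-in one. Baseline rows use landmark `baseline_mv` with the value in
#' the `sample_index` column.
#'
#' @param fid A [fiducial_map].
#' @param record_id Record identifier written with each row.
#' @param path CSV path.
#' @return `read_fiducials_csv` returns a named list of fiducial maps.
#' @export
write_fiducials_csv <- function(fid, record_id, path) {
  lm <- c(fiducial_landmarks(), "baseline_mv")
  long <- do.call(rbind, lapply(lm, function(l) {
    data.frame(record_id = record_id, lead = fid$lead, beat = fid$beat,
               landmark = l, sample_index = fid[[l]])
  }))
  long <- long[!is.na(long$sample_index), ]
  long <- long[order(long$lead, long$beat), ]
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_fiducials_csv
#' @export
read_fiducials_csv <- function(path) {
  long <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("record_id", "lead", "beat", "landmark", "sample_index")
  if (!all(need %in% names(long))) stop("fiducial CSV missing columns")
  lapply(split(long, long$record_id), function(d) {
    wide <- stats::reshape(d[, c("lead", "beat", "landmark", "sample_index")],
                           idvar = c("lead", "beat"), timevar = "landmark",
                           direction = "wide")
    names(wide) <- sub("^sample_index\\.", "", names(wide))
    for (l in setdiff(c(fiducial_landmarks(), "baseline_mv"), names(wide)))
      wide[[l]] <- NA_real_
    if (all(is.na(wide$baseline_mv))) wide$baseline_mv <- 0
    fiducial_map(wide)
  })
}
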