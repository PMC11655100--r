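#' Default per-lead wave parameters of the synthetic generator
#'
#' Each of the 12 leads carries five Gaussian-shaped waves (P, Q, R, S, T)
#' described by amplitude (mV), center offset relative to the R peak (s) and
#' Gaussian width sigma (s). Amplitudes follow textbook adult surface-ECG
#' morphology: positive R with tall precordial transition towards V4-V5,
#' deep right-precordial S, predominantly negative aVR, small P, and an
#' upright T wave concordant with the QRS.
#'
#' @return Named list (one entry per lead) of data frames with columns
#'   `wave`, `amp`, `center`, `width`.
#' @export
default_wave_params <- function() {
  mk <- function(p, q, r, s, t_) {
    data.frame(
      wave   = c("P", "Q", "R", "S", "T"),
      amp    = c(p, q, r, s, t_),
      center = c(-0.210, -0.045, 0.000, 0.040, 0.300),
      width  = c(0.020, 0.008, 0.010, 0.008, 0.060))
  }
  list(
    I   = mk(0.05, -0.06, 0.70, -0.15, 0.25),
    II  = mk(0.10, -0.08, 1.00, -0.15, 0.30),
    III = mk(0.05, -0.05, 0.40, -0.10, 0.10),
    aVR = mk(-0.08, 0.05, -0.60, 0.10, -0.25),
    aVL = mk(0.03, -0.05, 0.35, -0.10, 0.10),
    aVF = mk(0.08, -0.06, 0.70, -0.10, 0.20),
    V1  = mk(0.04, 0.00, 0.25, -1.10, 0.10),
    V2  = mk(0.05, 0.00, 0.45, -1.30, 0.25),
    V3  = mk(0.05, -0.05, 0.80, -0.90, 0.35),
    V4  = mk(0.06, -0.06, 1.40, -0.50, 0.40),
    V5  = mk(0.06, -0.08, 1.50, -0.30, 0.35),
    V6  = mk(0.06, -0.08, 1.20, -0.20, 0.30))
}

#' Default hypertrophy-class morphology shift
#'
#' The LVH-like class adds the classic voltage/strain pattern on top of the
#' control morphology: taller lateral R waves (V5, V6, I, aVL), deeper
#' right-precordial S waves (V1, V2), T-wave inversion in the lateral
#' precordial leads and a modestly widened QRS complex.
#'
#' @param r_amp_delta Added to the R amplitude (mV) in `r_leads`.
#' @param s_amp_delta Added to the S amplitude (mV) in `s_leads` (negative =
#'   deeper).
#' @param t_flip_leads Leads whose T amplitude flips sign.
#' @param qrs_width_scale Multiplier on the Q, R, S wave widths (the
#'   default stretches the control QRS duration by about 20 ms).
#' @return List describing the class shift.
#' @export
lvh_class_shift <- function(r_amp_delta = 0.8,
                            r_leads = c("V5", "V6", "I", "aVL"),
                            s_amp_delta = -0.8,
                            s_leads = c("V1", "V2"),
                            t_flip_leads = c("V5", "V6"),
                            qrs_width_scale = 1.33) {
  list(r_amp_delta = r_amp_delta, r_leads = r_leads,
       s_amp_delta = s_amp_delta, s_leads = s_leads,
       t_flip_leads = t_flip_leads, qrs_width_scale = qrs_width_scale)
}

#' Configuration of the synthetic 12-lead ECG generator
#'
#' @param fs Sampling rate, Hz.
#' @param duration_s Record duration, seconds.
#' @param heart_rate_bpm Mean heart rate.
#' @param hr_jitter_bpm SD of the per-record heart-rate draw.
#' @param rr_jitter_s SD of the per-beat RR-interval jitter, seconds.
#' @param amp_scale_sd SD of the per-record global amplitude scale factor
#'   (body-habitus-like variation common to all leads).
#' @param amp_jitter_cv Coefficient of variation of the independent
#'   per-lead, per-wave amplitude jitter.
#' @param noise_sd_mv SD of additive white noise, mV.
#' @param baseline_wander_mv Amplitude of a slow sinusoidal baseline drift
#'   (random frequency 0.15-0.4 Hz and phase per lead), mV.
#' @param t_asym Ratio of the descending to ascending T-wave half-widths
#'   (two half-Gaussians; 1 = symmetric T).
#' @param onset_frac Fraction of peak amplitude defining ground-truth wave
#'   onsets/offsets (default 1 percent).
#' @param waves Per-lead wave parameter list, as [default_wave_params()].
#' @param class_shift LVH-class morphology shift, as [lvh_class_shift()].
#' @param seed Default seed used when `generate_record()` is called without
#'   one.
#' @return Object of class `synthetic_config`.
#' @export
synthetic_config <- function(fs = 500, duration_s = 10,
                             heart_rate_bpm = 60, hr_jitter_bpm = 2,
                             rr_jitter_s = 0.01,
                             amp_scale_sd = 0.15, amp_jitter_cv = 0.10,
                             noise_sd_mv = 0.02, baseline_wander_mv = 0.05,
                             t_asym = 1.2, onset_frac = 0.01,
                             waves = default_wave_params(),
                             class_shift = lvh_class_shift(),
                             seed = 1L) {
  if (fs <= 0) stop("fs must be positive")
  if (duration_s <= 0) stop("duration_s must be positive")
  if (noise_sd_mv < 0) stop("noise_sd_mv must be non-negative")
  if (onset_frac <= 0 || onset_frac >= 1) stop("onset_frac must be in (0,1)")
  if (!setequal(names(waves), standard_leads()))
    stop("waves must cover exactly the 12 standard leads")
  for (w in waves) {
    if (any(w$width <= 0)) stop("wave widths must be positive")
  }
  structure(
    list(fs = fs, duration_s = duration_s,
         heart_rate_bpm = heart_rate_bpm, hr_jitter_bpm = hr_jitter_bpm,
         rr_jitter_s = rr_jitter_s, amp_scale_sd = amp_scale_sd,
         amp_jitter_cv = amp_jitter_cv, noise_sd_mv = noise_sd_mv,
         baseline_wander_mv = baseline_wander_mv, t_asym = t_asym,
         onset_frac = onset_frac, waves = waves[standard_leads()],
         class_shift = class_shift, seed = as.integer(seed)),
    class = "synthetic_config")
}

# Apply the LVH class shift to a wave-parameter list.
apply_class_shift <- function(waves, shift) {
  for (ld in shift$r_leads)
    waves[[ld]]$amp[waves[[ld]]$wave == "R"] <-
      waves[[ld]]$amp[waves[[ld]]$wave == "R"] + shift$r_amp_delta
  for (ld in shift$s_leads)
    waves[[ld]]$amp[waves[[ld]]$wave == "S"] <-
      waves[[ld]]$amp[waves[[ld]]$wave == "S"] + shift$s_amp_delta
  for (ld in shift$t_flip_leads)
    waves[[ld]]$amp[waves[[ld]]$wave == "T"] <-
      -waves[[ld]]$amp[waves[[ld]]$wave == "T"]
  for (ld in names(waves)) {
    qrs <- waves[[ld]]$wave %in% c("Q", "R", "S")
    waves[[ld]]$width[qrs] <- waves[[ld]]$width[qrs] * shift$qrs_width_scale
  }
  waves
}

# Add one (possibly asymmetric) Gaussian bump to x in place-ish fashion.
# For the T wave the ascending half uses `width` and the descending half
# `width * asym`.
add_bump <- function(x, fs, amp, center, width, asym = 1) {
  if (amp == 0) return(x)
  lo <- max(1L, floor((center - 5 * width) * fs) + 1L)
  hi <- min(length(x), ceiling((center + 5 * width * asym) * fs) + 1L)
  if (lo > hi) return(x)
  t <- ((lo:hi) - 1) / fs - center
  w <- ifelse(t < 0, width, width * asym)
  x[lo:hi] <- x[lo:hi] + amp * exp(-t^2 / (2 * w^2))
  x
}

#' Generate one synthetic 12-lead ECG record with ground-truth fiducials
#'
#' Each beat is a sum of five Gaussian-shaped waves per lead (the T wave may
#' be asymmetric), repeated along a beat train with configurable rate and
#' jitter, plus optional baseline wander and white noise. Ground-truth
#' fiducials are placed analytically: peaks at the Gaussian centers,
#' onsets/offsets where the wave reaches `onset_frac` of its peak
#' amplitude, QRS onset/offset as the extreme onset/offset over the present
#' Q/R/S waves. Identical `(config, label, seed)` reproduce the output
#' bit-for-bit.
#'
#' @param config A [synthetic_config()].
#' @param label `"control"` or `"lvh"`.
#' @param seed Integer seed (defaults to `config$seed`).
#' @param record_id Optional record identifier.
#' @return List with elements `record` ([ecg_record]) and `fiducials`
#'   ([fiducial_map]; ground truth, baseline 0 mV).
#' @export
generate_record <- function(config, label = c("control", "lvh"),
                            seed = config$seed, record_id = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  label <- match.arg(label)
  if (is.null(record_id)) record_id <- sprintf("syn_%s_%d", label, seed)
  fs <- config$fs
  n <- round(fs * config$duration_s)
  leads <- standard_leads()
  waves <- config$waves
  if (label == "lvh") waves <- apply_class_shift(waves, config$class_shift)
  kons <- sqrt(-2 * log(config$onset_frac))  # onset half-width in sigmas

  out <- with_seed(seed, {
    hr <- config$heart_rate_bpm + stats::rnorm(1, 0, config$hr_jitter_bpm)
    hr <- max(30, min(180, hr))
    rr <- 60 / hr

    # complete beats only: every wave (incl. ground-truth onset/offset)
    # must fall inside the record
    ext_lo <- min(vapply(waves, function(w) min(w$center - (kons + 0.5) * w$width), 0))
    ext_hi <- max(vapply(waves, function(w) {
      a <- ifelse(w$wave == "T", config$t_asym, 1)
      max(w$center + (kons + 0.5) * w$width * a)
    }, 0))
    r_times <- c()
    t0 <- -ext_lo + 0.05
    while (t0 + ext_hi < config$duration_s) {
      r_times <- c(r_times, t0)
      t0 <- t0 + rr + stats::rnorm(1, 0, config$rr_jitter_s)
    }
    if (!length(r_times)) stop("record too short for a single beat")

    scale_rec <- max(0.2, 1 + stats::rnorm(1, 0, config$amp_scale_sd))
    jit <- matrix(pmax(0.2, 1 + stats::rnorm(12L * 5L, 0, config$amp_jitter_cv)),
                  nrow = 12L, dimnames = list(leads, c("P", "Q", "R", "S", "T")))

    sig <- matrix(0, nrow = 12L, ncol = n, dimnames = list(leads, NULL))
    fid_rows <- vector("list", 12L * length(r_times))
    k <- 0L
    for (li in seq_along(leads)) {
      ld <- leads[li]
      wp <- waves[[ld]]
      amps <- wp$amp * scale_rec * jit[ld, wp$wave]
      x <- numeric(n)
      for (bi in seq_along(r_times)) {
        rt <- r_times[bi]
        lmk <- stats::setNames(rep(NA_real_, length(fiducial_landmarks())),
                               fiducial_landmarks())
        for (wi in seq_len(nrow(wp))) {
          wv <- wp$wave[wi]; a <- amps[wi]
          ctr <- rt + wp$center[wi]; wd <- wp$width[wi]
          asym <- if (wv == "T") config$t_asym else 1
          x <- add_bump(x, fs, a, ctr, wd, asym)
          if (a != 0) {
            on <- ctr - kons * wd
            off <- ctr + kons * wd * asym
            if (wv == "P") {
              lmk["P_on"] <- on; lmk["P_peak"] <- ctr; lmk["P_off"] <- off
            } else if (wv == "T") {
              lmk["T_on"] <- on; lmk["T_peak"] <- ctr; lmk["T_off"] <- off
            } else {
              lmk[wv] <- ctr
              lmk["QRS_on"] <- min(lmk["QRS_on"], on, na.rm = TRUE)
              lmk["J"] <- max(lmk["J"], off, na.rm = TRUE)
            }
          }
        }
        k <- k + 1L
        fid_rows[[k]] <- data.frame(lead = ld, beat = bi,
                                    t(round(lmk * fs) + 1), baseline_mv = 0)
      }
      if (config$baseline_wander_mv > 0) {
        f <- stats::runif(1, 0.15, 0.4); ph <- stats::runif(1, 0, 2 * pi)
        x <- x + config$baseline_wander_mv * sin(2 * pi * f * ((0:(n - 1)) / fs) + ph)
      }
      if (config$noise_sd_mv > 0) x <- x + stats::rnorm(n, 0, config$noise_sd_mv)
      sig[li, ] <- x
    }
    list(sig = sig, fid = do.call(rbind, fid_rows[seq_len(k)]))
  })

  rec <- ecg_record(record_id, out$sig, fs, label)
  fid <- fiducial_map(out$fid, n_samples = n)
  list(record = rec, fiducials = fid)
}

#' Generate a labelled cohort of synthetic records
#'
#' Per-record seeds are derived as `seed + record index`, so cohorts are
#' reproducible and records mutually independent. Controls come first.
#'
#' @param n_control,n_lvh Number of records per class (non-negative).
#' @param config A [synthetic_config()].
#' @param seed Master integer seed.
#' @return List with `records` (list of [ecg_record]), `labels` (character
#'   vector) and `fiducials` (list of ground-truth [fiducial_map]s).
#' @export
generate_cohort <- function(n_control, n_lvh, config = synthetic_config(),
                            seed = config$seed) {
  stopifnot(is_count(n_control), is_count(n_lvh))
  labels <- c(rep("control", n_control), rep("lvh", n_lvh))
  records <- vector("list", length(labels))
  fiducials <- vector("list", length(labels))
  for (i in seq_along(labels)) {
    g <- generate_record(config, labels[i], seed = seed + i,
                         record_id = sprintf("syn%05d", i))
    records[[i]] <- g$record
    fiducials[[i]] <- g$fiducials
  }
  list(records = records, labels = labels, fiducials = fiducials)
}
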