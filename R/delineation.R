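#' Detect R peaks on a single lead
#'
#' Pan-Tompkins-style detector: band-pass (5-15 Hz), differentiate, square,
#' moving-window integrate (150 ms), then adaptive signal/noise thresholding
#' on the integrated transform with a 200 ms refractory period. Candidate
#' beats are refined to the sample of largest absolute deviation of the raw
#' signal within +/-80 ms, so the detector is polarity-insensitive.
#'
#' @param x Single-lead signal, mV.
#' @param fs Sampling rate, Hz.
#' @return Integer vector of R-peak sample indices (1-based).
#' @export
detect_r_peaks <- function(x, fs) {
  if (length(x) < 2 * fs) stop("need at least 2 s of signal")
  if (stats::sd(x) == 0) stop("no beats detectable: flat signal")
  bp <- signal::filtfilt(signal::butter(2, c(5, 15) / (fs / 2), type = "pass"), x)
  d2 <- c(diff(bp), 0)^2
  w <- max(3L, round(0.15 * fs))
  mwi <- as.numeric(stats::filter(d2, rep(1 / w, w), sides = 2))
  mwi[is.na(mwi)] <- 0

  # local maxima of the integrated transform
  cand <- which(diff(sign(diff(mwi))) < 0) + 1L
  cand <- cand[mwi[cand] > 0.01 * max(mwi)]
  if (!length(cand)) stop("no beats detectable")

  init <- mwi[seq_len(min(length(mwi), round(2 * fs)))]
  spki <- 0.5 * max(init)
  npki <- 0.5 * mean(init)
  refr <- round(0.2 * fs)
  peaks <- integer(0)
  last <- -refr
  for (i in cand) {
    thr <- npki + 0.25 * (spki - npki)
    if (mwi[i] >= thr && (i - last) >= refr) {
      peaks <- c(peaks, i)
      last <- i
      spki <- 0.125 * mwi[i] + 0.875 * spki
    } else {
      npki <- 0.125 * mwi[i] + 0.875 * npki
    }
  }
  if (!length(peaks)) stop("no beats detectable")

  # refine onto the raw signal (largest |deviation| from local median)
  hw <- round(0.08 * fs)
  med <- stats::median(x)
  ref <- vapply(peaks, function(p) {
    lo <- max(1L, p - hw); hi <- min(length(x), p + hw)
    as.integer(lo + which.max(abs(x[lo:hi] - med)) - 1L)
  }, 0L)
  ref <- sort(unique(ref))
  # collapse refinements that landed within the refractory window
  if (length(ref) > 1L) {
    keep <- c(TRUE, diff(ref) >= refr)
    ref <- ref[keep]
  }
  ref
}

# Walk outward from a wave peak until the signal re-enters the baseline
# tolerance band (frac of the wave's own peak-to-baseline amplitude, with
# an absolute floor so additive noise cannot defeat the crossing test).
walk_to_baseline <- function(x, from, dir, baseline, frac, max_steps,
                             floor_mv = 0) {
  a <- abs(x[from] - baseline)
  if (a == 0) return(from)
  tol <- max(frac * a, floor_mv)
  if (tol >= a) return(from + dir)
  i <- from
  steps <- 0L
  n <- length(x)
  while (steps < max_steps) {
    j <- i + dir
    if (j < 1L || j > n) break
    if (abs(x[j] - baseline) < tol) return(j)
    i <- j
    steps <- steps + 1L
  }
  i
}

# Extremum (max |x - baseline|, sign preserved) in [lo, hi]; NA window -> NA.
window_extremum <- function(x, lo, hi, baseline) {
  lo <- max(1L, lo); hi <- min(length(x), hi)
  if (lo > hi) return(NA_integer_)
  lo + which.max(abs(x[lo:hi] - baseline)) - 1L
}

#' Delineate P, QRS and T waves on every lead
#'
#' Uses beat anchors (R peaks, typically detected on lead II) and locates,
#' per lead and beat: the per-lead R peak near the anchor; Q and S as the
#' extrema of polarity opposite to R within +/-80 ms; QRS onset / J point by
#' walking outward from Q/S (or R when absent) until the signal re-enters a
#' 1 percent-of-wave-amplitude band around the baseline; the P peak as the
#' extremum in \[R-300, R-100\] ms; the T peak as the largest-amplitude
#' extremum in \[J+80, J+420\] ms (sign preserved, so inverted T waves get
#' negative amplitude); and wave onsets/offsets by the same baseline-return
#' rule. The per-beat baseline is the median of the 40 ms PR-segment window
#' ending 20 ms before QRS onset. Waves with peak-to-baseline amplitude
#' below `presence_mv` are flagged absent (NA), never fabricated. Beats
#' whose search windows exceed the record bounds are skipped.
#'
#' @param record An [ecg_record].
#' @param r_peaks Beat anchor indices; default: detected on lead II.
#' @param presence_mv Minimum |amplitude| for a wave to count as present.
#' @param onset_frac Baseline-band tolerance as a fraction of wave
#'   amplitude.
#' @return A [fiducial_map].
#' @export
delineate_waves <- function(record, r_peaks = NULL, presence_mv = 0.025,
                            onset_frac = 0.01) {
  stopifnot(inherits(record, "ecg_record"))
  fs <- record$fs
  if (is.null(r_peaks)) r_peaks <- detect_r_peaks(record$signals["II", ], fs)
  if (!length(r_peaks)) stop("need at least one R peak")
  n <- ncol(record$signals)
  ms <- function(k) round(k / 1000 * fs)
  rows <- list()
  for (ld in record$lead_names) {
    x <- record$signals[ld, ]
    # white-noise level estimate: second differences of a smooth ECG are
    # near zero over most of the beat, so their MAD reflects additive
    # noise only (var of the second difference of white noise is 6 sigma^2)
    nz <- stats::mad(diff(x, differences = 2)) / sqrt(6)
    floor_mv <- 2.5 * nz
    presence <- max(presence_mv, 2.5 * nz)
    for (bi in seq_along(r_peaks)) {
      a <- r_peaks[bi]
      if (a - ms(320) < 1L || a + ms(500) > n) next  # incomplete beat: skip
      b0 <- stats::median(x[(a - ms(100)):(a - ms(60))])
      # R is near-simultaneous across leads; a narrow window around the
      # anchor avoids locking onto a deep S (e.g. right-precordial leads)
      r <- window_extremum(x, a - ms(10), a + ms(10), b0)
      r_sign <- sign(x[r] - b0)
      if (r_sign == 0) r_sign <- 1
      pick_opp <- function(lo, hi) {
        lo <- max(1L, lo); hi <- min(n, hi)
        if (lo > hi) return(NA_integer_)
        seg <- (x[lo:hi] - b0) * r_sign
        lo + which.min(seg) - 1L
      }
      q <- pick_opp(r - ms(80), r - 1L)
      s <- pick_opp(r + 1L, r + ms(80))
      q_ok <- !is.na(q) && abs(x[q] - b0) >= presence
      s_ok <- !is.na(s) && abs(x[s] - b0) >= presence

      qrs_on <- walk_to_baseline(x, if (q_ok) q else r, -1L, b0, onset_frac,
                                 ms(150), floor_mv)
      jpt <- walk_to_baseline(x, if (s_ok) s else r, +1L, b0, onset_frac,
                              ms(150), floor_mv)

      # final baseline: PR segment, 40 ms window ending 20 ms before QRS onset
      blo <- max(1L, qrs_on - ms(60)); bhi <- max(blo, qrs_on - ms(20))
      b <- stats::median(x[blo:bhi])

      p <- window_extremum(x, a - ms(300), a - ms(100), b)
      p_ok <- !is.na(p) && abs(x[p] - b) >= presence && p < qrs_on - 1L
      if (p_ok) {
        p_on <- walk_to_baseline(x, p, -1L, b, onset_frac, ms(120), floor_mv)
        p_off <- min(walk_to_baseline(x, p, +1L, b, onset_frac, ms(120), floor_mv),
                     qrs_on - 1L)
        if (p_on >= p || p_off <= p) p <- p_on <- p_off <- NA_integer_
      } else p <- p_on <- p_off <- NA_integer_

      tp <- window_extremum(x, jpt + ms(80), jpt + ms(420), b)
      t_ok <- !is.na(tp) && abs(x[tp] - b) >= presence
      if (t_ok) {
        t_on <- max(walk_to_baseline(x, tp, -1L, b, onset_frac, ms(250), floor_mv),
                    jpt + 1L)
        t_off <- walk_to_baseline(x, tp, +1L, b, onset_frac, ms(300), floor_mv)
        if (t_on >= tp || t_off <= tp) tp <- t_on <- t_off <- NA_integer_
      } else tp <- t_on <- t_off <- NA_integer_

      rows[[length(rows) + 1L]] <- data.frame(
        lead = ld, beat = bi,
        P_on = p_on, P_peak = p, P_off = p_off,
        QRS_on = qrs_on,
        Q = if (q_ok) q else NA_integer_, R = r,
        S = if (s_ok) s else NA_integer_, J = jpt,
        T_on = t_on, T_peak = tp, T_off = t_off,
        baseline_mv = b)
    }
  }
  if (!length(rows)) stop("no delineatable beats (record too short?)")
  fiducial_map(do.call(rbind, rows), n_samples = n)
}

#' Build per-lead averaged beat templates with beat-quality control
#'
#' Beats are aligned on R and extracted on a window spanning the lead's
#' median QRS onset minus 150 ms to its median T offset plus 50 ms. Each
#' beat is correlated with the pointwise median beat; beats with Pearson
#' correlation below `min_corr` are discarded. If any lead retains fewer
#' than `min_beats` beats the whole record is excluded (a valid outcome,
#' returned with a reason code, mirroring quality control that drops
#' recordings without a minimum number of low-deviation beats).
#'
#' @param record An [ecg_record].
#' @param fiducials A [fiducial_map] for the record.
#' @param min_beats Minimum retained beats per lead (default 5).
#' @param min_corr Minimum correlation to the median beat (default 0.90).
#' @return List with `excluded` (logical), `reason` (string or NA) and, if
#'   kept, `templates`: per lead a list with `samples` (mean of retained
#'   beats, mV), `r_index` (R position within the window), `n_beats_used`,
#'   `beats_used`, `correlations`, `offsets` (median landmark offsets
#'   relative to R, samples), `baseline` (median beat baseline, mV) and
#'   `fs`.
#' @export
build_templates <- function(record, fiducials, min_beats = 5, min_corr = 0.90) {
  stopifnot(inherits(record, "ecg_record"))
  fs <- record$fs
  n <- ncol(record$signals)
  ms <- function(k) round(k / 1000 * fs)
  templates <- list()
  for (ld in record$lead_names) {
    fd <- fiducials[fiducials$lead == ld, ]
    if (!nrow(fd)) {
      return(list(excluded = TRUE,
                  reason = sprintf("no_beats_lead_%s", ld), templates = NULL))
    }
    med_on <- stats::median(fd$QRS_on - fd$R, na.rm = TRUE)
    med_toff <- stats::median(fd$T_off - fd$R, na.rm = TRUE)
    if (is.na(med_toff)) med_toff <- stats::median(fd$J - fd$R, na.rm = TRUE) + ms(300)
    lo_off <- round(med_on) - ms(150)
    hi_off <- round(med_toff) + ms(50)
    ok <- fd$R + lo_off >= 1 & fd$R + hi_off <= n
    fd <- fd[ok, ]
    if (nrow(fd) < min_beats) {
      return(list(excluded = TRUE,
                  reason = sprintf("too_few_beats_lead_%s", ld), templates = NULL))
    }
    seg <- t(vapply(fd$R, function(r) record$signals[ld, (r + lo_off):(r + hi_off)],
                    numeric(hi_off - lo_off + 1L)))
    # remove per-beat linear drift (baseline wander): fit a line through
    # the two isoelectric anchor regions of each beat -- the PR segment
    # (40 ms ending 20 ms before the median QRS onset) and the tail after
    # the T offset -- and subtract it
    m <- ncol(seg)
    pr_idx <- (ms(150) - ms(60)):(ms(150) - ms(20)) + 1L
    tail_idx <- (m - ms(40)):m
    t1 <- stats::median(pr_idx); t2 <- stats::median(tail_idx)
    b1 <- apply(seg[, pr_idx, drop = FALSE], 1L, stats::median)
    b2 <- apply(seg[, tail_idx, drop = FALSE], 1L, stats::median)
    sl <- (b2 - b1) / (t2 - t1)
    seg <- seg - (b1 + outer(sl, seq_len(m) - t1))
    medbeat <- apply(seg, 2L, stats::median)
    cors <- apply(seg, 1L, function(b) {
      if (stats::sd(b) == 0 || stats::sd(medbeat) == 0) return(0)
      stats::cor(b, medbeat)
    })
    keep <- which(cors >= min_corr)
    if (length(keep) < min_beats) {
      return(list(excluded = TRUE,
                  reason = sprintf("qc_corr_lead_%s", ld), templates = NULL))
    }
    tmpl <- colMeans(seg[keep, , drop = FALSE])
    # isoelectric level of the template: median of its PR segment
    # (40 ms window ending 20 ms before the median QRS onset)
    pr_idx <- (ms(150) - ms(60)):(ms(150) - ms(20)) + 1L
    tmpl_baseline <- stats::median(tmpl[pr_idx])
    lmn <- fiducial_landmarks()
    offs <- vapply(lmn, function(l)
      round(stats::median(fd[[l]][keep] - fd$R[keep], na.rm = TRUE)), 0)
    offs[is.nan(offs)] <- NA_real_
    templates[[ld]] <- list(
      samples = tmpl, r_index = 1L - lo_off,
      n_beats_used = length(keep), beats_used = fd$beat[keep],
      correlations = cors,
      offsets = offs,
      baseline = tmpl_baseline,
      fs = fs)
  }
  list(excluded = FALSE, reason = NA_character_, templates = templates)
}
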