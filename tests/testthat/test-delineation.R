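test_that("R peaks on a clean 60 bpm record are found within one sample", {
  g <- generate_record(zero_noise_config(), "control", seed = 1)
  rp <- detect_r_peaks(g$record$signals["II", ], g$record$fs)
  truth <- g$fiducials$R[g$fiducials$lead == "II"]
  expect_gte(length(rp), 9)
  expect_lte(length(rp), 10)
  expect_equal(length(rp), length(truth))
  expect_lte(max(abs(rp - truth)), 1)
})

test_that("flat or all-zero signals raise a no-beats error", {
  expect_error(detect_r_peaks(rep(0, 5000), 500), "flat|no beats")
  expect_error(detect_r_peaks(rep(1.3, 5000), 500), "flat|no beats")
  expect_error(detect_r_peaks(rep(0, 100), 500), "2 s")
})

test_that("the detector is polarity-insensitive", {
  g <- generate_record(synthetic_config(), "control", seed = 13)
  x <- g$record$signals["II", ]
  expect_equal(length(detect_r_peaks(-x, 500)), length(detect_r_peaks(x, 500)))
})

test_that("zero-noise landmark recovery is within 2 samples for >= 99%", {
  total <- 0; ok <- 0
  for (lab in c("control", "lvh")) {
    g <- generate_record(zero_noise_config(), lab, seed = 17)
    fid <- delineate_waves(g$record)
    m <- merge(as.data.frame(fid), as.data.frame(g$fiducials),
               by = c("lead", "beat"), suffixes = c("", ".t"))
    for (l in c("P_on", "P_peak", "P_off", "QRS_on", "Q", "R", "S", "J",
                "T_on", "T_peak", "T_off")) {
      truth <- m[[paste0(l, ".t")]]
      err <- abs(m[[l]] - truth)
      total <- total + sum(!is.na(truth))
      ok <- ok + sum(err <= 2, na.rm = TRUE)
    }
  }
  expect_gte(ok / total, 0.99)
})

test_that("fiducial monotonicity holds on delineated noisy records", {
  for (s in 1:5) {
    g <- generate_record(synthetic_config(), sample(c("control", "lvh"), 1),
                         seed = 500 + s)
    fid <- delineate_waves(g$record)
    expect_true(validate_fiducials(fid, ncol(g$record$signals)))
  }
})

test_that("a zero-amplitude P wave is flagged absent, not fabricated", {
  w <- default_wave_params()
  for (ld in names(w)) w[[ld]]$amp[w[[ld]]$wave == "P"] <- 0
  g <- generate_record(zero_noise_config(waves = w), "control", seed = 2)
  fid <- delineate_waves(g$record)
  expect_true(all(is.na(fid$P_peak)))
  expect_true(all(is.na(fid$P_on)))
})

test_that("an inverted T wave keeps its negative sign", {
  g <- generate_record(zero_noise_config(), "lvh", seed = 2)
  fid <- delineate_waves(g$record)
  f <- fid[fid$lead == "V5", ]
  amps <- g$record$signals["V5", f$T_peak] - f$baseline_mv
  expect_true(all(amps < 0))
})

test_that("templates of identical beats reproduce the beat exactly", {
  g <- generate_record(zero_noise_config(), "control", seed = 8)
  fid <- delineate_waves(g$record)
  tm <- build_templates(g$record, fid)
  expect_false(tm$excluded)
  for (ld in c("II", "V2")) {
    tp <- tm$templates[[ld]]
    expect_true(all(tp$correlations > 0.9999))
    expect_equal(tp$n_beats_used, sum(fid$lead == ld))
    # identical beats: the template's R-peak amplitude matches the signal's
    r_amp_tpl <- tp$samples[tp$r_index] - tp$baseline
    f <- fid[fid$lead == ld, ][1, ]
    expect_lt(abs(r_amp_tpl - (g$record$signals[ld, f$R] - f$baseline_mv)),
              0.005)
  }
})

test_that("corrupted beats are dropped by QC while the record is kept", {
  g <- generate_record(zero_noise_config(), "control", seed = 8)
  fid <- delineate_waves(g$record)
  rec <- g$record
  bad <- c(3, 5, 8)
  rII <- fid$R[fid$lead == "II"]
  set.seed(99)
  for (b in bad) {
    win <- (rII[b] - 150):(rII[b] + 250)
    rec$signals[, win] <- matrix(rnorm(12 * length(win), sd = 1), nrow = 12)
  }
  tm <- build_templates(rec, fid, min_beats = 5, min_corr = 0.9)
  expect_false(tm$excluded)
  for (ld in standard_leads())
    expect_false(any(bad %in% tm$templates[[ld]]$beats_used))
})

test_that("records with too few QC-passing beats are excluded with a reason", {
  g <- generate_record(zero_noise_config(), "control", seed = 8)
  fid <- delineate_waves(g$record)
  n_beats <- max(fid$beat)
  tm <- build_templates(g$record, fid, min_beats = n_beats + 1)
  expect_true(tm$excluded)
  expect_match(tm$reason, "too_few_beats")
})
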