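# Deterministic generator configs used across the suite.

# All stochastic terms off: every beat is an exact copy of the analytic
# wave model, so extracted quantities can be compared with ground truth.
zero_noise_config <- function(...) {
  synthetic_config(noise_sd_mv = 0, baseline_wander_mv = 0,
                   hr_jitter_bpm = 0, rr_jitter_s = 0,
                   amp_scale_sd = 0, amp_jitter_cv = 0, ...)
}

# Gaussian-feature two-class data frame mimicking a separable cohort:
# `shift` is the class mean difference (in SD units) of the informative
# features; extra columns are pure noise.
make_gaussian_fm <- function(n_control, n_lvh, n_informative = 1,
                             n_noise = 0, shift = 2, sd = 1, seed = 1) {
  set.seed(seed)
  n <- n_control + n_lvh
  labels <- c(rep("control", n_control), rep("lvh", n_lvh))
  X <- matrix(rnorm(n * (n_informative + n_noise), sd = sd),
              nrow = n)
  if (n_informative > 0)
    X[labels == "lvh", seq_len(n_informative)] <-
      X[labels == "lvh", seq_len(n_informative)] + shift
  colnames(X) <- c(if (n_informative) paste0("inf", seq_len(n_informative)),
                   if (n_noise) paste0("noise", seq_len(n_noise)))
  cbind(data.frame(record_id = sprintf("r%03d", seq_len(n)), label = labels),
        as.data.frame(X))
}

# Synthetic T-wave ensemble drawn from the two-term dominant-T-wave model
# with a known std[w2]/std[w1] ratio (in ms). The dominant waveform is a
# symmetric Gaussian bump, so its derivative is orthogonal to it and the
# factorization is identifiable.
make_vindex_ensemble <- function(ratio_ms = 30, noise_frac = 0.01,
                                 n_leads = 8, fs = 500, m = 150) {
  tgrid <- ((seq_len(m) - m / 2) / fs)
  Td <- exp(-tgrid^2 / (2 * 0.04^2))
  Td <- Td / sqrt(sum(Td^2))
  dTd <- numeric(m)
  dTd[2:(m - 1)] <- (Td[3:m] - Td[1:(m - 2)]) / 2
  dTd[1] <- Td[2] - Td[1]; dTd[m] <- Td[m] - Td[m - 1]
  dTd <- dTd * fs
  w1 <- rnorm(n_leads, 1, 0.3)
  w2 <- rnorm(n_leads, 0, sd(w1) * ratio_ms / 1000)
  Psi <- outer(w1, Td) + outer(w2, dTd)
  Psi <- Psi + matrix(rnorm(length(Psi), 0, noise_frac * max(abs(Psi))),
                      nrow = n_leads)
  rownames(Psi) <- paste0("L", seq_len(n_leads))
  list(psi = structure(list(Psi = Psi, leads = rownames(Psi), fs = fs),
                       class = "t_wave_ensemble"),
       w1 = w1, w2 = w2, Td = Td, dTd = dTd,
       true_ratio_ms = sd(w2) / sd(w1) * 1000)
}

# Brute-force minimum of the ROC-corner objective over every realizable
# prediction set (independent oracle for choose_threshold).
brute_force_corner_objective <- function(scores, labels, positive = "lvh") {
  pos <- labels == positive
  cuts <- c(-Inf, sort(unique(scores)), Inf)
  min(vapply(cuts, function(ct) {
    pred <- scores >= ct
    fpr <- sum(pred & !pos) / sum(!pos)
    tpr <- sum(pred & pos) / sum(pos)
    fpr^2 + (1 - tpr)^2
  }, 0))
}

# A feature row (all amplitudes zero, QRS duration 100 ms) for criteria
# tests; amplitudes in mV.
zero_feature_row <- function() {
  nm <- c(outer(c("P_amp", "Q_amp", "R_amp", "S_amp", "J_amp", "T_amp",
                  "QRS_dur"), standard_leads(), paste, sep = "_"))
  v <- stats::setNames(rep(0, length(nm)), nm)
  v[grep("^QRS_dur_", nm)] <- 100
  v
}
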