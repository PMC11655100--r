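#' Build the cross-lead T-wave ensemble
#'
#' Stacks baseline-corrected T-wave segments of the lead templates on a
#' common time grid: the window spans from the earliest per-lead median T
#' onset minus 10 ms to the latest T offset plus 10 ms (relative to R), so
#' every row covers the same instants. By default the eight linearly
#' independent leads (I, II, V1-V6) are used; the augmented limb leads are
#' linear combinations of I and II and would bias the cross-lead standard
#' deviations.
#'
#' @param templates The `templates` element of [build_templates()].
#' @param leads Lead subset (default I, II, V1-V6).
#' @return Object of class `t_wave_ensemble`: list with `Psi` (L x M
#'   matrix, mV), `leads`, `fs`.
#' @export
t_wave_ensemble <- function(templates,
                            leads = c("I", "II", paste0("V", 1:6))) {
  leads <- intersect(leads, names(templates))
  if (length(leads) < 3L) stop("need at least 3 leads with templates")
  fs <- templates[[leads[1]]]$fs
  pad <- round(0.01 * fs)
  ons <- vapply(leads, function(ld) templates[[ld]]$offsets[["T_on"]], 0)
  offs <- vapply(leads, function(ld) templates[[ld]]$offsets[["T_off"]], 0)
  if (any(is.na(ons)) || any(is.na(offs)))
    stop("T wave not delineated on all requested leads")
  lo <- min(ons) - pad
  hi <- max(offs) + pad
  # clip to the span available on every template so all rows share a grid
  lo <- max(lo, max(vapply(leads, function(ld) 1 - templates[[ld]]$r_index, 0)))
  hi <- min(hi, min(vapply(leads, function(ld)
    length(templates[[ld]]$samples) - templates[[ld]]$r_index, 0)))
  if (hi - lo < 19L) stop("T-wave segment too short (< 20 samples)")
  rows <- lapply(leads, function(ld) {
    tp <- templates[[ld]]
    tp$samples[(tp$r_index + lo):(tp$r_index + hi)] - tp$baseline
  })
  Psi <- do.call(rbind, rows)
  rownames(Psi) <- leads
  if (ncol(Psi) < 20L) stop("T-wave segment too short (< 20 samples)")
  structure(list(Psi = Psi, leads = leads, fs = fs),
            class = "t_wave_ensemble")
}

#' Estimate the dominant T-wave and its time derivative
#'
#' The dominant T-wave is the first singular direction of the lead-by-time
#' ensemble matrix (the common waveform of the rank-1 lead-factor model),
#' with unit L2 norm and sign chosen so that its correlation with the mean
#' row of the ensemble is positive. Its time derivative is computed with a
#' wide cubic Savitzky-Golay differentiator (31-point window): plain central
#' differences amplify any noise left in the estimated waveform, which
#' would corrupt the derivative regressor, while the polynomial
#' differentiator is exact on smooth waveforms.
#'
#' @param psi A [t_wave_ensemble()].
#' @return List with `Td` (length-M waveform), `dTd` (its derivative, 1/s
#'   scaled), `fs`.
#' @export
dominant_t_wave <- function(psi) {
  stopifnot(inherits(psi, "t_wave_ensemble"))
  P <- psi$Psi
  if (all(P == 0)) stop("ensemble has rank 0 (all-zero T waves)")
  sv <- svd(P, nu = 0, nv = 1)
  Td <- sv$v[, 1]
  mrow <- colMeans(P)
  s <- sum(Td * mrow)
  if (s < 0) Td <- -Td
  m <- length(Td)
  n_sg <- min(31L, if (m %% 2 == 1) m else m - 1L)
  dTd <- signal::sgolayfilt(Td, p = min(3L, n_sg - 1L), n = n_sg, m = 1L,
                            ts = 1 / psi$fs)
  list(Td = Td, dTd = dTd, fs = psi$fs)
}

#' Per-lead coefficients of the second-order dominant-T-wave model
#'
#' Each lead's T wave is approximated as
#' \deqn{\Psi_\ell \approx w_1(\ell) T_d + w_2(\ell) \dot T_d}
#' by two-regressor least squares. `w1` is dimensionless; `w2` carries
#' units of seconds (the derivative regressor is 1/s scaled).
#'
#' @param psi A [t_wave_ensemble()].
#' @param dominant Result of [dominant_t_wave()] on the same ensemble.
#' @return List with numeric vectors `w1` and `w2` (one entry per lead).
#' @export
lead_coefficients <- function(psi, dominant) {
  X <- cbind(dominant$Td, dominant$dTd)
  G <- crossprod(X)
  if (rcond(G) < 1e-12)
    stop("dominant T-wave and its derivative are numerically collinear")
  W <- t(solve(G, t(psi$Psi %*% X)))
  list(w1 = stats::setNames(W[, 1], psi$leads),
       w2 = stats::setNames(W[, 2], psi$leads))
}

#' V-index of spatial repolarization heterogeneity
#'
#' The V-index approximates the standard deviation of ventricular
#' repolarization times as the ratio of the cross-lead standard deviations
#' of the second-order model coefficients,
#' \deqn{V = std[w_2] / std[w_1]}
#' expressed in milliseconds (`w2` is in seconds). A zero spread of `w1`
#' makes the index undefined; `NA` is returned with a warning.
#'
#' @param w1,w2 Per-lead coefficient vectors from [lead_coefficients()].
#' @return Scalar V-index in ms (>= 0), or NA if undefined.
#' @export
v_index <- function(w1, w2) {
  if (length(w1) < 3L) stop("need at least 3 leads")
  s1 <- stats::sd(w1)
  if (!is.finite(s1) || s1 == 0) {
    warning("v_index undefined: std[w1] = 0")
    return(NA_real_)
  }
  stats::sd(w2) / s1 * 1000
}

#' V-index of one record from its lead templates
#'
#' Convenience wrapper: builds the T-wave ensemble, estimates the dominant
#' T-wave, fits the per-lead coefficients and returns the V-index.
#'
#' @param templates The `templates` element of [build_templates()].
#' @param leads Lead subset (see [t_wave_ensemble()]).
#' @return List with `v_index` (ms), `w1`, `w2`, `dominant`.
#' @export
v_index_record <- function(templates, leads = c("I", "II", paste0("V", 1:6))) {
  psi <- t_wave_ensemble(templates, leads)
  dom <- dominant_t_wave(psi)
  w <- lead_coefficients(psi, dom)
  list(v_index = v_index(w$w1, w$w2), w1 = w$w1, w2 = w$w2, dominant = dom)
}
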