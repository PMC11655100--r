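# For each criterion: a function placing amplitudes (mV) so the left-hand
# side equals a requested value L in mm (QRS duration fixed at 100 ms).
criterion_setters <- function() {
  list(
    "Lewis"         = function(v, L) { v["R_amp_I"] <- L / 10; v },
    "Gubner1"       = function(v, L) { v["R_amp_I"] <- L / 10; v },
    "Gubner2"       = function(v, L) { v["R_amp_I"] <- L / 10; v },
    "Sokolow-Lyon1" = function(v, L) { v["R_amp_aVL"] <- L / 10; v },
    "Goldberger"    = function(v, L) { v["R_amp_aVF"] <- L / 10; v },
    "Schack"        = function(v, L) { v["Q_amp_aVR"] <- -L / 10; v },
    "Romhilt1"      = function(v, L) { v["R_amp_I"] <- L / 10; v },
    "Wilson1"       = function(v, L) { v["S_amp_V1"] <- -L / 10; v },
    "Mazzoleni"     = function(v, L) { v["S_amp_V2"] <- -L / 10; v },
    "Sokolow-Lyon2" = function(v, L) { v["S_amp_V1"] <- -1; v["R_amp_V5"] <- (L - 10) / 10; v },
    "Romhilt2"      = function(v, L) { v["S_amp_V2"] <- -1; v["R_amp_V6"] <- (L - 10) / 10; v },
    "Murphy"        = function(v, L) { v["S_amp_V1"] <- -1; v["R_amp_V5"] <- (L - 10) / 10; v },
    "Grant1"        = function(v, L) { v["S_amp_V2"] <- -1; v["R_amp_V6"] <- (L - 10) / 10; v },
    "Grant2"        = function(v, L) { v["R_amp_V3"] <- L / 10; v },
    "Holt"          = function(v, L) { v["R_amp_V6"] <- 1; v["R_amp_V5"] <- L; v },
    "McPhie"        = function(v, L) { v["R_amp_V4"] <- L / 10; v },
    "Wolff"         = function(v, L) { v["S_amp_V2"] <- -1; v["R_amp_V4"] <- (L - 10) / 10; v },
    "Wilson2"       = function(v, L) { v["R_amp_V5"] <- L / 10; v },
    "Wilson3"       = function(v, L) { v["R_amp_V6"] <- L / 10; v },
    "Siegel"        = function(v, L) { v["R_amp_I"] <- L / 10; v },
    "Molloy1"       = function(v, L) { v["R_amp_aVL"] <- L / 100 / 10; v },
    "Molloy2"       = function(v, L) { v["R_amp_I"] <- L / 100 / 10; v })
}

test_that("mm conversion uses the 10 mm/mV calibration with magnitudes for depths", {
  expect_equal(to_millimeters(1.0), 10)
  expect_equal(to_millimeters(0), 0)
  expect_equal(to_millimeters(abs(-2.3)), 23)
})

test_that("the battery evaluates exactly 22 criteria, all negative on zero input", {
  rep <- evaluate_criteria(zero_feature_row())
  expect_equal(nrow(rep), 22)
  expect_identical(rep$criterion, criteria_names())
  expect_true(all(rep$positive %in% FALSE))
})

test_that("every criterion crosses its threshold exactly where codified", {
  setters <- criterion_setters()
  expect_setequal(names(setters), criteria_names())
  rep0 <- evaluate_criteria(zero_feature_row())
  thr <- stats::setNames(rep0$threshold, rep0$criterion)
  for (nm in names(setters)) {
    above <- evaluate_criteria(setters[[nm]](zero_feature_row(), thr[nm] * 1.001))
    below <- evaluate_criteria(setters[[nm]](zero_feature_row(), thr[nm] * 0.999))
    at <- evaluate_criteria(setters[[nm]](zero_feature_row(), thr[nm]))
    expect_true(above$positive[above$criterion == nm], label = paste(nm, "above"))
    expect_false(below$positive[below$criterion == nm], label = paste(nm, "below"))
    # strict inequality: boundary equality is negative
    expect_false(at$positive[at$criterion == nm], label = paste(nm, "at"))
    expect_equal(above$lhs[above$criterion == nm], unname(thr[nm]) * 1.001,
                 tolerance = 1e-9)
  }
})

test_that("worked examples: Sokolow-Lyon voltage and the Holt ratio", {
  v <- zero_feature_row()
  v["S_amp_V1"] <- -2.0; v["R_amp_V5"] <- 1.6
  rep <- evaluate_criteria(v)
  expect_equal(rep$lhs[rep$criterion == "Sokolow-Lyon2"], 36)
  expect_true(rep$positive[rep$criterion == "Sokolow-Lyon2"])

  v <- zero_feature_row()
  v["R_amp_V5"] <- 1.0; v["R_amp_V6"] <- 0.8
  rep <- evaluate_criteria(v)
  expect_equal(rep$lhs[rep$criterion == "Holt"], 1.25)
  expect_true(rep$positive[rep$criterion == "Holt"])
})

test_that("positivity is preserved under uniform voltage scaling", {
  set.seed(8)
  for (i in 1:20) {
    v <- zero_feature_row()
    amps <- grep("_amp_", names(v))
    v[amps] <- rnorm(length(amps), 0, 1.2)
    r1 <- evaluate_criteria(v)
    v2 <- v; v2[amps] <- v2[amps] * 1.7
    r2 <- evaluate_criteria(v2)
    flipped <- which(r1$positive %in% TRUE & r2$positive %in% FALSE)
    expect_length(flipped, 0)
  }
})

test_that("missing operands yield missing criteria, treated as negative in combos", {
  v <- zero_feature_row()
  v["S_amp_V1"] <- NA
  rep <- evaluate_criteria(v)
  expect_true(is.na(rep$positive[rep$criterion == "Sokolow-Lyon2"]))
  expect_true(is.na(rep$positive[rep$criterion == "Wilson1"]))
  expect_false(is.na(rep$positive[rep$criterion == "Gubner2"]))
  expect_false(combine_any(rep, c("Sokolow-Lyon2", "Wilson1")))
})

test_that("any-of combination follows the stated rules and is monotone", {
  v <- zero_feature_row()
  v["R_amp_I"] <- 2.0  # Siegel lhs 20 < 175: still negative; raise total
  v[grep("^R_amp_", names(v))] <- 1.6  # total voltage 192 mm -> Siegel positive
  rep <- evaluate_criteria(v)
  expect_true(rep$positive[rep$criterion == "Siegel"])
  expect_true(combine_any(rep, top_five_criteria()))
  expect_false(combine_any(evaluate_criteria(zero_feature_row()),
                           top_five_criteria()))
  expect_false(combine_any(rep, character(0)))
  # monotone under set inclusion
  expect_true(combine_any(rep, c(top_five_criteria(), "Holt")))
  expect_error(combine_any(rep, "NotACriterion"), "unknown")
})
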