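#' Standard 12-lead names in conventional order
#'
#' Limb leads I, II, III, aVR, aVL, aVF followed by precordial leads V1-V6.
#' All signal matrices in the package use this row order.
#'
#' @return Character vector of length 12.
#' @export
standard_leads <- function() {
  c("I", "II", "III", "aVR", "aVL", "aVF",
    "V1", "V2", "V3", "V4", "V5", "V6")
}

.limb_leads <- function() c("I", "II", "III", "aVR", "aVL", "aVF")
.precordial_leads <- function() paste0("V", 1:6)

# Evaluate expr under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched.
with_seed <- function(seed, expr) {
  if (!is.null(old <- get0(".Random.seed", globalenv()))) {
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Deterministic child seed, kept inside 32-bit integer range.
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 10007 + as.double(index)) %% 2147483647L)
}

#' Rank-statistic area under the ROC curve
#'
#' AUC computed as the Mann-Whitney rank statistic: the probability that a
#' randomly chosen positive record outscores a randomly chosen negative one
#' (ties count one half).
#'
#' @param scores Numeric vector of classifier scores (higher = more positive).
#' @param labels Vector of class labels aligned with `scores`.
#' @param positive Label treated as the positive class (default `"lvh"`).
#' @return AUC in \[0, 1\].
#' @export
auc_rank <- function(scores, labels, positive = "lvh") {
  stopifnot(length(scores) == length(labels))
  pos <- labels == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present to compute AUC")
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x == round(x)
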