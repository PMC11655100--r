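#' Down-sample the majority class to balance a two-class label vector
#'
#' All minority-class rows are kept; a uniform random subset of the
#' majority class of equal size is kept. Deterministic given the seed.
#'
#' @param labels Vector of class labels (two classes).
#' @param seed Integer seed.
#' @return Sorted integer vector of retained row indices.
#' @export
balance_downsample <- function(labels, seed = 1L) {
  tab <- table(labels)
  if (length(tab) != 2L) stop("balance_downsample needs exactly two classes")
  minority <- names(tab)[which.min(tab)]
  majority <- names(tab)[which.max(tab)]
  if (tab[[minority]] == tab[[majority]]) return(seq_along(labels))
  min_idx <- which(labels == minority)
  maj_idx <- which(labels == majority)
  keep_maj <- with_seed(seed, sample(maj_idx, length(min_idx)))
  sort(c(min_idx, keep_maj))
}

#' Choose the classification threshold closest to the ideal ROC corner
#'
#' Scans all realizable score cuts (midpoints between consecutive distinct
#' sorted scores, plus sentinels below the minimum and above the maximum)
#' and returns the threshold minimizing
#' \deqn{FPR(\theta)^2 + (1 - TPR(\theta))^2,}
#' i.e. the operating point nearest the perfect-classification corner
#' (0, 1) of the ROC plane. A score >= threshold predicts the positive
#' class. Ties in the objective are broken toward the larger (more
#' specific) threshold.
#'
#' @param scores Numeric classifier scores.
#' @param labels Aligned class labels.
#' @param positive Positive-class label (default `"lvh"`).
#' @return The chosen threshold.
#' @export
choose_threshold <- function(scores, labels, positive = "lvh") {
  stopifnot(length(scores) == length(labels), all(is.finite(scores)))
  pos <- labels == positive
  if (!any(pos) || all(pos)) stop("both classes must be present")
  su <- sort(unique(scores))
  cand <- c(su[1] - 1, if (length(su) > 1) (su[-1] + su[-length(su)]) / 2,
            su[length(su)] + 1)
  n1 <- sum(pos); n0 <- sum(!pos)
  obj <- vapply(cand, function(th) {
    pred <- scores >= th
    fpr <- sum(pred & !pos) / n0
    tpr <- sum(pred & pos) / n1
    fpr^2 + (1 - tpr)^2
  }, 0)
  best <- which(obj <= min(obj) + 1e-12)
  cand[max(best)]
}

# Fit one learner kind on a (balanced, imputed, scaled) training matrix.
fit_learner <- function(X, y, kind, seed, ntree = 150) {
  yf <- factor(y, levels = c("control", "lvh"))
  with_seed(seed, switch(kind,
    logreg = {
      d <- data.frame(X, check.names = FALSE)
      d$.y <- yf
      suppressWarnings(stats::glm(.y ~ ., data = d, family = stats::binomial()))
    },
    rf = randomForest::randomForest(x = X, y = yf, ntree = ntree),
    svm = e1071::svm(x = X, y = yf, kernel = "radial", probability = TRUE),
    stop("unknown model kind: ", kind)))
}

# Positive-class score of a fitted learner on new rows.
score_learner <- function(fit, X, kind) {
  switch(kind,
    logreg = {
      unname(stats::predict(fit, newdata = data.frame(X, check.names = FALSE),
                            type = "response"))
    },
    rf = unname(stats::predict(fit, X, type = "prob")[, "lvh"]),
    svm = {
      p <- stats::predict(fit, X, probability = TRUE)
      unname(attr(p, "probabilities")[, "lvh"])
    })
}

# Column medians for imputation; NaN (all-NA column) -> 0.
col_medians <- function(X) {
  m <- apply(X, 2L, stats::median, na.rm = TRUE)
  m[!is.finite(m)] <- 0
  m
}

impute_cols <- function(X, med) {
  for (j in seq_len(ncol(X))) {
    nas <- is.na(X[, j])
    if (any(nas)) X[nas, j] <- med[j]
  }
  X
}

prep_matrix <- function(fm, features) {
  X <- as.matrix(fm[, features, drop = FALSE])
  storage.mode(X) <- "double"
  X
}

#' Train one classifier with balanced stratified cross-validation
#'
#' Runs `k` stratified folds; the training part of each fold is
#' independently balanced by majority-class down-sampling, missing values
#' are imputed with training-part medians, and (for logistic regression and
#' SVM) columns are standardized with training-part statistics only.
#' Out-of-fold scores are pooled to compute the cross-validated AUC and to
#' choose the operating threshold via [choose_threshold()]; the final
#' learner is refit on the full (balanced) data. All derived seeds are
#' stored in the returned model.
#'
#' @param fm Feature matrix data frame (`record_id`, `label`, features).
#' @param kind `"logreg"`, `"rf"` or `"svm"`.
#' @param features Character vector of feature columns to use.
#' @param k Number of folds (default 10).
#' @param seed Integer seed.
#' @param ntree Random-forest size (default 150 trees).
#' @return Object of class `trained_model`.
#' @export
train_with_cv <- function(fm, kind = c("logreg", "rf", "svm"),
                          features, k = 10, seed = 1L, ntree = 150) {
  kind <- match.arg(kind)
  y <- fm$label
  if (length(unique(y)) != 2L) stop("need both classes for training")
  X <- prep_matrix(fm, features)
  n <- nrow(X)
  folds <- with_seed(derive_seed(seed, 1L), {
    f <- integer(n)
    for (cl in unique(y)) {
      idx <- which(y == cl)
      f[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
    f
  })
  if (any(tapply(seq_len(n), folds, function(i) length(unique(y[i]))) < 2L))
    stop("a fold contains a single class; use fewer folds")

  scale_it <- kind %in% c("logreg", "svm")
  oof <- rep(NA_real_, n)
  for (fi in seq_len(k)) {
    tr <- which(folds != fi); te <- which(folds == fi)
    bal <- tr[balance_downsample(y[tr], derive_seed(seed, 100L + fi))]
    med <- col_medians(X[bal, , drop = FALSE])
    Xtr <- impute_cols(X[bal, , drop = FALSE], med)
    Xte <- impute_cols(X[te, , drop = FALSE], med)
    if (scale_it) {
      ctr <- colMeans(Xtr); scl <- apply(Xtr, 2L, stats::sd)
      scl[scl == 0 | !is.finite(scl)] <- 1
      Xtr <- scale(Xtr, ctr, scl); Xte <- scale(Xte, ctr, scl)
    }
    fit <- fit_learner(Xtr, y[bal], kind, derive_seed(seed, 200L + fi), ntree)
    oof[te] <- score_learner(fit, Xte, kind)
  }
  cv_auc <- auc_rank(oof, y)
  theta <- choose_threshold(oof, y)

  bal <- balance_downsample(y, derive_seed(seed, 300L))
  med <- col_medians(X[bal, , drop = FALSE])
  Xf <- impute_cols(X[bal, , drop = FALSE], med)
  ctr <- NULL; scl <- NULL
  if (scale_it) {
    ctr <- colMeans(Xf); scl <- apply(Xf, 2L, stats::sd)
    scl[scl == 0 | !is.finite(scl)] <- 1
    Xf <- scale(Xf, ctr, scl)
  }
  fit <- fit_learner(Xf, y[bal], kind, derive_seed(seed, 400L), ntree)
  structure(
    list(kind = kind, feature_names = features, fit = fit,
         threshold = theta, cv_auc = cv_auc,
         impute_medians = med, center = ctr, scale = scl,
         seed = seed, k = k, ntree = ntree),
    class = "trained_model")
}

#' Score / classify new records with a trained model
#'
#' @param model A [train_with_cv()] model (for `predict_scores`) or
#'   ensemble.
#' @param fm Feature matrix data frame containing the model's features.
#' @return `predict_scores`: numeric positive-class scores;
#'   `predict.trained_model`: `"control"`/`"lvh"` labels using the model's
#'   stored threshold.
#' @export
predict_scores <- function(model, fm) UseMethod("predict_scores")

#' @export
predict_scores.trained_model <- function(model, fm) {
  X <- impute_cols(prep_matrix(fm, model$feature_names), model$impute_medians)
  if (!is.null(model$center)) X <- scale(X, model$center, model$scale)
  score_learner(model$fit, X, model$kind)
}

#' @rdname predict_scores
#' @param object,... S3 predict method arguments.
#' @export
predict.trained_model <- function(object, fm, ...) {
  ifelse(predict_scores(object, fm) >= object$threshold, "lvh", "control")
}

#' Build a majority-vote ensemble of independently balanced models
#'
#' Trains `n_models` copies of [train_with_cv()] with independent derived
#' seeds, so each member sees a different down-sampling draw of the
#' majority class. The member order is fixed and persisted because the
#' voting tie rule depends on it.
#'
#' @inheritParams train_with_cv
#' @param n_models Number of members (default 100).
#' @return Object of class `ensemble_model`.
#' @export
build_ensemble <- function(fm, kind, features, n_models = 100, k = 10,
                           seed = 1L, ntree = 150) {
  models <- lapply(seq_len(n_models), function(i)
    train_with_cv(fm, kind, features, k = k,
                  seed = derive_seed(seed, i), ntree = ntree))
  structure(list(models = models, kind = kind, feature_names = features,
                 n_models = n_models, seed = seed,
                 vote_rule = "majority; ties resolved by the first member"),
            class = "ensemble_model")
}

#' Combine a vote matrix by majority with first-member tie break
#'
#' @param votes Character matrix, rows = records, columns = ensemble
#'   members in their persisted order, entries `"control"`/`"lvh"`.
#' @return Character vector of majority labels; exact ties take the first
#'   member's vote.
#' @export
majority_vote <- function(votes) {
  votes <- as.matrix(votes)
  apply(votes, 1L, function(v) {
    n_lvh <- sum(v == "lvh")
    n_ctl <- length(v) - n_lvh
    if (n_lvh > n_ctl) "lvh" else if (n_ctl > n_lvh) "control" else v[1]
  })
}

#' Predict by majority vote of an ensemble
#'
#' Each member votes using its own stored threshold; the majority label
#' wins, with exact ties resolved by the first member's prediction.
#'
#' @param ens An [build_ensemble()] ensemble.
#' @param fm Feature matrix data frame.
#' @return Character vector of predicted labels.
#' @export
predict_majority <- function(ens, fm) {
  stopifnot(inherits(ens, "ensemble_model"))
  votes <- vapply(ens$models, function(m) predict(m, fm),
                  character(nrow(fm)))
  if (is.null(dim(votes))) votes <- matrix(votes, nrow = 1L)
  majority_vote(votes)
}

#' @export
predict_scores.ensemble_model <- function(model, fm) {
  sc <- vapply(model$models, function(m) predict_scores(m, fm),
               numeric(nrow(fm)))
  if (is.null(dim(sc))) sc <- matrix(sc, nrow = 1L)
  rowMeans(sc)
}

#' Classification metrics against true labels
#'
#' Sensitivity = TP/(TP+FN), specificity = TN/(TN+FP), accuracy,
#' balanced accuracy = (sensitivity+specificity)/2, and (when scores are
#' supplied) the rank-statistic AUC.
#'
#' @param true_labels,pred_labels Aligned label vectors.
#' @param scores Optional numeric scores for AUC.
#' @param positive Positive-class label.
#' @return Object of class `eval_metrics` (a list).
#' @export
compute_metrics <- function(true_labels, pred_labels, scores = NULL,
                            positive = "lvh") {
  stopifnot(length(true_labels) == length(pred_labels))
  pos <- true_labels == positive
  ppos <- pred_labels == positive
  tp <- sum(pos & ppos); fn <- sum(pos & !ppos)
  tn <- sum(!pos & !ppos); fp <- sum(!pos & ppos)
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  out <- list(sensitivity = sens, specificity = spec,
              accuracy = (tp + tn) / length(pos),
              balanced_accuracy = (sens + spec) / 2,
              auc = if (!is.null(scores)) auc_rank(scores, true_labels, positive)
                    else NA_real_,
              TP = tp, FP = fp, TN = tn, FN = fn)
  class(out) <- "eval_metrics"
  out
}

#' @export
print.eval_metrics <- function(x, ...) {
  cat(sprintf(paste0("sensitivity %.3f  specificity %.3f  accuracy %.3f  ",
                     "balanced accuracy %.3f  AUC %s\n"),
              x$sensitivity, x$specificity, x$accuracy, x$balanced_accuracy,
              ifelse(is.na(x$auc), "NA", sprintf("%.3f", x$auc))))
  cat(sprintf("TP %d  FP %d  TN %d  FN %d\n", x$TP, x$FP, x$TN, x$FN))
  invisible(x)
}
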