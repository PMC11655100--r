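#' Sequential floating forward selection by cross-validated AUC
#'
#' Greedy forward selection with conditional backward elimination
#' (floating): at each step the feature whose addition yields the best
#' mean AUC is added, then features are removed as long as removal
#' strictly improves the best AUC recorded for the smaller subset size.
#' Subsets are scored by the mean AUC over `n_repeats` Monte-Carlo
#' stratified 70/30 train/test splits (the same splits for every candidate
#' subset); the training part of each split is balanced by majority-class
#' down-sampling. The search stops at `max_features`; the selected subset
#' is the best-mean-AUC subset visited (ties favor fewer features).
#' Constant columns are excluded up front and can never be selected.
#'
#' @param fm Feature matrix data frame (`record_id`, `label`, features).
#' @param kind Learner used for scoring (default `"logreg"`, the cheapest).
#' @param max_features Hard cap on subset size (default 30).
#' @param n_repeats Monte-Carlo repeats (default 5).
#' @param seed Integer seed; split seeds are derived and recorded.
#' @param ntree Random-forest size when `kind = "rf"`.
#' @return Object of class `sffs_trace`: list with `trace` (one row per
#'   visited subset: action, feature, size, mean/sd AUC), `selected`
#'   (character vector), `best_by_size`, `split_seeds`, `kind`.
#' @export
sffs_select <- function(fm, kind = c("logreg", "rf", "svm"),
                        max_features = 30, n_repeats = 5, seed = 1L,
                        ntree = 150) {
  kind <- match.arg(kind)
  y <- fm$label
  if (length(unique(y)) != 2L) stop("need both classes for feature selection")
  feats <- setdiff(names(fm), c("record_id", "label"))
  stopifnot(max_features >= 1, max_features <= length(feats))
  X <- prep_matrix(fm, feats)
  sds <- apply(X, 2L, stats::sd, na.rm = TRUE)
  feats <- feats[is.finite(sds) & sds > 0]
  if (!length(feats)) stop("no non-constant features available")

  split_seeds <- vapply(seq_len(n_repeats), function(i) derive_seed(seed, i), 0L)
  splits <- lapply(split_seeds, function(s) with_seed(s, {
    tr <- unlist(lapply(unique(y), function(cl) {
      idx <- which(y == cl)
      sample(idx, round(0.7 * length(idx)))
    }))
    list(train = sort(tr), test = setdiff(seq_along(y), tr))
  }))

  scale_it <- kind %in% c("logreg", "svm")
  cache <- new.env(parent = emptyenv())
  score_subset <- function(cols) {
    key <- paste(sort(cols), collapse = "|")
    if (!is.null(v <- cache[[key]])) return(v)
    aucs <- vapply(seq_along(splits), function(si) {
      sp <- splits[[si]]
      tr <- sp$train
      bal <- tr[balance_downsample(y[tr], derive_seed(split_seeds[si], 7L))]
      Xs <- X[, cols, drop = FALSE]
      med <- col_medians(Xs[bal, , drop = FALSE])
      Xtr <- impute_cols(Xs[bal, , drop = FALSE], med)
      Xte <- impute_cols(Xs[sp$test, , drop = FALSE], med)
      if (scale_it) {
        ctr <- colMeans(Xtr); scl <- apply(Xtr, 2L, stats::sd)
        scl[scl == 0 | !is.finite(scl)] <- 1
        Xtr <- scale(Xtr, ctr, scl); Xte <- scale(Xte, ctr, scl)
      }
      fit <- fit_learner(Xtr, y[bal], kind, derive_seed(split_seeds[si], 13L),
                         ntree)
      auc_rank(score_learner(fit, Xte, kind), y[sp$test])
    }, 0)
    v <- c(mean = mean(aucs), sd = stats::sd(aucs))
    cache[[key]] <- v
    v
  }

  S <- character(0)
  best_by_size <- list()
  trace <- list()
  step <- 0L
  note <- function(action, feature, cols, sc) {
    step <<- step + 1L
    trace[[step]] <<- data.frame(
      step = step, action = action, feature = feature,
      size = length(cols), subset = paste(cols, collapse = ";"),
      mean_auc = sc[["mean"]], sd_auc = sc[["sd"]])
    k <- length(cols)
    if (k >= 1 && (length(best_by_size) < k || is.null(best_by_size[[k]]) ||
                   sc[["mean"]] > best_by_size[[k]]$mean_auc)) {
      best_by_size[[k]] <<- list(subset = cols, mean_auc = sc[["mean"]],
                                 sd_auc = sc[["sd"]])
    }
  }

  while (length(S) < max_features) {
    cands <- setdiff(feats, S)
    if (!length(cands)) break
    sc <- lapply(cands, function(f) score_subset(c(S, f)))
    means <- vapply(sc, `[[`, 0, "mean")
    bi <- which.max(means)
    S <- c(S, cands[bi])
    note("add", cands[bi], S, sc[[bi]])
    # floating backward elimination
    while (length(S) > 2) {
      sc_rm <- lapply(S, function(f) score_subset(setdiff(S, f)))
      means_rm <- vapply(sc_rm, `[[`, 0, "mean")
      ri <- which.max(means_rm)
      k1 <- length(S) - 1L
      prev_best <- if (length(best_by_size) >= k1 && !is.null(best_by_size[[k1]]))
        best_by_size[[k1]]$mean_auc else -Inf
      if (means_rm[ri] > prev_best + 1e-12) {
        removed <- S[ri]
        S <- setdiff(S, removed)
        note("remove", removed, S, sc_rm[[ri]])
      } else break
    }
  }

  sizes <- which(!vapply(best_by_size, is.null, TRUE))
  best_means <- vapply(sizes, function(k) best_by_size[[k]]$mean_auc, 0)
  sel_k <- sizes[which.max(best_means)]  # which.max takes the first (smallest) on ties
  structure(
    list(trace = do.call(rbind, trace),
         selected = best_by_size[[sel_k]]$subset,
         best_by_size = best_by_size,
         split_seeds = split_seeds, kind = kind, seed = seed),
    class = "sffs_trace")
}

#' First k features in selection order
#'
#' Returns the first `k` features of the final selected subset, ordered by
#' the step at which each was (last) added during the forward search; used
#' to build the reduced few-feature models.
#'
#' @param trace An [sffs_select()] result.
#' @param k Number of features.
#' @return Character vector of length `min(k, length(selected))`.
#' @export
sffs_top_k <- function(trace, k = 5) {
  stopifnot(inherits(trace, "sffs_trace"))
  adds <- trace$trace[trace$trace$action == "add", ]
  last_add <- tapply(adds$step, adds$feature, max)
  sel <- trace$selected
  sel <- sel[order(last_add[sel])]
  utils::head(sel, k)
}
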