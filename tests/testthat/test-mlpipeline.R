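test_that("down-sampling balances classes and keeps every minority row", {
  labels <- c(rep("lvh", 30), rep("control", 70))
  idx <- balance_downsample(labels, seed = 1)
  expect_length(idx, 60)
  expect_equal(as.integer(table(labels[idx])), c(30L, 30L))
  expect_true(all(which(labels == "lvh") %in% idx))
  # already balanced -> identity
  bal <- c(rep("lvh", 10), rep("control", 10))
  expect_identical(balance_downsample(bal, 5), 1:20)
  # different seeds: same counts, generally different majority subsets
  i2 <- balance_downsample(labels, seed = 2)
  expect_length(i2, 60)
  expect_false(identical(idx, i2))
})

test_that("choose_threshold picks the ROC point nearest (0, 1)", {
  # three operating points: (0,0), (0.1,0.8), (1,1)
  scores <- c(rep(1, 9), 5, rep(5, 8), rep(1, 2))
  labels <- c(rep("control", 10), rep("lvh", 10))
  th <- choose_threshold(scores, labels)
  expect_equal(th, 3)  # midpoint cut realizing (0.1, 0.8), objective 0.05
  # perfectly separating scores attain the corner
  s2 <- c(rep(0.1, 5), rep(0.9, 5))
  l2 <- c(rep("control", 5), rep("lvh", 5))
  th2 <- choose_threshold(s2, l2)
  pred <- s2 >= th2
  expect_identical(pred, l2 == "lvh")
  expect_error(choose_threshold(1:5, rep("lvh", 5)), "both classes")
})

test_that("choose_threshold matches exhaustive minimization on random instances", {
  set.seed(42)
  for (i in 1:100) {
    n <- sample(10:60, 1)
    labels <- sample(c("control", "lvh"), n, replace = TRUE)
    if (length(unique(labels)) < 2) labels[1:2] <- c("control", "lvh")
    scores <- round(rnorm(n), sample(0:2, 1))  # ties included
    th <- choose_threshold(scores, labels)
    pos <- labels == "lvh"
    pred <- scores >= th
    obj <- (sum(pred & !pos) / sum(!pos))^2 + (1 - sum(pred & pos) / sum(pos))^2
    expect_equal(obj, brute_force_corner_objective(scores, labels),
                 tolerance = 1e-12)
  }
})

test_that("separable features give perfect cross-validated AUC and threshold", {
  fm <- make_gaussian_fm(40, 40, shift = 10, sd = 0.5, seed = 1)
  m <- train_with_cv(fm, "logreg", "inf1", k = 5, seed = 3)
  expect_equal(m$cv_auc, 1.0)
  expect_identical(unname(predict(m, fm)), fm$label)
})

test_that("permuted labels give chance-level cross-validated AUC", {
  aucs <- vapply(1:20, function(s) {
    fm <- make_gaussian_fm(30, 30, n_informative = 0, n_noise = 3, seed = s)
    train_with_cv(fm, "logreg", paste0("noise", 1:3), k = 5, seed = s)$cv_auc
  }, 0)
  expect_lt(abs(mean(aucs) - 0.5), 0.05)
})

test_that("training is deterministic under a fixed seed for all three kinds", {
  fm <- make_gaussian_fm(25, 25, n_noise = 2, shift = 2, seed = 4)
  for (kind in c("logreg", "rf", "svm")) {
    m1 <- train_with_cv(fm, kind, c("inf1", "noise1", "noise2"), k = 5,
                        seed = 7, ntree = 50)
    m2 <- train_with_cv(fm, kind, c("inf1", "noise1", "noise2"), k = 5,
                        seed = 7, ntree = 50)
    expect_identical(m1$cv_auc, m2$cv_auc)
    expect_identical(m1$threshold, m2$threshold)
    expect_identical(predict_scores(m1, fm), predict_scores(m2, fm))
  }
})

test_that("SFFS selects the planted informative feature first", {
  hits <- vapply(1:20, function(s) {
    fm <- make_gaussian_fm(40, 40, n_informative = 1, n_noise = 9,
                           shift = 2.5, seed = 100 + s)
    tr <- sffs_select(fm, "logreg", max_features = 2, n_repeats = 5, seed = s)
    adds <- tr$trace[tr$trace$action == "add", ]
    adds$feature[1] == "inf1"
  }, TRUE)
  expect_gte(mean(hits), 0.95)
})

test_that("with max_features = 1 SFFS agrees with the exhaustive single-feature oracle", {
  agree <- vapply(1:10, function(s) {
    fm <- make_gaussian_fm(30, 30, n_informative = 1, n_noise = 8,
                           shift = 2, seed = 200 + s)
    tr <- sffs_select(fm, "logreg", max_features = 1, n_repeats = 5, seed = s)
    feats <- setdiff(names(fm), c("record_id", "label"))
    # oracle: feature with the largest two-sided rank AUC on the full data
    aucs <- vapply(feats, function(f) {
      a <- auc_rank(fm[[f]], fm$label); max(a, 1 - a)
    }, 0)
    identical(tr$selected, names(which.max(aucs)))
  }, TRUE)
  expect_gte(mean(agree), 0.9)
})

test_that("SFFS is deterministic and rejects degenerate inputs", {
  fm <- make_gaussian_fm(20, 20, n_noise = 4, seed = 5)
  t1 <- sffs_select(fm, "logreg", max_features = 2, seed = 9)
  t2 <- sffs_select(fm, "logreg", max_features = 2, seed = 9)
  expect_identical(t1$trace, t2$trace)
  expect_identical(t1$selected, t2$selected)
  # constant columns can never be selected
  fm$const <- 1
  t3 <- sffs_select(fm, "logreg", max_features = 3, seed = 9)
  expect_false("const" %in% t3$selected)
  fm1 <- fm[fm$label == "control", ]
  expect_error(sffs_select(fm1, "logreg", max_features = 1), "both classes")
})

test_that("majority voting follows the tie rule on constructed patterns", {
  v51 <- matrix(c(rep("lvh", 51), rep("control", 49)), nrow = 1)
  expect_identical(majority_vote(v51), "lvh")
  tie_ctl <- matrix(c("control", rep(c("lvh", "control"), 49), "lvh"), nrow = 1)
  expect_identical(majority_vote(tie_ctl), "control")  # first member votes control
  tie_lvh <- matrix(c("lvh", rep(c("control", "lvh"), 49), "control"), nrow = 1)
  expect_identical(majority_vote(tie_lvh), "lvh")
  all_same <- matrix(rep("control", 10), nrow = 1)
  expect_identical(majority_vote(all_same), "control")
})

test_that("an ensemble of one model predicts exactly like its member", {
  fm <- make_gaussian_fm(20, 20, shift = 2, n_noise = 1, seed = 6)
  ens <- build_ensemble(fm, "logreg", c("inf1", "noise1"), n_models = 1,
                        k = 5, seed = 11)
  expect_identical(predict_majority(ens, fm),
                   unname(predict(ens$models[[1]], fm)))
  # same master seed -> identical ensemble
  ens2 <- build_ensemble(fm, "logreg", c("inf1", "noise1"), n_models = 1,
                         k = 5, seed = 11)
  expect_identical(predict_scores(ens, fm), predict_scores(ens2, fm))
})

test_that("on separable data all ensemble members agree on every record", {
  fm <- make_gaussian_fm(25, 25, shift = 8, sd = 0.5, seed = 7)
  ens <- build_ensemble(fm, "logreg", "inf1", n_models = 5, k = 5, seed = 13)
  votes <- vapply(ens$models, function(m) predict(m, fm), character(nrow(fm)))
  expect_true(all(apply(votes, 1, function(v) length(unique(v)) == 1)))
})

test_that("metrics follow their defining formulas", {
  truth <- c(rep("lvh", 4), rep("control", 6))
  pred <- c("lvh", "lvh", "lvh", "control", rep("control", 4), "lvh", "lvh")
  m <- compute_metrics(truth, pred)
  expect_equal(m$TP, 3); expect_equal(m$FN, 1)
  expect_equal(m$TN, 4); expect_equal(m$FP, 2)
  expect_equal(m$sensitivity, 0.75)
  expect_equal(m$specificity, 2 / 3)
  expect_equal(m$accuracy, 0.7)
  expect_equal(m$balanced_accuracy, (0.75 + 2 / 3) / 2)
  perfect <- compute_metrics(truth, truth, scores = c(rep(1, 4), rep(0, 6)))
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$auc, 1)
})

test_that("rank AUC equals the exhaustive pairing probability and is monotone-invariant", {
  set.seed(21)
  for (i in 1:20) {
    n <- sample(10:50, 1)
    labels <- sample(c("control", "lvh"), n, replace = TRUE)
    if (length(unique(labels)) < 2) labels[1:2] <- c("control", "lvh")
    scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)
    pos <- scores[labels == "lvh"]; neg <- scores[labels == "control"]
    pairs <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
    expect_equal(auc_rank(scores, labels), mean(pairs))
    expect_equal(auc_rank(exp(3 * scores), labels), mean(pairs))
  }
})

test_that("member-to-member CV-AUC spread under re-downsampling is small", {
  fm <- make_gaussian_fm(100, 100, n_informative = 3, n_noise = 2,
                         shift = 1.5, seed = 30)
  ens <- build_ensemble(fm, "logreg", setdiff(names(fm), c("record_id", "label")),
                        n_models = 20, k = 5, seed = 31)
  cv <- vapply(ens$models, `[[`, 0, "cv_auc")
  expect_lt(sd(cv), 0.02)
})
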