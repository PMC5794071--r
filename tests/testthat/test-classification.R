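test_that("t-test feature selection keeps discriminative columns only", {
  withr::with_seed(1, {
    x <- matrix(rnorm(100 * 8), 100, 8)
    y <- factor(rep(c("a", "b"), each = 50))
    x[y == "b", 1:2] <- x[y == "b", 1:2] + 1.5   # planted columns
  })
  sel <- ttest_select(x, y, alpha = 0.01)
  expect_setequal(as.integer(sel), 1:2)
  # vacuous threshold keeps everything
  expect_length(ttest_select(x, y, alpha = 1), 8)
  # a column identical across classes is never selected below alpha = 1
  x2 <- x; x2[, 3] <- rep(seq_len(50), 2)
  expect_false(3 %in% ttest_select(x2, y, alpha = 0.5))
  # empty selection falls back to the single best column
  xn <- matrix(rnorm(40 * 3), 40, 3)
  yn <- factor(rep(c("a", "b"), each = 20))
  expect_warning(selx <- ttest_select(xn, yn, alpha = 1e-12), "smallest-p")
  expect_length(selx, 1)
})

test_that("planted discriminative columns are recovered across seeded runs", {
  # d = 1.5 per column at n = 100 gives a noncentral-t power near 1 at alpha = .01
  hits <- vapply(1:10, function(r) {
    withr::with_seed(100 + r, {
      x <- matrix(rnorm(100 * 20), 100, 20)
      y <- factor(rep(c("a", "b"), each = 50))
      x[y == "b", 1:5] <- x[y == "b", 1:5] + 1.5
    })
    all(1:5 %in% ttest_select(x, y, alpha = 0.01))
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("nested CV separates well-separated classes and is deterministic", {
  gc2 <- gaussian_classes(50, 10, d = 4, seed = 2)
  cfg <- classifier_config(kernels = c("linear", "radial"),
                          c_grid = c(0.1, 1, 10), n_repeats = 2, seed = 7)
  rep1 <- nested_cv(gc2$x, gc2$y, cfg)
  expect_gte(rep1$accuracy, 0.95)
  expect_gte(rep1$auc, 0.98)
  expect_true(all(rep1$per_repeat$accuracy >= 0 & rep1$per_repeat$accuracy <= 1))
  rep2 <- nested_cv(gc2$x, gc2$y, cfg)
  expect_identical(rep1$predictions, rep2$predictions)
  expect_equal(rep1$accuracy, rep2$accuracy)
})

test_that("nested CV stays at chance on label-independent data", {
  withr::with_seed(3, {
    x <- matrix(rnorm(40 * 5), 40, 5)
    y <- factor(rep(c("a", "b"), each = 20))
  })
  cfg <- classifier_config(kernels = "linear", c_grid = c(0.1, 1),
                          n_repeats = 2, seed = 11)
  rep <- nested_cv(x, y, cfg)
  # 99% binomial band around the 0.5 majority rate at n = 40
  expect_gt(rep$accuracy, 0.5 - 2.58 * sqrt(0.25 / 40) - 0.1)
  expect_lt(rep$accuracy, 0.5 + 2.58 * sqrt(0.25 / 40) + 0.1)
})

test_that("in-fold selection does not leak: many-noise-feature null stays at chance", {
  # with t-test selection fitted on ALL subjects, 200 noise columns at n = 40
  # would yield optimistically separable features; the in-fold pipeline must not
  withr::with_seed(4, {
    x <- matrix(rnorm(40 * 200), 40, 200)
    y <- factor(rep(c("a", "b"), each = 20))
  })
  cfg <- classifier_config(kernels = "linear", c_grid = 1,
                          selection_alpha = 0.01, n_repeats = 2, seed = 5)
  rep <- nested_cv(x, y, cfg)
  expect_lt(rep$accuracy, 0.75)
  # the leaky analogue for contrast: select on everything, then resubstitute
  sel <- ttest_select(x, y, alpha = 0.01)
  leaky <- mean(predict(e1071::svm(x[, sel, drop = FALSE], y), x[, sel]) == y)
  expect_gt(leaky, 0.8)
})

test_that("ROC/AUC equals the exhaustive pair-counting oracle", {
  pair_auc <- function(scores, labels, positive) {
    pos <- which(labels == positive); neg <- which(labels != positive)
    tot <- 0
    for (i in pos) for (j in neg) {
      tot <- tot + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
    }
    tot / (length(pos) * length(neg))
  }
  s <- c(0.9, 0.8, 0.8, 0.35, 0.3, 0.1)
  l <- c("b", "a", "b", "b", "a", "a")
  got <- roc_auc(s, l, positive = "b")
  expect_equal(got$auc, pair_auc(s, l, "b"), tolerance = 1e-12)
  # trapezoidal area under the returned polygon equals the rank AUC
  roc <- got$roc
  trap <- sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) + roc$tpr[-1]) / 2)
  expect_equal(trap, got$auc, tolerance = 1e-12)
  for (r in 1:5) {
    withr::with_seed(r, {
      sr <- sample(seq(0, 1, by = 0.1), 12, replace = TRUE)
      lr <- sample(c("a", "b"), 12, replace = TRUE, prob = c(0.5, 0.5))
    })
    if (length(unique(lr)) < 2) next
    expect_equal(roc_auc(sr, lr, positive = "b")$auc,
                 pair_auc(sr, lr, "b"), tolerance = 1e-12)
  }
  expect_equal(roc_auc(c(3, 2, 1, 0), c("b", "b", "a", "a"),
                       positive = "b")$auc, 1)
  expect_error(roc_auc(1:4, rep("a", 4)), "both classes")
})

test_that("permutation p-values use the add-one estimator", {
  gc2 <- gaussian_classes(25, 5, d = 5, seed = 6)
  cfg <- classifier_config(kernels = "linear", c_grid = 1, n_repeats = 1,
                          n_permutations = 5, seed = 9)
  pt <- permutation_test(gc2$x, gc2$y, cfg)
  # observed accuracy on d = 5 classes beats every label permutation
  expect_equal(pt$p, 1 / 6)
  expect_gte(pt$observed, 0.95)
  expect_length(pt$perm_accuracies, 5)
  expect_true(all(pt$perm_accuracies < pt$observed))
})

test_that("accuracy-distribution comparisons handle paired and degenerate cases", {
  a <- c(0.8, 0.82, 0.78, 0.81)
  expect_equal(compare_accuracy_distributions(a, a)$p, 1)
  off <- compare_accuracy_distributions(a + 0.05, a)
  expect_equal(off$p, 0)
  expect_equal(off$mean_diff, 0.05)
  withr::with_seed(8, { u <- runif(20, 0.7, 0.9); v <- runif(20, 0.7, 0.9) })
  got <- compare_accuracy_distributions(u, v)
  ref <- stats::t.test(u - v)
  expect_equal(got$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(got$p, ref$p.value, tolerance = 1e-12)
  got2 <- compare_accuracy_distributions(u, v, paired = FALSE)
  ref2 <- stats::t.test(u, v)
  expect_equal(got2$p, ref2$p.value, tolerance = 1e-12)
  expect_error(compare_accuracy_distributions(u, v[1:3]), "equal-length")
})

test_that("fusion tends to beat single modalities when signal is split across them", {
  eff <- data.frame(roi = c(2, 4), modality = c("gm", "fa"), d = 1.2)
  cfg <- classifier_config(kernels = "linear", c_grid = c(0.1, 1),
                          n_repeats = 3, seed = 21)
  wins <- vapply(1:5, function(r) {
    out <- generate_cohort(cohort_config(60, n_roi = 6, n_timepoints = 80,
                                         effects = eff, seed = 700 + r))
    fs <- fusion_features(out$cohort)
    accs <- vapply(c("fusion", "fmri", "smri", "dti"), function(ms) {
      nested_cv(measure_design(fs, ms), out$cohort$labels$group, cfg)$accuracy
    }, numeric(1))
    accs[["fusion"]] >= max(accs[c("fmri", "smri", "dti")])
  }, logical(1))
  expect_gte(sum(wins), 3)
})
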