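#' Nested cross-validation SVM configuration
#'
#' Settings for [nested_cv()]: the kernel and cost grids searched on the
#' tuning fold, the in-fold t-test feature-selection threshold, the fold
#' count, the number of repeated fold randomizations, and the number of label
#' permutations for [permutation_test()].
#'
#' @param kernels Subset of `c("linear", "polynomial", "radial")`.
#' @param c_grid Positive trade-off parameters searched.
#' @param selection_alpha Two-sample t-test p threshold for feature inclusion.
#' @param n_folds Number of folds (>= 3: train/tune/test roles need three
#'   disjoint parts).
#' @param n_repeats Repeats with re-randomized fold assignment.
#' @param n_permutations Label permutations for the significance test.
#' @param poly_degree Polynomial kernel degree (the kernel's only free shape
#'   parameter here).
#' @param seed Integer seed controlling fold assignment and permutations.
#' @return A `classifier_config` list.
#' @export
classifier_config <- function(kernels = c("linear", "polynomial", "radial"),
                              c_grid = c(0.001, 0.01, 0.1, 1, 10,
                                         100, 1000, 10000),
                              selection_alpha = 0.05,
                              n_folds = 10,
                              n_repeats = 100,
                              n_permutations = 100,
                              poly_degree = 3,
                              seed = 1L) {
  kernels <- match.arg(kernels, c("linear", "polynomial", "radial"),
                       several.ok = TRUE)
  stopifnot(length(c_grid) >= 1, all(c_grid > 0),
            selection_alpha > 0, selection_alpha <= 1,
            n_folds >= 3, n_repeats >= 1)
  structure(list(kernels = kernels, c_grid = c_grid,
                 selection_alpha = selection_alpha,
                 n_folds = as.integer(n_folds),
                 n_repeats = as.integer(n_repeats),
                 n_permutations = as.integer(n_permutations),
                 poly_degree = poly_degree,
                 seed = as.integer(seed)),
            class = "classifier_config")
}

#' Select features by two-sample t-test
#'
#' Columns whose pooled-variance two-sided t-test p (computed on the supplied
#' rows only — inside cross-validation these are the training subjects) falls
#' below `alpha`. If no column passes, the single smallest-p column is
#' returned with a warning so downstream fitting never receives an empty
#' design.
#'
#' @param x Numeric matrix, subjects x features.
#' @param y Two-level factor of class labels.
#' @param alpha Inclusion threshold.
#' @return Integer vector of selected column indices; per-column p-values are
#'   attached as attribute `p`.
#' @export
ttest_select <- function(x, y, alpha) {
  y <- droplevels(as.factor(y))
  stopifnot(nlevels(y) == 2, nrow(x) == length(y))
  i1 <- y == levels(y)[1]
  n1 <- sum(i1); n2 <- sum(!i1)
  stopifnot(n1 >= 2, n2 >= 2)
  m1 <- colMeans(x[i1, , drop = FALSE])
  m2 <- colMeans(x[!i1, , drop = FALSE])
  v1 <- apply(x[i1, , drop = FALSE], 2, var)
  v2 <- apply(x[!i1, , drop = FALSE], 2, var)
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  t <- ifelse(sp2 > 0, (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2)), 0)
  p <- 2 * pt(-abs(t), df = n1 + n2 - 2)
  p[sp2 == 0 & m1 == m2] <- 1
  sel <- which(p < alpha)
  if (!length(sel)) {
    warn("no feature passed the t-test threshold; keeping the smallest-p column")
    sel <- which.min(p)
  }
  attr(sel, "p") <- p
  sel
}

stratified_folds <- function(y, n_folds) {
  folds <- integer(length(y))
  for (lv in levels(y)) {
    idx <- which(y == lv)
    folds[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
  }
  folds
}

oriented_scores <- function(model, newx, positive) {
  pred <- predict(model, newx, decision.values = TRUE)
  dv <- attr(pred, "decision.values")
  first <- strsplit(colnames(dv)[1], "/", fixed = TRUE)[[1]][1]
  score <- if (first == positive) dv[, 1] else -dv[, 1]
  list(pred = pred, score = as.numeric(score))
}

fit_predict_fold <- function(x, y, train, tune, test, cfg, positive) {
  mu <- colMeans(x[train, , drop = FALSE])
  sig <- apply(x[train, , drop = FALSE], 2, sd)
  sig[sig == 0] <- 1
  xs <- scale(x, center = mu, scale = sig)
  sel <- suppressWarnings(
    ttest_select(xs[train, , drop = FALSE], y[train], cfg$selection_alpha))
  xtr <- xs[train, sel, drop = FALSE]
  best <- NULL
  for (kern in cfg$kernels) {
    for (C in cfg$c_grid) {
      model <- e1071::svm(xtr, y[train], kernel = kern, cost = C,
                          degree = cfg$poly_degree, scale = FALSE)
      acc <- mean(predict(model, xs[tune, sel, drop = FALSE]) == y[tune])
      if (is.null(best) || acc > best$acc) {
        best <- list(model = model, acc = acc, kernel = kern, cost = C)
      }
    }
  }
  out <- oriented_scores(best$model, xs[test, sel, drop = FALSE], positive)
  list(pred = out$pred, score = out$score, selected = sel,
       kernel = best$kernel, cost = best$cost)
}

#' Nested cross-validated SVM classification
#'
#' Ten-fold (by default) cross-validation with three fold roles: eight folds
#' train the classifier (feature selection and z-normalization are refit on
#' them alone), one fold tunes the kernel and cost by accuracy, and the
#' held-out fold is scored. Roles rotate over all folds so every subject gets
#' an out-of-fold prediction; the whole assignment is re-randomized
#' `n_repeats` times and accuracy, sensitivity, specificity and AUC are
#' aggregated over repeats.
#'
#' @param x Numeric matrix, subjects x features, with subject row names.
#' @param y Two-level factor (or coercible) of class labels, one per row.
#' @param cfg A [classifier_config()].
#' @param positive Label treated as positive for sensitivity and decision
#'   scores; defaults to the second factor level.
#' @return A `cv_report` list: `accuracy`, `accuracy_sd`, `sensitivity`,
#'   `specificity`, `auc`, `roc` (tibble of ROC points), `per_repeat`
#'   (tibble of per-repeat metrics), `predictions` (per-repeat out-of-fold
#'   predictions and decision scores), `selected_freq` (selection frequency
#'   per feature), `best_params` (tuning choices per fold), and `config`.
#' @export
nested_cv <- function(x, y, cfg = classifier_config(), positive = NULL) {
  x <- as.matrix(x)
  if (is.null(rownames(x))) rownames(x) <- sprintf("S%03d", seq_len(nrow(x)))
  y <- droplevels(as.factor(y))
  stopifnot(nlevels(y) == 2, nrow(x) == length(y))
  if (any(table(y) < cfg$n_folds))
    abort("each class needs at least `n_folds` subjects for stratification")
  positive <- positive %||% levels(y)[2]
  negative <- setdiff(levels(y), positive)
  preds <- vector("list", cfg$n_repeats)
  params <- vector("list", cfg$n_repeats)
  sel_count <- numeric(ncol(x))
  n_fits <- 0
  for (r in seq_len(cfg$n_repeats)) {
    withr::with_seed(cfg$seed + r, {
      folds <- stratified_folds(y, cfg$n_folds)
      rep_rows <- vector("list", cfg$n_folds)
      rep_par <- vector("list", cfg$n_folds)
      for (f in seq_len(cfg$n_folds)) {
        test <- which(folds == f)
        tune <- which(folds == (f %% cfg$n_folds) + 1)
        train <- setdiff(seq_along(y), c(test, tune))
        fit <- fit_predict_fold(x, y, train, tune, test, cfg, positive)
        sel_count[fit$selected] <- sel_count[fit$selected] + 1
        n_fits <- n_fits + 1
        rep_rows[[f]] <- tibble(
          repeat_id = r, fold = f, subject = rownames(x)[test],
          true = as.character(y[test]), pred = as.character(fit$pred),
          score = fit$score)
        rep_par[[f]] <- tibble(repeat_id = r, fold = f,
                               kernel = fit$kernel, cost = fit$cost)
      }
      preds[[r]] <- dplyr::bind_rows(rep_rows)
      params[[r]] <- dplyr::bind_rows(rep_par)
    })
  }
  predictions <- dplyr::bind_rows(preds)
  per_repeat <- predictions |>
    dplyr::group_by(.data$repeat_id) |>
    dplyr::summarise(
      accuracy = mean(.data$pred == .data$true),
      sensitivity = mean(.data$pred[.data$true == positive] == positive),
      specificity = mean(.data$pred[.data$true == negative] == negative),
      .groups = "drop")
  mean_scores <- predictions |>
    dplyr::group_by(.data$subject) |>
    dplyr::summarise(score = mean(.data$score),
                     true = .data$true[1], .groups = "drop")
  roc <- roc_auc(mean_scores$score, mean_scores$true, positive = positive)
  structure(list(
    accuracy = mean(per_repeat$accuracy),
    accuracy_sd = sd(per_repeat$accuracy),
    sensitivity = mean(per_repeat$sensitivity),
    specificity = mean(per_repeat$specificity),
    auc = roc$auc,
    roc = roc$roc,
    per_repeat = per_repeat,
    predictions = predictions,
    selected_freq = tibble(
      feature = colnames(x) %||% paste0("V", seq_len(ncol(x))),
      freq = sel_count / n_fits),
    best_params = dplyr::bind_rows(params),
    positive = positive,
    config = cfg), class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf(paste0(
    "<cv_report> %d-fold nested CV, %d repeat(s)\n",
    "  accuracy %.4f (sd %.4f), sensitivity %.4f, specificity %.4f, AUC %.4f\n"),
    x$config$n_folds, x$config$n_repeats, x$accuracy, x$accuracy_sd,
    x$sensitivity, x$specificity, x$auc))
  if (!is.null(x$permutation_p))
    cat(sprintf("  permutation p = %.4f\n", x$permutation_p))
  invisible(x)
}

#' Permutation test of classification accuracy
#'
#' Reruns the full nested cross-validation on label-permuted data
#' `n_permutations` times and reports the add-one Monte-Carlo p-value
#' `p = (1 + #\{permuted >= observed\}) / (1 + n_permutations)`, the
#' probability of a permuted accuracy at least as large as the observed one
#' (never exactly 0; with 100 permutations the smallest attainable p is
#' 1/101).
#'
#' @param x,y,cfg As in [nested_cv()] (the permutation runs use `cfg` with
#'   per-permutation seeds derived from `cfg$seed`).
#' @param observed_accuracy Accuracy from [nested_cv()] on the unpermuted
#'   labels; computed if missing.
#' @param positive Positive class label.
#' @return A list with `p`, `observed`, and the vector `perm_accuracies`.
#' @export
permutation_test <- function(x, y, cfg = classifier_config(),
                             observed_accuracy = NULL, positive = NULL) {
  if (cfg$n_permutations < 1) abort("`n_permutations` must be >= 1")
  if (is.null(observed_accuracy))
    observed_accuracy <- nested_cv(x, y, cfg, positive)$accuracy
  perm <- vapply(seq_len(cfg$n_permutations), function(b) {
    yb <- withr::with_seed(cfg$seed + 100000L + b, sample(y))
    cfg_b <- cfg
    cfg_b$seed <- cfg$seed + 200000L + b
    nested_cv(x, yb, cfg_b, positive)$accuracy
  }, numeric(1))
  list(p = (1 + sum(perm >= observed_accuracy)) / (1 + cfg$n_permutations),
       observed = observed_accuracy,
       perm_accuracies = perm)
}

#' Empirical ROC curve and AUC
#'
#' Rank-based AUC (the probability that a random positive subject outscores a
#' random negative one, with ties counted half) and the empirical ROC polygon;
#' the trapezoidal area under the polygon equals the rank-based AUC.
#'
#' @param scores Numeric decision values, larger meaning more
#'   positive-looking.
#' @param labels Two-level class labels.
#' @param positive Positive class; defaults to the second level.
#' @return A list with `auc` and `roc`, a tibble of `(fpr, tpr)` points.
#' @export
#' @examples
#' roc_auc(c(0.9, 0.8, 0.3, 0.2), c("b", "a", "b", "a"), positive = "b")
roc_auc <- function(scores, labels, positive = NULL) {
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) != 2)
    abort("both classes must be present to compute a ROC curve")
  stopifnot(all(is.finite(scores)), length(scores) == length(labels))
  positive <- positive %||% levels(labels)[2]
  pos <- labels == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  r <- rank(scores)
  auc <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  ord <- order(scores, decreasing = TRUE)
  tp <- cumsum(pos[ord]); fp <- cumsum(!pos[ord])
  keep <- !duplicated(scores[ord], fromLast = TRUE)
  roc <- tibble(fpr = c(0, fp[keep] / n0), tpr = c(0, tp[keep] / n1))
  list(auc = auc, roc = roc)
}

#' Compare two per-repeat accuracy distributions
#'
#' Two-sided t-test between the per-repeat cross-validation accuracies of two
#' classifiers: paired when both used the same fold randomizations (the
#' default), Welch's unpaired otherwise. Degenerate zero-variance cases are
#' resolved by sign.
#'
#' @param acc_a,acc_b Numeric vectors of per-repeat accuracies.
#' @param paired Pair by repeat (requires equal lengths).
#' @return A tibble with columns `t`, `df`, `p`, `mean_diff`.
#' @export
compare_accuracy_distributions <- function(acc_a, acc_b, paired = TRUE) {
  if (paired) {
    if (length(acc_a) != length(acc_b))
      abort("paired comparison needs equal-length accuracy vectors")
    d <- acc_a - acc_b
    if (sd(d) == 0) {
      if (mean(d) == 0) return(tibble(t = 0, df = length(d) - 1,
                                      p = 1, mean_diff = 0))
      return(tibble(t = sign(mean(d)) * Inf, df = length(d) - 1,
                    p = 0, mean_diff = mean(d)))
    }
    ht <- stats::t.test(d)
  } else {
    ht <- stats::t.test(acc_a, acc_b)
  }
  tibble(t = unname(ht$statistic), df = unname(ht$parameter),
         p = ht$p.value, mean_diff = mean(acc_a) - mean(acc_b))
}

#' Flatten a fusion feature set into one design matrix
#'
#' Binds the requested measure set's columns across all ROIs into a single
#' subjects x features matrix (columns named `roi<index>_<feature>`), the
#' whole-brain input the classifier and the contribution models operate on.
#'
#' @param fs A `fusion_features` object.
#' @param measure One of `"fusion"`, `"fmri"`, `"smri"`, `"dti"`.
#' @return A numeric matrix with subject row names.
#' @export
measure_design <- function(fs, measure = "fusion") {
  stopifnot(inherits(fs, "fusion_features"))
  cols <- measure_columns(fs, match.arg(measure,
                                        c("fusion", "fmri", "smri", "dti")))
  out <- do.call(cbind, lapply(seq_len(fs$n_roi), function(i) {
    m <- fs$features[[i]][, cols, drop = FALSE]
    colnames(m) <- paste0("roi", i, "_", colnames(m))
    m
  }))
  rownames(out) <- fs$subjects
  out
}
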