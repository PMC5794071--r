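#' Constant-correlation matrix recipe
#'
#' Builds an exchangeable ROI-by-ROI correlation matrix with unit diagonal and
#' a constant off-diagonal correlation `rho`. Positive definite for
#' `-1/(n_roi - 1) < rho < 1`.
#'
#' @param n_roi Number of regions.
#' @param rho Common off-diagonal correlation.
#' @return An `n_roi` x `n_roi` correlation matrix.
#' @export
#' @examples
#' constant_corr(4, 0.3)
constant_corr <- function(n_roi, rho) {
  stopifnot(n_roi >= 1, is.numeric(rho), length(rho) == 1)
  m <- matrix(rho, n_roi, n_roi)
  diag(m) <- 1
  m
}

scalar_modalities <- c("gm", "wm", "fa", "rd", "md")
effect_modalities <- c("fc", scalar_modalities)

# Defaults chosen as plausible per-ROI summaries: volumes in cm^3, FA unitless,
# diffusivities in 1e-3 mm^2/s.
default_scalar_means <- c(gm = 7.5, wm = 5.0, fa = 0.45, rd = 0.60, md = 0.80)
default_scalar_sds   <- c(gm = 1.2, wm = 1.0, fa = 0.05, rd = 0.06, md = 0.06)

#' Configuration for a synthetic two-group multimodal cohort
#'
#' Describes the study conditions for [generate_cohort()]: group sizes, ROI
#' count, BOLD series length, the baseline inter-regional correlation
#' structure, the scalar-modality baselines, and the injected group effects.
#'
#' Effects are given as a data frame with columns `roi`, `modality` and, for
#' scalar modalities (`gm`, `wm`, `fa`, `rd`, `md`), an effect size `d` in
#' pooled-SD units applied as a mean shift to group 2. Functional-connectivity
#' effects use `modality = "fc"` with a `partner` ROI and a correlation `delta`
#' added to the group-2 target correlation between `roi` and `partner`.
#'
#' @param n_per_group Subjects per group.
#' @param n_roi Number of regions (default 90, the AAL cortical/subcortical
#'   parcellation used throughout).
#' @param n_timepoints BOLD volumes per subject (default 200).
#' @param base_corr Baseline ROI x ROI correlation matrix; if `NULL`, an
#'   exchangeable matrix with off-diagonal `rho` is used.
#' @param rho Off-diagonal correlation for the exchangeable recipe.
#' @param effects Data frame of injected effects (see Details); `NULL` for a
#'   null cohort.
#' @param scalar_means,scalar_sds Named numeric vectors of per-modality
#'   baseline means and SDs (names `gm`, `wm`, `fa`, `rd`, `md`).
#' @param seed Integer seed; fans out deterministically to per-subject streams
#'   so adding subjects never reshuffles earlier ones.
#' @return An object of class `cohort_config`.
#' @export
#' @examples
#' cfg <- cohort_config(20, n_roi = 10, n_timepoints = 50,
#'                      effects = data.frame(roi = 3, modality = "gm", d = 1))
cohort_config <- function(n_per_group,
                          n_roi = 90,
                          n_timepoints = 200,
                          base_corr = NULL,
                          rho = 0.1,
                          effects = NULL,
                          scalar_means = default_scalar_means,
                          scalar_sds = default_scalar_sds,
                          seed = 1L) {
  stopifnot(n_per_group >= 1, n_roi >= 2, n_timepoints >= 2)
  if (is.null(base_corr)) base_corr <- constant_corr(n_roi, rho)
  check_corr_matrix(base_corr, n_roi)
  effects <- normalize_effects(effects, n_roi)
  stopifnot(all(scalar_modalities %in% names(scalar_means)),
            all(scalar_modalities %in% names(scalar_sds)),
            all(scalar_sds[scalar_modalities] > 0))
  structure(
    list(n_per_group = as.integer(n_per_group),
         n_roi = as.integer(n_roi),
         n_timepoints = as.integer(n_timepoints),
         base_corr = base_corr,
         effects = effects,
         scalar_means = scalar_means[scalar_modalities],
         scalar_sds = scalar_sds[scalar_modalities],
         seed = as.integer(seed)),
    class = "cohort_config")
}

check_corr_matrix <- function(m, n_roi, what = "base_corr") {
  if (!is.matrix(m) || nrow(m) != n_roi || ncol(m) != n_roi)
    abort(sprintf("`%s` must be a %d x %d matrix", what, n_roi, n_roi))
  if (max(abs(m - t(m))) > 1e-10)
    abort(sprintf("`%s` must be symmetric", what))
  if (max(abs(diag(m) - 1)) > 1e-10)
    abort(sprintf("`%s` must have unit diagonal", what))
  ev <- min(eigen(m, symmetric = TRUE, only.values = TRUE)$values)
  if (ev <= 1e-10)
    abort(sprintf("`%s` is not positive definite (smallest eigenvalue %.3g)",
                  what, ev))
  invisible(ev)
}

normalize_effects <- function(effects, n_roi) {
  if (is.null(effects) || nrow(as.data.frame(effects)) == 0) {
    return(tibble(roi = integer(), modality = character(), d = double(),
                  partner = integer(), delta = double()))
  }
  eff <- as_tibble(as.data.frame(effects))
  if (!all(c("roi", "modality") %in% names(eff)))
    abort("`effects` needs columns `roi` and `modality`")
  if (!"d" %in% names(eff)) eff$d <- NA_real_
  if (!"partner" %in% names(eff)) eff$partner <- NA_integer_
  if (!"delta" %in% names(eff)) eff$delta <- NA_real_
  bad <- setdiff(unique(eff$modality), effect_modalities)
  if (length(bad))
    abort(sprintf("unknown effect modality %s; valid names are: %s",
                  paste(sQuote(bad), collapse = ", "),
                  paste(effect_modalities, collapse = ", ")))
  stopifnot(all(eff$roi >= 1), all(eff$roi <= n_roi))
  is_fc <- eff$modality == "fc"
  if (any(is_fc)) {
    stopifnot(all(is.finite(eff$delta[is_fc])),
              all(eff$partner[is_fc] >= 1), all(eff$partner[is_fc] <= n_roi),
              all(eff$partner[is_fc] != eff$roi[is_fc]))
  }
  if (any(!is_fc) && !all(is.finite(eff$d[!is_fc])))
    abort("scalar effects need a finite effect size `d`")
  eff$roi <- as.integer(eff$roi)
  eff$partner <- as.integer(eff$partner)
  eff
}

#' Draw an ROI x time BOLD-like series with a target correlation structure
#'
#' Colors i.i.d. standard-normal innovations with the Cholesky factor of
#' `target_corr`, so ROI rows have the stated pairwise population correlation
#' and draws are independent across time (no temporal autocorrelation is
#' modelled).
#'
#' @param target_corr Positive-definite ROI x ROI correlation matrix.
#' @param n_timepoints Number of time points (>= 2).
#' @param seed Optional integer seed; if `NULL`, the current RNG stream is
#'   used.
#' @return A `n_roi` x `n_timepoints` numeric matrix.
#' @export
#' @examples
#' x <- generate_roi_timeseries(constant_corr(5, 0.3), 100, seed = 1)
generate_roi_timeseries <- function(target_corr, n_timepoints, seed = NULL) {
  stopifnot(n_timepoints >= 2)
  check_corr_matrix(target_corr, nrow(target_corr), what = "target_corr")
  if (!is.null(seed)) set.seed(seed)
  l <- t(chol(target_corr))
  z <- matrix(rnorm(nrow(target_corr) * n_timepoints),
              nrow = nrow(target_corr))
  unname(l %*% z)
}

subject_seed <- function(seed, idx) {
  as.integer((as.double(seed) %% 2147483647 * 48271 + idx * 9973) %% 2147483647)
}

#' Generate a synthetic two-group multimodal cohort
#'
#' Simulates per-subject ROI time series (Cholesky-colored Gaussian
#' innovations) and per-ROI scalar modalities (Gaussian, with group-2 means
#' shifted by `d` pooled SDs at affected ROIs). Functional-connectivity
#' effects are applied as edits to group 2's target correlation matrix, so the
#' Fisher-z feature pipeline is exercised end to end; the edited matrix must
#' remain positive definite or the generator rejects the configuration.
#'
#' @param config A [cohort_config()].
#' @return A list with components `cohort` (class `multimodal_cohort`: `ts`, a
#'   named list of ROI x time matrices; `scalars`, a long tibble with columns
#'   `subject`, `roi`, `modality`, `value`; `labels`, a tibble with `subject`
#'   and a two-level `group` factor) and `truth` (tibble of the injected
#'   effects, with the affected ROI set as attribute `affected_rois`).
#' @export
#' @examples
#' out <- generate_cohort(cohort_config(10, n_roi = 8, n_timepoints = 40))
#' out$truth
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  eff <- config$effects
  corr <- list(config$base_corr, config$base_corr)
  fc <- eff[eff$modality == "fc", , drop = FALSE]
  if (nrow(fc)) {
    c2 <- corr[[2]]
    for (i in seq_len(nrow(fc))) {
      a <- fc$roi[i]; b <- fc$partner[i]
      c2[a, b] <- c2[a, b] + fc$delta[i]
      c2[b, a] <- c2[a, b]
      if (abs(c2[a, b]) >= 1) {
        abort(sprintf(
          "fc delta at ROI pair (%d, %d) drives |correlation| to %.3f >= 1",
          a, b, abs(c2[a, b])))
      }
    }
    check_corr_matrix(c2, config$n_roi, what = "group-2 target correlation")
    corr[[2]] <- c2
  }

  n <- config$n_per_group
  n_roi <- config$n_roi
  subjects <- sprintf("S%03d", seq_len(2L * n))
  group <- factor(rep(c("control", "patient"), each = n),
                  levels = c("control", "patient"))

  shift <- matrix(0, n_roi, length(scalar_modalities),
                  dimnames = list(NULL, scalar_modalities))
  sc <- eff[eff$modality != "fc", , drop = FALSE]
  for (i in seq_len(nrow(sc))) {
    shift[sc$roi[i], sc$modality[i]] <-
      shift[sc$roi[i], sc$modality[i]] +
      sc$d[i] * config$scalar_sds[[sc$modality[i]]]
  }

  ts <- vector("list", length(subjects))
  names(ts) <- subjects
  scalar_vals <- vector("list", length(subjects))
  for (j in seq_along(subjects)) {
    g <- if (j <= n) 1L else 2L
    set.seed(subject_seed(config$seed, j))
    ts[[j]] <- generate_roi_timeseries(corr[[g]], config$n_timepoints)
    vals <- vapply(scalar_modalities, function(mod) {
      x <- config$scalar_means[[mod]] +
        config$scalar_sds[[mod]] * rnorm(n_roi)
      if (g == 2L) x <- x + shift[, mod]
      x
    }, numeric(n_roi))
    scalar_vals[[j]] <- tibble(
      subject = subjects[j],
      roi = rep(seq_len(n_roi), times = length(scalar_modalities)),
      modality = rep(scalar_modalities, each = n_roi),
      value = as.vector(vals))
  }

  cohort <- structure(
    list(ts = ts,
         scalars = dplyr::bind_rows(scalar_vals),
         labels = tibble(subject = subjects, group = group),
         n_roi = n_roi),
    class = "multimodal_cohort")

  truth <- eff
  truth$magnitude <- ifelse(truth$modality == "fc", truth$delta, truth$d)
  attr(truth, "affected_rois") <- sort(unique(truth$roi))
  list(cohort = cohort, truth = truth)
}

#' @export
print.multimodal_cohort <- function(x, ...) {
  cat(sprintf(
    "<multimodal_cohort> %d subjects (%s), %d ROIs, %d timepoints\n",
    length(x$ts),
    paste(sprintf("%d %s", table(x$labels$group),
                  levels(x$labels$group)), collapse = " / "),
    x$n_roi, ncol(x$ts[[1]])))
  invisible(x)
}
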