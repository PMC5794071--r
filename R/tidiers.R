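#' Tidy per-repeat metrics of a cross-validation report
#'
#' @param x A `cv_report` from [nested_cv()].
#' @param ... Unused.
#' @return Tibble of per-repeat accuracy, sensitivity and specificity.
#' @exportS3Method generics::tidy
#' @export
tidy.cv_report <- function(x, ...) x$per_repeat

#' One-row summary of a cross-validation report
#'
#' @param x A `cv_report`.
#' @param ... Unused.
#' @return A one-row tibble: mean/sd accuracy, sensitivity, specificity, AUC,
#'   repeats, folds, and the permutation p-value if attached.
#' @exportS3Method generics::glance
#' @export
glance.cv_report <- function(x, ...) {
  tibble(accuracy = x$accuracy, accuracy_sd = x$accuracy_sd,
         sensitivity = x$sensitivity, specificity = x$specificity,
         auc = x$auc, n_repeats = x$config$n_repeats,
         n_folds = x$config$n_folds,
         permutation_p = x$permutation_p %||% NA_real_)
}

#' Tidy logistic-fit coefficients
#'
#' @param x A `logistic_fit`.
#' @param ... Unused.
#' @return Tibble with columns `term`, `estimate`.
#' @exportS3Method generics::tidy
#' @export
tidy.logistic_fit <- function(x, ...) {
  tibble(term = names(x$coef), estimate = unname(x$coef))
}

#' One-row summary of a logistic fit
#'
#' @param x A `logistic_fit`.
#' @param ... Unused.
#' @return Tibble with log-likelihoods, Cox-Snell R-squared, n, ridge and
#'   convergence flag.
#' @exportS3Method generics::glance
#' @export
glance.logistic_fit <- function(x, ...) {
  tibble(loglik = x$loglik, null_loglik = x$null_loglik,
         r2_cox_snell = cox_snell_r2(x), n = x$n, ridge = x$ridge,
         converged = x$converged, iterations = x$iterations)
}
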