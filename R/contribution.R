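#' Fit a (ridge-penalized) logistic regression by Newton iteration
#'
#' Maximum-likelihood Bernoulli-logit fit with an optional quadratic penalty
#' `ridge/2 * ||beta||^2` on the non-intercept coefficients, iterated until
#' the gradient norm falls below `tol`. Ridge keeps the fit finite under
#' quasi-complete separation, which is a real risk at the 94-feature fusion
#' width; at `ridge = 0`, separation is detected and reported as an error
#' rather than returning diverged coefficients.
#'
#' @param x Numeric matrix, subjects x features.
#' @param y Binary labels: 0/1 numeric, logical, or a two-level factor (second
#'   level = 1).
#' @param ridge Penalty >= 0 (default 0).
#' @param tol Convergence tolerance on the gradient max-norm.
#' @param max_iter Iteration cap.
#' @return A `logistic_fit` object: `coef` (named, intercept first), `fitted`
#'   probabilities, `loglik`, `null_loglik` (intercept-only fit on the same
#'   subjects), `n`, `ridge`, `converged`, `iterations`.
#' @export
#' @examples
#' x <- matrix(rnorm(60), 30, 2)
#' y <- rbinom(30, 1, plogis(x[, 1]))
#' fit_logistic(x, y)$coef
fit_logistic <- function(x, y, ridge = 0, tol = 1e-8, max_iter = 100) {
  x <- as.matrix(x)
  if (is.character(y)) y <- as.factor(y)
  if (is.factor(y)) y <- as.integer(droplevels(y)) - 1L
  y <- as.numeric(y)
  stopifnot(all(y %in% c(0, 1)), nrow(x) == length(y), ridge >= 0)
  if (length(unique(y)) < 2) abort("both classes must be present")
  n <- length(y)
  log1pexp <- function(eta) ifelse(eta > 30, eta, log1p(exp(pmin(eta, 30))))
  X <- cbind(`(Intercept)` = 1,
             x[, , drop = FALSE])
  if (is.null(colnames(x))) colnames(X)[-1] <- paste0("x", seq_len(ncol(x)))
  p <- ncol(X)
  pen <- c(0, rep(ridge, p - 1))
  beta <- rep(0, p)
  beta[1] <- stats::qlogis(mean(pmin(pmax(y, 1e-3), 1 - 1e-3)))
  loglik_at <- function(b) {
    eta <- drop(X %*% b)
    sum(y * eta - log1pexp(eta)) - sum(pen * b^2) / 2
  }
  converged <- FALSE
  iter <- 0
  ll <- loglik_at(beta)
  while (iter < max_iter) {
    iter <- iter + 1
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    grad <- drop(crossprod(X, y - mu)) - pen * beta
    if (max(abs(grad)) < tol) { converged <- TRUE; break }
    w <- mu * (1 - mu)
    H <- crossprod(X * w, X) + diag(pen + 1e-12, p)
    step <- tryCatch(solve(H, grad), error = function(e) NULL)
    if (is.null(step))
      abort("singular Hessian in the logistic fit; consider `ridge > 0`")
    # backtracking so a full Newton step never decreases the objective
    s <- 1
    repeat {
      cand <- beta + s * step
      ll_new <- loglik_at(cand)
      if (ll_new >= ll - 1e-12 || s < 1e-8) break
      s <- s / 2
    }
    beta <- cand
    ll <- ll_new
  }
  eta <- drop(X %*% beta)
  separated <- ridge == 0 && length(beta) > 1 &&
    all((2 * y - 1) * eta > 0) && max(abs(eta)) > 15
  if (separated)
    abort(paste("apparent (quasi-)separation: coefficients diverging;",
                "refit with `ridge > 0`"))
  if (!converged)
    abort(sprintf("logistic fit did not converge in %d iterations", max_iter))
  p0 <- mean(y)
  null_ll <- n * (p0 * log(p0) + (1 - p0) * log(1 - p0))
  structure(list(
    coef = setNames(beta, colnames(X)),
    fitted = stats::plogis(eta),
    loglik = sum(y * eta - log1pexp(eta)),
    null_loglik = null_ll,
    n = n, ridge = ridge, converged = converged, iterations = iter),
    class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf(
    "<logistic_fit> n = %d, %d coefficient(s), ridge = %g, loglik = %.4f\n",
    x$n, length(x$coef), x$ridge, x$loglik))
  invisible(x)
}

#' Cox-Snell R-squared of a logistic fit
#'
#' `R^2 = 1 - exp(2 * (l0 - l1) / n)`, the likelihood-ratio goodness-of-fit
#' index bounded above by `1 - exp(2 * l0 / n) < 1`. `l0` is the intercept-only
#' log-likelihood on the same subjects; `l1` the fitted model's.
#'
#' @param fit A `logistic_fit`.
#' @return R-squared in `[0, 1)`.
#' @export
cox_snell_r2 <- function(fit) {
  stopifnot(inherits(fit, "logistic_fit"))
  if (fit$loglik < fit$null_loglik - 1e-6)
    abort("model log-likelihood below the null model's: failed optimization")
  max(0, 1 - exp(2 * (fit$null_loglik - fit$loglik) / fit$n))
}

#' Modality contributions to the fusion feature set
#'
#' Fits four logistic models — one on the fusion design and one per modality
#' block, all on identical subjects — and reports each modality's Cox-Snell
#' R-squared together with its contribution ratio
#' `R2_modality / R2_fusion`. Accepts either a `fusion_features` object
#' (blocks pooled across all ROIs via [measure_design()]) or a named list of
#' design matrices.
#'
#' @param x A `fusion_features` object, or a named list of subjects x features
#'   matrices (one per modality; the fusion design is their column-bind).
#' @param y Binary labels aligned to the design rows (tibble with
#'   `subject`/`group` columns also accepted for `fusion_features` input).
#' @param ridge Ridge penalty passed to every fit; the default `1e-4` tames
#'   separation at fusion width, `0` gives plain maximum likelihood.
#' @return A `contribution_result` tibble with columns `model`, `r2`, `ratio`
#'   (`NA` ratio for the fusion row; all ratios `NA` when `R2_fusion = 0`,
#'   reported with a warning).
#' @export
contribution_ratios <- function(x, y, ridge = 1e-4) {
  if (inherits(x, "fusion_features")) {
    if (is.data.frame(y)) y <- y$group[match(x$subjects, y$subject)]
    blocks <- intersect(c("fmri", "smri", "dti"), unique(x$blocks))
    designs <- lapply(setNames(blocks, blocks),
                      function(b) measure_design(x, b))
  } else {
    stopifnot(is.list(x), !is.null(names(x)))
    designs <- lapply(x, as.matrix)
    ns <- vapply(designs, nrow, integer(1))
    stopifnot(all(ns == ns[1]))
  }
  fusion <- do.call(cbind, designs)
  fits <- c(list(fusion = fit_logistic(fusion, y, ridge = ridge)),
            lapply(designs, fit_logistic, y = y, ridge = ridge))
  r2 <- vapply(fits, cox_snell_r2, numeric(1))
  if (r2[["fusion"]] == 0) {
    warn("fusion model has R^2 = 0: contribution ratios undefined")
    ratio <- rep(NA_real_, length(r2))
  } else {
    ratio <- r2 / r2[["fusion"]]
    ratio[1] <- NA_real_
  }
  out <- tibble(model = names(fits), r2 = unname(r2), ratio = unname(ratio))
  attr(out, "fits") <- fits
  class(out) <- c("contribution_result", class(out))
  out
}
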