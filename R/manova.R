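#' Within-, between- and total dispersion matrices
#'
#' Computes the three m x m dispersion matrices of a grouped multivariate
#' sample: W sums squared deviations about group means, B sums group-size
#' weighted squared deviations of group means about the grand mean, and
#' T = W + B sums squared deviations about the grand mean.
#'
#' @param x Numeric matrix, observations x variables.
#' @param groups Factor (or coercible) of group membership, one per row.
#' @return A list with components `W`, `B`, `T` and the sample sizes `n`,
#'   `n_g`, `G`, `m`.
#' @export
#' @examples
#' x <- matrix(rnorm(30), 15, 2)
#' d <- dispersion_matrices(x, rep(c("a", "b"), c(7, 8)))
#' max(abs(d$T - (d$W + d$B)))
dispersion_matrices <- function(x, groups) {
  x <- as.matrix(x)
  if (ncol(x) == 0) abort("at least one variable is required")
  groups <- droplevels(as.factor(groups))
  stopifnot(nrow(x) == length(groups))
  n_g <- table(groups)
  if (any(n_g < 2)) abort("every group needs at least 2 observations")
  n <- nrow(x); m <- ncol(x); G <- nlevels(groups)
  grand <- colMeans(x)
  W <- matrix(0, m, m)
  B <- matrix(0, m, m)
  for (g in levels(groups)) {
    xg <- x[groups == g, , drop = FALSE]
    mu_g <- colMeans(xg)
    cg <- sweep(xg, 2, mu_g)
    W <- W + crossprod(cg)
    dg <- mu_g - grand
    B <- B + nrow(xg) * tcrossprod(dg)
  }
  Tm <- crossprod(sweep(x, 2, grand))
  list(W = W, B = B, T = Tm, n = n, n_g = as.integer(n_g), G = G, m = m)
}

logdet_psd <- function(m) {
  d <- determinant(m, logarithm = TRUE)
  if (d$sign <= 0) return(-Inf)
  as.numeric(d$modulus)
}

#' Wilk's lambda statistic
#'
#' `lambda = det(W) / det(T)`, evaluated through log-determinants for
#' numerical stability; values near 0 indicate strong group separation and
#' `lambda = 1` indicates none. If `T` is singular (e.g. more variables than
#' error degrees of freedom), the statistic is undefined and an error is
#' raised; `ridge = TRUE` adds `eps * trace(T)/m` to both diagonals as a
#' diagnostic fallback.
#'
#' @param d Dispersion matrices from [dispersion_matrices()].
#' @param ridge Apply ridge regularization to `W` and `T` (off by default).
#' @param eps Relative ridge magnitude.
#' @return The scalar lambda in `(0, 1]`.
#' @export
wilks_lambda <- function(d, ridge = FALSE, eps = 1e-8) {
  W <- d$W; Tm <- d$T
  if (ridge) {
    pen <- eps * sum(diag(Tm)) / ncol(Tm)
    W <- W + diag(pen, ncol(W))
    Tm <- Tm + diag(pen, ncol(Tm))
  } else {
    if (d$n - d$G < d$m)
      abort(paste("within-group dispersion matrix is singular (n - G < m);",
                  "reduce the variable set or use `ridge = TRUE`"))
    evT <- eigen(Tm, symmetric = TRUE, only.values = TRUE)$values
    if (min(evT) <= 1e-10 * max(evT))
      abort(paste("total dispersion matrix is singular;",
                  "reduce the variable set or use `ridge = TRUE`"))
  }
  lt <- logdet_psd(Tm)
  if (!is.finite(lt))
    abort(paste("total dispersion matrix is singular;",
                "reduce the variable set or use `ridge = TRUE`"))
  lw <- logdet_psd(W)
  if (!is.finite(lw))
    abort(paste("within-group dispersion matrix is singular;",
                "reduce the variable set or use `ridge = TRUE`"))
  min(exp(lw - lt), 1)
}

#' Bartlett's chi-square approximation for Wilk's lambda
#'
#' Transforms lambda to `chi2 = -(n - 1 - (G + m)/2) * log(lambda)`, which
#' under equal group means is approximately chi-square with `m * (G - 1)`
#' degrees of freedom for large n.
#'
#' @param lambda Wilk's lambda in `(0, 1]`.
#' @param n Total sample size.
#' @param G Number of groups.
#' @param m Number of variables.
#' @return A tibble with columns `chi2`, `df`, `p`.
#' @export
#' @examples
#' bartlett_chi2_p(exp(-1), n = 101, G = 2, m = 4)
bartlett_chi2_p <- function(lambda, n, G, m) {
  stopifnot(lambda > 0, lambda <= 1 + 1e-12)
  scale <- n - 1 - (G + m) / 2
  if (scale <= 0)
    abort(sprintf(
      "sample too small for Bartlett's approximation (n - 1 - (G + m)/2 = %.1f <= 0)",
      scale))
  chi2 <- -scale * log(min(lambda, 1))
  df <- m * (G - 1)
  tibble(chi2 = chi2, df = df, p = pchisq(chi2, df = df, lower.tail = FALSE))
}

measure_columns <- function(fs, measure) {
  switch(measure,
    fusion = seq_along(fs$blocks),
    fmri = which(fs$blocks == "fmri"),
    smri = which(fs$blocks == "smri"),
    dti = which(fs$blocks == "dti"),
    abort(sprintf("unknown measure set '%s'", measure)))
}

#' Per-ROI Wilk's-lambda screening of fusion features
#'
#' For every ROI and every requested measure set (single-modality blocks or
#' the full fusion vector), tests for a multivariate group mean difference via
#' Wilk's lambda with Bartlett's chi-square approximation. ROIs where a
#' measure set fails its preconditions (singular total dispersion, too few
#' error degrees of freedom) are recorded with `NA` statistics and a reason
#' rather than dropped.
#'
#' @param fs A `fusion_features` object.
#' @param labels Group labels: a factor/vector (one per subject, in
#'   `fs$subjects` order) or a tibble with columns `subject`, `group`.
#' @param measures Measure sets to screen, from
#'   `c("fusion", "fmri", "smri", "dti")`.
#' @return A `roi_screen` tibble with columns `roi`, `measure`, `m`,
#'   `lambda`, `chi2`, `df`, `p`, `neglog10p`, `reason`.
#' @export
screen_rois <- function(fs, labels,
                        measures = c("fusion", "fmri", "smri", "dti")) {
  stopifnot(inherits(fs, "fusion_features"))
  if (is.data.frame(labels)) {
    labels <- labels$group[match(fs$subjects, labels$subject)]
  }
  groups <- droplevels(as.factor(labels))
  if (nlevels(groups) < 2) abort("at least 2 groups are required")
  measures <- match.arg(measures, c("fusion", "fmri", "smri", "dti"),
                        several.ok = TRUE)
  present <- unique(fs$blocks)
  n <- length(fs$subjects)
  G <- nlevels(groups)
  res <- purrr::map_dfr(measures, function(ms) {
    if (ms != "fusion" && !ms %in% present)
      abort(sprintf("measure set '%s' not present in the feature set", ms))
    cols <- measure_columns(fs, ms)
    m <- length(cols)
    purrr::map_dfr(seq_len(fs$n_roi), function(i) {
      row <- tibble(roi = i, measure = ms, m = m, lambda = NA_real_,
                    chi2 = NA_real_, df = m * (G - 1), p = NA_real_,
                    neglog10p = NA_real_, reason = NA_character_)
      if (n <= m + G) {
        row$reason <- sprintf("n = %d too small for m = %d, G = %d", n, m, G)
        return(row)
      }
      out <- tryCatch({
        d <- dispersion_matrices(fs$features[[i]][, cols, drop = FALSE],
                                 groups)
        lam <- wilks_lambda(d)
        bt <- bartlett_chi2_p(lam, n, G, m)
        row$lambda <- lam
        row$chi2 <- bt$chi2
        row$p <- bt$p
        row$neglog10p <- -log10(max(bt$p, .Machine$double.xmin))
        row
      }, error = function(e) {
        row$reason <- conditionMessage(e)
        row
      })
      out
    })
  })
  class(res) <- c("roi_screen", class(res))
  res
}

#' Tally which measure set wins each ROI
#'
#' Assigns every ROI to the measure set with the smallest screening p-value
#' and counts ROIs per measure set. Exact ties are broken by the fixed
#' precedence fusion > fmri > smri > dti (with a warning), so tallies are
#' reproducible.
#'
#' @param screen A `roi_screen` tibble from [screen_rois()].
#' @return A tibble with columns `measure`, `n_roi` (counts sum to the number
#'   of ROIs with complete results); the per-ROI winner is attached as
#'   attribute `best`.
#' @export
tally_best_measure <- function(screen) {
  stopifnot(all(c("roi", "measure", "p") %in% names(screen)))
  precedence <- c("fusion", "fmri", "smri", "dti")
  wide <- tidyr::pivot_wider(screen[, c("roi", "measure", "p")],
                             names_from = "measure", values_from = "p")
  pm <- as.matrix(wide[, setdiff(names(wide), "roi"), drop = FALSE])
  keep <- stats::complete.cases(pm)
  if (!all(keep))
    warn(sprintf("%d ROI(s) dropped from the tally (missing p-values)",
                 sum(!keep)))
  pm <- pm[keep, , drop = FALSE]
  ord <- order(match(colnames(pm), precedence))
  pm <- pm[, ord, drop = FALSE]
  ties <- apply(pm, 1, function(p) sum(p == min(p)) > 1)
  if (any(ties))
    warn(sprintf("exact p ties at %d ROI(s); broken by precedence %s",
                 sum(ties), paste(colnames(pm), collapse = " > ")))
  best <- colnames(pm)[apply(pm, 1, which.min)]
  counts <- tibble(measure = colnames(pm),
                   n_roi = as.integer(table(factor(best,
                                                   levels = colnames(pm)))))
  attr(counts, "best") <- tibble(roi = wide$roi[keep], best = best)
  counts
}

#' Pooled-variance two-sample t-test, from raw data or printed summaries
#'
#' Classical equal-variance two-sample t with `df = n1 + n2 - 2` and a
#' two-sided p-value. Each side may be a numeric vector of raw values or a
#' summary `c(mean, sd, n)`, so published demographic tables can be checked
#' directly.
#'
#' @param x1,x2 Numeric vector of raw values, or length-3 numeric
#'   `c(mean, sd, n)`.
#' @return A tibble with columns `t`, `df`, `p`.
#' @export
#' @examples
#' pooled_t_test(c(44.99, 11.5, 161), c(43.17, 10.8, 168))
pooled_t_test <- function(x1, x2) {
  summarize_side <- function(x) {
    if (length(x) == 3 && !is.null(names(x)) &&
        all(c("mean", "sd", "n") %in% names(x))) {
      return(list(mean = x[["mean"]], sd = x[["sd"]], n = x[["n"]]))
    }
    if (length(x) == 3 && is.null(names(x))) {
      return(list(mean = x[1], sd = x[2], n = x[3]))
    }
    list(mean = mean(x), sd = sd(x), n = length(x))
  }
  a <- summarize_side(x1); b <- summarize_side(x2)
  stopifnot(a$n >= 2, b$n >= 2)
  df <- a$n + b$n - 2
  sp2 <- ((a$n - 1) * a$sd^2 + (b$n - 1) * b$sd^2) / df
  if (sp2 == 0) {
    if (a$mean == b$mean) return(tibble(t = 0, df = df, p = 1))
    abort("zero pooled variance with unequal means")
  }
  t <- (a$mean - b$mean) / sqrt(sp2 * (1 / a$n + 1 / b$n))
  tibble(t = t, df = df, p = 2 * pt(-abs(t), df))
}

#' Pearson chi-square test on a 2x2 table
#'
#' Pearson's chi-square without continuity correction on counts
#' `(a, b; c, d)`, with 1 degree of freedom.
#'
#' @param a,b,c,d Nonnegative cell counts (rows = groups, columns =
#'   categories).
#' @return A tibble with columns `chi2`, `df`, `p`.
#' @export
#' @examples
#' pearson_chi2_2x2(66, 95, 72, 96)
pearson_chi2_2x2 <- function(a, b, c, d) {
  tab <- c(a, b, c, d)
  stopifnot(all(tab >= 0))
  n <- sum(tab)
  marg <- c(a + b, c + d, a + c, b + d)
  if (any(marg == 0)) abort("all row and column marginals must be positive")
  chi2 <- n * (a * d - b * c)^2 / prod(marg)
  tibble(chi2 = chi2, df = 1L,
         p = pchisq(chi2, df = 1, lower.tail = FALSE))
}
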