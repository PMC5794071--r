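#' Fisher r-to-z transform with finite-sample clipping
#'
#' `atanh(r)` after clipping `|r|` at `1 - 1e-7`, so perfectly (anti)correlated
#' series yield a large finite z rather than infinity; a warning is emitted
#' when clipping occurs.
#'
#' @param r Numeric vector of correlations in `[-1, 1]`.
#' @return Numeric vector of z values.
#' @export
fisher_z <- function(r) {
  lim <- 1 - 1e-7
  if (any(abs(r) >= lim, na.rm = TRUE))
    warn("|r| >= 1 - 1e-7 clipped before the r-to-z transform")
  atanh(pmin(pmax(r, -lim), lim))
}

#' Functional-connectivity vector of one ROI
#'
#' Pearson correlations between the given ROI's time series and every other
#' ROI's, Fisher r-to-z transformed: the length `n_roi - 1` functional measure
#' of that region.
#'
#' @param ts ROI x time numeric matrix for one subject.
#' @param roi ROI row index.
#' @return Named numeric vector of `n_roi - 1` z-transformed correlations.
#' @export
#' @examples
#' ts <- generate_roi_timeseries(constant_corr(5, 0.2), 100, seed = 1)
#' fc_vector(ts, 2)
fc_vector <- function(ts, roi) {
  stopifnot(is.matrix(ts), roi >= 1, roi <= nrow(ts))
  v <- apply(ts, 1, sd)
  if (any(v == 0))
    abort(sprintf("zero-variance time series at ROI(s): %s",
                  paste(which(v == 0), collapse = ", ")))
  r <- drop(cor(t(ts))[roi, -roi])
  z <- fisher_z(r)
  names(z) <- paste0("fc_roi", setdiff(seq_len(nrow(ts)), roi))
  z
}

#' Diffusion-tensor scalar summaries from eigenvalues
#'
#' Computes fractional anisotropy, radial diffusivity and mean diffusivity
#' from the three tensor eigenvalues: RD = (lambda2 + lambda3)/2,
#' MD = (lambda1 + lambda2 + lambda3)/3, and FA via the standard normalized
#' eigenvalue-dispersion form
#' `sqrt(3/2) * ||lambda - mean(lambda)|| / ||lambda||`, which lies in
#' `[0, 1]`.
#'
#' @param ev Numeric vector of three finite eigenvalues (any order; sorted
#'   descending internally).
#' @return Named numeric vector `c(fa, rd, md)`.
#' @export
#' @examples
#' dti_scalars(c(1.5, 1.0, 0.5) * 1e-3)
dti_scalars <- function(ev) {
  stopifnot(length(ev) == 3, all(is.finite(ev)))
  ev <- sort(ev, decreasing = TRUE)
  nrm <- sqrt(sum(ev^2))
  if (nrm == 0) {
    warn("all-zero eigenvalues: FA defined as 0")
    fa <- 0
  } else {
    fa <- sqrt(3 / 2) * sqrt(sum((ev - mean(ev))^2)) / nrm
  }
  c(fa = fa, rd = (ev[2] + ev[3]) / 2, md = mean(ev))
}

modality_block_features <- function(cohort, modality) {
  n_roi <- cohort$n_roi
  subjects <- cohort$labels$subject
  if (modality == "fmri") {
    zs <- lapply(cohort$ts[subjects], function(ts) {
      v <- apply(ts, 1, sd)
      if (any(v == 0))
        abort(sprintf("zero-variance time series at ROI(s): %s",
                      paste(which(v == 0), collapse = ", ")))
      r <- cor(t(ts))
      diag(r) <- 0   # self-correlations are never used as features
      fisher_z(r)
    })
    lapply(seq_len(n_roi), function(i) {
      m <- t(vapply(zs, function(z) z[i, -i], numeric(n_roi - 1)))
      dimnames(m) <- list(subjects,
                          paste0("fc_roi", setdiff(seq_len(n_roi), i)))
      m
    })
  } else {
    mods <- if (modality == "smri") c("gm", "wm") else c("fa", "rd", "md")
    wide <- tidyr::pivot_wider(
      cohort$scalars[cohort$scalars$modality %in% mods, ],
      names_from = "modality", values_from = "value")
    lapply(seq_len(n_roi), function(i) {
      sub <- wide[wide$roi == i, , drop = FALSE]
      sub <- sub[match(subjects, sub$subject), , drop = FALSE]
      m <- as.matrix(sub[, mods, drop = FALSE])
      rownames(m) <- subjects
      m
    })
  }
}

#' Assemble per-ROI fusion feature matrices from modality blocks
#'
#' Binds per-ROI feature matrices from up to three modality blocks into the
#' multi-index fusion set, in fixed `[fMRI | sMRI | DTI]` column order
#' restricted to the supplied blocks. All blocks must cover the same subjects
#' (matched by row name) and the same ROIs.
#'
#' @param fmri,smri,dti Lists (one element per ROI) of subjects x width
#'   feature matrices with subject row names, or `NULL` to omit the block.
#' @return A `fusion_features` object: per-ROI feature matrices plus a
#'   per-column modality tag.
#' @export
assemble_fusion <- function(fmri = NULL, smri = NULL, dti = NULL) {
  blocks <- list(fmri = fmri, smri = smri, dti = dti)
  blocks <- blocks[!vapply(blocks, is.null, logical(1))]
  if (!length(blocks)) abort("at least one modality block is required")
  n_roi <- length(blocks[[1]])
  stopifnot(all(vapply(blocks, length, integer(1)) == n_roi))
  subj_sets <- lapply(blocks, function(b) rownames(b[[1]]))
  ref <- subj_sets[[1]]
  for (nm in names(subj_sets)[-1]) {
    diff <- c(setdiff(ref, subj_sets[[nm]]), setdiff(subj_sets[[nm]], ref))
    if (length(diff))
      abort(sprintf("subject mismatch between %s and %s blocks: %s",
                    names(blocks)[1], nm, paste(diff, collapse = ", ")))
  }
  tags <- unlist(lapply(names(blocks),
                        function(nm) rep(nm, ncol(blocks[[nm]][[1]]))))
  feats <- lapply(seq_len(n_roi), function(i) {
    do.call(cbind, lapply(blocks, function(b) b[[i]][ref, , drop = FALSE]))
  })
  structure(
    list(features = feats, blocks = tags, subjects = ref,
         n_roi = n_roi, normalized = FALSE, fit_subjects = NULL),
    class = "fusion_features")
}

#' Build the per-ROI multi-index fusion feature set of a cohort
#'
#' For each ROI, concatenates the requested modality blocks into one subjects
#' x features matrix: 89 Fisher-z functional-connectivity coefficients with
#' the other ROIs (fMRI), grey- and white-matter volume (sMRI), and FA/RD/MD
#' (DTI) — 94 features per ROI when all three blocks of a 90-ROI cohort are
#' requested.
#'
#' @param cohort A `multimodal_cohort` (see [generate_cohort()] or
#'   [read_cohort()]).
#' @param blocks Subset of `c("fmri", "smri", "dti")`.
#' @return A `fusion_features` object.
#' @export
#' @examples
#' co <- generate_cohort(cohort_config(8, n_roi = 6, n_timepoints = 40))$cohort
#' fs <- fusion_features(co)
#' dim(fs$features[[1]])
fusion_features <- function(cohort, blocks = c("fmri", "smri", "dti")) {
  stopifnot(inherits(cohort, "multimodal_cohort"))
  blocks <- match.arg(blocks, c("fmri", "smri", "dti"), several.ok = TRUE)
  built <- lapply(setNames(blocks, blocks),
                  function(b) modality_block_features(cohort, b))
  do.call(assemble_fusion, built[intersect(c("fmri", "smri", "dti"), blocks)])
}

#' @export
print.fusion_features <- function(x, ...) {
  cat(sprintf(
    "<fusion_features> %d subjects, %d ROIs, %d features per ROI (%s)%s\n",
    length(x$subjects), x$n_roi, length(x$blocks),
    paste(sprintf("%d %s", table(x$blocks)[unique(x$blocks)],
                  unique(x$blocks)), collapse = " + "),
    if (x$normalized) ", z-normalized" else ""))
  invisible(x)
}

#' Tidy a fusion feature set into a long tibble
#'
#' @param x A `fusion_features` object.
#' @param ... Unused.
#' @return A tibble with columns `subject`, `roi`, `feature`, `block`,
#'   `value`.
#' @exportS3Method generics::tidy
#' @export
tidy.fusion_features <- function(x, ...) {
  purrr::map_dfr(seq_len(x$n_roi), function(i) {
    m <- x$features[[i]]
    tibble(subject = rep(rownames(m), times = ncol(m)),
           roi = i,
           feature = rep(colnames(m), each = nrow(m)),
           block = rep(x$blocks, each = nrow(m)),
           value = as.vector(m))
  })
}

resolve_subjects <- function(fs, fit_on) {
  if (is.null(fit_on)) return(fs$subjects)
  if (is.numeric(fit_on)) fit_on <- fs$subjects[fit_on]
  missing <- setdiff(fit_on, fs$subjects)
  if (length(missing))
    abort(sprintf("unknown subjects in `fit_on`: %s",
                  paste(missing, collapse = ", ")))
  fit_on
}

#' Z-score normalize fusion features
#'
#' Centers and scales every feature column to mean 0 and SD 1 on the `fit_on`
#' subjects; the learned transform is applied unchanged to all remaining
#' subjects (so test folds keep their offsets). With the default
#' `fit_on = NULL`, all subjects are used, mirroring a single global
#' normalization.
#'
#' @param fs A `fusion_features` object.
#' @param fit_on Character vector of subject ids (or integer indices) to fit
#'   the normalizer on; `NULL` for all subjects.
#' @return The normalized `fusion_features` object.
#' @export
zscore_normalize <- function(fs, fit_on = NULL) {
  stopifnot(inherits(fs, "fusion_features"))
  fit <- resolve_subjects(fs, fit_on)
  if (!length(fit)) abort("`fit_on` must be nonempty")
  fs$features <- lapply(seq_len(fs$n_roi), function(i) {
    m <- fs$features[[i]]
    mu <- colMeans(m[fit, , drop = FALSE])
    sig <- apply(m[fit, , drop = FALSE], 2, sd)
    if (any(sig == 0))
      abort(sprintf("zero-SD feature column(s) at ROI %d: %s", i,
                    paste(colnames(m)[sig == 0], collapse = ", ")))
    scale(m, center = mu, scale = sig)[, , drop = FALSE]
  })
  fs$normalized <- TRUE
  fs$fit_subjects <- fit
  fs
}

#' Replace the fMRI block by its leading principal components
#'
#' Fits a per-ROI PCA on the functional-connectivity block (on the `fit_on`
#' subjects) and replaces the block by the first `k` component scores,
#' reducing a 94-wide fusion vector to `k + 5` columns. Scores for subjects
#' outside `fit_on` are projections onto the fitted axes.
#'
#' @param fs A `fusion_features` object containing an fMRI block.
#' @param k Number of components to keep (default 5).
#' @param fit_on Subjects used to fit the rotation; `NULL` for all.
#' @return A list: `features` (the reduced `fusion_features`) and `explained`
#'   (tibble with per-ROI per-component variance fractions and the cumulative
#'   fraction at `k`).
#' @export
pca_reduce_fmri_block <- function(fs, k = 5, fit_on = NULL) {
  stopifnot(inherits(fs, "fusion_features"))
  idx <- which(fs$blocks == "fmri")
  if (!length(idx)) abort("no fMRI block present")
  if (k < 1 || k > length(idx))
    abort(sprintf("`k` must be in 1..%d (fMRI block width)", length(idx)))
  fit <- resolve_subjects(fs, fit_on)
  expl <- vector("list", fs$n_roi)
  for (i in seq_len(fs$n_roi)) {
    m <- fs$features[[i]]
    pc <- prcomp(m[fit, idx, drop = FALSE], center = TRUE, scale. = FALSE)
    if (k > sum(pc$sdev > 1e-12))
      abort(sprintf("`k` = %d exceeds the rank of ROI %d's fMRI block", k, i))
    scores <- predict(pc, m[, idx, drop = FALSE])[, seq_len(k), drop = FALSE]
    colnames(scores) <- paste0("fc_pc", seq_len(k))
    vf <- pc$sdev^2 / sum(pc$sdev^2)
    expl[[i]] <- tibble(roi = i, component = seq_len(k),
                        var_fraction = vf[seq_len(k)],
                        cum_fraction = cumsum(vf)[seq_len(k)])
    fs$features[[i]] <- cbind(scores,
                              m[, -idx, drop = FALSE])
  }
  fs$blocks <- c(rep("fmri", k), fs$blocks[-idx])
  list(features = fs, explained = dplyr::bind_rows(expl))
}

#' Screen fusion features for covariate confounding via canonical correlation
#'
#' For each ROI, computes the maximum canonical correlation between the ROI's
#' fusion features and a single continuous covariate — equal to the multiple
#' correlation of the covariate regressed on the features — with Bartlett's
#' asymptotic chi-square test and Benjamini-Hochberg adjustment across ROIs.
#' Used to check that a nuisance variable (e.g. education) does not drive the
#' fusion features.
#'
#' @param fs A `fusion_features` object.
#' @param covariate Numeric vector, one value per subject (in `fs$subjects`
#'   order, or named by subject).
#' @param alpha FDR level for the significance flag.
#' @return A tibble with columns `roi`, `cancor`, `chi2`, `df`, `p`, `p_adj`,
#'   `significant`.
#' @export
confound_cca_screen <- function(fs, covariate, alpha = 0.05) {
  stopifnot(inherits(fs, "fusion_features"))
  if (!is.null(names(covariate))) covariate <- covariate[fs$subjects]
  stopifnot(length(covariate) == length(fs$subjects),
            all(is.finite(covariate)))
  if (sd(covariate) == 0) abort("`covariate` is constant")
  n <- length(covariate)
  res <- purrr::map_dfr(seq_len(fs$n_roi), function(i) {
    x <- fs$features[[i]]
    m <- ncol(x)
    # suppress lm's perfect-fit chatter; r^2 = 1 is a legitimate outcome here
    r2 <- suppressWarnings(summary(lm(covariate ~ x))$r.squared)
    r2 <- min(r2, 1 - 1e-12)
    chi2 <- -(n - 1 - (m + 2) / 2) * log(1 - r2)
    tibble(roi = i, cancor = sqrt(r2), chi2 = chi2, df = m,
           p = pchisq(chi2, df = m, lower.tail = FALSE))
  })
  res$p_adj <- stats::p.adjust(res$p, method = "BH")
  res$significant <- res$p_adj < alpha
  res
}

#' AAL 90-region names
#'
#' The standard automated-anatomical-labeling parcellation order used for ROI
#' indexing throughout the package (1-based, left/right interleaved).
#'
#' @return A tibble with columns `roi`, `name`.
#' @export
aal_rois <- function() {
  readr::read_tsv(system.file("extdata", "aal90_rois.tsv",
                              package = "roifuse"),
                  show_col_types = FALSE)
}
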