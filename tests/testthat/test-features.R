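test_that("fc vectors are Fisher-z Pearson correlations with the expected layout", {
  ts <- generate_roi_timeseries(constant_corr(6, 0.2), 80, seed = 1)
  v <- fc_vector(ts, 3)
  expect_length(v, 5)
  # direct oracle: atanh of the plain correlations
  expect_equal(unname(v), atanh(cor(t(ts))[3, -3]), tolerance = 1e-12)
  # symmetry: the (i,j) entry appears identically in both ROIs' vectors
  expect_equal(fc_vector(ts, 1)[["fc_roi4"]], fc_vector(ts, 4)[["fc_roi1"]])
  # invariance to affine rescaling of one ROI's series
  ts2 <- ts; ts2[2, ] <- 5 * ts2[2, ] + 3
  expect_equal(fc_vector(ts2, 1), fc_vector(ts, 1), tolerance = 1e-12)
})

test_that("fisher z is the closed-form atanh, clipped near |r| = 1", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), log(3) / 2)
  expect_true(all(diff(fisher_z(seq(-0.99, 0.99, by = 0.01))) > 0))
  expect_warning(z <- fisher_z(1), "clipped")
  expect_true(is.finite(z))
  ts <- matrix(rnorm(20), 2)
  ts[2, ] <- 1   # constant series
  expect_error(fc_vector(ts, 1), "zero-variance")
})

test_that("DTI scalar summaries match their closed forms", {
  iso <- dti_scalars(c(2, 2, 2))
  expect_equal(unname(iso), c(0, 2, 2))
  lim <- dti_scalars(c(1, 0, 0))
  expect_equal(unname(lim), c(1, 0, 1 / 3))
  ev <- c(1.5, 1.0, 0.5) * 1e-3
  got <- dti_scalars(ev)
  # brute-force evaluation of the normalized dispersion FA formula
  fa_direct <- sqrt(3 / 2) * sqrt(sum((ev - mean(ev))^2)) / sqrt(sum(ev^2))
  expect_equal(got[["fa"]], fa_direct, tolerance = 1e-12)
  expect_equal(got[["rd"]], 0.75e-3)
  expect_equal(got[["md"]], 1.0e-3)
  expect_true(got[["fa"]] >= 0 && got[["fa"]] <= 1)
  expect_warning(z <- dti_scalars(c(0, 0, 0)), "FA defined as 0")
  expect_equal(z[["fa"]], 0)
})

test_that("fusion assembly produces the documented widths and block tags", {
  out <- tiny_cohort(n_per_group = 3, n_roi = 90, n_timepoints = 40, seed = 5)
  fs <- fusion_features(out$cohort)
  expect_equal(ncol(fs$features[[1]]), 94)
  expect_equal(as.vector(table(fs$blocks)[c("fmri", "smri", "dti")]),
               c(89, 2, 3))
  sd_only <- fusion_features(out$cohort, blocks = c("smri", "dti"))
  expect_equal(ncol(sd_only$features[[1]]), 5)
  expect_equal(sd_only$blocks, c("smri", "smri", "dti", "dti", "dti"))
})

test_that("assembly rejects subject mismatches, listing the difference", {
  out <- tiny_cohort(n_per_group = 3, seed = 5)
  a <- fusion_features(out$cohort, "smri")
  b <- fusion_features(out$cohort, "dti")
  smri <- lapply(a$features, identity)
  dti <- lapply(b$features, function(m) {
    rownames(m)[1] <- "SX99"
    m
  })
  expect_error(assemble_fusion(smri = smri, dti = dti), "SX99")
})

test_that("z-normalization fits on the designated subjects only", {
  out <- tiny_cohort(n_per_group = 10, seed = 6)
  fs <- fusion_features(out$cohort)
  fit <- fs$subjects[1:10]
  norm <- zscore_normalize(fs, fit_on = fit)
  m <- norm$features[[2]]
  expect_lt(max(abs(colMeans(m[fit, ]))), 1e-8)
  expect_lt(max(abs(apply(m[fit, ], 2, sd) - 1)), 1e-8)
  # held-out subjects keep their offsets
  expect_gt(max(abs(colMeans(m[setdiff(fs$subjects, fit), ]))), 1e-4)
  # full-cohort fit: every column standardized
  all_norm <- zscore_normalize(fs)
  expect_lt(max(abs(colMeans(all_norm$features[[1]]))), 1e-8)

  # constant column is an error naming the column
  fs2 <- fs
  fs2$features[[1]][, "gm"] <- 1
  expect_error(zscore_normalize(fs2), "gm")
})

test_that("normalization preserves subject order and block tags", {
  out <- tiny_cohort(n_per_group = 5, seed = 8)
  fs <- fusion_features(out$cohort)
  norm <- zscore_normalize(fs)
  expect_identical(norm$subjects, fs$subjects)
  expect_identical(norm$blocks, fs$blocks)
  expect_identical(rownames(norm$features[[3]]), rownames(fs$features[[3]]))
})

test_that("PCA reduction of the fMRI block matches an eigendecomposition oracle", {
  out <- tiny_cohort(n_per_group = 15, seed = 10)
  fs <- zscore_normalize(fusion_features(out$cohort))
  red <- pca_reduce_fmri_block(fs, k = 3)
  expect_equal(ncol(red$features$features[[1]]), 3 + 5)
  expect_equal(red$features$blocks,
               c(rep("fmri", 3), "smri", "smri", "dti", "dti", "dti"))

  # oracle: eigendecomposition of the covariance of the fMRI columns
  idx <- which(fs$blocks == "fmri")
  x <- fs$features[[4]][, idx]
  xc <- scale(x, center = TRUE, scale = FALSE)
  eig <- eigen(crossprod(xc) / (nrow(xc) - 1), symmetric = TRUE)
  oracle <- xc %*% eig$vectors[, 1:3]
  got <- red$features$features[[4]][, 1:3]
  for (j in 1:3) {
    expect_lt(min(max(abs(got[, j] - oracle[, j])),
                  max(abs(got[, j] + oracle[, j]))), 1e-8)
  }

  # explained fraction: monotone in k, 1 at full rank / exact low rank
  expect_true(all(red$explained$var_fraction >= 0))
  expect_true(all(diff(red$explained$cum_fraction[red$explained$roi == 1]) >= 0))
  full <- pca_reduce_fmri_block(fs, k = length(idx))
  expect_equal(max(full$explained$cum_fraction[full$explained$roi == 1]), 1)
})

test_that("PCA reduction detects rank and rejects excessive k", {
  out <- tiny_cohort(n_per_group = 4, seed = 12)   # 8 subjects, rank <= 7
  fs <- fusion_features(out$cohort)
  expect_error(pca_reduce_fmri_block(fs, k = 99), "block width")
  # data lying in a 2-dimensional subspace: 2 components explain everything
  fs2 <- fusion_features(tiny_cohort(n_per_group = 10, seed = 13)$cohort)
  idx <- which(fs2$blocks == "fmri")
  basis <- matrix(rnorm(2 * length(idx)), 2)
  fs2$features[[1]][, idx] <- matrix(rnorm(20 * 2), 20) %*% basis
  red <- pca_reduce_fmri_block(fs2, k = 2)
  expect_equal(red$explained$cum_fraction[red$explained$roi == 1][2], 1,
               tolerance = 1e-10)
})

test_that("covariate CCA screen reduces to known special cases", {
  out <- tiny_cohort(n_per_group = 20, seed = 14)
  fs <- fusion_features(out$cohort, blocks = c("smri", "dti"))
  # covariate equal to one feature column: canonical correlation 1
  cov1 <- fs$features[[2]][, "fa"]
  sc <- confound_cca_screen(fs, cov1)
  expect_gt(sc$cancor[sc$roi == 2], 1 - 1e-6)
  # single-feature ROI: canonical correlation equals |Pearson r|
  fs1 <- fs
  fs1$features <- lapply(fs1$features, function(m) m[, "gm", drop = FALSE])
  fs1$blocks <- "smri"
  cov2 <- withr::with_seed(1, rnorm(length(fs$subjects)))
  sc1 <- confound_cca_screen(fs1, cov2)
  expect_equal(sc1$cancor[1],
               abs(cor(cov2, fs1$features[[1]][, 1])), tolerance = 1e-10)
  expect_error(confound_cca_screen(fs, rep(1, length(fs$subjects))),
               "constant")
})

test_that("covariate screen stays near its nominal false-positive rate under the null", {
  # global null: BH controls the familywise rate at alpha, so replicates with
  # any flagged ROI should be rare
  hits <- vapply(1:30, function(r) {
    out <- tiny_cohort(n_per_group = 15, n_roi = 5, n_timepoints = 30,
                       seed = 100 + r)
    fs <- fusion_features(out$cohort, blocks = c("smri", "dti"))
    cov <- withr::with_seed(999 + r, rnorm(30))
    any(confound_cca_screen(fs, cov)$significant)
  }, logical(1))
  expect_lte(sum(hits), 6)   # Binom(30, 0.05): P(> 6) < 1e-3
})

test_that("the AAL region table has the expected shape", {
  rois <- aal_rois()
  expect_equal(nrow(rois), 90)
  expect_equal(rois$roi, 1:90)
  expect_true(all(grepl("_(L|R)$", rois$name)))
})
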