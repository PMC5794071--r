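# Small seeded fixtures shared across test files.

tiny_cohort <- function(n_per_group = 10, n_roi = 6, n_timepoints = 50,
                        effects = NULL, seed = 42, rho = 0.1) {
  generate_cohort(cohort_config(n_per_group, n_roi = n_roi,
                                n_timepoints = n_timepoints,
                                effects = effects, rho = rho, seed = seed))
}

# Two-class Gaussian design matrix with a mean shift of `d` (Mahalanobis,
# spread equally over the columns) between the classes.
gaussian_classes <- function(n_per_class, m, d, seed = 1) {
  withr::with_seed(seed, {
    shift <- d / sqrt(m)
    x <- rbind(matrix(rnorm(n_per_class * m), n_per_class),
               matrix(rnorm(n_per_class * m, mean = shift), n_per_class))
    rownames(x) <- sprintf("S%03d", seq_len(2 * n_per_class))
    list(x = x, y = factor(rep(c("control", "patient"), each = n_per_class)))
  })
}
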