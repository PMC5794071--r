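#' Write a multimodal cohort to a directory of plain-text files
#'
#' Layout: `ts/<subject>.csv` (one per subject; first column `roi`, remaining
#' columns `t1..tT`), `<modality>.csv` for each scalar modality (subjects x
#' ROIs, columns `roi<index>_<modality>`), `labels.csv`, and optionally
#' `ground_truth.json`.
#'
#' @param cohort A `multimodal_cohort`.
#' @param dir Output directory (created if needed).
#' @param truth Optional ground-truth tibble from [generate_cohort()].
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, truth = NULL) {
  stopifnot(inherits(cohort, "multimodal_cohort"))
  dir.create(file.path(dir, "ts"), recursive = TRUE, showWarnings = FALSE)
  for (s in names(cohort$ts)) {
    m <- cohort$ts[[s]]
    df <- data.frame(roi = seq_len(nrow(m)), m)
    names(df)[-1] <- paste0("t", seq_len(ncol(m)))
    readr::write_csv(df, file.path(dir, "ts", paste0(s, ".csv")))
  }
  for (mod in unique(cohort$scalars$modality)) {
    sub <- cohort$scalars[cohort$scalars$modality == mod, ]
    wide <- tidyr::pivot_wider(sub[, c("subject", "roi", "value")],
                               names_from = "roi", values_from = "value",
                               names_prefix = "roi")
    names(wide)[-1] <- paste0(names(wide)[-1], "_", mod)
    readr::write_csv(wide, file.path(dir, paste0(mod, ".csv")))
  }
  readr::write_csv(cohort$labels, file.path(dir, "labels.csv"))
  if (!is.null(truth)) {
    jsonlite::write_json(
      list(effects = truth,
           affected_rois = attr(truth, "affected_rois") %||% integer()),
      file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' Read a multimodal cohort from the documented directory layout
#'
#' Inverse of [write_cohort()]. Subjects are aligned across modalities by
#' identifier; inconsistent subject sets, non-binary label files and ROI-count
#' mismatches are rejected with informative errors.
#'
#' @param dir Directory written by [write_cohort()] (or hand-assembled in the
#'   same layout).
#' @return A `multimodal_cohort`.
#' @export
read_cohort <- function(dir) {
  labels <- readr::read_csv(file.path(dir, "labels.csv"),
                            show_col_types = FALSE)
  if (!all(c("subject", "group") %in% names(labels)))
    abort("labels.csv needs columns `subject` and `group`")
  lv <- sort(unique(as.character(labels$group)))
  if (length(lv) != 2)
    abort(sprintf("binary design required; labels.csv has %d group(s): %s",
                  length(lv), paste(lv, collapse = ", ")))
  labels$group <- factor(labels$group, levels = lv)
  ts_files <- list.files(file.path(dir, "ts"), pattern = "\\.csv$",
                         full.names = TRUE)
  ts_subjects <- sub("\\.csv$", "", basename(ts_files))
  diff <- c(setdiff(labels$subject, ts_subjects),
            setdiff(ts_subjects, labels$subject))
  if (length(diff))
    abort(sprintf("subjects differ between labels.csv and ts/: %s",
                  paste(diff, collapse = ", ")))
  ts <- lapply(setNames(ts_files, ts_subjects), function(f) {
    df <- readr::read_csv(f, show_col_types = FALSE)
    as.matrix(df[, -1, drop = FALSE])
  })
  ts <- ts[labels$subject]
  n_roi <- nrow(ts[[1]])
  bad <- names(ts)[vapply(ts, nrow, integer(1)) != n_roi]
  if (length(bad))
    abort(sprintf("ROI-count mismatch in time-series files: %s",
                  paste(bad, collapse = ", ")))
  scalars <- purrr::map_dfr(scalar_modalities, function(mod) {
    f <- file.path(dir, paste0(mod, ".csv"))
    if (!file.exists(f))
      abort(sprintf("missing scalar modality file: %s", basename(f)))
    wide <- readr::read_csv(f, show_col_types = FALSE)
    diff <- c(setdiff(labels$subject, wide$subject),
              setdiff(wide$subject, labels$subject))
    if (length(diff))
      abort(sprintf("subjects differ between labels.csv and %s: %s",
                    basename(f), paste(diff, collapse = ", ")))
    if (ncol(wide) - 1 != n_roi)
      abort(sprintf("ROI-count mismatch: %s has %d ROIs, ts/ has %d",
                    basename(f), ncol(wide) - 1, n_roi))
    long <- tidyr::pivot_longer(wide, -"subject", names_to = "col",
                                values_to = "value")
    long$roi <- as.integer(sub("^roi(\\d+)_.*$", "\\1", long$col))
    long$modality <- mod
    long[, c("subject", "roi", "modality", "value")]
  })
  structure(list(ts = ts, scalars = scalars, labels = labels, n_roi = n_roi),
            class = "multimodal_cohort")
}

#' Assemble a pipeline run configuration
#'
#' @param n_per_group,n_roi,n_timepoints,effects,rho Cohort settings passed to
#'   [cohort_config()] when simulating (ignored when `input_dir` is given).
#' @param input_dir Optional directory of an existing cohort (read with
#'   [read_cohort()]) instead of simulating.
#' @param measures Measure sets to screen and classify.
#' @param classifier Named list of [classifier_config()] overrides.
#' @param pca_k If non-`NULL`, reduce the fMRI block to this many principal
#'   components before screening/classification.
#' @param paper_mode If `TRUE`, normalization (and PCA) are fit once on all
#'   subjects and the classifier consumes the globally normalized features;
#'   the default refits them inside each training partition to avoid
#'   information leakage.
#' @param seed Master seed for every stochastic stage.
#' @param out_dir Output directory.
#' @return A `run_config` list.
#' @export
run_config <- function(n_per_group = 50, n_roi = 20, n_timepoints = 100,
                       effects = NULL, rho = 0.1, input_dir = NULL,
                       measures = c("fusion", "fmri", "smri", "dti"),
                       classifier = list(), pca_k = NULL,
                       paper_mode = FALSE, seed = 1L, out_dir = "roifuse_run") {
  structure(list(n_per_group = n_per_group, n_roi = n_roi,
                 n_timepoints = n_timepoints, effects = effects, rho = rho,
                 input_dir = input_dir, measures = measures,
                 classifier = classifier, pca_k = pca_k,
                 paper_mode = paper_mode, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "run_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path Path to a YAML file whose keys match the arguments of
#'   [run_config()]; `effects` may be a list of `{roi, modality, d, partner,
#'   delta}` records.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$effects))
    raw$effects <- dplyr::bind_rows(lapply(raw$effects, as.data.frame))
  do.call(run_config, raw)
}

#' Run the full fusion pipeline
#'
#' simulate (or read) -> fuse -> screen -> classify -> concord -> contribute,
#' writing `screen.csv`, one `report_<measure>.json` + `roc_<measure>.csv`
#' per measure set, `predictions.csv`, `concord.csv`, `contrib.json` and a
#' `manifest.json` (seed, configuration hash, package version) to the output
#' directory. Every stochastic stage is seeded from `cfg$seed`, so a rerun
#' with the same configuration is bit-identical.
#'
#' @param cfg A [run_config()].
#' @return Invisibly, a list with the in-memory stage results.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(cfg$out_dir, "log.txt")
  logf <- function(fmt, ...) {
    cat(sprintf(paste0(fmt, "\n"), ...), file = log_path, append = TRUE)
  }
  stage <- function(name, expr) {
    logf("[%s] start", name)
    out <- tryCatch(expr, error = function(e) {
      logf("[%s] FAILED: %s", name, conditionMessage(e))
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)))
    })
    logf("[%s] done", name)
    out
  }

  cohort <- stage("simulate", {
    if (!is.null(cfg$input_dir)) {
      read_cohort(cfg$input_dir)
    } else {
      sim <- generate_cohort(cohort_config(
        n_per_group = cfg$n_per_group, n_roi = cfg$n_roi,
        n_timepoints = cfg$n_timepoints, rho = cfg$rho,
        effects = cfg$effects, seed = cfg$seed))
      write_cohort(sim$cohort, file.path(cfg$out_dir, "cohort"), sim$truth)
      sim$cohort
    }
  })

  fs_raw <- stage("fuse", fusion_features(cohort))
  fs <- stage("normalize", {
    out <- zscore_normalize(fs_raw)
    if (!is.null(cfg$pca_k)) out <- pca_reduce_fmri_block(out, cfg$pca_k)$features
    out
  })

  screen <- stage("screen", screen_rois(fs, cohort$labels, cfg$measures))
  readr::write_csv(screen, file.path(cfg$out_dir, "screen.csv"))

  ccfg <- do.call(classifier_config,
                  modifyList(list(seed = cfg$seed), cfg$classifier))
  clf_fs <- if (cfg$paper_mode) fs else fs_raw
  reports <- stage("classify", {
    lapply(setNames(cfg$measures, cfg$measures), function(ms) {
      rep <- nested_cv(measure_design(clf_fs, ms), cohort$labels$group, ccfg)
      jsonlite::write_json(
        glance(rep), file.path(cfg$out_dir, sprintf("report_%s.json", ms)),
        auto_unbox = TRUE, digits = NA)
      readr::write_csv(rep$roc,
                       file.path(cfg$out_dir, sprintf("roc_%s.csv", ms)))
      rep
    })
  })

  concord <- stage("concord", {
    pt <- consensus_predictions(reports)
    readr::write_csv(pt, file.path(cfg$out_dir, "predictions.csv"))
    pairs <- utils::combn(names(reports), 2, simplify = FALSE)
    cc <- pairwise_concordance(pt, pairs)
    readr::write_csv(cc, file.path(cfg$out_dir, "concord.csv"))
    cc
  })

  contrib <- stage("contribute", {
    ct <- contribution_ratios(fs, cohort$labels)
    jsonlite::write_json(as.data.frame(ct),
                         file.path(cfg$out_dir, "contrib.json"),
                         auto_unbox = TRUE, digits = NA)
    ct
  })

  manifest <- list(
    package = "roifuse",
    version = as.character(utils::packageVersion("roifuse")),
    seed = cfg$seed,
    config_hash = rlang::hash(unclass(cfg)),
    measures = cfg$measures,
    paper_mode = cfg$paper_mode)
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(cohort = cohort, features = fs, screen = screen,
                 reports = reports, concordance = concord,
                 contribution = contrib, manifest = manifest))
}

#' Write a fusion feature set to a directory
#'
#' One `roi<index>.csv` per ROI (subjects x features, subject ids in the
#' first column) plus a `manifest.json` recording block tags, normalization
#' state and the normalizer's fitting subjects.
#'
#' @param fs A `fusion_features` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fusion_features <- function(fs, dir) {
  stopifnot(inherits(fs, "fusion_features"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(fs$n_roi)) {
    df <- data.frame(subject = rownames(fs$features[[i]]),
                     fs$features[[i]], check.names = FALSE)
    readr::write_csv(df, file.path(dir, sprintf("roi%03d.csv", i)))
  }
  jsonlite::write_json(
    list(n_roi = fs$n_roi, blocks = fs$blocks, subjects = fs$subjects,
         normalized = fs$normalized,
         fit_subjects = fs$fit_subjects %||% character()),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a fusion feature set written by [write_fusion_features()]
#'
#' @param dir Directory containing the per-ROI CSVs and `manifest.json`.
#' @return A `fusion_features` object.
#' @export
read_fusion_features <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  feats <- lapply(seq_len(man$n_roi), function(i) {
    df <- readr::read_csv(file.path(dir, sprintf("roi%03d.csv", i)),
                          show_col_types = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df$subject
    m
  })
  structure(
    list(features = feats, blocks = man$blocks, subjects = man$subjects,
         n_roi = man$n_roi, normalized = isTRUE(man$normalized),
         fit_subjects = if (length(man$fit_subjects)) man$fit_subjects),
    class = "fusion_features")
}
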