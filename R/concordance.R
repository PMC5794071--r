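#' Jaccard similarity between two sets
#'
#' `|A intersect B| / |A union B|`; by convention 1 when both sets are empty
#' (two classifiers that correctly classify nobody agree perfectly).
#'
#' @param set_a,set_b Vectors interpreted as sets (duplicates ignored).
#' @return A number in `[0, 1]`.
#' @export
#' @examples
#' jaccard(c(1, 2, 3), c(2, 3, 4))
jaccard <- function(set_a, set_b) {
  a <- unique(set_a); b <- unique(set_b)
  u <- length(union(a, b))
  if (u == 0) return(1)
  length(intersect(a, b)) / u
}

#' Cohen's kappa between two label vectors
#'
#' Chance-corrected agreement `(Pr(a) - Pr(e)) / (1 - Pr(e))`, where `Pr(a)`
#' is the observed agreement fraction and `Pr(e)` the agreement expected if
#' each rater labelled independently with its own marginal frequencies. When
#' both raters are constant with identical marginals (`Pr(e) = 1`), kappa is
#' defined as 1 if the agreement is perfect and is an error otherwise.
#'
#' @param labels_a,labels_b Equal-length category vectors.
#' @return Kappa in `[-1, 1]`.
#' @export
#' @examples
#' cohen_kappa(c("x", "x", "y", "y"), c("x", "y", "y", "y"))
cohen_kappa <- function(labels_a, labels_b) {
  stopifnot(length(labels_a) == length(labels_b), length(labels_a) >= 1)
  cats <- union(unique(labels_a), unique(labels_b))
  a <- factor(labels_a, levels = cats)
  b <- factor(labels_b, levels = cats)
  pr_a <- mean(a == b)
  pr_e <- sum(prop.table(table(a)) * prop.table(table(b)))
  if (1 - pr_e < 1e-12) {
    if (pr_a == 1) return(1)
    abort("Pr(e) = 1 with imperfect agreement: kappa undefined")
  }
  (pr_a - pr_e) / (1 - pr_e)
}

#' Consensus out-of-fold predictions from repeated cross-validation
#'
#' Reduces each classifier's per-repeat out-of-fold predictions to one label
#' per subject by majority vote over repeats; exact ties go to the positive
#' class (a message reports how many).
#'
#' @param reports Named list of `cv_report` objects (names identify the
#'   classifiers), all fitted on the same subjects.
#' @return A `prediction_table` tibble: `subject`, `true`, and one predicted
#'   label column per classifier.
#' @export
consensus_predictions <- function(reports) {
  stopifnot(length(reports) >= 1, !is.null(names(reports)))
  vote <- function(rep) {
    pos <- rep$positive
    tab <- rep$predictions |>
      dplyr::group_by(.data$subject) |>
      dplyr::summarise(
        true = .data$true[1],
        n_pos = sum(.data$pred == pos),
        n_tot = dplyr::n(), .groups = "drop")
    ties <- sum(tab$n_pos * 2 == tab$n_tot)
    if (ties > 0)
      inform(sprintf("%d majority-vote tie(s) resolved to '%s'", ties, pos))
    neg <- setdiff(unique(tab$true), pos)
    tab$pred <- ifelse(tab$n_pos * 2 >= tab$n_tot, pos, neg[1])
    tab[, c("subject", "true", "pred")]
  }
  out <- NULL
  for (nm in names(reports)) {
    v <- vote(reports[[nm]])
    names(v)[names(v) == "pred"] <- nm
    out <- if (is.null(out)) v else dplyr::inner_join(out, v[, c("subject", nm)],
                                                      by = "subject")
  }
  class(out) <- c("prediction_table", class(out))
  out
}

parse_pairs <- function(pairs) {
  if (is.character(pairs)) pairs <- strsplit(pairs, ":", fixed = TRUE)
  lapply(pairs, function(p) {
    stopifnot(length(p) == 2)
    as.character(p)
  })
}

#' Pairwise concordance between classifiers
#'
#' For each requested pair of classifiers: the Jaccard coefficient between
#' their sets of correctly-classified subjects (similarity of what they get
#' right) and Cohen's kappa between their predicted-label vectors
#' (chance-corrected agreement of what they say). An alternative Jaccard on
#' predicted-positive subject sets is available via
#' `jaccard_on = "predicted_positive"`.
#'
#' @param pt A `prediction_table` from [consensus_predictions()] (columns
#'   `subject`, `true`, one per classifier).
#' @param pairs List of length-2 character vectors, or strings like
#'   `"fmri:smri"`.
#' @param jaccard_on `"correct"` (default) or `"predicted_positive"`.
#' @param positive Positive label for the `"predicted_positive"` variant;
#'   defaults to the last sorted label.
#' @return A tibble with columns `a`, `b`, `jaccard`, `kappa`.
#' @export
pairwise_concordance <- function(pt, pairs, jaccard_on = c("correct",
                                                           "predicted_positive"),
                                 positive = NULL) {
  jaccard_on <- match.arg(jaccard_on)
  pairs <- parse_pairs(pairs)
  clf <- setdiff(names(pt), c("subject", "true"))
  purrr::map_dfr(pairs, function(p) {
    missing <- setdiff(p, clf)
    if (length(missing))
      abort(sprintf("unknown classifier(s): %s (available: %s)",
                    paste(missing, collapse = ", "),
                    paste(clf, collapse = ", ")))
    sets <- lapply(p, function(nm) {
      if (jaccard_on == "correct") {
        pt$subject[pt[[nm]] == pt$true]
      } else {
        pos <- positive %||% sort(unique(pt$true))[length(unique(pt$true))]
        pt$subject[pt[[nm]] == pos]
      }
    })
    tibble(a = p[1], b = p[2],
           jaccard = jaccard(sets[[1]], sets[[2]]),
           kappa = cohen_kappa(pt[[p[1]]], pt[[p[2]]]))
  })
}
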