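# Construction of the clinical analysis matrix X (n x 8, or n x 9 with SES)
# and the structural matrix Y (n x 33) from validated cohort tables.

#' Age-residualize a raw score
#'
#' Regresses a raw neuropsychological score on age at testing by ordinary
#' least squares and returns the standardized residuals (residuals divided by
#' their sample SD, denominator n - 1), the standard correction for the strong
#' age-related increase in executive and socio-emotional performance. The
#' output has mean 0 and SD 1 by construction.
#'
#' @param scores Numeric raw scores.
#' @param ages Ages in months, same length as `scores`.
#' @param measure Name used in error messages.
#' @return Numeric vector of standardized residuals.
#' @examples
#' age_residualize(c(1, 2, 3, 4), c(10, 10, 20, 20))
#' @export
age_residualize <- function(scores, ages, measure = "score") {
  if (length(scores) != length(ages)) {
    stop(sprintf("'%s': scores and ages differ in length", measure))
  }
  if (length(scores) < 3) {
    stop(sprintf("'%s': at least 3 subjects required", measure))
  }
  if (anyNA(scores) || anyNA(ages)) {
    stop(sprintf("'%s': missing values not permitted", measure))
  }
  if (stats::sd(ages) == 0) {
    stop(sprintf("'%s': ages are constant; cannot regress on age", measure))
  }
  res <- stats::lm.fit(cbind(1, ages), scores)$residuals
  s <- stats::sd(res)
  if (s < 1e-12 * max(1, stats::sd(scores))) {
    stop(sprintf(
      "'%s': residual variance is zero after regressing on age", measure))
  }
  res / s
}

#' Flanker inhibition score
#'
#' Attentional-control score from the flanker task: accuracy in the
#' incongruent condition minus accuracy in the congruent condition (computed
#' before age-residualization).
#'
#' @param acc_incongruent,acc_congruent Accuracy proportions in \[0, 1\].
#' @return `acc_incongruent - acc_congruent`.
#' @examples
#' inhibition_score(0.8, 0.95)
#' @export
inhibition_score <- function(acc_incongruent, acc_congruent) {
  ok <- function(x) all(x >= 0 & x <= 1, na.rm = FALSE) && !anyNA(x)
  if (!ok(acc_incongruent) || !ok(acc_congruent)) {
    stop("inhibition_score: accuracies must lie in [0, 1]")
  }
  acc_incongruent - acc_congruent
}

#' Build the PLSC analysis matrices
#'
#' Selects one analysis group, passes age, gestational age and IQ through
#' unchanged, age-residualizes the five raw scores (working memory, processing
#' speed, inhibition, affect recognition, theory of mind) *within the selected
#' group*, and assembles the clinical matrix X (columns `age_months, ga_weeks,
#' iq, wm, ps, inhibition, affect_recognition, theory_of_mind[, ses]`) next to
#' the structural matrix Y (33 canonical columns). Processing speed keeps its
#' natural sign (larger = slower reaction time).
#'
#' @param clinical,structural Validated cohort tables.
#' @param group `"VPT"`, `"FT"` or `"all"`.
#' @param include_ses Append the Largo socio-economic score as a 9th column?
#' @param y A matrix to use as Y instead of the raw structural measures (e.g.
#'   a W-score table from [compute_w_scores()]); must have 33 canonical
#'   columns and row ids matching the structural table.
#' @return An object of class `analysis_matrices`: list with `X`, `Y`,
#'   `row_ids`, `x_names`, `y_names`, `group`.
#' @export
build_matrices <- function(clinical, structural,
                           group = c("VPT", "FT", "all"),
                           include_ses = FALSE, y = NULL) {
  group <- match.arg(group)
  paired <- align_by_subject(clinical, structural)
  if (group != "all") paired <- paired[paired$group == group, , drop = FALSE]
  if (!nrow(paired)) stop(sprintf("group '%s' is empty", group))
  if (include_ses && (!"ses" %in% names(paired) || anyNA(paired$ses))) {
    stop("include_ses = TRUE but 'ses' is absent or incomplete")
  }

  raw <- residualized_raw_cols()
  resid_cols <- lapply(seq_along(raw), function(i) {
    age_residualize(paired[[raw[[i]]]], paired$age_months,
                    measure = names(raw)[i])
  })
  names(resid_cols) <- names(raw)

  X <- cbind(age_months = paired$age_months, ga_weeks = paired$ga_weeks,
             iq = paired$iq, do.call(cbind, resid_cols))
  if (include_ses) X <- cbind(X, ses = paired$ses)
  rownames(X) <- paired$subject_id

  if (is.null(y)) {
    Y <- as.matrix(paired[, cc_measure_names()])
  } else {
    if (is.data.frame(y) && "subject_id" %in% names(y)) {
      ids <- y$subject_id
      y <- as.matrix(y[, cc_measure_names()])
      rownames(y) <- ids
    } else {
      y <- as.matrix(y[, cc_measure_names()])
    }
    if (is.null(rownames(y))) {
      stop("'y' must carry subject ids (a subject_id column or rownames)")
    }
    idx <- match(paired$subject_id, rownames(y))
    if (anyNA(idx)) {
      stop(sprintf("'y' is missing %d subject(s) of group '%s'",
                   sum(is.na(idx)), group))
    }
    Y <- y[idx, , drop = FALSE]
  }
  rownames(Y) <- paired$subject_id
  if (!all(is.finite(X)) || !all(is.finite(Y))) {
    stop("analysis matrices contain non-finite entries")
  }
  structure(list(X = X, Y = Y, row_ids = paired$subject_id,
                 x_names = colnames(X), y_names = colnames(Y),
                 group = group),
            class = "analysis_matrices")
}

#' @export
print.analysis_matrices <- function(x, ...) {
  cat(sprintf("<analysis_matrices> group=%s  X: %d x %d  Y: %d x %d\n",
              x$group, nrow(x$X), ncol(x$X), nrow(x$Y), ncol(x$Y)))
  invisible(x)
}
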