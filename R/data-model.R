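#' @importFrom rlang .data
NULL

# Validation -------------------------------------------------------------------

stop_schema <- function(msg) stop(structure(
  class = c("ccnorm_schema_error", "error", "condition"),
  list(message = msg, call = NULL)))

stop_validation <- function(msg) stop(structure(
  class = c("ccnorm_validation_error", "error", "condition"),
  list(message = msg, call = NULL)))

check_range <- function(df, col, lo, hi, table, strict_lo = FALSE) {
  v <- df[[col]]
  bad <- if (strict_lo) !(v > lo & v <= hi) else !(v >= lo & v <= hi)
  bad <- bad & !is.na(v)
  if (any(bad)) {
    stop_validation(sprintf(
      "%s: '%s' out of range [%s, %s] for subject(s) %s",
      table, col, lo, hi, paste(df$subject_id[bad], collapse = ", ")))
  }
  invisible(TRUE)
}

#' Validate a clinical table
#'
#' Checks the canonical clinical schema: required columns, unique subject ids,
#' group/sex levels, ages in 60-200 months, gestational age consistent with
#' group membership (VPT < 32 weeks, FT within 37-42 weeks), positive IQ and,
#' when present, a Largo socio-economic score within 0-12.
#'
#' @param clinical A data frame with the clinical columns.
#' @return The validated table as a tibble (invisibly usable in pipelines).
#' @export
validate_clinical <- function(clinical) {
  clinical <- tibble::as_tibble(clinical)
  missing <- setdiff(clinical_required_cols(), names(clinical))
  if (length(missing)) {
    stop_schema(sprintf("clinical table: missing required column(s) %s",
                        paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(clinical$subject_id)) {
    dup <- unique(clinical$subject_id[duplicated(clinical$subject_id)])
    stop_validation(sprintf("clinical table: duplicate subject_id %s",
                            paste(dup, collapse = ", ")))
  }
  if (!all(clinical$group %in% c("VPT", "FT"))) {
    stop_validation("clinical table: 'group' must be 'VPT' or 'FT'")
  }
  if (!all(clinical$sex %in% c("F", "M"))) {
    stop_validation("clinical table: 'sex' must be 'F' or 'M'")
  }
  check_range(clinical, "age_months", 60, 200, "clinical table")
  vpt <- clinical[clinical$group == "VPT", ]
  ft <- clinical[clinical$group == "FT", ]
  if (nrow(vpt) && any(vpt$ga_weeks >= 32, na.rm = TRUE)) {
    bad <- vpt$subject_id[vpt$ga_weeks >= 32]
    stop_validation(sprintf(
      "clinical table: VPT subject(s) %s have ga_weeks >= 32",
      paste(stats::na.omit(bad), collapse = ", ")))
  }
  if (nrow(ft)) check_range(ft, "ga_weeks", 37, 42, "clinical table")
  if (any(clinical$iq <= 0, na.rm = TRUE)) {
    stop_validation("clinical table: 'iq' must be positive")
  }
  if ("ses" %in% names(clinical)) {
    check_range(clinical, "ses", 0, 12, "clinical table")
  }
  clinical
}

#' Validate a structural table
#'
#' Checks that the 33 canonical measure columns are all present (in canonical
#' order after validation), FA/NDI/ODI lie in \[0, 1\], MD (in 1e-3 mm^2/s) is
#' positive and partition volumes (mm^3) are positive.
#'
#' @param structural A data frame with `subject_id` plus the 33 measures.
#' @return The validated table as a tibble, measure columns in canonical order.
#' @export
validate_structural <- function(structural) {
  structural <- tibble::as_tibble(structural)
  measures <- cc_measure_names()
  missing <- setdiff(c("subject_id", measures), names(structural))
  if (length(missing)) {
    stop_schema(sprintf("structural table: missing required column(s) %s",
                        paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(structural$subject_id)) {
    dup <- unique(structural$subject_id[duplicated(structural$subject_id)])
    stop_validation(sprintf("structural table: duplicate subject_id %s",
                            paste(dup, collapse = ", ")))
  }
  fam <- cc_measure_families()
  for (m in measures) {
    if (fam[[m]] %in% c("fa", "ndi", "odi")) {
      check_range(structural, m, 0, 1, "structural table")
    } else {
      v <- structural[[m]]
      bad <- !is.na(v) & v <= 0
      if (any(bad)) {
        stop_validation(sprintf(
          "structural table: '%s' must be positive for subject(s) %s",
          m, paste(structural$subject_id[bad], collapse = ", ")))
      }
    }
  }
  structural[, c("subject_id", measures)]
}

# Loading / writing ------------------------------------------------------------

normalize_headers <- function(df, canonical) {
  idx <- match(tolower(canonical), tolower(names(df)))
  found <- !is.na(idx)
  names(df)[idx[found]] <- canonical[found]
  df
}

drop_incomplete <- function(df, cols, label) {
  cols <- intersect(cols, names(df))
  keep <- stats::complete.cases(df[, cols, drop = FALSE])
  if (any(!keep)) {
    message(sprintf("%s: dropped %d subject(s) with missing analysed values",
                    label, sum(!keep)))
  }
  df[keep, , drop = FALSE]
}

#' Load a cohort from delimited text
#'
#' Reads the clinical and structural CSV files (comma-separated, header row,
#' `.` decimal separator, UTF-8), matches headers case-insensitively against
#' the canonical names, drops subjects with missing values in any analysed
#' column (with a logged count - the analyses are complete-case), and
#' validates both tables.
#'
#' @param clinical_path,structural_path Paths to the two CSV files.
#' @return A list with elements `clinical` and `structural` (tibbles).
#' @seealso [write_cohort()], [align_by_subject()]
#' @export
load_cohort <- function(clinical_path, structural_path) {
  for (p in c(clinical_path, structural_path)) {
    if (!file.exists(p)) stop(sprintf("file not found: %s", p))
  }
  clinical <- readr::read_csv(clinical_path, show_col_types = FALSE,
                              progress = FALSE)
  structural <- readr::read_csv(structural_path, show_col_types = FALSE,
                                progress = FALSE)
  clinical <- normalize_headers(
    clinical, c(clinical_required_cols(), clinical_optional_cols()))
  structural <- normalize_headers(structural,
                                  c("subject_id", cc_measure_names()))
  clinical <- drop_incomplete(clinical, clinical_required_cols(), "clinical")
  structural <- drop_incomplete(structural, c("subject_id", cc_measure_names()),
                                "structural")
  clinical <- validate_clinical(clinical)
  structural <- validate_structural(structural)
  if (nrow(clinical) && nrow(structural) &&
      !length(intersect(clinical$subject_id, structural$subject_id))) {
    stop_validation("no subject_id is shared between the two tables")
  }
  list(clinical = clinical, structural = structural)
}

#' Write a cohort to delimited text
#'
#' Serializes validated tables as `clinical.csv` and `structural.csv` with
#' canonical headers at full precision, so that
#' `load_cohort()` on the written files reproduces the tables exactly.
#'
#' @param clinical,structural Validated cohort tables.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a character vector of the two file paths.
#' @export
write_cohort <- function(clinical, structural, out_dir) {
  clinical <- validate_clinical(clinical)
  structural <- validate_structural(structural)
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop(sprintf("cannot create directory: %s", out_dir))
  }
  paths <- c(clinical = file.path(out_dir, "clinical.csv"),
             structural = file.path(out_dir, "structural.csv"))
  readr::write_csv(clinical, paths[["clinical"]], progress = FALSE)
  readr::write_csv(structural, paths[["structural"]], progress = FALSE)
  invisible(paths)
}

#' Pair clinical and structural tables by subject
#'
#' Inner join on `subject_id`; the result keeps the clinical table's row order
#' restricted to the intersection, and the number of subjects dropped from
#' either side is reported via `message()`.
#'
#' @param clinical,structural Validated cohort tables.
#' @return A tibble with the clinical columns followed by the 33 canonical
#'   structural measures, one row per shared subject.
#' @export
align_by_subject <- function(clinical, structural) {
  clinical <- validate_clinical(clinical)
  structural <- validate_structural(structural)
  shared <- intersect(clinical$subject_id, structural$subject_id)
  if (!length(shared)) stop_validation("empty subject_id intersection")
  n_drop <- (nrow(clinical) - length(shared)) +
    (nrow(structural) - length(shared))
  if (n_drop > 0) {
    message(sprintf("align_by_subject: dropped %d unmatched subject(s)",
                    n_drop))
  }
  dplyr::inner_join(clinical, structural, by = "subject_id")
}
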