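#' Canonical corpus callosum measure names
#'
#' The 33 structural measures analysed by the pipeline, in the fixed canonical
#' order shared by every module: the 5 FreeSurfer-style callosal partition
#' volumes (anterior to posterior), then mean FA, MD, NDI and ODI over the 7
#' tract segments (cc1 = rostrum ... cc7 = splenium).
#'
#' @return Character vector of length 33.
#' @examples
#' cc_measure_names()
#' @export
cc_measure_names <- function() {
  c(
    paste0("volume_", c("anterior", "mid_anterior", "central",
                        "mid_posterior", "posterior")),
    paste0("fa_cc", 1:7),
    paste0("md_cc", 1:7),
    paste0("ndi_cc", 1:7),
    paste0("odi_cc", 1:7)
  )
}

#' Measure family of each canonical structural column
#'
#' @return Named character vector mapping each of the 33 canonical measure
#'   names to its family: `"volume"`, `"fa"`, `"md"`, `"ndi"` or `"odi"`.
#' @export
cc_measure_families <- function() {
  m <- cc_measure_names()
  stats::setNames(sub("_.*$", "", m), m)
}

# Maturation direction per family: sign of the expected change with age in
# typical development (FA/NDI/volume rise, MD/ODI fall).
cc_family_signs <- function() {
  c(volume = 1, fa = 1, md = -1, ndi = 1, odi = -1)
}

# Clinical schema -------------------------------------------------------------

clinical_required_cols <- function() {
  c("subject_id", "group", "sex", "age_months", "ga_weeks", "iq",
    "wm_raw", "ps_raw", "inh_raw", "affect_raw", "tom_raw")
}

clinical_optional_cols <- function() {
  c("birth_weight_g", "ses")
}

# X-matrix column order used by build_matrices() (ses appended when requested)
clinical_analysis_cols <- function() {
  c("age_months", "ga_weeks", "iq", "wm", "ps", "inhibition",
    "affect_recognition", "theory_of_mind")
}

# Raw clinical columns that are age-residualized into the X matrix
residualized_raw_cols <- function() {
  c(wm = "wm_raw", ps = "ps_raw", inhibition = "inh_raw",
    affect_recognition = "affect_raw", theory_of_mind = "tom_raw")
}
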