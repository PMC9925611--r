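# Synthetic VPT/FT cohort generator with planted ground truth.
#
# The generator emulates the *derived* feature tables of a preterm-birth
# neurodevelopment study (clinical/neuropsychological record + 33 callosal
# tractometry measures), not raw MRI. Structural measures follow linear
# maturation trends with age (FA/NDI/volume up, MD/ODI down), a scalar latent
# "maturation" factor couples the clinical scores to the structural families,
# and VPT subjects accrue an additional deviation from the normative trend
# proportional to age and to weeks of prematurity below 32.

default_measure_baselines <- function() {
  # typical values at 120 months of age; volumes in mm^3, MD in 1e-3 mm^2/s
  stats::setNames(c(
    900, 700, 650, 700, 1000,                      # partition volumes
    0.55, 0.58, 0.60, 0.62, 0.64, 0.66, 0.70,      # FA, rostrum -> splenium
    0.95, 0.92, 0.90, 0.88, 0.87, 0.86, 0.84,      # MD
    0.50, 0.52, 0.54, 0.55, 0.56, 0.58, 0.60,      # NDI
    0.25, 0.22, 0.20, 0.18, 0.17, 0.16, 0.15       # ODI
  ), cc_measure_names())
}

#' Specification of a synthetic VPT/FT cohort
#'
#' Bundles the generative parameters of [generate_cohort()]. Defaults match
#' the study conditions the pipeline targets: 39 full-term and 65 very preterm
#' subjects aged 72-173 months, gestational age 39.83 (1.33) weeks for FT and
#' 29.59 (1.73) weeks (truncated below 32) for VPT.
#'
#' @param n_ft,n_vpt Group sizes.
#' @param age_range_months Length-2 interval ages are drawn uniformly from.
#' @param ga_ft,ga_vpt Length-2 `c(mean, sd)` of gestational age in weeks; FT
#'   draws are truncated to \[37, 42\], VPT draws to \[22, 32).
#' @param age_slopes Named per-family maturation slope per month of age
#'   (families `volume`, `fa`, `md`, `ndi`, `odi`).
#' @param vpt_deviation_rate Deviation from the normative trend accrued by VPT
#'   subjects, in units of the family residual SD per (month of age x week of
#'   gestation below 32). 0 disables the planted deviation.
#' @param clinical_coupling Named loadings (standardized scale) of the scalar
#'   latent maturation factor on the six neuropsychological scores
#'   (`iq`, `wm`, `ps`, `inhibition`, `affect`, `tom`).
#' @param struct_coupling Loading of the latent factor on each structural
#'   measure, in units of the family residual SD (applied along the family's
#'   maturation direction).
#' @param noise_sd Named per-family residual SD on the measure's native scale.
#' @param age_ga_corr When `TRUE`, VPT ages are shifted with prematurity so
#'   that age and gestational age correlate negatively (about -0.25);
#'   off by default to keep the generative model exchangeable.
#' @param seed Integer seed; identical specs produce identical cohorts.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_ft = 39,
                        n_vpt = 65,
                        age_range_months = c(72, 173),
                        ga_ft = c(39.83, 1.33),
                        ga_vpt = c(29.59, 1.73),
                        age_slopes = c(volume = 1.5, fa = 8e-4, md = -6e-4,
                                       ndi = 8e-4, odi = -4e-4),
                        vpt_deviation_rate = 0.006,
                        clinical_coupling = c(iq = 0.6, wm = 0.5, ps = -0.5,
                                              inhibition = 0.25, affect = 0.3,
                                              tom = 0.3),
                        struct_coupling = 0.8,
                        noise_sd = c(volume = 60, fa = 0.025, md = 0.03,
                                     ndi = 0.03, odi = 0.02),
                        age_ga_corr = FALSE,
                        seed = 1L) {
  spec <- list(
    n_ft = as.integer(n_ft), n_vpt = as.integer(n_vpt),
    age_range_months = as.numeric(age_range_months),
    ga_ft = as.numeric(ga_ft), ga_vpt = as.numeric(ga_vpt),
    age_slopes = age_slopes, vpt_deviation_rate = vpt_deviation_rate,
    clinical_coupling = clinical_coupling, struct_coupling = struct_coupling,
    noise_sd = noise_sd, age_ga_corr = isTRUE(age_ga_corr),
    seed = as.integer(seed))
  class(spec) <- "cohort_spec"
  validate_cohort_spec(spec)
  spec
}

validate_cohort_spec <- function(spec) {
  fams <- names(cc_family_signs())
  if (spec$n_ft < 8 || spec$n_vpt < 8) {
    stop("cohort_spec: n_ft and n_vpt must both be >= 8 (four age bins)")
  }
  if (length(spec$age_range_months) != 2 ||
      diff(spec$age_range_months) <= 0) {
    stop("cohort_spec: age_range_months must be a nonempty interval")
  }
  if (!all(fams %in% names(spec$age_slopes)) ||
      !all(fams %in% names(spec$noise_sd))) {
    stop("cohort_spec: age_slopes and noise_sd need entries for families ",
         paste(fams, collapse = ", "))
  }
  if (any(spec$noise_sd <= 0)) stop("cohort_spec: noise_sd must be positive")
  if (spec$vpt_deviation_rate < 0) {
    stop("cohort_spec: vpt_deviation_rate must be >= 0")
  }
  invisible(spec)
}

rnorm_trunc <- function(n, mean, sd, lo, hi) {
  # inverse-CDF sampling keeps draw count fixed so seeds stay aligned
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

clip_count <- new.env(parent = emptyenv())

clip_to <- function(x, lo, hi) {
  n <- sum(x < lo | x > hi, na.rm = TRUE)
  clip_count$n <- clip_count$n + n
  pmin(pmax(x, lo), hi)
}

#' Generate a synthetic cohort
#'
#' Draws clinical and structural tables under the generative model of
#' [cohort_spec()]. Values falling outside their legal range are clipped (and
#' counted in the `clipped` attribute of the structural table); at default
#' parameters clipping is essentially never triggered.
#'
#' @param spec A [cohort_spec()].
#' @return A list with validated `clinical` and `structural` tibbles. The
#'   structural table carries an integer attribute `clipped`.
#' @examples
#' cohort <- generate_cohort(cohort_spec(seed = 42))
#' dim(cohort$structural)
#' @export
generate_cohort <- function(spec) {
  validate_cohort_spec(spec)
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old_seed <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  }
  set.seed(spec$seed)
  clip_count$n <- 0L

  n <- spec$n_ft + spec$n_vpt
  group <- c(rep("FT", spec$n_ft), rep("VPT", spec$n_vpt))
  subject_id <- c(sprintf("FT%03d", seq_len(spec$n_ft)),
                  sprintf("VPT%03d", seq_len(spec$n_vpt)))
  is_vpt <- group == "VPT"

  ga <- numeric(n)
  ga[!is_vpt] <- rnorm_trunc(spec$n_ft, spec$ga_ft[1], spec$ga_ft[2], 37, 42)
  ga[is_vpt] <- rnorm_trunc(spec$n_vpt, spec$ga_vpt[1], spec$ga_vpt[2],
                            22, 32 - 1e-9)
  age <- stats::runif(n, spec$age_range_months[1], spec$age_range_months[2])
  if (spec$age_ga_corr) {
    prem <- 32 - ga[is_vpt]
    age[is_vpt] <- pmin(pmax(age[is_vpt] + 4.2 * (prem - mean(prem)),
                             spec$age_range_months[1]),
                        spec$age_range_months[2])
  }
  sex <- sample(c("F", "M"), n, replace = TRUE)
  z <- stats::rnorm(n)  # scalar latent maturation factor

  # structural block ------------------------------------------------------
  measures <- cc_measure_names()
  fam <- cc_measure_families()
  sgn <- cc_family_signs()
  base <- default_measure_baselines()
  prem_weeks <- ifelse(is_vpt, 32 - ga, 0)
  clip_count$n <- 0L
  Y <- matrix(NA_real_, n, length(measures),
              dimnames = list(NULL, measures))
  for (m in measures) {
    f <- fam[[m]]
    mu <- base[[m]] + spec$age_slopes[[f]] * (age - 120) -
      spec$vpt_deviation_rate * spec$noise_sd[[f]] * age * prem_weeks *
        sgn[[f]] +
      spec$struct_coupling * spec$noise_sd[[f]] * sgn[[f]] * z
    v <- mu + stats::rnorm(n, sd = spec$noise_sd[[f]])
    Y[, m] <- if (f %in% c("fa", "ndi", "odi")) clip_to(v, 0, 1)
              else clip_to(v, 1e-6, Inf)
  }
  struct_clipped <- clip_count$n

  # clinical block --------------------------------------------------------
  mix <- function(c_load) {
    c_load * z + sqrt(1 - c_load^2) * stats::rnorm(n)
  }
  cc <- spec$clinical_coupling
  iq <- clip_to(100 + 15 * mix(cc[["iq"]]), 40, Inf)
  wm_raw <- round(clip_to(4 + 0.05 * age + 2.5 * mix(cc[["wm"]]), 0, Inf))
  ps_raw <- clip_to(1100 - 3 * age + 80 * mix(cc[["ps"]]), 150, Inf)
  inh_raw <- clip_to(0.02 + 5e-4 * age + 0.06 * mix(cc[["inhibition"]]),
                     -1, 1)
  affect_raw <- round(clip_to(10 + 0.08 * age + 3 * mix(cc[["affect"]]),
                              0, Inf))
  tom_raw <- round(clip_to(8 + 0.07 * age + 3 * mix(cc[["tom"]]), 0, Inf))
  ses <- clip_to(ifelse(is_vpt, stats::rnorm(n, 4.44, 2.55),
                        stats::rnorm(n, 2.89, 1.29)), 0, 12)
  birth_weight_g <- ifelse(is_vpt,
                           clip_to(stats::rnorm(n, 1288.00, 378.62), 400, Inf),
                           clip_to(stats::rnorm(n, 3438.72, 412.05), 1500, Inf))

  clinical <- tibble::tibble(
    subject_id = subject_id, group = group, sex = sex,
    age_months = age, ga_weeks = ga, birth_weight_g = birth_weight_g,
    iq = iq, wm_raw = wm_raw, ps_raw = ps_raw, inh_raw = inh_raw,
    affect_raw = affect_raw, tom_raw = tom_raw, ses = ses)
  structural <- tibble::tibble(subject_id = subject_id,
                               tibble::as_tibble(Y))
  structural <- validate_structural(structural)
  attr(structural, "clipped") <- struct_clipped
  list(clinical = validate_clinical(clinical), structural = structural,
       latent = z)
}

#' Ground truth planted by a cohort specification
#'
#' Returns the sign pattern a recovery analysis should find on a cohort drawn
#' from `spec`: the expected loading sign of each clinical and structural
#' variable on the dominant (maturation-oriented) latent component, and the
#' expected sign of the W-score trend of each measure family against age and
#' against gestational age. Signs are encoded +1 / -1 / 0 ("no planted
#' association"); loading signs are defined up to a joint flip of both blocks.
#'
#' @param spec A [cohort_spec()].
#' @param group Which analysis group the pattern refers to: `"all"`, `"vpt"`
#'   or `"ft"` (gestational age carries a planted sign only where the VPT
#'   deviation is present).
#' @return A list with `clinical_signs`, `structural_signs`, `w_trend_age`
#'   and `w_trend_ga`.
#' @export
planted_truth <- function(spec, group = c("all", "vpt", "ft")) {
  validate_cohort_spec(spec)
  group <- match.arg(group)
  sgn <- cc_family_signs()
  fam <- cc_measure_families()
  cc <- spec$clinical_coupling
  has_dev <- spec$vpt_deviation_rate > 0 && group != "ft"
  clinical_signs <- c(
    age_months = if (any(spec$age_slopes != 0)) 1 else 0,
    ga_weeks = if (has_dev) 1 else 0,
    iq = sign(cc[["iq"]]), wm = sign(cc[["wm"]]), ps = sign(cc[["ps"]]),
    inhibition = sign(cc[["inhibition"]]),
    affect_recognition = sign(cc[["affect"]]),
    theory_of_mind = sign(cc[["tom"]]))
  structural_signs <- stats::setNames(unname(sgn[fam]), names(fam))
  dev <- if (spec$vpt_deviation_rate > 0) 1 else 0
  w_trend_age <- stats::setNames(-dev * sgn, names(sgn))
  w_trend_ga <- stats::setNames(dev * sgn, names(sgn))
  list(clinical_signs = clinical_signs, structural_signs = structural_signs,
       w_trend_age = w_trend_age, w_trend_ga = w_trend_ga)
}
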