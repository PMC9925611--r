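# Small in-code fixtures shared across test files.

tiny_clinical <- function(n = 3) {
  tibble::tibble(
    subject_id = sprintf("S%02d", seq_len(n)),
    group = rep(c("VPT", "FT"), length.out = n),
    sex = rep(c("F", "M"), length.out = n),
    age_months = seq(80, 160, length.out = n),
    ga_weeks = ifelse(rep(c(TRUE, FALSE), length.out = n), 29, 40),
    birth_weight_g = seq(1200, 3400, length.out = n),
    iq = seq(95, 110, length.out = n),
    wm_raw = seq(8, 14, length.out = n),
    ps_raw = seq(900, 600, length.out = n),
    inh_raw = seq(-0.1, 0.2, length.out = n),
    affect_raw = seq(12, 22, length.out = n),
    tom_raw = seq(10, 18, length.out = n),
    ses = seq(2, 6, length.out = n))
}

tiny_structural <- function(n = 3) {
  m <- cc_measure_names()
  fam <- cc_measure_families()
  base <- c(volume = 800, fa = 0.6, md = 0.9, ndi = 0.55, odi = 0.2)
  vals <- sapply(seq_along(m), function(j) {
    base[[fam[[m[j]]]]] * (1 + 0.01 * seq_len(n) + 0.001 * j)
  })
  if (n == 1) vals <- matrix(vals, nrow = 1)
  colnames(vals) <- m
  tibble::tibble(subject_id = sprintf("S%02d", seq_len(n)),
                 tibble::as_tibble(vals))
}

# signs helper: do the robust loadings match the planted truth, allowing the
# joint global flip both blocks share?
signs_match_truth <- function(res, truth, component = 1) {
  lx <- res$loadings_X[, component]
  ly <- res$loadings_Y[, component]
  rx <- res$robust_X[, component]
  ry <- res$robust_Y[, component]
  ex <- truth$clinical_signs[names(lx)]
  ey <- truth$structural_signs[names(ly)]
  check <- function(flip) {
    okx <- all((sign(lx) * flip == ex)[rx & ex != 0])
    oky <- all((sign(ly) * flip == ey)[ry & ey != 0])
    okx && oky
  }
  any(ry) && (check(1) || check(-1))
}
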