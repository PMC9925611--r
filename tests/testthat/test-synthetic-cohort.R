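test_that("default cohort has the target group sizes and passes validation", {
  cohort <- generate_cohort(cohort_spec(seed = 11))
  expect_identical(sum(cohort$clinical$group == "VPT"), 65L)
  expect_identical(sum(cohort$clinical$group == "FT"), 39L)
  expect_identical(nrow(cohort$structural), 104L)
  am <- build_matrices(cohort$clinical, cohort$structural, group = "VPT")
  expect_identical(dim(am$X), c(65L, 8L))
  expect_identical(dim(am$Y), c(65L, 33L))
})

test_that("identical seeds reproduce the cohort, different seeds do not", {
  a <- generate_cohort(cohort_spec(seed = 5))
  b <- generate_cohort(cohort_spec(seed = 5))
  c <- generate_cohort(cohort_spec(seed = 6))
  expect_identical(a$clinical, b$clinical)
  expect_identical(a$structural, b$structural)
  expect_false(identical(a$structural, c$structural))
})

test_that("spec invariants are enforced", {
  expect_error(cohort_spec(n_ft = 5), ">= 8")
  expect_error(cohort_spec(age_range_months = c(100, 100)), "interval")
  expect_error(cohort_spec(noise_sd = c(volume = 60, fa = 0, md = 0.03,
                                        ndi = 0.03, odi = 0.02)),
               "positive")
  expect_error(cohort_spec(vpt_deviation_rate = -1), ">= 0")
})

test_that("the FT age slope is recovered by OLS at low noise", {
  spec <- cohort_spec(n_ft = 60, n_vpt = 8, vpt_deviation_rate = 0,
                      struct_coupling = 0,
                      noise_sd = c(volume = 1, fa = 0.002, md = 0.002,
                                   ndi = 0.002, odi = 0.002),
                      seed = 21)
  cohort <- generate_cohort(spec)
  ft <- dplyr::filter(align_by_subject(cohort$clinical, cohort$structural),
                      group == "FT")
  fit <- summary(stats::lm(fa_cc7 ~ age_months, data = ft))
  est <- fit$coefficients["age_months", ]
  expect_lt(abs(est[["Estimate"]] - spec$age_slopes[["fa"]]),
            3 * est[["Std. Error"]])
})

test_that("gestational-age draws match the group distributions within 3 SE", {
  cohort <- generate_cohort(cohort_spec(seed = 31))
  vpt <- cohort$clinical$ga_weeks[cohort$clinical$group == "VPT"]
  ft <- cohort$clinical$ga_weeks[cohort$clinical$group == "FT"]
  expect_lt(abs(mean(vpt) - 29.59), 3 * 1.73 / sqrt(65))
  expect_lt(abs(mean(ft) - 39.83), 3 * 1.33 / sqrt(39))
  expect_lt(abs(sd(vpt) - 1.73), 3 * 1.73 / sqrt(2 * 64))
  expect_lt(abs(sd(ft) - 1.33), 3 * 1.33 / sqrt(2 * 38))
  expect_true(all(vpt < 32))
  expect_true(all(ft >= 37 & ft <= 42))
})

test_that("the optional age-GA coupling induces a negative correlation", {
  cohort <- generate_cohort(cohort_spec(age_ga_corr = TRUE, seed = 41))
  vpt <- cohort$clinical[cohort$clinical$group == "VPT", ]
  expect_lt(cor(vpt$age_months, vpt$ga_weeks), 0)
})

test_that("planted_truth reflects the spec's slopes and couplings", {
  truth <- planted_truth(cohort_spec())
  expect_true(all(truth$structural_signs[paste0("fa_cc", 1:7)] == 1))
  expect_true(all(truth$structural_signs[paste0("odi_cc", 1:7)] == -1))
  expect_identical(unname(truth$clinical_signs[["age_months"]]), 1)
  expect_identical(unname(truth$clinical_signs[["ps"]]), -1)
  expect_identical(unname(truth$w_trend_age[["fa"]]), -1)
  expect_identical(unname(truth$w_trend_age[["odi"]]), 1)
  expect_identical(unname(truth$w_trend_ga[["fa"]]), 1)

  flat <- planted_truth(cohort_spec(
    clinical_coupling = c(iq = 0, wm = 0, ps = 0, inhibition = 0,
                          affect = 0, tom = 0)))
  neuro <- c("iq", "wm", "ps", "inhibition", "affect_recognition",
             "theory_of_mind")
  expect_true(all(flat$clinical_signs[neuro] == 0))

  no_dev <- planted_truth(cohort_spec(vpt_deviation_rate = 0))
  expect_true(all(no_dev$w_trend_age == 0))
  expect_identical(unname(no_dev$clinical_signs[["ga_weeks"]]), 0)
  ft_truth <- planted_truth(cohort_spec(), group = "ft")
  expect_identical(unname(ft_truth$clinical_signs[["ga_weeks"]]), 0)
})

test_that("default parameters essentially never clip structural values", {
  clip_free <- vapply(1:100, function(s) {
    attr(generate_cohort(cohort_spec(seed = 300 + s))$structural,
         "clipped") == 0L
  }, logical(1))
  expect_gte(mean(clip_free), 0.99)
})

test_that("without planted effects the groups are equal in law", {
  null_spec <- function(s) cohort_spec(
    vpt_deviation_rate = 0, struct_coupling = 0,
    clinical_coupling = c(iq = 0, wm = 0, ps = 0, inhibition = 0,
                          affect = 0, tom = 0), seed = s)
  reject <- vapply(1:100, function(s) {
    ch <- generate_cohort(null_spec(s))
    paired <- align_by_subject(ch$clinical, ch$structural)
    grp <- paired$group
    suppressWarnings(stats::ks.test(
      paired$fa_cc4[grp == "VPT"], paired$fa_cc4[grp == "FT"]))$p.value < 0.05
  }, logical(1))
  # nominal 5% false-positive rate; 99% binomial envelope for 100 draws
  expect_lte(sum(reject), 11)
})
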