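test_that("LOESS reproduces noise-free linear data exactly", {
  x <- seq(72, 173, length.out = 25)
  y <- 0.4 + 0.002 * x
  for (span in c(0.3, 0.6, 1)) {
    for (degree in 1:2) {
      expect_lt(max(abs(loess_predict(x, y, span, degree) - y)), 1e-8)
    }
  }
})

test_that("constant response gives constant predictions", {
  x <- runif(15, 0, 10)
  expect_equal(loess_predict(x, rep(2.5, 15), span = 0.5, x_new = c(1, 9)),
               c(2.5, 2.5), tolerance = 1e-10)
})

test_that("the symmetric 3-point design matches the hand WLS oracle", {
  # span 1, degree 1 at x0 = 0: tricube weights (0, 1, 0); the weighted
  # least-squares fitted value at 0 is uniquely the middle response, 0
  expect_equal(loess_predict(c(-1, 0, 1), c(1, 0, 1), span = 1, degree = 1,
                             x_new = 0), 0, tolerance = 1e-12)
})

test_that("a span keeping too few neighbours errors, naming the span", {
  x <- seq(1, 30)
  expect_error(loess_predict(x, x, span = 0.05, degree = 2), "0.05")
})

test_that("predictions agree with the reference local-regression smoother", {
  set.seed(42)
  x <- sort(runif(60, 72, 173))
  y <- 0.5 + 0.002 * x - 6e-6 * (x - 120)^2 + rnorm(60, sd = 0.01)
  ours <- loess_predict(x, y, span = 0.75, degree = 2)
  ref <- stats::predict(stats::loess(y ~ x, span = 0.75, degree = 2,
                                     surface = "direct",
                                     family = "gaussian"))
  expect_lt(max(abs(ours - ref)), 0.1 * sd(y))
})

test_that("Brent span search solves an analytic objective", {
  x <- seq(1, 40)
  s <- optimize_span(x, x, objective = function(s) (s - 0.4)^2)
  expect_equal(s, 0.4, tolerance = 1e-4)
})

test_that("Brent span search matches a 0.005-resolution grid oracle", {
  set.seed(9)
  x <- sort(runif(40, 72, 173))
  y <- 1 + 0.01 * x - 5e-5 * (x - 120)^2 + rnorm(40, sd = 0.3)
  sse_of <- function(s) {
    sum((y - loess_predict(x, y, s, degree = 2))^2)
  }
  lower <- 4 / 40  # smallest span keeping degree + 2 neighbours
  grid <- seq(lower, 1, by = 0.005)
  grid_val <- vapply(grid, sse_of, numeric(1))
  s_opt <- suppressMessages(optimize_span(x, y, degree = 2,
                                          objective = "sse"))
  ok <- sse_of(s_opt) <= min(grid_val) + 1e-6 ||
    abs(s_opt - grid[which.min(grid_val)]) <= 0.005
  expect_true(ok)
})

test_that("paper-mode bins reproduce the four canonical intervals", {
  edges <- make_age_bins("paper")
  expect_equal(edges, c(72, 96.6, 122.1, 148.1, 173))
  eq <- make_age_bins("equal", 0, 100, 4)
  expect_equal(diff(eq), rep(25, 4))
  expect_equal(make_age_bins("equal", 60, 200, 1), c(60, 200))
})

test_that("bin norms match the two-point closed form and error when empty", {
  struct <- tiny_structural(4)
  ages <- c(80, 90, 130, 140)  # bins 1, 1, 3, 3 of the paper scheme
  expect_error(
    compute_bin_norms(struct, ages, make_age_bins("paper")),
    "bin")
  # two equal-width bins, two subjects each
  norms <- suppressWarnings(
    compute_bin_norms(struct, ages, make_age_bins("equal", 72, 173, 2)))
  v <- struct$fa_cc1[1:2]
  expect_equal(unname(norms$mu[1, "fa_cc1"]), mean(v))
  expect_equal(unname(norms$sigma[1, "fa_cc1"]), sd(v))
  expect_identical(norms$n, c(2L, 2L))
  struct2 <- tiny_structural(4)
  struct2$fa_cc1 <- rep(0.6, 4)  # zero within-bin SD
  expect_error(suppressWarnings(compute_bin_norms(
    struct2, ages, make_age_bins("equal", 72, 173, 2))),
    "zero normative SD")
})

test_that("39 uniform FT ages fill all paper bins in nearly every draw", {
  set.seed(101)
  ok <- vapply(1:100, function(i) {
    ages <- runif(39, 72, 173)
    all(tabulate(findInterval(ages, make_age_bins("paper"),
                              rightmost.closed = TRUE), 4) >= 2)
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("W-scores obey the formula identities", {
  cohort <- generate_cohort(cohort_spec(seed = 17))
  paired <- align_by_subject(cohort$clinical, cohort$structural)
  ft <- paired[paired$group == "FT", ]
  sub <- ft[, c("subject_id", cc_measure_names())]
  norms <- suppressWarnings(
    compute_bin_norms(sub, ft$age_months, make_age_bins("paper")))
  # value at the bin mean -> w = 0; one sigma above -> w = 1
  probe <- sub[1, ]
  b <- findInterval(ft$age_months[1], norms$bin_edges,
                    rightmost.closed = TRUE)
  probe[1, cc_measure_names()] <- as.list(norms$mu[b, ])
  w0 <- compute_w_scores(probe, ft$age_months[1], norms)
  expect_lt(max(abs(as.matrix(w0[, cc_measure_names()]))), 1e-10)
  probe[1, cc_measure_names()] <- as.list(norms$mu[b, ] + norms$sigma[b, ])
  w1 <- compute_w_scores(probe, ft$age_months[1], norms)
  expect_equal(unname(as.matrix(w1[, cc_measure_names()]))[1, ],
               rep(1, 33), tolerance = 1e-10)
})

test_that("FT subjects scored on their own norms give per-bin mean 0, SD 1", {
  cohort <- generate_cohort(cohort_spec(seed = 18))
  paired <- align_by_subject(cohort$clinical, cohort$structural)
  ft <- paired[paired$group == "FT", ]
  sub <- ft[, c("subject_id", cc_measure_names())]
  norms <- suppressWarnings(
    compute_bin_norms(sub, ft$age_months, make_age_bins("paper")))
  w <- compute_w_scores(sub, ft$age_months, norms)
  for (b in sort(unique(w$bin_index))) {
    wb <- as.matrix(w[w$bin_index == b, cc_measure_names()])
    expect_lt(max(abs(colMeans(wb))), 1e-8)
    expect_equal(unname(apply(wb, 2, sd)), rep(1, 33), tolerance = 1e-8)
  }
})

test_that("W-scores are invariant to joint affine transforms of a measure", {
  cohort <- generate_cohort(cohort_spec(seed = 19))
  paired <- align_by_subject(cohort$clinical, cohort$structural)
  ft <- paired[paired$group == "FT", c("subject_id", cc_measure_names())]
  vpt <- paired[paired$group == "VPT", c("subject_id", cc_measure_names())]
  ages_ft <- paired$age_months[paired$group == "FT"]
  ages_vpt <- paired$age_months[paired$group == "VPT"]
  norms <- suppressWarnings(
    compute_bin_norms(ft, ages_ft, make_age_bins("paper")))
  w <- compute_w_scores(vpt, ages_vpt, norms)
  # same affine map applied to FT and VPT volumes (units change)
  ft2 <- ft; vpt2 <- vpt
  ft2$volume_central <- 2.5 * ft2$volume_central + 10
  vpt2$volume_central <- 2.5 * vpt2$volume_central + 10
  norms2 <- suppressWarnings(
    compute_bin_norms(ft2, ages_ft, make_age_bins("paper")))
  w2 <- compute_w_scores(vpt2, ages_vpt, norms2)
  expect_equal(w2$volume_central, w$volume_central, tolerance = 1e-10)
})

test_that("ages outside the bins go to the nearest bin with a warning", {
  struct <- tiny_structural(4)
  norms <- suppressWarnings(compute_bin_norms(
    struct, c(80, 90, 130, 140), make_age_bins("equal", 72, 173, 2)))
  expect_warning(w <- compute_w_scores(struct[1, ], 60, norms), "nearest")
  expect_identical(w$bin_index, 1L)
  expect_warning(w2 <- compute_w_scores(struct[1, ], 190, norms), "nearest")
  expect_identical(w2$bin_index, 2L)
})

test_that("the LOESS basis gives an alternative, finite deviation map", {
  cohort <- generate_cohort(cohort_spec(seed = 20))
  paired <- align_by_subject(cohort$clinical, cohort$structural)
  ft <- paired[paired$group == "FT", c("subject_id", cc_measure_names())]
  vpt <- paired[paired$group == "VPT", c("subject_id", cc_measure_names())]
  norms <- suppressWarnings(fit_normative_model(
    ft, paired$age_months[paired$group == "FT"], span = 0.8, degree = 1))
  w <- compute_w_scores(vpt, paired$age_months[paired$group == "VPT"],
                        norms, basis = "loess")
  expect_true(all(is.finite(as.matrix(w[, cc_measure_names()]))))
  bare <- compute_bin_norms(ft, paired$age_months[paired$group == "FT"],
                            make_age_bins("paper")) |> suppressWarnings()
  expect_error(compute_w_scores(vpt, paired$age_months[paired$group == "VPT"],
                                bare, basis = "loess"), "loess")
})

test_that("VPT W-scores are centred under the null generator", {
  # 50 cohorts without planted deviation: per measure, the mean of the
  # per-cohort mean W-scores should sit within 3 SE of zero
  cohort_means <- sapply(1:50, function(s) {
    ch <- generate_cohort(cohort_spec(vpt_deviation_rate = 0, seed = 400 + s))
    paired <- align_by_subject(ch$clinical, ch$structural)
    ft <- paired[paired$group == "FT", ]
    vpt <- paired[paired$group == "VPT", ]
    norms <- suppressWarnings(compute_bin_norms(
      ft[, c("subject_id", cc_measure_names())], ft$age_months,
      make_age_bins("paper")))
    w <- compute_w_scores(vpt[, c("subject_id", cc_measure_names())],
                          vpt$age_months, norms)
    colMeans(as.matrix(w[, cc_measure_names()]))
  })
  grand <- rowMeans(cohort_means)
  se <- apply(cohort_means, 1, sd) / sqrt(50)
  expect_true(all(abs(grand) < 3 * se))
})
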