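# Cohort-based age-normative modelling: LOESS developmental trajectories
# fitted on the full-term group, age-bin norms, and W-score deviation maps
# for the very preterm group.

# -- LOESS smoother -----------------------------------------------------------
# Local polynomial regression with tricube weights over the ceil(span * n)
# nearest neighbours of each query point. Implemented directly (rather than
# through a generic smoother interface) so the span optimizer and the
# degenerate-design behaviour are fully specified.

tricube_weights <- function(d, d_max) {
  w <- (1 - pmin(d / d_max, 1)^3)^3
  w[d > d_max] <- 0
  w
}

loess_check <- function(x, y, span, degree) {
  n <- length(x)
  if (length(y) != n) stop("loess: x and y differ in length")
  if (n < degree + 2) stop("loess: need at least degree + 2 points")
  if (span < 0.05 || span > 1) stop("loess: span must lie in [0.05, 1]")
  k <- ceiling(span * n)
  if (k < degree + 1) {
    stop(sprintf(
      "loess: span %.4g keeps only %d neighbour(s); need >= %d for degree %d",
      span, k, degree + 1, degree))
  }
  min(k, n)
}

loess_point <- function(x, y, x0, k, degree) {
  d <- abs(x - x0)
  d_max <- sort(d, partial = k)[k]
  if (d_max == 0) return(mean(y[d == 0]))
  w <- tricube_weights(d, d_max)
  use <- w > 0
  Z <- outer(x[use] - x0, 0:degree, `^`)
  fit <- stats::lm.wfit(Z, y[use], w[use])
  cf <- fit$coefficients
  cf[1]  # design is centred at x0, so the intercept is the prediction
}

#' LOESS prediction at new ages
#'
#' Locally weighted polynomial regression: for each query point, a weighted
#' least-squares polynomial of the given degree is fitted over the
#' `ceiling(span * n)` nearest neighbours with tricube weights
#' `(1 - (d/d_max)^3)^3` and evaluated at the query point.
#'
#' @param x,y Training ages (months) and measure values.
#' @param span Fraction of points in each local fit, in \[0.05, 1\].
#' @param degree Local polynomial degree (2 by default, the convention for
#'   developmental trajectory fitting; 1 gives local linear fits).
#' @param x_new Ages to predict at (defaults to `x`).
#' @return Numeric vector of predictions at `x_new`.
#' @examples
#' x <- seq(72, 173, length.out = 20)
#' loess_predict(x, 0.5 + 0.001 * x, span = 0.75, degree = 1, x_new = c(100))
#' @export
loess_predict <- function(x, y, span, degree = 2, x_new = x) {
  k <- loess_check(x, y, span, degree)
  vapply(x_new, function(x0) loess_point(x, y, x0, k, degree), numeric(1))
}

fit_loess <- function(x, y, span, degree = 2) {
  fitted <- loess_predict(x, y, span, degree, x_new = x)
  structure(list(span = span, degree = degree, x = x, y = y,
                 fitted = fitted, sse = sum((y - fitted)^2),
                 resid_sd = stats::sd(y - fitted)),
            class = "loess_fit")
}

#' Optimize the LOESS span
#'
#' Selects the span minimizing the chosen objective over \[0.05, 1\] by
#' Brent's bounded scalar minimization (convergence tolerance 1e-4). The
#' default objective is the in-sample sum of squared errors; `"loocv"` uses
#' leave-one-out prediction SSE instead. When 5% of the points are too few
#' for the local polynomial, the lower bound is raised to the smallest
#' feasible span (with a message). A function `objective(span)` may also be
#' supplied directly. Because the built-in objectives depend on the span only
#' through the neighbour count, the Brent solution is refined by an exact
#' sweep over the attainable neighbour counts and the better point returned.
#'
#' @param x,y Ages and values.
#' @param degree Local polynomial degree.
#' @param objective `"sse"`, `"loocv"`, or a function of the span.
#' @return The optimized span (scalar in \[0.05, 1\]).
#' @export
optimize_span <- function(x, y, degree = 2, objective = c("sse", "loocv")) {
  n <- length(x)
  lower <- 0.05
  feasible <- (degree + 2) / n  # keep >= degree+1 points with positive weight
  if (feasible > lower) {
    lower <- min(feasible, 1)
    message(sprintf("optimize_span: lower bound raised to %.4g", lower))
  }
  if (is.function(objective)) {
    fn <- objective
  } else {
    objective <- match.arg(objective)
    fn <- switch(objective,
      sse = function(s) fit_loess(x, y, s, degree)$sse,
      loocv = function(s) {
        sum(vapply(seq_len(n), function(i) {
          (y[i] - loess_predict(x[-i], y[-i], s, degree, x_new = x[i]))^2
        }, numeric(1)))
      })
  }
  opt <- stats::optim(par = (lower + 1) / 2, fn = fn, method = "Brent",
                      lower = lower, upper = 1,
                      control = list(reltol = 1e-4))
  # The SSE/LOO objectives depend on the span only through the neighbour
  # count k = ceiling(span * n), i.e. they are step functions whose minimum
  # can sit at an isolated point of the interval; an exact sweep over the
  # attainable k values refines the Brent solution.
  cand <- unique(pmax(seq(ceiling(lower * n), n) / n, lower))
  cand_val <- vapply(cand, fn, numeric(1))
  if (min(cand_val) < opt$value) cand[which.min(cand_val)] else opt$par
}

# -- Age bins and norms -------------------------------------------------------

#' Age-bin boundaries for normative alignment
#'
#' In `"paper"` mode the four canonical developmental bins used to align the
#' FT and VPT groups over 72-173 months are returned: 72-96.5, 96.6-122,
#' 122.1-148 and 148.1-173 months. Bins are applied half-open (`[lo, hi)`,
#' last bin closed), which absorbs the 0.1-month gaps between the printed
#' interval edges. `"equal"` mode splits `[age_min, age_max]` into `n_bins`
#' equal-width bins.
#'
#' @param mode `"paper"` or `"equal"`.
#' @param age_min,age_max Age range in months (used by `"equal"` mode).
#' @param n_bins Number of equal-width bins.
#' @return Numeric vector of `n_bins + 1` bin edges.
#' @export
make_age_bins <- function(mode = c("paper", "equal"), age_min = 72,
                          age_max = 173, n_bins = 4) {
  mode <- match.arg(mode)
  if (mode == "paper") return(c(72, 96.6, 122.1, 148.1, 173))
  if (age_min >= age_max) stop("make_age_bins: age_min must be < age_max")
  if (n_bins < 1) stop("make_age_bins: n_bins must be >= 1")
  seq(age_min, age_max, length.out = n_bins + 1)
}

assign_bins <- function(ages, bin_edges, warn_outside = TRUE) {
  b <- findInterval(ages, bin_edges, rightmost.closed = TRUE)
  n_bins <- length(bin_edges) - 1L
  outside <- b < 1 | b > n_bins
  if (any(outside) && warn_outside) {
    warning(sprintf(
      "%d age(s) outside all bins were assigned to the nearest bin",
      sum(outside)), call. = FALSE)
  }
  pmin(pmax(b, 1L), n_bins)
}

#' Full-term age-bin norms
#'
#' For each age bin and each of the 33 structural measures, computes the
#' normative mean and standard deviation (denominator n - 1) from the
#' full-term group. Errors on bins with fewer than 2 subjects or zero SD;
#' warns on bins with fewer than 5 subjects.
#'
#' @param ft_structural Validated structural table of the FT group.
#' @param ft_ages FT ages in months, aligned with the table rows.
#' @param bin_edges Bin edges from [make_age_bins()].
#' @return An object of class `normative_model` with elements `bin_edges`,
#'   `mu`, `sigma` (bins x measures matrices), `n` (per-bin counts) and
#'   `loess` (`NULL`; see [fit_normative_model()]).
#' @export
compute_bin_norms <- function(ft_structural, ft_ages, bin_edges) {
  ft_structural <- validate_structural(ft_structural)
  measures <- cc_measure_names()
  if (length(ft_ages) != nrow(ft_structural)) {
    stop("ft_ages must match the structural table rows")
  }
  n_bins <- length(bin_edges) - 1
  b <- assign_bins(ft_ages, bin_edges)
  counts <- tabulate(b, nbins = n_bins)
  if (any(counts < 2)) {
    stop(sprintf("age bin(s) %s contain fewer than 2 full-term subjects",
                 paste(which(counts < 2), collapse = ", ")))
  }
  if (any(counts < 5)) {
    warning(sprintf("age bin(s) %s contain fewer than 5 full-term subjects",
                    paste(which(counts < 5), collapse = ", ")), call. = FALSE)
  }
  Ym <- as.matrix(ft_structural[, measures])
  mu <- matrix(NA_real_, n_bins, length(measures),
               dimnames = list(NULL, measures))
  sigma <- mu
  for (bb in seq_len(n_bins)) {
    rows <- Ym[b == bb, , drop = FALSE]
    mu[bb, ] <- colMeans(rows)
    sigma[bb, ] <- apply(rows, 2, stats::sd)
  }
  if (any(sigma <= 0)) {
    bad <- which(sigma <= 0, arr.ind = TRUE)
    stop(sprintf("zero normative SD in bin %d for measure %s",
                 bad[1, 1], measures[bad[1, 2]]))
  }
  structure(list(bin_edges = bin_edges, mu = mu, sigma = sigma, n = counts,
                 loess = NULL),
            class = "normative_model")
}

#' Fit the full normative model
#'
#' Combines the age-bin norms of [compute_bin_norms()] with a per-measure
#' LOESS developmental trajectory fitted on the full-term group (span chosen
#' per measure by [optimize_span()] unless given). The bin norms are what
#' W-scores use by default; the LOESS fits serve trajectory reporting and the
#' alternative `basis = "loess"` of [compute_w_scores()].
#'
#' @inheritParams compute_bin_norms
#' @param degree LOESS polynomial degree.
#' @param span A fixed span, or `NULL` to optimize per measure.
#' @param objective Span-selection objective, see [optimize_span()].
#' @return A `normative_model` whose `loess` element is a named list of
#'   per-measure LOESS fits.
#' @export
fit_normative_model <- function(ft_structural, ft_ages,
                                bin_edges = make_age_bins("paper"),
                                degree = 2, span = NULL,
                                objective = "sse") {
  norms <- compute_bin_norms(ft_structural, ft_ages, bin_edges)
  measures <- cc_measure_names()
  Ym <- as.matrix(validate_structural(ft_structural)[, measures])
  norms$loess <- lapply(stats::setNames(measures, measures), function(m) {
    s <- if (is.null(span)) {
      suppressMessages(optimize_span(ft_ages, Ym[, m], degree, objective))
    } else span
    fit_loess(ft_ages, Ym[, m], s, degree)
  })
  norms
}

#' @export
print.normative_model <- function(x, ...) {
  cat(sprintf("<normative_model> %d bins x %d measures; per-bin n: %s%s\n",
              nrow(x$mu), ncol(x$mu), paste(x$n, collapse = ", "),
              if (is.null(x$loess)) "" else "; LOESS trajectories fitted"))
  invisible(x)
}

# -- W-scores -----------------------------------------------------------------

#' W-score deviations from full-term norms
#'
#' For every subject and measure, the deviation from normative
#' neurodevelopment in normative-SD units:
#' `w = (value - mu_norm) / sigma_norm`, with the norm taken from the
#' subject's age bin (default) or from the LOESS trajectory evaluated at the
#' subject's age (with the SD of the FT trajectory residuals as scale).
#' Subjects whose age falls outside all bins are assigned to the nearest bin
#' with a warning, never dropped.
#'
#' @param structural Validated structural table of the scored (typically VPT)
#'   subjects.
#' @param ages Ages in months, aligned with the table rows.
#' @param norms A `normative_model`.
#' @param basis `"bins"` (age-bin norms) or `"loess"` (trajectory norms;
#'   requires a model from [fit_normative_model()]).
#' @return A tibble with `subject_id`, `age_months`, `bin_index` and the 33
#'   canonical measure columns holding W-scores.
#' @export
compute_w_scores <- function(structural, ages, norms,
                             basis = c("bins", "loess")) {
  basis <- match.arg(basis)
  structural <- validate_structural(structural)
  measures <- cc_measure_names()
  if (length(ages) != nrow(structural)) {
    stop("ages must match the structural table rows")
  }
  b <- assign_bins(ages, norms$bin_edges)
  Ym <- as.matrix(structural[, measures])
  if (basis == "bins") {
    W <- (Ym - norms$mu[b, , drop = FALSE]) / norms$sigma[b, , drop = FALSE]
  } else {
    if (is.null(norms$loess)) {
      stop("basis = 'loess' requires a model from fit_normative_model()")
    }
    W <- Ym
    for (m in measures) {
      f <- norms$loess[[m]]
      mu <- loess_predict(f$x, f$y, f$span, f$degree, x_new = ages)
      W[, m] <- (Ym[, m] - mu) / f$resid_sd
    }
  }
  if (!all(is.finite(W))) stop("non-finite W-scores produced")
  tibble::tibble(subject_id = structural$subject_id, age_months = ages,
                 bin_index = b, tibble::as_tibble(W))
}
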