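# Partial least squares correlation (PLSC) between a clinical block X and a
# structural block Y: SVD of the cross-correlation matrix, permutation
# testing of the singular values, and bootstrap stability of the loadings.

zscore_cols <- function(M, label) {
  s <- apply(M, 2, stats::sd)
  if (any(s == 0)) {
    stop(sprintf("%s: constant column(s) %s", label,
                 paste(colnames(M)[s == 0], collapse = ", ")))
  }
  scale(M, center = TRUE, scale = s)
}

as_xy <- function(X, Y) {
  if (inherits(X, "analysis_matrices")) {
    return(list(X = X$X, Y = X$Y))
  }
  list(X = as.matrix(X), Y = as.matrix(Y))
}

#' Fit a partial least squares correlation
#'
#' Columns of X and Y are z-scored (mean 0, SD 1, denominator n - 1), the
#' cross-correlation matrix `R = t(Xz) Yz / (n - 1)` is formed, and its full
#' singular value decomposition `R = U S t(V)` extracted. Each latent
#' component k pairs a clinical salience `U[, k]` with a structural salience
#' `V[, k]`; latent scores are the z-scored blocks projected on the
#' saliences, and loadings (structure coefficients) are the correlations of
#' the original columns with the latent scores, bounded in \[-1, 1\]. The
#' decomposition is made deterministic by forcing the largest-magnitude entry
#' of each clinical salience to be positive (the structural salience is
#' flipped jointly).
#'
#' @param X n x p clinical matrix, or an `analysis_matrices` object from
#'   [build_matrices()] (in which case `Y` is ignored).
#' @param Y n x q structural (or W-score) matrix.
#' @return An object of class `plsc_fit`: list with `singular_values` (length
#'   `K = min(p, q)`, non-increasing), `saliences_X`, `saliences_Y`,
#'   `latent_X`, `latent_Y`, `loadings_X`, `loadings_Y`, `R`, `n`.
#' @export
plsc_fit <- function(X, Y = NULL) {
  xy <- as_xy(X, Y)
  X <- xy$X; Y <- xy$Y
  n <- nrow(X)
  if (is.null(n) || n != nrow(Y)) stop("X and Y must have matching rows")
  if (n < 3) stop("plsc_fit: at least 3 subjects required")
  Xz <- zscore_cols(X, "X")
  Yz <- zscore_cols(Y, "Y")
  R <- crossprod(Xz, Yz) / (n - 1)
  K <- min(ncol(X), ncol(Y))
  sv <- svd(R, nu = K, nv = K)
  U <- sv$u
  V <- sv$v
  for (k in seq_len(K)) {  # deterministic orientation
    if (U[which.max(abs(U[, k])), k] < 0) {
      U[, k] <- -U[, k]
      V[, k] <- -V[, k]
    }
  }
  latent_X <- Xz %*% U
  latent_Y <- Yz %*% V
  comp <- paste0("LC", seq_len(K))
  dimnames(U) <- list(colnames(X), comp)
  dimnames(V) <- list(colnames(Y), comp)
  dimnames(latent_X) <- list(rownames(X), comp)
  dimnames(latent_Y) <- list(rownames(Y), comp)
  structure(list(
    singular_values = sv$d[seq_len(K)],
    saliences_X = U, saliences_Y = V,
    latent_X = latent_X, latent_Y = latent_Y,
    loadings_X = stats::cor(X, latent_X),
    loadings_Y = stats::cor(Y, latent_Y),
    R = R, n = n), class = "plsc_fit")
}

#' Permutation p-values for the singular values
#'
#' Rows of X are permuted (Y held fixed), the PLSC refitted, and the k-th
#' permuted singular value compared with the observed one. The p-value uses
#' the add-one convention `p_k = (1 + #\{S*_k >= S_k\}) / (1 + n_perm)`, so
#' the smallest attainable value at 1000 permutations is 1/1001 (printed as
#' 0.001); components are conventionally called significant at p < 0.01.
#'
#' @inheritParams plsc_fit
#' @param n_perm Number of permutations (1000 by default).
#' @param seed Integer seed for the permutation stream.
#' @return Numeric vector of K p-values in (0, 1\].
#' @export
permutation_pvalues <- function(X, Y = NULL, n_perm = 1000, seed = 1L) {
  xy <- as_xy(X, Y)
  if (n_perm < 1) stop("n_perm must be >= 1")
  fit <- plsc_fit(xy$X, xy$Y)
  K <- length(fit$singular_values)
  n <- fit$n
  Xz <- zscore_cols(xy$X, "X")
  Yz <- zscore_cols(xy$Y, "Y")
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old_seed <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  }
  set.seed(seed)
  count <- integer(K)
  for (b in seq_len(n_perm)) {
    perm <- sample.int(n)
    d <- svd(crossprod(Xz[perm, , drop = FALSE], Yz) / (n - 1),
             nu = 0, nv = 0)$d[seq_len(K)]
    count <- count + (d >= fit$singular_values)
  }
  (1 + count) / (1 + n_perm)
}

#' Bootstrap stability of the loadings
#'
#' Subjects are resampled with replacement jointly in X and Y and the PLSC
#' refitted per resample. Each resample's saliences are sign-aligned to the
#' original fit (component k is flipped, on both blocks jointly, when the dot
#' product of its clinical salience with the original is negative), and the
#' loadings recomputed on the resampled data. The bootstrap SD of each
#' loading yields a z-score (original loading / bootstrap SD) and a two-sided
#' normal-tail p-value. Resamples producing a constant column are redrawn (at
#' most 10 retries each). A zero bootstrap SD (perfect-association
#' degeneracy) reports `boot_z = Inf` and `boot_p = 0`.
#'
#' @inheritParams plsc_fit
#' @param n_boot Number of bootstrap resamples (500 by default).
#' @param seed Integer seed for the resampling stream.
#' @return List with `boot_mean_X`, `boot_mean_Y` (mean loadings over
#'   resamples), `boot_sd_X`, `boot_sd_Y`, `boot_z_X`, `boot_z_Y`,
#'   `boot_p_X`, `boot_p_Y`, and `n_redrawn`.
#' @export
bootstrap_loadings <- function(X, Y = NULL, n_boot = 500, seed = 1L) {
  xy <- as_xy(X, Y)
  X <- xy$X; Y <- xy$Y
  if (n_boot < 1) stop("n_boot must be >= 1")
  fit <- plsc_fit(X, Y)
  K <- length(fit$singular_values)
  n <- fit$n
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old_seed <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  }
  set.seed(seed)
  lx <- array(NA_real_, c(ncol(X), K, n_boot))
  ly <- array(NA_real_, c(ncol(Y), K, n_boot))
  n_redrawn <- 0L
  for (b in seq_len(n_boot)) {
    for (try in seq_len(11L)) {
      idx <- sample.int(n, replace = TRUE)
      Xb <- X[idx, , drop = FALSE]
      Yb <- Y[idx, , drop = FALSE]
      ok <- all(apply(Xb, 2, stats::sd) > 0) &&
        all(apply(Yb, 2, stats::sd) > 0)
      if (ok) break
      n_redrawn <- n_redrawn + 1L
      if (try == 11L) stop("bootstrap: constant column after 10 redraws")
    }
    fb <- plsc_fit(Xb, Yb)
    flip <- sign(colSums(fb$saliences_X * fit$saliences_X))
    flip[flip == 0] <- 1
    lb_x <- stats::cor(Xb, fb$latent_X %*% diag(flip, K))
    lb_y <- stats::cor(Yb, fb$latent_Y %*% diag(flip, K))
    lx[, , b] <- lb_x
    ly[, , b] <- lb_y
  }
  if (n_redrawn > 0) {
    message(sprintf("bootstrap_loadings: %d resample(s) redrawn", n_redrawn))
  }
  summarize <- function(arr, loadings) {
    bsd <- apply(arr, c(1, 2), stats::sd)
    degen <- bsd < 1e-12  # perfect-association degeneracy
    bz <- loadings / bsd
    bz[degen] <- Inf * sign(loadings[degen])
    bp <- 2 * stats::pnorm(-abs(bz))
    bp[degen] <- 0
    dimnames(bsd) <- dimnames(bz) <- dimnames(bp) <- dimnames(loadings)
    bmean <- apply(arr, c(1, 2), mean)
    dimnames(bmean) <- dimnames(loadings)
    list(mean = bmean, sd = bsd, z = bz, p = bp)
  }
  sx <- summarize(lx, fit$loadings_X)
  sy <- summarize(ly, fit$loadings_Y)
  list(boot_mean_X = sx$mean, boot_mean_Y = sy$mean,
       boot_sd_X = sx$sd, boot_sd_Y = sy$sd,
       boot_z_X = sx$z, boot_z_Y = sy$z,
       boot_p_X = sx$p, boot_p_Y = sy$p,
       n_redrawn = n_redrawn)
}

#' Robustness mask for loadings
#'
#' A loading is declared robust when its bootstrap p-value is below `alpha`
#' *and* its magnitude is at least `r_threshold` (the conventional
#' p < 0.01, |r| >= 0.4 rule for structure coefficients).
#'
#' @param loadings Matrix of loadings.
#' @param boot_p Matrix of bootstrap p-values, same shape.
#' @param alpha Stability level (default 0.01).
#' @param r_threshold Loading-magnitude threshold (default 0.4).
#' @return List of logical matrices: `robust`, `stable` (p rule only) and
#'   `large` (magnitude rule only).
#' @export
robust_mask <- function(loadings, boot_p, alpha = 0.01, r_threshold = 0.4) {
  if (!all(dim(loadings) == dim(boot_p))) {
    stop("robust_mask: shapes of loadings and boot_p disagree")
  }
  stable <- boot_p < alpha
  large <- abs(loadings) >= r_threshold
  list(robust = stable & large, stable = stable, large = large)
}

#' Full PLSC analysis
#'
#' Convenience wrapper running [plsc_fit()], [permutation_pvalues()],
#' [bootstrap_loadings()] and [robust_mask()] in one call.
#'
#' @inheritParams plsc_fit
#' @inheritParams permutation_pvalues
#' @inheritParams bootstrap_loadings
#' @inheritParams robust_mask
#' @return An object of class `plsc_result` extending the `plsc_fit` fields
#'   with `perm_p`, the bootstrap summaries, `robust_X`, `robust_Y`,
#'   `alpha`, `r_threshold`, `n_perm`, `n_boot` and `seed`.
#' @examples
#' \donttest{
#' cohort <- generate_cohort(cohort_spec(seed = 3))
#' am <- build_matrices(cohort$clinical, cohort$structural, group = "all")
#' res <- plsc(am, n_perm = 100, n_boot = 100, seed = 3)
#' res$perm_p[1]
#' }
#' @export
plsc <- function(X, Y = NULL, n_perm = 1000, n_boot = 500, seed = 1L,
                 alpha = 0.01, r_threshold = 0.4) {
  xy <- as_xy(X, Y)
  fit <- plsc_fit(xy$X, xy$Y)
  fit$perm_p <- permutation_pvalues(xy$X, xy$Y, n_perm = n_perm, seed = seed)
  boot <- bootstrap_loadings(xy$X, xy$Y, n_boot = n_boot, seed = seed + 1L)
  fit[names(boot)] <- boot
  fit$robust_X <- robust_mask(fit$loadings_X, boot$boot_p_X,
                              alpha, r_threshold)$robust
  fit$robust_Y <- robust_mask(fit$loadings_Y, boot$boot_p_Y,
                              alpha, r_threshold)$robust
  fit$alpha <- alpha
  fit$r_threshold <- r_threshold
  fit$n_perm <- n_perm
  fit$n_boot <- n_boot
  fit$seed <- seed
  class(fit) <- c("plsc_result", "plsc_fit")
  fit
}

#' @export
print.plsc_fit <- function(x, ...) {
  K <- length(x$singular_values)
  cat(sprintf("<%s> n=%d, K=%d components\n", class(x)[1], x$n, K))
  sv <- signif(x$singular_values, 3)
  if (!is.null(x$perm_p)) {
    cat("  singular values (perm p):",
        paste(sprintf("%s (%.3g)", sv, x$perm_p), collapse = ", "), "\n")
    cat(sprintf("  robust loadings on LC1: %d clinical, %d structural\n",
                sum(x$robust_X[, 1]), sum(x$robust_Y[, 1])))
  } else {
    cat("  singular values:", paste(sv, collapse = ", "), "\n")
  }
  invisible(x)
}
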