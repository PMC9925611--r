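# Run configuration, end-to-end pipeline driver and figure generation.

#' @importFrom ggplot2 ggplot aes geom_col geom_errorbar geom_point geom_line
#'   geom_vline labs theme_minimal scale_fill_manual facet_wrap
NULL

default_config <- function() {
  list(
    simulate = list(),          # cohort_spec() arguments; NULL to read files
    clinical_path = NULL,
    structural_path = NULL,
    group = "vpt",              # vpt | ft | all
    y_source = "measures",      # measures | wscores
    include_ses = FALSE,
    n_perm = 1000,
    n_boot = 500,
    bin_mode = "paper",
    n_bins = 4,
    wscore_basis = "bins",
    alpha = 0.01,
    r_threshold = 0.4,
    seed = NULL,
    out_dir = NULL,
    figures = TRUE)
}

normalize_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading a YAML config requires the 'yaml' package")
    }
    config <- yaml::read_yaml(config)
  }
  cfg <- utils::modifyList(default_config(), config)
  if (!is.null(cfg$clinical_path)) cfg$simulate <- NULL
  if (is.null(cfg$seed)) stop("config: 'seed' is mandatory")
  cfg$seed <- as.integer(cfg$seed)
  cfg$group <- match.arg(tolower(cfg$group), c("vpt", "ft", "all"))
  cfg$y_source <- match.arg(cfg$y_source, c("measures", "wscores"))
  if (cfg$y_source == "wscores" && cfg$group != "vpt") {
    stop("config: W-scores are defined for the VPT group against FT norms; ",
         "use group = 'vpt'")
  }
  if (cfg$n_perm < 100 || cfg$n_boot < 100) {
    warning("config: n_perm/n_boot below 100 give coarse inference",
            call. = FALSE)
  }
  if (is.null(cfg$out_dir)) stop("config: 'out_dir' is required")
  cfg
}

#' Run the full analysis pipeline
#'
#' Executes the configured chain: cohort input (simulated via
#' [generate_cohort()] or loaded from CSV) -> baseline descriptives ->
#' optional normative modelling and W-scores -> PLSC with permutation and
#' bootstrap inference -> tables, figures and a JSON summary. Identical
#' configuration and seed produce a byte-identical JSON summary. On error,
#' files already written by the failing run are removed and the stage name is
#' reported.
#'
#' @param config A named list, or path to a YAML file, overriding the
#'   defaults: `simulate` ([cohort_spec()] arguments, or `NULL` with
#'   `clinical_path`/`structural_path` to read files), `group`
#'   (`vpt|ft|all`), `y_source` (`measures|wscores`), `include_ses`,
#'   `n_perm`, `n_boot`, `bin_mode`, `n_bins`, `wscore_basis`, `alpha`,
#'   `r_threshold`, `seed` (mandatory), `out_dir` (mandatory), `figures`.
#' @return Invisibly, a list with the `plsc_result`, the cohort tables, the
#'   normative model (if fitted), the summary list and the output paths.
#' @export
run_pipeline <- function(config) {
  cfg <- normalize_config(config)
  if (!dir.exists(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  }
  written <- character(0)
  log_lines <- character(0)
  note <- function(...) {
    log_lines <<- c(log_lines, sprintf(...))
    message(sprintf(...))
  }
  out <- function(...) {
    p <- file.path(cfg$out_dir, ...)
    written <<- c(written, p)
    p
  }
  stage <- "setup"
  result <- tryCatch({
    # -- input ----------------------------------------------------------
    stage <- "input"
    if (!is.null(cfg$simulate)) {
      spec <- do.call(cohort_spec,
                      utils::modifyList(list(seed = cfg$seed), cfg$simulate))
      cohort <- generate_cohort(spec)
      note("simulated cohort: %d FT + %d VPT subjects (seed %d)",
           spec$n_ft, spec$n_vpt, spec$seed)
      write_cohort(cohort$clinical, cohort$structural, cfg$out_dir)
      written <- c(written, file.path(cfg$out_dir,
                                      c("clinical.csv", "structural.csv")))
      truth <- planted_truth(spec, group = cfg$group)
      jsonlite::write_json(truth, out("truth.json"), auto_unbox = TRUE,
                           digits = NA)
    } else {
      cohort <- load_cohort(cfg$clinical_path, cfg$structural_path)
      note("loaded cohort: %d clinical, %d structural rows",
           nrow(cohort$clinical), nrow(cohort$structural))
    }

    # -- descriptives ---------------------------------------------------
    stage <- "descriptives"
    readr::write_csv(cohort_summary(cohort$clinical), out("table1.csv"),
                     progress = FALSE)

    # -- normative modelling --------------------------------------------
    stage <- "normative"
    norms <- NULL
    wsc <- NULL
    if (cfg$y_source == "wscores") {
      paired <- align_by_subject(cohort$clinical, cohort$structural)
      ft <- paired[paired$group == "FT", ]
      vpt <- paired[paired$group == "VPT", ]
      edges <- if (cfg$bin_mode == "paper") make_age_bins("paper") else
        make_age_bins("equal", min(ft$age_months), max(ft$age_months),
                      cfg$n_bins)
      norms <- fit_normative_model(
        ft[, c("subject_id", cc_measure_names())], ft$age_months, edges)
      norm_tab <- tidyr::pivot_longer(
        dplyr::bind_cols(
          tibble::tibble(bin = seq_along(norms$n), n = norms$n),
          tibble::as_tibble(norms$mu)),
        -c("bin", "n"), names_to = "measure", values_to = "mu")
      norm_tab$sigma <- as.vector(t(norms$sigma))
      readr::write_csv(norm_tab, out("norms.csv"), progress = FALSE)
      wsc <- compute_w_scores(vpt[, c("subject_id", cc_measure_names())],
                              vpt$age_months, norms,
                              basis = cfg$wscore_basis)
      readr::write_csv(wsc, out("wscores.csv"), progress = FALSE)
      note("normative model: %d bins, per-bin n = %s", length(norms$n),
           paste(norms$n, collapse = "/"))
    }

    # -- PLSC -----------------------------------------------------------
    stage <- "plsc"
    group_arg <- c(vpt = "VPT", ft = "FT", all = "all")[[cfg$group]]
    am <- build_matrices(cohort$clinical, cohort$structural,
                         group = group_arg, include_ses = cfg$include_ses,
                         y = wsc)
    res <- plsc(am, n_perm = cfg$n_perm, n_boot = cfg$n_boot,
                seed = cfg$seed, alpha = cfg$alpha,
                r_threshold = cfg$r_threshold)
    note("PLSC: K = %d components; LC1 singular value %.4g (p = %.4g)",
         length(res$singular_values), res$singular_values[1], res$perm_p[1])

    # -- tables + summary ----------------------------------------------
    stage <- "report"
    load_tab <- dplyr::bind_rows(
      loading_table(res, "clinical"),
      loading_table(res, "structural"))
    readr::write_csv(load_tab, out("plsc_loadings.csv"), progress = FALSE)
    summary <- list(
      config = cfg[c("group", "y_source", "include_ses", "n_perm", "n_boot",
                     "bin_mode", "wscore_basis", "alpha", "r_threshold",
                     "seed")],
      n = res$n,
      K = length(res$singular_values),
      singular_values = res$singular_values,
      perm_p = res$perm_p,
      robust_clinical = rownames(res$robust_X)[res$robust_X[, 1]],
      robust_structural = rownames(res$robust_Y)[res$robust_Y[, 1]])
    jsonlite::write_json(summary, out("plsc_summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)

    # -- figures --------------------------------------------------------
    if (isTRUE(cfg$figures)) {
      stage <- "figures"
      fig_dir <- file.path(cfg$out_dir, "figures")
      dir.create(fig_dir, showWarnings = FALSE)
      save_fig <- function(name, plot, width = 6, height = 5) {
        p <- file.path(fig_dir, name)
        written <<- c(written, p)
        ggplot2::ggsave(p, plot, device = grDevices::png, dpi = 100,
                        width = width, height = height)
      }
      save_fig("loadings_clinical.png", plot_loadings(res, 1, "clinical"))
      save_fig("loadings_structural.png",
               plot_loadings(res, 1, "structural"), height = 7)
      save_fig("latent_scores.png", plot_latent_scores(res, 1))
      if (!is.null(norms)) {
        save_fig("trajectory_fa_cc7.png", plot_trajectory(norms, "fa_cc7"))
      }
    }
    list(result = res, cohort = cohort, norms = norms, wscores = wsc,
         summary = summary, matrices = am)
  }, error = function(e) {
    unlink(written)
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  log_lines <- c(log_lines,
                 sprintf("seed: %d (permutations), %d (bootstrap)",
                         cfg$seed, cfg$seed + 1L))
  writeLines(log_lines, file.path(cfg$out_dir, "run.log"))
  invisible(c(result, list(out_dir = cfg$out_dir)))
}

loading_table <- function(result, block = c("clinical", "structural")) {
  block <- match.arg(block)
  L <- if (block == "clinical") result$loadings_X else result$loadings_Y
  sd <- if (block == "clinical") result$boot_sd_X else result$boot_sd_Y
  bm <- if (block == "clinical") result$boot_mean_X else result$boot_mean_Y
  rb <- if (block == "clinical") result$robust_X else result$robust_Y
  K <- ncol(L)
  dplyr::bind_rows(lapply(seq_len(K), function(k) {
    tibble::tibble(block = block, component = k, variable = rownames(L),
                   loading = L[, k], boot_mean = bm[, k], boot_sd = sd[, k],
                   robust = rb[, k])
  }))
}

#' Diverging loading plot
#'
#' Horizontal diverging bar chart of one component's loadings: bootstrap-mean
#' correlations with bootstrap-SD error bars, robust loadings highlighted.
#' Structural loadings are grouped by measure family. When the component's
#' permutation p-value is not below `alpha`, the subtitle flags it.
#'
#' @param result A `plsc_result` from [plsc()].
#' @param component Component index (<= K).
#' @param block `"clinical"` or `"structural"`.
#' @return A ggplot object.
#' @export
plot_loadings <- function(result, component = 1,
                          block = c("clinical", "structural")) {
  block <- match.arg(block)
  K <- length(result$singular_values)
  if (component < 1 || component > K) {
    stop(sprintf("component %d out of range (K = %d)", component, K))
  }
  tab <- loading_table(result, block)
  tab <- tab[tab$component == component, ]
  tab$variable <- factor(tab$variable, levels = rev(tab$variable))
  if (block == "structural") {
    fam <- cc_measure_families()
    tab$family <- factor(fam[as.character(tab$variable)],
                         levels = c("volume", "fa", "md", "ndi", "odi"))
  }
  subtitle <- if (!is.null(result$perm_p) &&
                  result$perm_p[component] >= result$alpha) {
    sprintf("p >= %.3g: component not significant", result$alpha)
  } else NULL
  p <- ggplot(tab, aes(x = .data$boot_mean, y = .data$variable,
                       fill = .data$robust)) +
    geom_col(orientation = "y") +
    geom_errorbar(aes(xmin = .data$boot_mean - .data$boot_sd,
                      xmax = .data$boot_mean + .data$boot_sd),
                  width = 0.3, orientation = "y") +
    geom_vline(xintercept = 0, linewidth = 0.3) +
    scale_fill_manual(values = c(`TRUE` = "#2166ac", `FALSE` = "grey70"),
                      limits = c("TRUE", "FALSE")) +
    labs(x = "bootstrap-mean loading ± bootstrap SD", y = NULL,
         title = sprintf("%s loadings, component %d", block, component),
         subtitle = subtitle, fill = "robust") +
    theme_minimal()
  if (block == "structural") {
    p <- p + facet_wrap(~family, scales = "free_y", ncol = 1)
  }
  p
}

#' Latent-score correlation plot
#'
#' Scatter of the clinical vs structural latent scores of one component (the
#' composite-score association the component expresses).
#'
#' @inheritParams plot_loadings
#' @return A ggplot object.
#' @export
plot_latent_scores <- function(result, component = 1) {
  K <- length(result$singular_values)
  if (component < 1 || component > K) {
    stop(sprintf("component %d out of range (K = %d)", component, K))
  }
  tab <- tibble::tibble(lx = result$latent_X[, component],
                        ly = result$latent_Y[, component])
  r <- stats::cor(tab$lx, tab$ly)
  ggplot(tab, aes(.data$lx, .data$ly)) +
    geom_point(colour = "#2166ac") +
    labs(x = "clinical latent score", y = "structural latent score",
         title = sprintf("component %d latent scores (r = %.2f)",
                         component, r)) +
    theme_minimal()
}

#' Normative trajectory plot
#'
#' FT data points of one measure with the fitted LOESS developmental
#' trajectory and the age-bin normative means.
#'
#' @param norms A `normative_model` from [fit_normative_model()].
#' @param measure One of [cc_measure_names()].
#' @return A ggplot object.
#' @export
plot_trajectory <- function(norms, measure) {
  if (is.null(norms$loess) || !measure %in% names(norms$loess)) {
    stop(sprintf("no LOESS trajectory stored for measure '%s'", measure))
  }
  f <- norms$loess[[measure]]
  grid <- seq(min(f$x), max(f$x), length.out = 100)
  line <- tibble::tibble(
    age = grid, fit = loess_predict(f$x, f$y, f$span, f$degree, grid))
  pts <- tibble::tibble(age = f$x, value = f$y)
  edges <- norms$bin_edges
  bins <- tibble::tibble(
    age = (utils::head(edges, -1) + utils::tail(edges, -1)) / 2,
    mu = norms$mu[, measure])
  ggplot(pts, aes(.data$age, .data$value)) +
    geom_point(colour = "goldenrod3") +
    geom_line(data = line, aes(.data$age, .data$fit), colour = "#2166ac") +
    geom_point(data = bins, aes(.data$age, .data$mu), shape = 15, size = 3) +
    geom_vline(xintercept = edges, linetype = "dotted", colour = "grey60") +
    labs(x = "age (months)", y = measure,
         title = sprintf("full-term normative trajectory: %s (span %.2f)",
                         measure, f$span)) +
    theme_minimal()
}
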