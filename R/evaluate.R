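#' The missingness scenario grid
#'
#' Expands the full study design: every proportion crossed with MCAR (no
#' strength) and each MAR and MNAR strength. The default grid is 4
#' proportions x (1 + 3 + 3) mechanism configurations = 28 cells; applying
#' all five strategies to each yields 140 scenario cells.
#'
#' @param proportions fractions of participant-days masked.
#' @param mar_strengths logistic slopes on SOFA under MAR.
#' @param mnar_strengths logistic slopes on delirium under MNAR.
#' @param mechanisms subset of `c("MCAR", "MAR", "MNAR")`.
#' @return data.frame with columns `config_id`, `mechanism`, `strength`
#'   (NA for MCAR), `proportion`.
#' @export
scenario_grid <- function(proportions = c(0.01, 0.05, 0.20, 0.35),
                          mar_strengths = c(0.01, 0.1, 0.2),
                          mnar_strengths = c(0.1, 0.5, 1.0),
                          mechanisms = c("MCAR", "MAR", "MNAR")) {
  mechanisms <- match.arg(mechanisms, several.ok = TRUE)
  rows <- list()
  if ("MCAR" %in% mechanisms) {
    rows <- c(rows, list(data.frame(mechanism = "MCAR", strength = NA_real_)))
  }
  if ("MAR" %in% mechanisms) {
    rows <- c(rows, list(data.frame(mechanism = "MAR", strength = mar_strengths)))
  }
  if ("MNAR" %in% mechanisms) {
    rows <- c(rows, list(data.frame(mechanism = "MNAR", strength = mnar_strengths)))
  }
  mech <- do.call(rbind, rows)
  grid <- merge(data.frame(proportion = proportions), mech, by = NULL)
  grid <- grid[order(match(grid$mechanism, c("MCAR", "MAR", "MNAR")),
                     grid$strength, grid$proportion), ]
  grid <- data.frame(config_id = seq_len(nrow(grid)),
                     mechanism = grid$mechanism,
                     strength = grid$strength,
                     proportion = grid$proportion,
                     row.names = NULL)
  grid
}

all_strategies <- c("complete_case", "adhoc_worst", "adhoc_best",
                    "passive_mi", "active_mi")

#' Run one simulation replicate
#'
#' The per-replicate pipeline: cluster-resample `n_participants` from the
#' base cohort, generate the outcome from the true durations, calibrate and
#' impose the scenario's missingness, then apply the requested strategies.
#' Deterministic given `(seed, config_id, replicate)`. The cohort draw and
#' outcome depend only on `(seed, replicate)`, so replicates are paired
#' across scenario cells (same data, different masking), which sharpens
#' between-scenario and between-strategy comparisons.
#'
#' @param base a fully observed base `cohort`.
#' @param mechanism,strength,proportion the scenario cell (see
#'   [scenario_grid()]); `proportion = 0` is allowed for testing and imposes
#'   no missingness.
#' @param replicate integer replicate index.
#' @param seed master integer seed.
#' @param n_participants sample size per replicate.
#' @param beta_del,intercept,resid_sd outcome-model parameters.
#' @param strategies character vector of strategies to apply.
#' @param B imputations for the MI strategies.
#' @param config_id integer distinguishing scenario cells in the seed
#'   stream.
#' @param predictors,active_method passed to [fit_strategy()].
#' @return named list of `strategy_fit` objects.
#' @export
run_replicate <- function(base, mechanism, strength, proportion, replicate,
                          seed, n_participants = 200, beta_del = -1,
                          intercept = 80, resid_sd = 12,
                          strategies = all_strategies, B = 10, config_id = 1L,
                          predictors = c("sofa", "outcome"),
                          active_method = "norm") {
  coh <- cluster_resample(base, n_participants,
                          seed = derive_seed(seed, 1L, replicate))
  coh <- generate_outcome(coh, intercept = intercept, beta_del = beta_del,
                          resid_sd = resid_sd,
                          seed = derive_seed(seed, 2L, replicate))
  if (proportion > 0) {
    spec <- missingness_spec(mechanism, proportion,
                             strength = if (mechanism == "MCAR") NULL else strength)
    spec <- calibrate_alpha(spec, coh)
    coh <- impose_missingness(
      coh, spec, seed = derive_seed(seed, 100L + config_id, replicate))
  }
  fits <- lapply(seq_along(strategies), function(i) {
    fit_strategy(coh, strategies[i], B = B,
                 seed = derive_seed(seed, 1000L * config_id + i, replicate),
                 predictors = predictors, active_method = active_method)
  })
  stats::setNames(fits, strategies)
}

#' Monte-Carlo performance metrics for one strategy in one scenario
#'
#' Over the estimable replicates: `bias = mean(beta_hat) - beta_true`,
#' `mean_se = mean(se)`, `coverage` = fraction of t-based confidence
#' intervals (each at its own df) containing `beta_true`, and the
#' Monte-Carlo standard error of the bias, `sd(beta_hat)/sqrt(n_estimable)`.
#'
#' @param fits list of `strategy_fit` objects (one per replicate).
#' @param beta_true generating slope.
#' @param ci_level nominal confidence level (default 0.95).
#' @return one-row data.frame (`ScenarioSummary`); when no replicate is
#'   estimable the metric columns are NA and `n_estimable` is 0.
#' @export
compute_metrics <- function(fits, beta_true, ci_level = 0.95) {
  if (length(fits) < 1) stop("no replicates supplied")
  ok <- vapply(fits, function(f) isTRUE(f$estimable), logical(1))
  n_est <- sum(ok)
  if (n_est == 0) {
    return(data.frame(strategy = fits[[1]]$strategy, bias = NA_real_,
                      mean_se = NA_real_, coverage = NA_real_,
                      mc_error_bias = NA_real_, n_estimable = 0L,
                      n_replicates = length(fits)))
  }
  beta <- vapply(fits[ok], `[[`, numeric(1), "beta_hat")
  se <- vapply(fits[ok], `[[`, numeric(1), "se")
  df <- vapply(fits[ok], `[[`, numeric(1), "df")
  tcrit <- stats::qt(1 - (1 - ci_level) / 2, df = df)
  covered <- abs(beta - beta_true) <= tcrit * se
  data.frame(
    strategy = fits[[1]]$strategy,
    bias = mean(beta) - beta_true,
    mean_se = mean(se),
    coverage = mean(covered),
    mc_error_bias = stats::sd(beta) / sqrt(n_est),
    n_estimable = n_est,
    n_replicates = length(fits)
  )
}

#' Run a scenario cell: replicate loop plus metrics
#'
#' @inheritParams run_replicate
#' @param n_replicates number of Monte-Carlo replicates.
#' @param ci_level nominal confidence level.
#' @return data.frame with one row per strategy (bias, mean SE, coverage,
#'   Monte-Carlo error, estimable counts).
#' @export
run_scenario <- function(base, mechanism, strength, proportion,
                         n_replicates = 200, seed = 1, n_participants = 200,
                         beta_del = -1, intercept = 80, resid_sd = 12,
                         strategies = all_strategies, B = 10, config_id = 1L,
                         ci_level = 0.95, predictors = c("sofa", "outcome"),
                         active_method = "norm") {
  reps <- lapply(seq_len(n_replicates), function(r) {
    run_replicate(base, mechanism, strength, proportion, r, seed,
                  n_participants = n_participants, beta_del = beta_del,
                  intercept = intercept, resid_sd = resid_sd,
                  strategies = strategies, B = B, config_id = config_id,
                  predictors = predictors, active_method = active_method)
  })
  out <- do.call(rbind, lapply(strategies, function(s) {
    compute_metrics(lapply(reps, `[[`, s), beta_true = beta_del,
                    ci_level = ci_level)
  }))
  cbind(data.frame(config_id = config_id, mechanism = mechanism,
                   strength = strength, proportion = proportion), out)
}

#' Run the full scenario-by-strategy simulation grid
#'
#' Expands the missingness grid (default: the full 28-configuration design),
#' runs every cell, and returns the long results table — one row per
#' (configuration, strategy), 140 rows for the default design with all five
#' strategies. Optionally writes the table as CSV together with a JSON run
#' manifest (seed, parameters, package version).
#'
#' @param base a fully observed base `cohort`; built from
#'   `base_params` when omitted.
#' @param grid a [scenario_grid()] data.frame.
#' @param n_replicates Monte-Carlo replicates per cell (the full study design
#'   uses 1000; the default here is 200 with Monte-Carlo error reported
#'   alongside every metric).
#' @param seed master integer seed.
#' @param base_params [base_cohort_params()] used when `base` is missing.
#' @param out_csv,out_manifest optional output paths.
#' @param verbose print per-cell progress to stderr.
#' @inheritParams run_scenario
#' @return the results data.frame, invisibly carrying the manifest as
#'   attribute `"manifest"`.
#' @export
run_grid <- function(base = NULL, grid = scenario_grid(), n_replicates = 200,
                     seed = 1, n_participants = 200, beta_del = -1,
                     intercept = 80, resid_sd = 12,
                     strategies = all_strategies, B = 10, ci_level = 0.95,
                     base_params = base_cohort_params(),
                     predictors = c("sofa", "outcome"),
                     active_method = "norm",
                     out_csv = NULL, out_manifest = NULL, verbose = FALSE) {
  if (is.null(base)) {
    base <- generate_base_cohort(base_params, seed = derive_seed(seed, 0L))
  }
  res <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    if (verbose) {
      message(sprintf("[%d/%d] %s p=%.2f strength=%s", i, nrow(grid),
                      g$mechanism, g$proportion,
                      ifelse(is.na(g$strength), "-", g$strength)))
    }
    res[[i]] <- run_scenario(base, g$mechanism, g$strength, g$proportion,
                             n_replicates = n_replicates, seed = seed,
                             n_participants = n_participants,
                             beta_del = beta_del, intercept = intercept,
                             resid_sd = resid_sd, strategies = strategies,
                             B = B, config_id = g$config_id,
                             ci_level = ci_level, predictors = predictors,
                             active_method = active_method)
  }
  res <- do.call(rbind, res)
  rownames(res) <- NULL
  manifest <- list(
    seed = seed, n_replicates = n_replicates, n_participants = n_participants,
    beta_del = beta_del, intercept = intercept, resid_sd = resid_sd,
    B = B, ci_level = ci_level, strategies = strategies,
    n_configs = nrow(grid), n_cells = nrow(res),
    package_version = as.character(utils::packageVersion("delmi"))
  )
  attr(res, "manifest") <- manifest
  if (!is.null(out_csv)) utils::write.csv(res, out_csv, row.names = FALSE)
  if (!is.null(out_manifest)) {
    jsonlite::write_json(manifest, out_manifest, auto_unbox = TRUE,
                         pretty = TRUE)
  }
  invisible(res)
}

#' Panel plots of grid results
#'
#' Base-graphics panels of one metric against the proportion of missingness,
#' one panel per mechanism/strength configuration, one line per strategy —
#' the conventional way these simulation studies are displayed.
#'
#' @param res a [run_grid()] results data.frame.
#' @param metric `"bias"`, `"mean_se"` or `"coverage"`.
#' @param ... passed to [graphics::matplot()].
#' @export
plot_grid_results <- function(res, metric = c("coverage", "bias", "mean_se"),
                              ...) {
  metric <- match.arg(metric)
  res$panel <- ifelse(is.na(res$strength), res$mechanism,
                      sprintf("%s (%.2g)", res$mechanism, res$strength))
  panels <- unique(res$panel)
  strategies <- unique(res$strategy)
  old <- graphics::par(mfrow = grDevices::n2mfrow(length(panels)),
                       mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  for (p in panels) {
    sub <- res[res$panel == p, ]
    props <- sort(unique(sub$proportion))
    m <- sapply(strategies, function(s) {
      ss <- sub[sub$strategy == s, ]
      ss[[metric]][match(props, ss$proportion)]
    })
    graphics::matplot(props, m, type = "b", pch = 1:5, lty = 1,
                      xlab = "proportion missing", ylab = metric, main = p,
                      ...)
    if (metric == "coverage") graphics::abline(h = 0.95, col = "grey40")
  }
  graphics::legend("bottomleft", legend = strategies, pch = 1:5, lty = 1,
                   col = seq_along(strategies), bty = "n", cex = 0.7)
  invisible(res)
}

#' Read a YAML run configuration
#'
#' Configuration keys mirror [run_grid()]'s arguments (`seed`,
#' `n_replicates`, `n_participants`, `B`, `ci_level`, `beta_del`,
#' `intercept`, `resid_sd`, `strategies`, plus a `base_params` block and a
#' `grid` block with `proportions`, `mar_strengths`, `mnar_strengths`,
#' `mechanisms`).
#'
#' @param path YAML file.
#' @return a list with `grid`, `base_params`, and the scalar arguments.
#' @export
read_run_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the yaml package is required to read run configurations")
  }
  cfg <- yaml::read_yaml(path)
  grid_args <- cfg$grid %||% list()
  bp_args <- cfg$base_params %||% list()
  list(
    grid = do.call(scenario_grid, grid_args),
    base_params = do.call(base_cohort_params, bp_args),
    args = cfg[setdiff(names(cfg), c("grid", "base_params"))]
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
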