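#' Fit the analysis model: unadjusted OLS of outcome on duration
#'
#' The analysis model is `outcome_i = alpha + beta_del * duration_i + eps_i`,
#' deliberately unadjusted so strategy comparisons isolate the handling of
#' missing assessments. Fit by [stats::lm()]; the slope, its standard error,
#' and residual degrees of freedom `n - 2` are extracted.
#'
#' @param tab data.frame with numeric columns `duration` and `outcome`
#'   (rows with NA duration or outcome are dropped).
#' @return a list with `beta_hat`, `se`, `df`, `n_used`.
#' @keywords internal
fit_analysis_model <- function(tab) {
  keep <- !is.na(tab$duration) & !is.na(tab$outcome)
  tab <- tab[keep, , drop = FALSE]
  n <- nrow(tab)
  if (n < 3) stop("analysis model needs at least 3 participants, got ", n)
  if (stats::var(tab$duration) == 0) {
    stop("duration is constant; slope not identifiable")
  }
  fit <- stats::lm(outcome ~ duration, data = tab)
  sfit <- suppressWarnings(summary(fit)) # silences lm's own perfect-fit notice
  se <- sfit$coefficients["duration", "Std. Error"]
  if (!is.finite(se) || se == 0 || isTRUE(all.equal(sfit$sigma, 0))) {
    warning("perfect fit: standard error reported as 0")
    se <- 0
  }
  list(beta_hat = unname(stats::coef(fit)["duration"]), se = unname(se),
       df = fit$df.residual, n_used = n)
}

# --- strategy_fit: the classed estimate object ------------------------------

new_strategy_fit <- function(strategy, beta_hat = NA_real_, se = NA_real_,
                             df = NA_real_, n_used = NA_integer_, B = 0L,
                             pooling = NULL, estimable = TRUE, message = NULL) {
  structure(list(strategy = strategy, beta_hat = beta_hat, se = se, df = df,
                 n_used = n_used, B = B, pooling = pooling,
                 estimable = estimable, message = message),
            class = "strategy_fit")
}

non_estimable <- function(strategy, message) {
  new_strategy_fit(strategy, estimable = FALSE, message = message)
}

#' Estimate the duration-outcome association under one missing-data strategy
#'
#' The single fitting entry point. Applies one of five strategies to a cohort
#' whose daily assessments may be missing, then fits the unadjusted linear
#' analysis model of outcome on delirium duration:
#' \describe{
#'   \item{`complete_case`}{drop every participant with any missing day.}
#'   \item{`adhoc_worst` / `adhoc_best`}{deterministically substitute missing
#'     days with delirium present / absent.}
#'   \item{`passive_mi`}{impute the daily assessments B times (logistic
#'     imputation model on daily SOFA and the participant outcome), compute
#'     the duration in each completed dataset, fit the analysis model, and
#'     pool with Rubin's rules ("impute then transform").}
#'   \item{`active_mi`}{impute the participant-level duration itself B times
#'     (Bayesian normal linear model on mean SOFA and the outcome), ignoring
#'     the observed daily assessments of participants with any missing day
#'     ("just another variable").}
#' }
#'
#' @param x a `cohort` with outcomes attached.
#' @param strategy strategy name.
#' @param B number of imputations for the MI strategies (>= 2); ignored
#'   otherwise.
#' @param seed optional integer seed for the stochastic strategies.
#' @param predictors imputation-model predictors for `passive_mi`:
#'   `c("sofa", "outcome")` (default, standard practice: the imputation model
#'   contains the analysis model's variables) or `"sofa"` alone.
#' @param active_method `"norm"` (Bayesian normal linear imputation with
#'   round-and-clip, default) or `"pmm"` (predictive mean matching, 5
#'   donors).
#' @return an object of class `strategy_fit` with the slope `beta_hat`, its
#'   `se`, the degrees of freedom `df` used for the CI (Rubin df for MI,
#'   `n - 2` otherwise), `n_used`, and for MI strategies the full
#'   `rubins_pool` result. A strategy that cannot be applied (e.g. fewer
#'   than 3 complete participants) returns a non-estimable fit rather than
#'   erroring, so simulation grids can tally such replicates.
#' @export
#' @examples
#' base <- generate_base_cohort(base_cohort_params(n_base = 300), seed = 1)
#' coh <- generate_outcome(cluster_resample(base, 200, seed = 2), seed = 3)
#' spec <- calibrate_alpha(missingness_spec("MAR", 0.2, 0.1), coh)
#' coh <- impose_missingness(coh, spec, seed = 4)
#' fit_strategy(coh, "passive_mi", B = 10, seed = 5)
fit_strategy <- function(x,
                         strategy = c("complete_case", "adhoc_worst",
                                      "adhoc_best", "passive_mi", "active_mi"),
                         B = 10, seed = NULL,
                         predictors = c("sofa", "outcome"),
                         active_method = c("norm", "pmm")) {
  strategy <- match.arg(strategy)
  stopifnot(inherits(x, "cohort"))
  switch(strategy,
    complete_case = complete_case(x),
    adhoc_worst = adhoc_impute(x, "worst"),
    adhoc_best = adhoc_impute(x, "best"),
    passive_mi = passive_mi(x, B = B, seed = seed, predictors = predictors),
    active_mi = active_mi(x, B = B, seed = seed,
                          method = match.arg(active_method))
  )
}

#' Complete-case analysis
#'
#' Excludes every participant with one or more missing daily assessments
#' (their duration is undefined) and fits the analysis model on the rest.
#'
#' @param x a `cohort`.
#' @return a `strategy_fit`; non-estimable if fewer than 3 complete
#'   participants remain.
#' @export
complete_case <- function(x) {
  tab <- compute_durations(x)
  n_complete <- sum(!is.na(tab$duration))
  if (n_complete < 3) {
    return(non_estimable("complete_case",
                         sprintf("only %d complete participants", n_complete)))
  }
  est <- tryCatch(fit_analysis_model(tab), error = function(e) NULL)
  if (is.null(est)) {
    return(non_estimable("complete_case", "analysis model not identifiable"))
  }
  new_strategy_fit("complete_case", est$beta_hat, est$se, est$df, est$n_used)
}

#' Ad hoc worst/best-case substitution
#'
#' Sets every missing daily assessment to delirium present (`"worst"`) or
#' absent (`"best"`), recomputes durations (all defined), and fits the
#' analysis model. Deterministic.
#'
#' @param x a `cohort`.
#' @param fill `"worst"` or `"best"`.
#' @return a `strategy_fit`.
#' @export
adhoc_impute <- function(x, fill = c("worst", "best")) {
  fill <- match.arg(fill)
  value <- if (fill == "worst") 1L else 0L
  x$days$delirium[is.na(x$days$delirium)] <- value
  tab <- compute_durations(x)
  est <- fit_analysis_model(tab)
  new_strategy_fit(paste0("adhoc_", fill), est$beta_hat, est$se, est$df,
                   est$n_used)
}

#' One stochastic completion of the daily assessments
#'
#' The daily-level ("proper") imputation draw behind passive MI. Fits a
#' logistic regression of the observed delirium statuses on the predictors
#' (default: daily SOFA and the participant outcome), draws a coefficient
#' vector from the large-sample posterior (multivariate normal at the MLE
#' with the inverse observed information as covariance), and fills each
#' missing day with a Bernoulli draw at its linear predictor. Separation or
#' non-convergence falls back to a weakly ridge-penalized fit (penalty 1e-4)
#' with a warning; one-class observed data imputes the observed class with a
#' warning.
#'
#' @param x a `cohort` with outcomes.
#' @param predictors `c("sofa", "outcome")` or `"sofa"`.
#' @param seed optional integer seed.
#' @return a completed `cohort` (no missing assessments).
#' @export
impute_binary_daily <- function(x, predictors = c("sofa", "outcome"),
                                seed = NULL) {
  stopifnot(inherits(x, "cohort"))
  predictors <- match.arg(predictors, c("sofa", "outcome"),
                          several.ok = TRUE)
  miss <- is.na(x$days$delirium)
  if (!any(miss)) return(x)
  m <- match(x$days$participant_id, x$participants$participant_id)
  X <- cbind(intercept = 1,
             if ("sofa" %in% predictors) cbind(sofa = as.numeric(x$days$sofa)),
             if ("outcome" %in% predictors)
               cbind(outcome = x$participants$outcome[m]))
  y <- x$days$delirium
  obs <- !miss
  if (sum(obs) < 20) {
    stop("need at least 20 observed days to fit the imputation model")
  }
  y_obs <- y[obs]
  local_seed(seed, {
    if (length(unique(y_obs)) == 1L) {
      warning("all observed assessments are one class; imputing that class")
      x$days$delirium[miss] <- y_obs[1]
      return(x)
    }
    post <- logistic_posterior(X[obs, , drop = FALSE], y_obs)
    beta <- MASS::mvrnorm(1, post$coef, post$vcov)
    p_mis <- stats::plogis(drop(X[miss, , drop = FALSE] %*% beta))
    x$days$delirium[miss] <- as.integer(stats::runif(sum(miss)) < p_mis)
    x
  })
}

# Logistic MLE with observed-information covariance; ridge fallback on
# separation / non-convergence. Returns list(coef, vcov).
logistic_posterior <- function(X, y, ridge = 1e-4) {
  fit <- suppressWarnings(
    stats::glm.fit(X, y, family = stats::binomial())
  )
  cf <- fit$coefficients
  separated <- !fit$converged || anyNA(cf) || any(abs(cf) > 15)
  if (separated) {
    warning("imputation model separated or not converged; ",
            "using ridge-penalized fit (penalty ", ridge, ")")
    cf <- ridge_logistic(X, y, lambda = ridge)
  }
  eta <- drop(X %*% cf)
  w <- stats::plogis(eta) * (1 - stats::plogis(eta))
  info <- crossprod(X * w, X)
  if (separated) info <- info + diag(2 * ridge, ncol(X))
  V <- tryCatch(chol2inv(chol(info)), error = function(e) {
    MASS::ginv(info)
  })
  dimnames(V) <- list(colnames(X), colnames(X))
  list(coef = cf, vcov = V)
}

# Newton iterations for ridge-penalized logistic log-likelihood
# (intercept included in the penalty; lambda is tiny so this only
# regularizes away separation).
ridge_logistic <- function(X, y, lambda = 1e-4, maxit = 50, tol = 1e-8) {
  beta <- numeric(ncol(X))
  for (i in seq_len(maxit)) {
    p <- stats::plogis(drop(X %*% beta))
    w <- pmax(p * (1 - p), 1e-10)
    g <- crossprod(X, y - p) - 2 * lambda * beta
    H <- crossprod(X * w, X) + diag(2 * lambda, ncol(X))
    step <- solve(H, g)
    beta <- beta + drop(step)
    if (max(abs(step)) < tol) break
  }
  stats::setNames(beta, colnames(X))
}

#' Passive multiple imputation ("impute then transform")
#'
#' Imputes the daily assessments `B` times with [impute_binary_daily()],
#' computes the delirium duration in each completed dataset, fits the
#' analysis model per dataset, and pools the B slope estimates with
#' [rubins_pool()]. Preserves and uses every observed assessment.
#'
#' @param x a `cohort` with outcomes.
#' @param B number of imputations (>= 2).
#' @param seed optional integer seed.
#' @param predictors imputation-model predictors (see [fit_strategy()]).
#' @return a `strategy_fit` with the pooled estimate and Rubin df.
#' @export
passive_mi <- function(x, B = 10, seed = NULL,
                       predictors = c("sofa", "outcome")) {
  stopifnot(inherits(x, "cohort"))
  if (B < 2) stop("passive_mi requires B >= 2 imputations")
  miss <- anyNA(x$days$delirium)
  local_seed(seed, {
    ests <- vector("list", B)
    for (b in seq_len(B)) {
      comp <- if (miss) impute_binary_daily(x, predictors = predictors) else x
      ests[[b]] <- fit_analysis_model(compute_durations(comp))
    }
    pool_strategy("passive_mi", ests, n_used = n_participants(x), B = B)
  })
}

#' Active multiple imputation ("just another variable")
#'
#' Builds the participant-level table (duration — undefined where any day is
#' missing —, mean SOFA over the stay, outcome) and imputes the duration
#' itself `B` times from a Bayesian normal linear regression of the observed
#' durations on mean SOFA and outcome: residual variance and coefficients
#' are drawn from the standard noninformative posterior, imputed durations
#' from the predictive distribution, then rounded and clipped to
#' `[0, length of stay]`. The observed daily assessments of participants
#' with an undefined duration are deliberately ignored. `method = "pmm"`
#' replaces the normal draw with predictive mean matching (5 nearest donors
#' on the predicted mean, ties broken at random).
#'
#' @param x a `cohort` with outcomes.
#' @param B number of imputations (>= 2).
#' @param seed optional integer seed.
#' @param method `"norm"` (default) or `"pmm"`.
#' @return a `strategy_fit`; non-estimable if fewer than 3 observed
#'   durations.
#' @export
active_mi <- function(x, B = 10, seed = NULL, method = c("norm", "pmm")) {
  stopifnot(inherits(x, "cohort"))
  method <- match.arg(method)
  if (B < 2) stop("active_mi requires B >= 2 imputations")
  tab <- compute_durations(x)
  obs <- !is.na(tab$duration)
  if (sum(obs) < 3) {
    return(non_estimable("active_mi",
                         sprintf("only %d observed durations", sum(obs))))
  }
  if (!any(!obs)) {
    est <- fit_analysis_model(tab)
    ests <- rep(list(est), B)
    return(pool_strategy("active_mi", ests, n_used = nrow(tab), B = B))
  }
  X <- cbind(1, tab$mean_sofa, tab$outcome)
  Xo <- X[obs, , drop = FALSE]
  yo <- tab$duration[obs]
  Xm <- X[!obs, , drop = FALSE]
  n <- nrow(Xo)
  k <- ncol(Xo)
  if (n <= k) {
    return(non_estimable("active_mi", "too few observed durations for the model"))
  }
  qr_o <- qr(Xo)
  beta_hat <- qr.coef(qr_o, yo)
  res <- yo - drop(Xo %*% beta_hat)
  ssr <- sum(res^2)
  XtX_inv <- chol2inv(qr.R(qr_o))
  local_seed(seed, {
    ests <- vector("list", B)
    for (b in seq_len(B)) {
      sigma2 <- ssr / stats::rchisq(1, df = n - k)
      beta <- beta_hat + drop(t(chol(sigma2 * XtX_inv)) %*% stats::rnorm(k))
      mu <- drop(Xm %*% beta)
      dur_imp <- if (method == "norm") {
        round(mu + stats::rnorm(nrow(Xm), 0, sqrt(sigma2)))
      } else {
        pmm_draw(mu_obs = drop(Xo %*% beta_hat), y_obs = yo, mu_mis = mu,
                 k_donors = 5)
      }
      dur_imp <- pmin(tab$los[!obs], pmax(0, dur_imp))
      tab_b <- tab
      tab_b$duration[!obs] <- dur_imp
      ests[[b]] <- fit_analysis_model(tab_b)
    }
    pool_strategy("active_mi", ests, n_used = nrow(tab), B = B)
  })
}

# Predictive mean matching: for each missing case, the k nearest observed
# predicted means form the donor pool; one donor's observed value is drawn
# uniformly (ties in distance broken at random via a random pre-shuffle).
pmm_draw <- function(mu_obs, y_obs, mu_mis, k_donors = 5) {
  k <- min(k_donors, length(mu_obs))
  shuffle <- sample.int(length(mu_obs))
  mu_s <- mu_obs[shuffle]
  y_s <- y_obs[shuffle]
  vapply(mu_mis, function(m) {
    donors <- order(abs(mu_s - m))[seq_len(k)]
    y_s[donors[sample.int(k, 1)]]
  }, numeric(1))
}

pool_strategy <- function(name, ests, n_used, B) {
  beta <- vapply(ests, `[[`, numeric(1), "beta_hat")
  se <- vapply(ests, `[[`, numeric(1), "se")
  pool <- rubins_pool(beta, se)
  new_strategy_fit(name, beta_hat = pool$q_bar, se = pool$se, df = pool$df,
                   n_used = n_used, B = B, pooling = pool)
}

#' Rubin's rules for pooling multiply imputed estimates
#'
#' Pools B point estimates and their standard errors: pooled estimate
#' `q_bar = mean(beta)`, within-imputation variance `w = mean(se^2)`,
#' between-imputation variance `b_var = var(beta)` (divisor B-1), total
#' variance `t_var = w + (1 + 1/B) b_var`, degrees of freedom
#' `df = (B - 1) (1 + w / ((1 + 1/B) b_var))^2` (infinite when `b_var = 0`),
#' pooled SE `sqrt(t_var)`.
#'
#' @param beta_hat numeric vector of B >= 2 point estimates.
#' @param se numeric vector of their standard errors (>= 0).
#' @return a list of class `rubins_pool` with `q_bar`, `w`, `b_var`, `t_var`,
#'   `df`, `se`, `B`.
#' @export
#' @examples
#' rubins_pool(c(1, 2, 3), sqrt(c(0.5, 0.5, 0.5)))
rubins_pool <- function(beta_hat, se) {
  B <- length(beta_hat)
  if (B < 2) stop("Rubin's rules require at least 2 imputations")
  stopifnot(length(se) == B, all(se >= 0), all(is.finite(beta_hat)))
  q_bar <- mean(beta_hat)
  w <- mean(se^2)
  b_var <- stats::var(beta_hat)
  t_var <- w + (1 + 1 / B) * b_var
  df <- if (b_var == 0) Inf else (B - 1) * (1 + w / ((1 + 1 / B) * b_var))^2
  structure(list(q_bar = q_bar, w = w, b_var = b_var, t_var = t_var,
                 df = df, se = sqrt(t_var), B = B),
            class = "rubins_pool")
}

#' @export
print.rubins_pool <- function(x, ...) {
  cat(sprintf(
    "Rubin's rules pooling of %d imputations\n  estimate %.4f (SE %.4f)\n",
    x$B, x$q_bar, x$se))
  cat(sprintf("  within %.5f, between %.5f, total %.5f, df %.1f\n",
              x$w, x$b_var, x$t_var, x$df))
  invisible(x)
}

# --- strategy_fit methods ---------------------------------------------------

#' @export
print.strategy_fit <- function(x, ...) {
  if (!x$estimable) {
    cat(sprintf("<strategy_fit> %s: non-estimable (%s)\n", x$strategy,
                x$message))
    return(invisible(x))
  }
  cat(sprintf("<strategy_fit> %s\n", x$strategy))
  cat(sprintf("  duration slope %.4f (SE %.4f, df %.1f, n = %d%s)\n",
              x$beta_hat, x$se, x$df, x$n_used,
              if (x$B > 0) sprintf(", B = %d", x$B) else ""))
  invisible(x)
}

#' @export
coef.strategy_fit <- function(object, ...) {
  c(duration = object$beta_hat)
}

#' @export
confint.strategy_fit <- function(object, parm = "duration", level = 0.95, ...) {
  if (!object$estimable) {
    ci <- matrix(NA_real_, 1, 2)
  } else {
    tcrit <- stats::qt(1 - (1 - level) / 2, df = object$df)
    ci <- matrix(object$beta_hat + c(-1, 1) * tcrit * object$se, 1, 2)
  }
  dimnames(ci) <- list("duration",
                       sprintf("%.1f %%", 100 * c((1 - level) / 2,
                                                  1 - (1 - level) / 2)))
  ci
}

#' @export
summary.strategy_fit <- function(object, level = 0.95, ...) {
  print(object)
  if (object$estimable) {
    ci <- confint(object, level = level)
    cat(sprintf("  %.0f%% CI [%.4f, %.4f] (t, df %.1f)\n", 100 * level,
                ci[1], ci[2], object$df))
    if (!is.null(object$pooling)) print(object$pooling)
  }
  invisible(object)
}
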