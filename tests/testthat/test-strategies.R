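test_that("the analysis model matches a normal-equations oracle", {
  set.seed(41)
  x <- sample(0:10, 50, replace = TRUE)
  y <- 80 - x + rnorm(50, 0, 12)
  est <- delmi:::fit_analysis_model(data.frame(duration = x, outcome = y))
  o <- ols_oracle(x, y)
  expect_equal(est$beta_hat, o$slope, tolerance = 1e-10)
  expect_equal(est$se, o$se, tolerance = 1e-10)
  expect_equal(est$df, o$df)
  expect_equal(est$n_used, 50L)
})

test_that("analysis-model edge cases: exact fit, tiny n, constant exposure", {
  expect_warning(
    est <- delmi:::fit_analysis_model(
      data.frame(duration = c(0, 1, 2, 3), outcome = c(5, 4, 3, 2))),
    "perfect fit")
  expect_equal(est$beta_hat, -1)
  expect_equal(est$se, 0)

  est3 <- delmi:::fit_analysis_model(
    data.frame(duration = c(0, 1, 2), outcome = c(0, 1, 2.5)))
  expect_equal(est3$beta_hat, 1.25)

  expect_error(delmi:::fit_analysis_model(
    data.frame(duration = c(0, 1), outcome = c(0, 1))), "at least 3")
  expect_error(delmi:::fit_analysis_model(
    data.frame(duration = c(2, 2, 2), outcome = c(0, 1, 2))), "constant")
})

test_that("Rubin's rules reproduce the worked arithmetic and the oracle", {
  p <- rubins_pool(c(1, 2, 3), sqrt(c(0.5, 0.5, 0.5)))
  expect_equal(p$q_bar, 2)
  expect_equal(p$w, 0.5)
  expect_equal(p$b_var, 1)
  expect_equal(p$t_var, 0.5 + (4 / 3) * 1)
  expect_equal(p$se, sqrt(11 / 6), tolerance = 1e-4)

  same <- rubins_pool(rep(1.5, 5), rep(0.3, 5))
  expect_equal(same$b_var, 0)
  expect_equal(same$t_var, same$w)
  expect_identical(same$df, Inf)

  set.seed(42)
  q <- rnorm(10)
  se <- runif(10, 0.1, 1)
  got <- rubins_pool(q, se)
  want <- rubin_oracle(q, se)
  for (f in c("q_bar", "w", "b_var", "t_var", "df", "se")) {
    expect_equal(got[[f]], want[[f]], tolerance = 1e-12)
  }
  expect_true(got$t_var >= got$w)
  expect_error(rubins_pool(1, 0.5), "at least 2")
})

test_that("ad hoc substitution forces the duration deterministically", {
  coh3 <- make_cohort(list(c(1L, 1L, NA, 1L, 0L), c(0L, NA), c(1L, 1L)),
                      outcomes = c(75, 80, 78))
  w <- coh3
  w$days$delirium[is.na(w$days$delirium)] <- 1L
  expect_identical(compute_durations(w)$duration, c(4L, 1L, 2L))
  b <- coh3
  b$days$delirium[is.na(b$days$delirium)] <- 0L
  expect_identical(compute_durations(b)$duration, c(3L, 0L, 2L))
})

test_that("worst-case duration dominates best-case, equal iff nothing missing", {
  base <- generate_base_cohort(base_cohort_params(n_base = 300), seed = 43)
  coh <- generate_outcome(base, seed = 44)
  coh <- impose_missingness(coh, missingness_spec("MCAR", 0.25), seed = 45)
  w <- coh; w$days$delirium[is.na(w$days$delirium)] <- 1L
  b <- coh; b$days$delirium[is.na(b$days$delirium)] <- 0L
  dw <- compute_durations(w)$duration
  db <- compute_durations(b)$duration
  has_missing <- tapply(is.na(coh$days$delirium), coh$days$participant_id, any)
  has_missing <- has_missing[order(as.numeric(names(has_missing)))]
  expect_true(all(dw >= db))
  expect_identical(unname(dw > db), as.logical(has_missing))
})

test_that("all five strategies coincide on a cohort with zero missingness", {
  coh <- small_complete_cohort(n = 60)
  fits <- lapply(c("complete_case", "adhoc_worst", "adhoc_best",
                   "passive_mi", "active_mi"),
                 function(s) fit_strategy(coh, s, B = 5, seed = 46))
  betas <- vapply(fits, `[[`, numeric(1), "beta_hat")
  ses <- vapply(fits, `[[`, numeric(1), "se")
  expect_true(all(abs(betas - betas[1]) < 1e-10))
  expect_true(all(abs(ses - ses[1]) < 1e-10))
  # MI strategies show zero between-imputation variance
  expect_equal(fits[[4]]$pooling$b_var, 0)
  expect_equal(fits[[5]]$pooling$b_var, 0)
  expect_identical(fits[[4]]$df, Inf)
})

test_that("complete case drops exactly the participants with missing days", {
  coh <- small_complete_cohort(n = 50)
  full <- complete_case(coh)
  expect_equal(full$n_used, 50)

  one <- coh
  one$days$delirium[match(7, one$days$participant_id)] <- NA_integer_
  cc <- complete_case(one)
  expect_equal(cc$n_used, 49)

  # fewer than 3 complete participants -> non-estimable, not an error
  wrecked <- coh
  keep <- wrecked$days$participant_id <= 2
  wrecked$days$delirium[!keep] <- NA_integer_
  ne <- complete_case(wrecked)
  expect_false(ne$estimable)
  expect_match(ne$message, "complete participants")
})

test_that("MCAR per-participant retention matches the binomial expectation", {
  # 5-day stays, 20% daily MCAR: P(complete) = 0.8^5
  coh <- generate_base_cohort(
    base_cohort_params(n_base = 3000, los_min = 5, los_max = 5, los_mean = 5),
    seed = 47)
  coh <- generate_outcome(coh, seed = 48)
  masked <- impose_missingness(coh, missingness_spec("MCAR", 0.2), seed = 49)
  frac <- complete_case(masked)$n_used / 3000
  p_exp <- 0.8^5
  expect_lt(abs(frac - p_exp), 3.29 * sqrt(p_exp * (1 - p_exp) / 3000))
})

test_that("daily imputation is calibrated when the signal is null", {
  # delirium independent of SOFA and of the outcome: imputed prevalence
  # should match the observed prevalence (~0.4) in the long run
  coh <- generate_base_cohort(
    base_cohort_params(n_base = 800, sofa_del_shift = 0), seed = 50)
  coh <- generate_outcome(coh, beta_del = 0, seed = 51)
  masked <- impose_missingness(coh, missingness_spec("MCAR", 0.3), seed = 52)
  miss <- is.na(masked$days$delirium)
  prev_obs <- mean(masked$days$delirium[!miss])
  imp_mean <- mean(vapply(1:20, function(b) {
    comp <- impute_binary_daily(masked, seed = 52 + b)
    mean(comp$days$delirium[miss])
  }, numeric(1)))
  expect_lt(abs(imp_mean - prev_obs), 0.03)
})

test_that("a separating predictor is recovered by the imputation draw", {
  # SOFA perfectly separates the classes; the ridge fallback should still
  # impute by the separating rule nearly always
  n <- 60
  del <- rep(c(1L, 0L), each = n * 3)
  sofa <- ifelse(del == 1, 16L, 6L)
  coh <- make_cohort(split(del, rep(seq_len(n), each = 6)),
                     sofa_list = split(sofa, rep(seq_len(n), each = 6)),
                     outcomes = rnorm(n, 80, 5))
  masked <- impose_missingness(coh, missingness_spec("MCAR", 0.2), seed = 53)
  miss <- is.na(masked$days$delirium)
  expect_warning(comp <- impute_binary_daily(masked, predictors = "sofa",
                                             seed = 54),
                 "ridge|separated")
  agree <- mean(comp$days$delirium[miss] == masked$days$true_delirium[miss])
  expect_gt(agree, 0.95)
})

test_that("one-class observed assessments impute the observed class", {
  coh <- make_cohort(rep(list(c(0L, 0L, 0L)), 12),
                     outcomes = rnorm(12, 80, 5))
  coh$days$delirium[c(1, 5, 9)] <- NA_integer_
  expect_warning(comp <- impute_binary_daily(coh, seed = 55), "one class")
  expect_true(all(comp$days$delirium == 0L))
})

test_that("passive and active MI honour their contracts at the edges", {
  coh <- small_complete_cohort(n = 40)
  expect_error(passive_mi(coh, B = 1), "B >= 2")
  expect_error(active_mi(coh, B = 1), "B >= 2")

  # zero missingness: pooled estimate equals the complete-data estimate
  cc <- complete_case(coh)
  pm <- passive_mi(coh, B = 3, seed = 56)
  am <- active_mi(coh, B = 3, seed = 57)
  expect_equal(pm$beta_hat, cc$beta_hat, tolerance = 1e-12)
  expect_equal(am$beta_hat, cc$beta_hat, tolerance = 1e-12)

  # every duration undefined -> active MI is non-estimable
  all_miss <- coh
  first_day <- !duplicated(all_miss$days$participant_id)
  all_miss$days$delirium[first_day] <- NA_integer_
  ne <- active_mi(all_miss, B = 3, seed = 58)
  expect_false(ne$estimable)
})

test_that("predictive mean matching draws durations from the observed pool", {
  base <- generate_base_cohort(base_cohort_params(n_base = 200), seed = 59)
  coh <- generate_outcome(base, seed = 60)
  masked <- impose_missingness(coh, missingness_spec("MCAR", 0.2), seed = 61)
  fit <- fit_strategy(masked, "active_mi", B = 5, seed = 62,
                      active_method = "pmm")
  expect_true(fit$estimable)
  expect_true(is.finite(fit$se) && fit$se > 0)
})

test_that("pooled total variance never falls below the within-imputation part", {
  base <- generate_base_cohort(base_cohort_params(n_base = 300), seed = 63)
  for (r in 1:5) {
    coh <- generate_outcome(cluster_resample(base, 150, seed = 63 + r),
                            seed = 70 + r)
    masked <- impose_missingness(coh, missingness_spec("MCAR", 0.25),
                                 seed = 80 + r)
    for (s in c("passive_mi", "active_mi")) {
      fit <- fit_strategy(masked, s, B = 4, seed = 90 + r)
      expect_gte(fit$pooling$t_var, fit$pooling$w)
    }
  }
})

test_that("MI standard errors grow with the missingness proportion", {
  base <- generate_base_cohort(base_cohort_params(n_base = 500), seed = 64)
  n_rep <- 25
  se_tab <- sapply(c(0.05, 0.35), function(p) {
    sapply(c("passive_mi", "active_mi"), function(s) {
      mean(vapply(seq_len(n_rep), function(r) {
        coh <- generate_outcome(cluster_resample(base, 200, seed = 200 + r),
                                seed = 300 + r)
        masked <- impose_missingness(coh, missingness_spec("MCAR", p),
                                     seed = 400 + r) # same seeds across p
        fit_strategy(masked, s, B = 5, seed = 500 + r)$se
      }, numeric(1)))
    })
  })
  # columns: p = 0.05, 0.35; paired cohorts and masking streams
  expect_gte(se_tab["passive_mi", 2], se_tab["passive_mi", 1])
  expect_gte(se_tab["active_mi", 2], se_tab["active_mi", 1])
})
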