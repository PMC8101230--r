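# Shared fixture builders and independent oracles.

# Build a cohort directly from a list of per-participant delirium vectors.
make_cohort <- function(delirium_list, sofa_list = NULL, outcomes = NULL) {
  n <- length(delirium_list)
  los <- lengths(delirium_list)
  if (is.null(sofa_list)) sofa_list <- lapply(los, function(l) rep(8L, l))
  days <- data.frame(
    participant_id = rep.int(seq_len(n), los),
    day = sequence(los),
    delirium = unlist(delirium_list, use.names = FALSE),
    sofa = unlist(sofa_list, use.names = FALSE)
  )
  participants <- data.frame(participant_id = seq_len(n), los = los,
                             outcome = if (is.null(outcomes)) NA_real_ else outcomes)
  cohort(days, participants)
}

# A small fully observed cohort with outcomes, for strategy identities.
small_complete_cohort <- function(n = 40, seed = 101) {
  base <- generate_base_cohort(base_cohort_params(n_base = n), seed = seed)
  generate_outcome(base, seed = seed + 1)
}

# Closed-form OLS slope and SE from the normal equations (the oracle kept
# independent of stats::lm).
ols_oracle <- function(x, y) {
  n <- length(x)
  xb <- mean(x); yb <- mean(y)
  sxx <- sum((x - xb)^2)
  slope <- sum((x - xb) * (y - yb)) / sxx
  inter <- yb - slope * xb
  res <- y - inter - slope * x
  sigma2 <- sum(res^2) / (n - 2)
  list(slope = slope, se = sqrt(sigma2 / sxx), df = n - 2)
}

# Textbook Rubin's-rules formulas, written out independently.
rubin_oracle <- function(q, se) {
  B <- length(q)
  qbar <- sum(q) / B
  w <- sum(se^2) / B
  b <- sum((q - qbar)^2) / (B - 1)
  t <- w + b + b / B
  r <- (1 + 1 / B) * b / w
  list(q_bar = qbar, w = w, b_var = b, t_var = t,
       df = if (b == 0) Inf else (B - 1) * (1 + 1 / r)^2,
       se = sqrt(t))
}

# Interval-containment count computed by brute force from (est, se, df).
coverage_oracle <- function(est, se, df, truth, level = 0.95) {
  hit <- 0L
  for (i in seq_along(est)) {
    tc <- stats::qt(1 - (1 - level) / 2, df[i])
    lo <- est[i] - tc * se[i]
    hi <- est[i] + tc * se[i]
    if (truth >= lo && truth <= hi) hit <- hit + 1L
  }
  hit / length(est)
}
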