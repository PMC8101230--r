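#' Parameters for the synthetic base cohort
#'
#' The base cohort emulates the participant-day structure of a critical-care
#' delirium study: variable lengths of stay up to 30 days, a serially
#' correlated daily binary delirium status, and a daily integer SOFA severity
#' score elevated on delirious days. Daily delirium follows a two-state
#' Markov chain, so the long-run prevalence is
#' `p_new_del / (p_new_del + 1 - p_stay_del)`. Defaults give a prevalence of
#' about 0.4 of participant-days and a mean duration of 2-3 days over a mean
#' stay of about 7 days.
#'
#' @param n_base number of base participants.
#' @param los_min,los_max length-of-stay bounds in days (1 <= min <= max <= 30).
#' @param los_mean target mean length of stay.
#' @param los_dist `"geometric"` (truncated, right-skewed; default) or
#'   `"poisson"` (truncated).
#' @param p_init probability of delirium on day 1.
#' @param p_stay_del P(delirium on day t+1 | delirium on day t).
#' @param p_new_del P(delirium on day t+1 | no delirium on day t); must not
#'   exceed `p_stay_del` (delirium persists).
#' @param sofa_base_mean,sofa_base_sd participant-level severity distribution.
#' @param sofa_del_shift additive SOFA elevation on delirium days; this is
#'   what makes SOFA a useful MAR auxiliary and MNAR proxy.
#' @param sofa_noise_sd day-level SOFA noise.
#' @return a list of class `base_cohort_params`.
#' @export
base_cohort_params <- function(n_base = 1000,
                               los_min = 2, los_max = 30, los_mean = 7,
                               los_dist = c("geometric", "poisson"),
                               p_init = 0.4, p_stay_del = 0.7, p_new_del = 0.2,
                               sofa_base_mean = 6, sofa_base_sd = 2.5,
                               sofa_del_shift = 2, sofa_noise_sd = 1.5) {
  los_dist <- match.arg(los_dist)
  stopifnot(n_base >= 1, los_min >= 1, los_max <= 30, los_min <= los_max,
            los_mean >= los_min, los_mean <= los_max,
            sofa_base_sd > 0, sofa_noise_sd >= 0)
  probs <- c(p_init = p_init, p_stay_del = p_stay_del, p_new_del = p_new_del)
  if (any(probs < 0 | probs > 1)) stop("probabilities must be in [0, 1]")
  if (p_new_del > p_stay_del) stop("p_stay_del must be >= p_new_del")
  structure(as.list(environment()), class = "base_cohort_params")
}

#' Generate a synthetic base cohort
#'
#' Draws lengths of stay from a truncated geometric (or Poisson)
#' distribution, simulates the two-state delirium Markov chain per
#' participant, and builds `sofa = round(clip(base_i + shift * delirium +
#' noise, 0, 24))`. All statuses are observed; no outcome is attached (see
#' [generate_outcome()]).
#'
#' @param params a [base_cohort_params()] list.
#' @param seed optional integer seed.
#' @return a fully observed `cohort` of `params$n_base` participants.
#' @export
generate_base_cohort <- function(params = base_cohort_params(), seed = NULL) {
  stopifnot(inherits(params, "base_cohort_params"))
  local_seed(seed, {
    n <- params$n_base
    los <- draw_los(n, params)
    nd <- sum(los)
    pid <- rep.int(seq_len(n), los)
    day <- sequence(los)
    # Markov chain vectorized over participants, one pass per study day
    del <- integer(nd)
    first <- c(0L, cumsum(los))[seq_len(n)] # offset of day 1 per participant
    state <- as.integer(stats::runif(n) < params$p_init)
    del[first + 1L] <- state
    for (t in seq_len(max(los))[-1]) {
      alive <- which(los >= t)
      if (!length(alive)) break
      p_next <- ifelse(state[alive] == 1L, params$p_stay_del, params$p_new_del)
      state[alive] <- as.integer(stats::runif(length(alive)) < p_next)
      del[first[alive] + t] <- state[alive]
    }
    base_sev <- stats::rnorm(n, params$sofa_base_mean, params$sofa_base_sd)
    sofa_raw <- base_sev[pid] + params$sofa_del_shift * del +
      stats::rnorm(nd, 0, params$sofa_noise_sd)
    sofa <- as.integer(pmin(24, pmax(0, round(sofa_raw))))
    days <- data.frame(participant_id = pid, day = day,
                       delirium = del, sofa = sofa)
    participants <- data.frame(participant_id = seq_len(n), los = los)
    cohort(days, participants,
           provenance = list(generator = unclass(params), seed = seed))
  })
}

draw_los <- function(n, params) {
  lo <- params$los_min
  hi <- params$los_max
  if (lo == hi) return(rep.int(lo, n))
  if (params$los_dist == "geometric") {
    prob <- 1 / (params$los_mean - lo + 1)
    draw <- function(k) lo + stats::rgeom(k, prob)
  } else {
    draw <- function(k) stats::rpois(k, params$los_mean)
  }
  los <- draw(n)
  # rejection on the truncation bounds; geometric overshoot is rare at
  # default parameters so this converges in a few rounds
  for (i in 1:100) {
    bad <- which(los < lo | los > hi)
    if (!length(bad)) break
    los[bad] <- draw(length(bad))
  }
  los[los < lo] <- lo
  los[los > hi] <- hi
  as.integer(los)
}

#' Descriptive summary of a cohort
#'
#' Calibration check for the generator: mean length of stay, delirium
#' prevalence over participant-days, duration quantiles, and mean SOFA by
#' delirium status.
#'
#' @param x a `cohort` (uses the pre-masking `true_delirium` status).
#' @return a list of class `cohort_summary`.
#' @export
summarize_base <- function(x) {
  stopifnot(inherits(x, "cohort"), n_participants(x) > 0)
  d <- x$days
  dur <- compute_durations(x, statuses = "true_delirium")$duration
  del <- d$true_delirium
  structure(list(
    n_participants = n_participants(x),
    n_days = n_days(x),
    mean_los = n_days(x) / n_participants(x),
    prevalence = mean(del),
    duration_quantiles = stats::quantile(dur, c(0, .25, .5, .75, 1)),
    mean_duration = mean(dur),
    sofa_mean_delirium = if (any(del == 1)) mean(d$sofa[del == 1]) else NA_real_,
    sofa_mean_no_delirium = if (any(del == 0)) mean(d$sofa[del == 0]) else NA_real_
  ), class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("Cohort: %d participants, %d participant-days (mean LOS %.2f)\n",
              x$n_participants, x$n_days, x$mean_los))
  cat(sprintf("Delirium prevalence: %.3f of days; mean duration %.2f days\n",
              x$prevalence, x$mean_duration))
  cat("Duration quantiles:",
      paste(names(x$duration_quantiles), x$duration_quantiles,
            sep = "=", collapse = " "), "\n")
  cat(sprintf("Mean SOFA: %.2f (delirium days) vs %.2f (non-delirium days)\n",
              x$sofa_mean_delirium, x$sofa_mean_no_delirium))
  invisible(x)
}
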