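#' Construct a participant-day cohort
#'
#' A cohort couples a long participant-day table (one row per ICU day) with a
#' participant-level table (length of stay, outcome). The daily delirium
#' status is the assessment that missingness acts on; `true_delirium` keeps
#' the pre-masking status for oracle checks and is never consulted by any
#' estimation strategy.
#'
#' @param days data.frame with columns `participant_id` (integer), `day`
#'   (integer, consecutive from 1 within participant), `delirium` (0/1/NA;
#'   NA means the assessment is missing), `sofa` (integer 0-24). An optional
#'   `true_delirium` column carries the pre-masking status; when absent it is
#'   copied from `delirium`.
#' @param participants data.frame with columns `participant_id`, `los`,
#'   `outcome` (numeric, may be NA before outcome generation) and optionally
#'   `true_duration`.
#' @param provenance list of free-form metadata (seed, generator parameters,
#'   source file).
#'
#' @return An object of class `cohort`.
#' @export
cohort <- function(days, participants, provenance = list()) {
  days <- as.data.frame(days)
  participants <- as.data.frame(participants)
  if (is.null(days$true_delirium)) days$true_delirium <- days$delirium
  if (is.null(participants$outcome)) participants$outcome <- NA_real_
  if (is.null(participants$true_duration)) {
    participants$true_duration <- NA_integer_
  }
  obj <- structure(
    list(days = days, participants = participants, provenance = provenance),
    class = "cohort"
  )
  validate_cohort(obj)
  obj
}

#' Validate cohort invariants
#'
#' Checks unique participant ids, consecutive days starting at 1, length of
#' stay within \[1, 30\], and SOFA scores (when present) integers in \[0, 24\].
#'
#' @param x a `cohort`.
#' @return `x`, invisibly; errors on violation.
#' @export
validate_cohort <- function(x) {
  stopifnot(inherits(x, "cohort"))
  d <- x$days
  p <- x$participants
  need <- c("participant_id", "day", "delirium", "sofa")
  if (!all(need %in% names(d))) {
    stop("days table must have columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(p$participant_id)) stop("duplicate participant ids")
  if (!all(d$participant_id %in% p$participant_id)) {
    stop("days reference unknown participants")
  }
  if (nrow(p) == 0L) stop("cohort has no participants")
  los <- tabulate(match(d$participant_id, p$participant_id), nbins = nrow(p))
  if (any(los < 1L) || any(los > 30L)) {
    stop("length of stay must be in [1, 30] for every participant")
  }
  if (!all(los == p$los)) stop("participant los disagrees with day counts")
  # consecutive days from 1: within participant the days must be 1..los
  ord <- order(d$participant_id, d$day)
  ds <- d[ord, ]
  run <- rle(ds$participant_id)$lengths
  if (!identical(as.integer(ds$day), as.integer(sequence(run)))) {
    stop("days must be consecutive integers starting at 1 within participant")
  }
  sofa <- d$sofa[!is.na(d$sofa)]
  if (length(sofa) && (any(sofa != round(sofa)) || any(sofa < 0 | sofa > 24))) {
    stop("sofa must be an integer in [0, 24]")
  }
  bad_del <- d$delirium[!is.na(d$delirium)]
  if (length(bad_del) && !all(bad_del %in% c(0, 1))) {
    stop("delirium must be 0/1/NA")
  }
  invisible(x)
}

#' Number of participants / participant-days
#' @param x a `cohort`.
#' @return integer count.
#' @export
n_participants <- function(x) nrow(x$participants)

#' @rdname n_participants
#' @export
n_days <- function(x) nrow(x$days)

#' Delirium duration of a single day sequence
#'
#' Duration is the count of days with delirium present. If any day's status
#' is missing the duration is undefined and `NA_integer_` is returned: this is
#' the complete-case semantics that the estimation strategies override.
#'
#' @param delirium vector of 0/1/NA daily statuses (at least one day).
#' @return integer count, or `NA_integer_` if any day is missing.
#' @export
#' @examples
#' compute_duration(c(1, 1, NA, 1, 0)) # NA: undefined
#' compute_duration(c(1, 0, 1))        # 2
compute_duration <- function(delirium) {
  if (length(delirium) == 0L) stop("participant must have at least one day")
  if (anyNA(delirium)) return(NA_integer_)
  as.integer(sum(delirium))
}

#' Per-participant durations for a whole cohort
#'
#' @param x a `cohort`.
#' @param statuses which daily status to summarise: the observed (possibly
#'   masked) `"delirium"` or the pre-masking `"true_delirium"`.
#' @return data.frame with `participant_id`, `duration` (NA where undefined),
#'   `los`, `mean_sofa`, `outcome`.
#' @export
compute_durations <- function(x, statuses = c("delirium", "true_delirium")) {
  statuses <- match.arg(statuses)
  d <- x$days
  p <- x$participants
  g <- match(d$participant_id, p$participant_id)
  dur <- rowsum(d[[statuses]], g)            # NA propagates: undefined duration
  msofa <- rowsum(as.numeric(d$sofa), g) / p$los[sort(unique(g))]
  out <- data.frame(
    participant_id = p$participant_id,
    duration = NA_integer_,
    los = p$los,
    mean_sofa = NA_real_,
    outcome = p$outcome
  )
  idx <- as.integer(rownames(dur))
  out$duration[idx] <- as.integer(dur[, 1])
  out$mean_sofa[idx] <- msofa[, 1]
  out
}

#' Single-stage cluster resampling of participants
#'
#' Draws a simple random sample of participants and carries every ICU day of
#' each sampled participant intact, preserving within-participant serial
#' correlation. Sampled participants receive fresh ids `1..n` so repeated
#' draws (with replacement) stay distinguishable.
#'
#' @param base a `cohort` to sample from.
#' @param n number of participants to draw.
#' @param replace sample with replacement? Default `FALSE`.
#' @param seed optional integer seed; the caller's RNG state is untouched.
#' @return a new `cohort` of exactly `n` participants.
#' @export
cluster_resample <- function(base, n, replace = FALSE, seed = NULL) {
  stopifnot(inherits(base, "cohort"), n >= 1)
  nb <- n_participants(base)
  if (!replace && n > nb) {
    stop("cannot sample ", n, " participants from ", nb,
         " without replacement")
  }
  pick <- local_seed(seed, sample.int(nb, n, replace = replace))
  day_idx <- split(seq_len(nrow(base$days)),
                   match(base$days$participant_id, base$participants$participant_id))
  rows <- day_idx[pick]
  days <- base$days[unlist(rows, use.names = FALSE), , drop = FALSE]
  days$participant_id <- rep.int(seq_len(n), lengths(rows))
  part <- base$participants[pick, , drop = FALSE]
  part$participant_id <- seq_len(n)
  rownames(days) <- rownames(part) <- NULL
  cohort(days, part, provenance = c(base$provenance,
                                    list(resample = list(n = n, replace = replace, seed = seed))))
}

#' Generate the continuous outcome from delirium duration
#'
#' Draws `outcome_i = intercept + beta_del * duration_i + eps_i` with
#' `eps_i ~ N(0, resid_sd^2)`. Must be called while every delirium status is
#' observed (before missingness is imposed); the generating duration is
#' recorded in `true_duration`.
#'
#' @param x a fully observed `cohort`.
#' @param intercept outcome intercept (default 80, an RBANS-like level; it
#'   does not affect bias/SE/coverage of the slope).
#' @param beta_del slope of outcome on duration (default -1).
#' @param resid_sd residual standard deviation (default 12).
#' @param seed optional integer seed.
#' @return the cohort with `outcome` and `true_duration` filled in.
#' @export
generate_outcome <- function(x, intercept = 80, beta_del = -1,
                             resid_sd = 12, seed = NULL) {
  stopifnot(inherits(x, "cohort"), resid_sd >= 0)
  dur <- compute_durations(x)$duration
  if (anyNA(dur)) {
    stop("outcome generation requires fully observed delirium statuses")
  }
  eps <- local_seed(seed, stats::rnorm(length(dur), 0, resid_sd))
  x$participants$outcome <- intercept + beta_del * dur + eps
  x$participants$true_duration <- dur
  x$provenance$outcome <- list(intercept = intercept, beta_del = beta_del,
                               resid_sd = resid_sd, seed = seed)
  x
}

#' Read / write the long-table cohort CSV
#'
#' One row per participant-day with columns `participant_id`, `day`,
#' `delirium` (Y/N/empty; an empty cell is a missing assessment), `sofa`, and
#' the participant-level `outcome` repeated on each row (empty when absent).
#'
#' @param path file path.
#' @return `read_cohort_csv` returns a `cohort`; `write_cohort_csv` returns
#'   `path` invisibly.
#' @export
read_cohort_csv <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(delirium = "character"))
  del <- trimws(raw$delirium)
  delirium <- ifelse(del == "Y", 1L, ifelse(del == "N", 0L, NA_integer_))
  days <- data.frame(participant_id = raw$participant_id, day = raw$day,
                     delirium = delirium, sofa = raw$sofa)
  first <- !duplicated(raw$participant_id)
  outcome <- if ("outcome" %in% names(raw)) as.numeric(raw$outcome[first]) else NA_real_
  participants <- data.frame(
    participant_id = raw$participant_id[first],
    los = as.integer(table(factor(raw$participant_id,
                                  levels = raw$participant_id[first]))),
    outcome = outcome
  )
  cohort(days, participants, provenance = list(source = path))
}

#' @rdname read_cohort_csv
#' @param x a `cohort`.
#' @export
write_cohort_csv <- function(x, path) {
  stopifnot(inherits(x, "cohort"))
  p <- x$participants
  m <- match(x$days$participant_id, p$participant_id)
  out <- data.frame(
    participant_id = x$days$participant_id,
    day = x$days$day,
    delirium = ifelse(is.na(x$days$delirium), "",
                      ifelse(x$days$delirium == 1, "Y", "N")),
    sofa = x$days$sofa,
    outcome = p$outcome[m]
  )
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @export
print.cohort <- function(x, ...) {
  nd <- n_days(x)
  np <- n_participants(x)
  miss <- mean(is.na(x$days$delirium))
  cat(sprintf("<cohort> %d participants, %d participant-days\n", np, nd))
  cat(sprintf("  mean LOS %.2f days; %.1f%% of assessments missing\n",
              nd / np, 100 * miss))
  if (!all(is.na(x$participants$outcome))) {
    cat(sprintf("  outcome: mean %.2f, sd %.2f\n",
                mean(x$participants$outcome), stats::sd(x$participants$outcome)))
  }
  invisible(x)
}

# Evaluate expr under a temporary RNG state seeded with `seed`; restores the
# caller's stream. seed = NULL runs expr on the ambient stream.
local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}

# Deterministic substream seeds below 2^31, spread over (stream, index).
derive_seed <- function(master, stream, index = 0L) {
  m <- as.double(master %% 2147483647)
  s <- (m * 48271 + as.double(stream) * 2654435 + as.double(index) * 9973) %%
    2147483629
  as.integer(s) + 1L
}
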