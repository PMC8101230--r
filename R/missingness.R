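#' Specify a missingness mechanism for daily assessments
#'
#' Missingness targets the daily delirium assessment only; SOFA and the
#' outcome are always observed. The per-day missingness probability is
#' \describe{
#'   \item{MCAR}{constant `p`,}
#'   \item{MAR}{`plogis(alpha + strength * sofa)` — depends on the observed
#'     severity score,}
#'   \item{MNAR}{`plogis(alpha + strength * delirium)` — depends on the
#'     (to-be-masked) delirium status itself.}
#' }
#' For MAR/MNAR the intercept `alpha_miss` is not user-set: it is calibrated
#' against a cohort so the expected fraction of missing participant-days hits
#' `proportion` (see [calibrate_alpha()]).
#'
#' @param mechanism one of `"MCAR"`, `"MAR"`, `"MNAR"`.
#' @param proportion target fraction of participant-days masked, in (0, 1).
#' @param strength logistic slope on the driver (SOFA for MAR, delirium for
#'   MNAR); the study grid uses 0.01/0.1/0.2 for MAR and 0.1/0.5/1.0 for
#'   MNAR. Ignored for MCAR.
#' @return a list of class `missingness_spec` with `alpha_miss = NA` until
#'   calibrated.
#' @export
missingness_spec <- function(mechanism = c("MCAR", "MAR", "MNAR"),
                             proportion, strength = NULL) {
  mechanism <- match.arg(mechanism)
  stopifnot(is.numeric(proportion), length(proportion) == 1,
            proportion > 0, proportion < 1)
  if (mechanism == "MCAR") {
    strength <- NA_real_
  } else {
    if (is.null(strength) || !is.numeric(strength) || strength < 0) {
      stop(mechanism, " requires a nonnegative strength")
    }
  }
  structure(list(mechanism = mechanism, proportion = proportion,
                 strength = strength, alpha_miss = NA_real_),
            class = "missingness_spec")
}

#' Calibrate the missingness intercept to the target proportion
#'
#' Solves `mean(plogis(alpha + strength * x)) = proportion` over the cohort's
#' participant-days, where `x` is SOFA (MAR) or the true delirium status
#' (MNAR). The mean is strictly increasing in `alpha`, so a bracketing root
#' find converges; the achieved expected proportion is within 1e-8 of the
#' target. MCAR specs are returned unchanged (no intercept is needed).
#'
#' @param spec a `missingness_spec`.
#' @param x a fully observed `cohort`.
#' @return the spec with `alpha_miss` filled in.
#' @export
calibrate_alpha <- function(spec, x) {
  stopifnot(inherits(spec, "missingness_spec"), inherits(x, "cohort"))
  if (spec$mechanism == "MCAR") return(spec)
  if (anyNA(x$days$delirium)) {
    stop("calibration requires a fully observed cohort")
  }
  z <- if (spec$mechanism == "MAR") x$days$sofa else x$days$delirium
  f <- function(a) mean(stats::plogis(a + spec$strength * z)) - spec$proportion
  sol <- stats::uniroot(f, lower = -60, upper = 60, tol = 1e-12,
                        extendInt = "upX")
  if (abs(f(sol$root)) > 1e-8) {
    stop("alpha calibration did not converge: residual ", f(sol$root),
         " at alpha = ", sol$root)
  }
  spec$alpha_miss <- sol$root
  spec
}

#' Per-day missingness probability
#'
#' @param spec a calibrated `missingness_spec`.
#' @param sofa integer SOFA score(s) (used under MAR).
#' @param delirium binary status(es) (used under MNAR).
#' @return vector of probabilities.
#' @export
missing_probability <- function(spec, sofa, delirium) {
  stopifnot(inherits(spec, "missingness_spec"))
  switch(spec$mechanism,
    MCAR = rep.int(spec$proportion, max(length(sofa), length(delirium), 1L)),
    MAR = {
      if (is.na(spec$alpha_miss)) stop("MAR spec is not calibrated")
      stats::plogis(spec$alpha_miss + spec$strength * sofa)
    },
    MNAR = {
      if (is.na(spec$alpha_miss)) stop("MNAR spec is not calibrated")
      stats::plogis(spec$alpha_miss + spec$strength * (delirium == 1))
    }
  )
}

#' Mask daily assessments according to a missingness spec
#'
#' Each participant-day's delirium status is independently set to missing
#' with its [missing_probability()]. Under MNAR the probability is driven by
#' the true pre-masking status. SOFA and the outcome are never masked. The
#' true status is retained in `true_delirium` for oracle checks only.
#'
#' @param x a fully observed `cohort`.
#' @param spec a `missingness_spec` (calibrated if MAR/MNAR).
#' @param seed optional integer seed.
#' @return the cohort with missing assessments set to `NA`.
#' @export
impose_missingness <- function(x, spec, seed = NULL) {
  stopifnot(inherits(x, "cohort"), inherits(spec, "missingness_spec"))
  if (anyNA(x$days$delirium)) stop("cohort already contains missing assessments")
  pr <- missing_probability(spec, x$days$sofa, x$days$delirium)
  miss <- local_seed(seed, stats::runif(n_days(x)) < pr)
  x$days$true_delirium <- x$days$delirium
  x$days$delirium[miss] <- NA_integer_
  x$provenance$missingness <- list(spec = unclass(spec), seed = seed,
                                   realized = mean(miss))
  x
}

#' @export
print.missingness_spec <- function(x, ...) {
  cat(sprintf("<missingness_spec> %s, target proportion %.3f", x$mechanism,
              x$proportion))
  if (x$mechanism != "MCAR") {
    cat(sprintf(", strength %.3g, alpha %s", x$strength,
                if (is.na(x$alpha_miss)) "uncalibrated"
                else sprintf("%.4f", x$alpha_miss)))
  }
  cat("\n")
  invisible(x)
}
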