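# Threshold mutation-rate model: irradiation at dose D produces a
# right-skewed distribution of per-individual mutation burdens whose mean
# grows linearly with dose; an individual survives iff its burden is below
# a fixed threshold T. Survivor mean burden therefore saturates toward T
# while survival keeps dropping, so raising the dose above the shoulder
# buys little extra mutation load per unit of survival lost.

#' Configuration of the threshold-burden survival model
#'
#' The per-individual mutation burden at dose `D` is distributed with
#' linear-scale mean `kappa * D` and a constant coefficient of variation
#' `cv`. The default family is lognormal, parameterised so that the
#' linear-scale mean is exactly `kappa * D`
#' (`sigma^2 = log(1 + cv^2)`, `mu(D) = log(kappa * D) - sigma^2 / 2`);
#' a gamma family with the same mean/CV is available as an alternative.
#'
#' @param threshold Tolerable mutation burden `T` (mutations/genome, > 0);
#'   an individual survives iff its burden is below `T`.
#' @param kappa Mean burden induced per Gy (mutations/genome/Gy, > 0).
#' @param cv Coefficient of variation of the burden at any dose (> 0).
#' @param family `"lognormal"` (default) or `"gamma"`.
#' @return An object of class `threshold_config`.
#' @export
threshold_config <- function(threshold, kappa, cv = 0.5,
                             family = c("lognormal", "gamma")) {
  family <- match.arg(family)
  for (nm in c("threshold", "kappa", "cv")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop("`", nm, "` must be a single positive, finite number", call. = FALSE)
    }
  }
  structure(list(threshold = threshold, kappa = kappa, cv = cv,
                 family = family),
            class = "threshold_config")
}

# distribution parameters at dose D (D > 0)
burden_params <- function(config, D) {
  mean_burden <- config$kappa * D
  if (config$family == "lognormal") {
    sigma2 <- log(1 + config$cv^2)
    list(meanlog = log(mean_burden) - sigma2 / 2, sdlog = sqrt(sigma2))
  } else {
    shape <- 1 / config$cv^2
    list(shape = shape, scale = mean_burden / shape)
  }
}

#' Survival probability under the threshold-burden model
#'
#' `P(X < T)` where `X` is the dose-`D` burden distribution. Strictly
#' decreasing in dose; `D = 0` is taken as survival 1 (no burden).
#'
#' @param config A [threshold_config()].
#' @param D Absorbed dose in Gy (vectorised, >= 0).
#' @return Survival probabilities in \[0, 1\].
#' @export
survival_probability <- function(config, D) {
  stopifnot(inherits(config, "threshold_config"))
  if (any(!is.finite(D)) || any(D < 0)) {
    stop("dose must be finite and non-negative", call. = FALSE)
  }
  vapply(D, function(d) {
    if (d == 0) return(1)
    p <- burden_params(config, d)
    if (config$family == "lognormal") {
      stats::plnorm(config$threshold, p$meanlog, p$sdlog)
    } else {
      stats::pgamma(config$threshold, shape = p$shape, scale = p$scale)
    }
  }, numeric(1))
}

#' Mean mutation burden of survivors
#'
#' The truncated mean `E[X | X < T]` at dose `D`, in closed form. For the
#' lognormal family this is
#' `E[X] * pnorm((log(T) - mu - sigma^2)/sigma) / pnorm((log(T) - mu)/sigma)`;
#' for the gamma family
#' `E[X] * pgamma(T, shape + 1, scale) / pgamma(T, shape, scale)`.
#' Always below `T`, and nondecreasing in dose.
#'
#' @inheritParams survival_probability
#' @return Mean burden of the surviving fraction (0 at `D = 0`).
#' @export
survivor_mean_burden <- function(config, D) {
  stopifnot(inherits(config, "threshold_config"))
  vapply(D, function(d) {
    if (d == 0) return(0)
    surv <- survival_probability(config, d)
    if (surv <= 0 || !is.finite(surv) ||
        surv < .Machine$double.xmin * 1e10) {
      stop("no survivors: survival probability is numerically zero at dose ",
           d, call. = FALSE)
    }
    p <- burden_params(config, d)
    mean_burden <- config$kappa * d
    if (config$family == "lognormal") {
      z <- (log(config$threshold) - p$meanlog) / p$sdlog
      mean_burden * stats::pnorm(z - p$sdlog) / stats::pnorm(z)
    } else {
      mean_burden *
        stats::pgamma(config$threshold, shape = p$shape + 1, scale = p$scale) /
        stats::pgamma(config$threshold, shape = p$shape, scale = p$scale)
    }
  }, numeric(1))
}

#' Simulate a cohort of irradiated individuals
#'
#' Draws `n` independent burdens from the dose-`D` distribution and flags
#' survival (`burden < threshold`). Reproducible under a fixed seed.
#'
#' @inheritParams survival_probability
#' @param n Number of individuals (>= 1).
#' @param seed Integer seed for the draw.
#' @return A `data.frame` with columns `burden` and `survived`.
#' @export
simulate_cohort <- function(config, D, n, seed) {
  stopifnot(inherits(config, "threshold_config"))
  if (length(D) != 1L || D <= 0) stop("`D` must be a single positive dose",
                                      call. = FALSE)
  if (n < 1) stop("`n` must be >= 1", call. = FALSE)
  set.seed(seed)
  p <- burden_params(config, D)
  burden <- if (config$family == "lognormal") {
    stats::rlnorm(n, p$meanlog, p$sdlog)
  } else {
    stats::rgamma(n, shape = p$shape, scale = p$scale)
  }
  data.frame(burden = burden, survived = burden < config$threshold)
}

#' Dose-efficiency trade-off table
#'
#' For each dose: survival, survivor mean burden, and the incremental gain
#' ratio between consecutive doses,
#' `(burden[i+1] - burden[i]) / (survival[i] - survival[i+1])` --- the
#' mutation load gained per unit of survival sacrificed. Above the shoulder
#' this ratio shrinks: survival keeps dropping but survivor burden has
#' saturated toward the threshold.
#'
#' @inheritParams survival_probability
#' @param doses Strictly increasing vector of >= 3 doses (Gy).
#' @return A `data.frame` with columns `dose_gy`, `survival`,
#'   `mean_burden_survivors`, `gain_ratio` (NA for the first row; `NaN`
#'   flags a degenerate constant-survival step).
#' @export
dose_efficiency_curve <- function(config, doses) {
  stopifnot(inherits(config, "threshold_config"))
  if (length(doses) < 3L) stop("need at least 3 doses", call. = FALSE)
  if (any(diff(doses) <= 0)) {
    stop("doses must be strictly increasing", call. = FALSE)
  }
  surv <- survival_probability(config, doses)
  burden <- survivor_mean_burden(config, doses)
  dsurv <- -diff(surv)
  gain <- ifelse(dsurv == 0, NaN, diff(burden) / dsurv)
  if (any(dsurv == 0)) {
    warning("constant-survival step: gain ratio undefined (NaN)", call. = FALSE)
  }
  data.frame(dose_gy = doses, survival = surv,
             mean_burden_survivors = burden,
             gain_ratio = c(NA_real_, gain))
}

#' Calibrate the threshold model to a fitted survival curve
#'
#' Maps a shoulder dose / LD50 pair from the multitarget fit onto a
#' [threshold_config()]. Because survival under the model depends on doses
#' only through `T / (kappa * D)`, only one dose can be matched exactly for
#' a fixed coefficient of variation: the threshold is placed at the median
#' burden of the LD50 dose (survival exactly 0.5 there). With
#' `match_shoulder = TRUE` the CV is instead solved so that survival at the
#' shoulder dose also equals the multitarget value, removing the free
#' degree of freedom.
#'
#' @param dq Shoulder dose in Gy.
#' @param ld50 LD50 in Gy.
#' @param kappa Mean burden per Gy; scales burdens but not survival.
#' @param cv Coefficient of variation (ignored when `match_shoulder`).
#' @param match_shoulder Solve the CV from the shoulder-dose survival of
#'   the multitarget curve implied by `(dq, ld50)`.
#' @return A [threshold_config()] (lognormal family).
#' @export
calibrate_threshold_model <- function(dq, ld50, kappa = 0.08, cv = 0.5,
                                      match_shoulder = FALSE) {
  pars <- solve_from_dq_ld50(dq, ld50)
  if (match_shoulder) {
    s_q <- survival_fraction(dq, pars$D0, pars$m)
    if (s_q <= 0.5) {
      stop("shoulder-dose survival must exceed 0.5 to calibrate the CV",
           call. = FALSE)
    }
    sigma <- log(ld50 / dq) / stats::qnorm(s_q)
    cv <- sqrt(exp(sigma^2) - 1)
  }
  sigma2 <- log(1 + cv^2)
  threshold <- kappa * ld50 * exp(-sigma2 / 2)
  threshold_config(threshold = threshold, kappa = kappa, cv = cv,
                   family = "lognormal")
}
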