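# Single-hit multitarget dose-survival model:
#   S(D) = 1 - (1 - exp(-D/D0))^m
# D0 is the dose reducing survival to 1/e on the exponential limb, m the
# extrapolation number. Shoulder dose Dq = D0 * ln(m); LD50 is the dose at
# which S = 0.5.

#' Survival fraction under the single-hit multitarget model
#'
#' Computes `S(D) = 1 - (1 - exp(-D/D0))^m`, the expected fraction of
#' individuals surviving an absorbed dose `D`.
#'
#' @param D Absorbed dose in Gy (vectorised, non-negative).
#' @param D0 Dose in Gy giving 37\% (1/e) survival on the exponential limb
#'   of the curve; must be positive.
#' @param m Extrapolation number (dimensionless, >= 1). `m = 1` collapses
#'   the model to a pure exponential.
#' @return Numeric vector of survival fractions in \[0, 1\].
#' @examples
#' survival_fraction(0, 300, 4)          # 1
#' survival_fraction(300, 300, 1)        # exp(-1)
#' @export
survival_fraction <- function(D, D0, m) {
  check_multitarget_params(D0, m)
  if (any(!is.finite(D)) || any(D < 0)) {
    stop("dose `D` must be finite and non-negative", call. = FALSE)
  }
  1 - (1 - exp(-D / D0))^m
}

#' Shoulder dose of the multitarget survival curve
#'
#' `Dq = D0 * ln(m)`: the dose at which the back-extrapolated exponential
#' limb reaches survival 1, i.e. where the shoulder of the curve ends and
#' survival starts to fall exponentially.
#'
#' @inheritParams survival_fraction
#' @return Shoulder dose in Gy (0 when `m = 1`).
#' @export
shoulder_dose <- function(D0, m) {
  check_multitarget_params(D0, m)
  D0 * log(m)
}

#' LD50 of the multitarget survival curve
#'
#' Closed form of the dose at which half of the individuals die:
#' `-D0 * ln(1 - 0.5^(1/m))`.
#'
#' @inheritParams survival_fraction
#' @return Dose in Gy at which the survival fraction equals 0.5.
#' @export
ld50 <- function(D0, m) {
  check_multitarget_params(D0, m)
  -D0 * log(1 - 0.5^(1 / m))
}

check_multitarget_params <- function(D0, m) {
  if (!is.numeric(D0) || length(D0) != 1L || !is.finite(D0) || D0 <= 0) {
    stop("`D0` must be a single positive, finite dose in Gy", call. = FALSE)
  }
  if (!is.numeric(m) || length(m) != 1L || !is.finite(m) || m < 1) {
    stop("extrapolation number `m` must be a single finite value >= 1",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Recover (D0, m) from a printed shoulder dose and LD50
#'
#' Inverts the two summary statistics of the multitarget model back to its
#' parameters. The ratio `LD50/Dq = -ln(1 - 0.5^(1/m)) / ln(m)` depends on
#' `m` alone and is strictly decreasing, so `m` is found by 1-D root
#' finding and then `D0 = Dq / ln(m)`.
#'
#' @param dq Shoulder dose in Gy (positive, less than `ld50`).
#' @param ld50 LD50 in Gy.
#' @return A list with components `D0` and `m` satisfying
#'   `shoulder_dose(D0, m) == dq` and `ld50(D0, m) == ld50` to ~1e-9
#'   relative accuracy.
#' @export
solve_from_dq_ld50 <- function(dq, ld50) {
  if (!is.numeric(dq) || !is.numeric(ld50) || length(dq) != 1L ||
      length(ld50) != 1L || !is.finite(dq) || !is.finite(ld50) ||
      dq <= 0 || ld50 <= dq) {
    stop("need LD50 > Dq > 0", call. = FALSE)
  }
  target <- ld50 / dq
  ratio_fun <- function(m) -log(1 - 0.5^(1 / m)) / log(m) - target
  lo <- 1.0001
  hi <- 1000
  if (ratio_fun(lo) < 0 || ratio_fun(hi) > 0) {
    stop("inconsistent Dq/LD50 pair: no extrapolation number in [1.0001, 1000]",
         call. = FALSE)
  }
  m <- stats::uniroot(ratio_fun, c(lo, hi), tol = 1e-12)$root
  list(D0 = dq / log(m), m = m)
}

#' Read a dose-survival table
#'
#' Expects a TSV with columns `dose_gy`, `survived`, `total`, one row per
#' dose x replicate (e.g. four replicates of 50 seeds per dose).
#'
#' @param path Path to the TSV file.
#' @return A `data.frame` with the three columns, validated.
#' @export
read_survival_tsv <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_survival_data(d)
  d
}

validate_survival_data <- function(data) {
  need <- c("dose_gy", "survived", "total")
  if (!all(need %in% names(data))) {
    stop("survival data needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (any(data$total <= 0)) {
    stop("`total` must be positive for every row", call. = FALSE)
  }
  if (any(data$survived < 0 | data$survived > data$total)) {
    stop("`survived` must satisfy 0 <= survived <= total", call. = FALSE)
  }
  if (any(data$dose_gy < 0)) stop("doses must be non-negative", call. = FALSE)
  invisible(TRUE)
}

# Collapse replicates to one survival fraction per dose. Default: unweighted
# mean of per-replicate fractions; weighted: pooled counts.
aggregate_survival <- function(data, weight_replicates = FALSE) {
  if ("fraction" %in% names(data)) {
    agg <- stats::aggregate(fraction ~ dose_gy, data = data, FUN = mean)
    return(agg[order(agg$dose_gy), ])
  }
  validate_survival_data(data)
  if (weight_replicates) {
    s <- stats::aggregate(cbind(survived, total) ~ dose_gy, data = data, FUN = sum)
    agg <- data.frame(dose_gy = s$dose_gy, fraction = s$survived / s$total)
  } else {
    data$frac <- data$survived / data$total
    a <- stats::aggregate(frac ~ dose_gy, data = data, FUN = mean)
    agg <- data.frame(dose_gy = a$dose_gy, fraction = a$frac)
  }
  agg[order(agg$dose_gy), ]
}

#' Fit the single-hit multitarget model to dose-survival data
#'
#' Least-squares fit of `S(D) = 1 - (1 - exp(-D/D0))^m` on the linear
#' survival-fraction scale. Replicates are first collapsed to one fraction
#' per dose (see `weight_replicates`). Optimisation is a coarse grid over
#' `(D0, m)` followed by Nelder-Mead and L-BFGS-B refinement, so noiseless
#' model-generated data are recovered essentially exactly.
#'
#' The classical radiobiology alternative, semilog extrapolation of the
#' terminal exponential limb (slope `-1/D0`, intercept `ln m`), is available
#' as `method = "semilog"`.
#'
#' @param data A `data.frame` with columns `dose_gy`, `survived`, `total`
#'   (one row per dose x replicate), or `dose_gy`, `fraction` for
#'   pre-computed survival fractions.
#' @param method `"ls"` (default, nonlinear least squares on the fraction
#'   scale) or `"semilog"` (terminal-limb regression of `log S` on dose).
#' @param weight_replicates If `TRUE`, replicates are pooled
#'   (sum survived / sum total) instead of averaging per-replicate fractions.
#' @param m_max Upper bound for the extrapolation number (default 1000).
#' @return An object of class `multitarget_fit`: a list with `D0`, `m`,
#'   `Dq`, `LD50`, `rss`, the aggregated data, and the method used.
#' @export
fit_multitarget <- function(data, method = c("ls", "semilog"),
                            weight_replicates = FALSE, m_max = 1000) {
  method <- match.arg(method)
  agg <- aggregate_survival(data, weight_replicates)
  doses <- agg$dose_gy
  frac <- agg$fraction

  if (length(unique(doses)) < 3L) {
    stop("fit refused: need at least 3 distinct doses", call. = FALSE)
  }
  if (max(frac) <= 0.8 || min(frac) >= 0.5) {
    stop("fit refused: need one dose with survival fraction > 0.8 and one ",
         "below 0.5 for a well-posed fit (observed range ",
         sprintf("%.3f-%.3f", min(frac), max(frac)), ")", call. = FALSE)
  }
  if (all(frac > 0.95) || all(frac < 0.05)) {
    stop("fit failure: survival is essentially constant (all ~1 or ~0); ",
         "the dose grid does not resolve the curve", call. = FALSE)
  }

  if (method == "semilog") {
    return(fit_multitarget_semilog(doses, frac, m_max))
  }

  sse <- function(D0, m) sum((frac - survival_fraction(doses, D0, m))^2)

  # coarse grid: D0 across [max dose/20, max dose], m log-spaced in [1, m_max]
  d0_grid <- seq(max(doses) / 20, max(doses), length.out = 50)
  m_grid <- exp(seq(0, log(m_max), length.out = 20))
  grid <- expand.grid(D0 = d0_grid, m = m_grid)
  grid_sse <- mapply(sse, grid$D0, grid$m)
  start <- grid[which.min(grid_sse), ]

  # optimise on (log D0, log m); m >= 1 enforced by the L-BFGS-B bound
  obj2 <- function(p) sse(exp(p[1]), exp(p[2]))
  p0 <- c(log(start$D0), log(max(start$m, 1 + 1e-9)))
  nm <- stats::optim(p0, obj2, method = "Nelder-Mead",
                     control = list(reltol = 1e-15, maxit = 5000))
  bb <- stats::optim(nm$par, obj2, method = "L-BFGS-B",
                     lower = c(log(max(doses) / 1e4), 0),
                     upper = c(log(max(doses) * 100), log(m_max)),
                     control = list(factr = 10, pgtol = 0, maxit = 1000))
  best <- if (bb$value <= nm$value) bb else nm
  D0 <- exp(best$par[1])
  m <- max(1, exp(best$par[2]))

  out <- list(D0 = D0, m = m, Dq = shoulder_dose(D0, m), LD50 = ld50(D0, m),
              rss = sse(D0, m), data = agg, method = method)
  class(out) <- "multitarget_fit"
  out
}

fit_multitarget_semilog <- function(doses, frac, m_max) {
  # terminal limb: points with survival <= exp(-1) (at least two; otherwise
  # fall back to survival <= 0.5)
  sel <- frac <= exp(-1) & frac > 0
  if (sum(sel) < 2L) sel <- frac <= 0.5 & frac > 0
  if (sum(sel) < 2L) {
    stop("fit failure: fewer than two doses on the exponential limb",
         call. = FALSE)
  }
  fitlm <- stats::lm(log(frac[sel]) ~ doses[sel])
  slope <- unname(stats::coef(fitlm)[2])
  if (slope >= 0) stop("fit failure: non-decreasing terminal limb", call. = FALSE)
  D0 <- -1 / slope
  m <- min(m_max, max(1, exp(unname(stats::coef(fitlm)[1]))))
  out <- list(D0 = D0, m = m, Dq = shoulder_dose(D0, m), LD50 = ld50(D0, m),
              rss = sum((frac - survival_fraction(doses, D0, m))^2),
              data = data.frame(dose_gy = doses, fraction = frac),
              method = "semilog")
  class(out) <- "multitarget_fit"
  out
}

#' @export
print.multitarget_fit <- function(x, ...) {
  cat("Single-hit multitarget survival fit (", x$method, ")\n", sep = "")
  cat(sprintf("  D0   = %.2f Gy\n", x$D0))
  cat(sprintf("  m    = %.4f\n", x$m))
  cat(sprintf("  Dq   = %.1f Gy (shoulder dose)\n", x$Dq))
  cat(sprintf("  LD50 = %.1f Gy\n", x$LD50))
  cat(sprintf("  rss  = %.3g (survival-fraction scale, %d doses)\n",
              x$rss, nrow(x$data)))
  invisible(x)
}
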