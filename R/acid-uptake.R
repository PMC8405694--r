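# Weak-acid (acetic acid) equilibrium and uptake analysis.
#
# At fermentation pH the undissociated acid crosses the plasma membrane by
# passive diffusion until its concentration equilibrates across the
# membrane; the intracellular pH then follows from the Henderson-Hasselbalch
# relation applied to the total intracellular acid. Uptake timecourses are
# fitted with a saturating rational curve and rate-vs-concentration series
# with an ordinary least-squares line whose slope is the net uptake rate.

#' Fraction of a weak acid in the undissociated form
#'
#' `1 / (1 + 10^(pH - pKa))`; equals 1/2 at `pH == pKa` and decreases
#' strictly with pH.
#'
#' @param pH solution pH.
#' @param pKa acid dissociation constant (acetic acid ~ 4.8).
#' @return fraction in (0, 1).
#' @export
fraction_undissociated <- function(pH, pKa = 4.8) {
  stopifnot(is.numeric(pH), is.numeric(pKa))
  1 / (1 + 10^(pH - pKa))
}

#' Create a weak-acid system state
#'
#' @param pKa acid pKa (default 4.8, acetic acid).
#' @param pH_out extracellular pH.
#' @param total_out total extracellular acid (mM).
#' @param total_in total intracellular acid (mM), optional.
#' @param pH_in intracellular pH, optional.
#' @return object of class `acid_system`.
#' @export
acid_system <- function(pKa = 4.8, pH_out, total_out,
                        total_in = NULL, pH_in = NULL) {
  stopifnot(pH_out > 0, pH_out < 14, total_out >= 0,
            is.null(total_in) || total_in >= 0,
            is.null(pH_in) || (pH_in > 0 && pH_in < 14))
  structure(list(pKa = pKa, pH_out = pH_out, total_out = total_out,
                 total_in = total_in, pH_in = pH_in),
            class = "acid_system")
}

#' Intracellular pH at transmembrane weak-acid equilibrium
#'
#' Assumes the undissociated acid concentration is equal on both sides of
#' the membrane: `HA = total_out * fraction_undissociated(pH_out, pKa)`.
#' The intracellular anion is `total_in - HA` and
#' `pH_in = pKa + log10(A- / HA)`. Requires `total_in > HA` (otherwise no
#' real pH solves the balance).
#'
#' @param sys an [acid_system()] with `total_in` set, or a list with fields
#'   `pKa`, `pH_out`, `total_out`, `total_in`.
#' @return intracellular pH.
#' @export
#' @examples
#' # 144 mM outside at pH 5.0; 96.6 mM accumulated inside
#' intracellular_ph(acid_system(4.8, 5.0, 144, total_in = 96.6))
intracellular_ph <- function(sys) {
  stopifnot(!is.null(sys$pKa), !is.null(sys$pH_out),
            !is.null(sys$total_out), !is.null(sys$total_in))
  ha <- sys$total_out * fraction_undissociated(sys$pH_out, sys$pKa)
  anion <- sys$total_in - ha
  if (anion <= 0)
    abort2(sprintf(
      "total_in (%.4g mM) must exceed the shared undissociated concentration (%.4g mM)",
      sys$total_in, ha), "infeasible_equilibrium")
  sys$pKa + log10(anion / ha)
}

#' Convert scintillation counts to amount of substance
#'
#' @param dpm background-subtracted disintegrations per minute.
#' @param specific_activity DPM per nmol of labelled acid (default 39300).
#' @return amount in nmol; negative inputs are clipped to 0 with a warning.
#' @export
dpm_to_amount <- function(dpm, specific_activity = 39300) {
  stopifnot(specific_activity > 0)
  if (any(dpm < 0)) {
    warning("negative post-subtraction DPM clipped to 0", call. = FALSE)
    dpm <- pmax(dpm, 0)
  }
  dpm / specific_activity
}

#' Fit a saturating uptake curve
#'
#' Least-squares fit of `c(t) = a t / (b + t)` (plateau `a`, half-time `b`)
#' to an uptake timecourse, with a pointwise confidence band from a seeded
#' parametric bootstrap. A degree-(1,1) rational alternative
#' `(p1 t + p2) / (t + q1)` is available via `form = "rational11"`.
#'
#' @param times sampling times (s), strictly increasing, >= 0.
#' @param amounts intracellular amounts/concentrations at `times`.
#' @param ci_level confidence level of the band (default 0.90).
#' @param n_boot bootstrap resamples (default 1000).
#' @param seed RNG seed for the bootstrap.
#' @param form `"saturating"` or `"rational11"`.
#' @return object of class `uptake_fit`: coefficients, `plateau`, residual
#'   `sigma` and `ci_band` (`time`, `fit`, `lower`, `upper`).
#' @export
fit_uptake_curve <- function(times, amounts, ci_level = 0.90,
                             n_boot = 1000L, seed = 1L,
                             form = c("saturating", "rational11")) {
  form <- match.arg(form)
  stopifnot(length(times) == length(amounts))
  if (length(times) < 3L)
    abort2("need at least 3 time points", "insufficient_data")
  if (any(diff(times) <= 0) || any(times < 0))
    abort2("times must be non-negative and strictly increasing",
           "invalid_argument")

  eps <- 1e-8
  df <- data.frame(t = times, y = amounts)
  if (stats::sd(amounts) == 0) {
    warning("constant series: plateau set to the constant, b floored at eps",
            call. = FALSE)
    coefs <- c(a = amounts[1L], b = eps)
    fitted_vals <- rep(amounts[1L], length(times))
    sigma <- 0
    predict_fn <- function(t, cf) cf[["a"]] * t / (cf[["b"]] + t)
  } else if (form == "saturating") {
    fit <- minpack.lm::nlsLM(y ~ a * t / (b + t), data = df,
                             start = list(a = max(amounts), b = max(stats::median(times), eps)),
                             lower = c(a = -Inf, b = eps),
                             control = minpack.lm::nls.lm.control(maxiter = 500))
    coefs <- stats::coef(fit)
    fitted_vals <- stats::fitted(fit)
    sigma <- sqrt(mean(stats::resid(fit)^2))
    predict_fn <- function(t, cf) cf[["a"]] * t / (cf[["b"]] + t)
  } else {
    fit <- minpack.lm::nlsLM(y ~ (p1 * t + p2) / (t + q1), data = df,
                             start = list(p1 = max(amounts), p2 = amounts[1L],
                                          q1 = max(stats::median(times), eps)),
                             lower = c(p1 = -Inf, p2 = -Inf, q1 = eps),
                             control = minpack.lm::nls.lm.control(maxiter = 500))
    coefs <- stats::coef(fit)
    fitted_vals <- stats::fitted(fit)
    sigma <- sqrt(mean(stats::resid(fit)^2))
    predict_fn <- function(t, cf) (cf[["p1"]] * t + cf[["p2"]]) / (t + cf[["q1"]])
  }
  plateau <- if (form == "saturating" || stats::sd(amounts) == 0)
    unname(coefs[[1L]]) else unname(coefs[["p1"]])

  # parametric bootstrap band at the observed times
  band <- NULL
  if (sigma > 0 && n_boot > 0) {
    set.seed(seed)
    boot_pred <- replicate(n_boot, {
      yb <- fitted_vals + stats::rnorm(length(times), 0, sigma)
      cf <- tryCatch({
        if (form == "saturating") {
          stats::coef(minpack.lm::nlsLM(
            yb ~ a * t / (b + t), data = data.frame(t = times, yb = yb),
            start = as.list(coefs), lower = c(a = -Inf, b = eps)))
        } else {
          stats::coef(minpack.lm::nlsLM(
            yb ~ (p1 * t + p2) / (t + q1),
            data = data.frame(t = times, yb = yb),
            start = as.list(coefs), lower = c(p1 = -Inf, p2 = -Inf, q1 = eps)))
        }
      }, error = function(e) coefs)
      predict_fn(times, cf)
    })
    qs <- apply(boot_pred, 1L, stats::quantile,
                probs = c((1 - ci_level) / 2, 1 - (1 - ci_level) / 2))
    band <- data.frame(time = times, fit = fitted_vals,
                       lower = qs[1L, ], upper = qs[2L, ])
  } else {
    band <- data.frame(time = times, fit = fitted_vals,
                       lower = fitted_vals, upper = fitted_vals)
  }
  structure(list(form = form, coefficients = coefs, plateau = plateau,
                 sigma = sigma, ci_level = ci_level, ci_band = band),
            class = "uptake_fit")
}

#' @export
print.uptake_fit <- function(x, ...) {
  cat(sprintf("Uptake fit (%s): plateau = %.4g, sigma = %.3g\n",
              x$form, x$plateau, x$sigma))
  print(x$coefficients)
  invisible(x)
}

#' Net uptake rate from a kinetic series
#'
#' Ordinary least-squares line of permeation rate against extracellular
#' concentration; under passive diffusion the relation is linear and the
#' slope is the net uptake rate coefficient.
#'
#' @param concentrations extracellular acid concentrations (mM).
#' @param rates permeation rates (nmol / (mg dry weight * s)).
#' @return list with `slope`, `slope_se`, `intercept`, `intercept_se`,
#'   `r_squared` and the `lm` fit.
#' @export
fit_kinetic_slope <- function(concentrations, rates) {
  stopifnot(length(concentrations) == length(rates))
  if (length(concentrations) < 2L)
    abort2("need at least 2 points", "insufficient_data")
  if (length(unique(concentrations)) < 2L)
    abort2("all concentrations identical: singular design", "singular_design")
  fit <- stats::lm(rates ~ concentrations)
  sm <- summary(fit)
  list(slope = unname(stats::coef(fit)[2L]),
       slope_se = sm$coefficients[2L, 2L],
       intercept = unname(stats::coef(fit)[1L]),
       intercept_se = sm$coefficients[1L, 2L],
       r_squared = sm$r.squared,
       fit = fit)
}

#' Convert growth-profiler green values to OD600
#'
#' Piecewise calibration: for GV < 10, `0.0322 * 2.72^(0.4328 GV)`
#' (the printed base 2.72 is used literally); for GV >= 10 a cubic
#' polynomial `-0.0004 GV^3 + 0.0398 GV^2 - 0.6506 GV + 5.4063`. The two
#' branches overlap in their stated domains at GV = 10; the polynomial wins
#' there and the ~0.03 OD step between the branches is a property of the
#' printed calibration, not of this implementation.
#'
#' @param gv background-subtracted green values (>= 0).
#' @return OD600 values.
#' @export
gv_to_od600 <- function(gv) {
  if (any(gv < 0)) abort2("green values must be >= 0", "validation_error")
  ifelse(gv < 10,
         0.0322 * 2.72^(0.4328 * gv),
         -0.0004 * gv^3 + 0.0398 * gv^2 - 0.6506 * gv + 5.4063)
}
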