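#' Kinetic parameters of the sensitizer/quencher pre-equilibrium scheme
#'
#' Bundles the rate constants and photophysical terms of the reaction
#' scheme: reversible formation of singlet oxygen from ground-state O2 by
#' energy transfer from the triplet-excited sensitizer (rate constant
#' `k1 = f_delta * kq`), first-order deactivation of 1O2 back to O2
#' (`k2`), and irreversible reaction of 1O2 with the probe compound
#' (`k3`).
#'
#' @param k2 first-order 1O2 deactivation rate constant (s^-1).
#' @param k3 second-order 1O2 + probe rate constant (M^-1 s^-1).
#' @param kq second-order quenching constant of the triplet sensitizer by
#'   O2 (M^-1 s^-1).
#' @param rf rate of triplet-sensitizer formation (M s^-1); set by the
#'   light source and sensitizer concentration.
#' @param f_delta singlet-oxygen formation yield of the triplet + O2
#'   reaction, in (0, 1]. Only the product `rf * f_delta` affects
#'   observable O2 consumption.
#' @return list of class `"kinetic_params"`.
#' @export
kinetic_params <- function(k2 = K2_SINGLET_O2, k3, kq = KQ_TRIPLET_O2,
                           rf, f_delta = 0.75) {
  vals <- c(k2 = k2, k3 = k3, kq = kq, rf = rf, f_delta = f_delta)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all kinetic parameters must be finite and strictly positive")
  }
  if (f_delta > 1) stop("f_delta must lie in (0, 1]")
  structure(as.list(vals), class = "kinetic_params")
}

#' Experimental conditions of one irradiation experiment
#'
#' @param probe_id probe compound: one of `"FFA"`, `"His"`, `"Tyr"`,
#'   `"Met"` or a user-defined label.
#' @param pc0 initial probe concentration (M).
#' @param rb0 sensitizer (rose bengal) concentration (M).
#' @param light_factor relative triplet-formation-rate multiplier
#'   (dimensionless; folds light source and geometry into one number).
#' @param o2_0 initial dissolved O2 (M); air-saturated water is
#'   about 2.7e-4 M.
#' @param duration irradiation time (s).
#' @return list of class `"experiment_conditions"`.
#' @export
experiment_conditions <- function(probe_id, pc0, rb0 = 4e-6,
                                  light_factor = 1, o2_0 = 2.7e-4,
                                  duration = 3600) {
  stopifnot(is.character(probe_id), length(probe_id) == 1L)
  if (pc0 < 0 || rb0 < 0) stop("concentrations must be >= 0")
  if (o2_0 <= 0) stop("o2_0 must be > 0")
  if (duration <= 0) stop("duration must be > 0")
  structure(list(probe_id = probe_id, pc0 = pc0, rb0 = rb0,
                 light_factor = light_factor, o2_0 = o2_0,
                 duration = duration),
            class = "experiment_conditions")
}

#' Steady-state concentration of the triplet-excited sensitizer
#'
#' With dissolved O2 as the dominant triplet quencher,
#' `[3RB*]_ss = rf / (kq * [O2])`.
#'
#' @param params a [kinetic_params()] object.
#' @param o2 dissolved O2 concentration (M), > 0.
#' @return steady-state triplet concentration (M).
#' @export
triplet_steady_state <- function(params, o2) {
  if (any(o2 <= 0)) stop("degenerate input: o2 must be > 0 for a triplet steady state")
  params$rf / (params$kq * o2)
}

#' Steady-state concentration of singlet oxygen
#'
#' `[1O2]_ss = k1 * [3RB*]_ss * [O2] / (k2 + k3 * [PC])` with
#' `k1 = f_delta * kq`.
#'
#' @param params a [kinetic_params()] object.
#' @param triplet_ss steady-state triplet concentration (M).
#' @param o2 dissolved O2 (M).
#' @param pc probe compound concentration (M).
#' @return steady-state 1O2 concentration (M).
#' @export
singlet_oxygen_steady_state <- function(params, triplet_ss, o2, pc) {
  if (any(c(triplet_ss, o2, pc) < 0)) stop("concentrations must be >= 0")
  k1 <- params$f_delta * params$kq
  k1 * triplet_ss * o2 / (params$k2 + params$k3 * pc)
}

#' O2 consumption rate of the pre-equilibrium scheme
#'
#' Substituting both steady states into the rate law collapses it to
#' `rate = rf * f_delta / (1 + k2 / (k3 * [PC]))`, independent of the
#' dissolved O2 concentration. The rate is zero at `pc = 0` and saturates
#' at the singlet-oxygen formation rate `rf * f_delta` for large `pc`
#' (zero-order plateau).
#'
#' @param params a [kinetic_params()] object.
#' @param pc probe concentration (M), >= 0; vectorised.
#' @return O2 consumption rate (M s^-1).
#' @export
o2_consumption_rate <- function(params, pc) {
  if (any(pc < 0)) stop("pc must be >= 0")
  ifelse(pc == 0, 0,
         params$rf * params$f_delta / (1 + params$k2 / (params$k3 * pc)))
}

#' Commitment factor of the irreversible singlet-oxygen reaction
#'
#' `c = k3 * [PC] / k2`: the ratio of the irreversible forward reaction
#' of 1O2 with the probe compound to its physical decay back to ground
#' state O2 — the direct analogue of the forward commitment to catalysis
#' in enzymatic pre-equilibrium kinetics. High commitment masks the
#' intrinsic isotope effect of the forward step.
#'
#' @param pc probe concentration (M), >= 0; vectorised.
#' @param params a [kinetic_params()] object; alternatively supply
#'   `k3_over_k2` directly.
#' @param k3_over_k2 ratio k3/k2 in M^-1 (overrides `params`).
#' @return dimensionless commitment factor(s).
#' @export
#' @examples
#' commitment(0.25, k3_over_k2 = K3_OVER_K2[["FFA"]])  # 120
commitment <- function(pc, params = NULL, k3_over_k2 = NULL) {
  if (any(pc < 0)) stop("pc must be >= 0")
  if (is.null(k3_over_k2)) {
    if (is.null(params)) stop("supply either params or k3_over_k2")
    k3_over_k2 <- params$k3 / params$k2
  }
  k3_over_k2 * pc
}

#' Classify the expected kinetic regime of O2 consumption
#'
#' Heuristic based on the initial probe-to-O2 concentration ratio:
#' zero-order when the probe is in large excess (`pc0 >= zero_ratio *
#' o2_0`), (pseudo-)first-order when the two are of similar magnitude
#' (`pc0 <= first_ratio * o2_0`), `"mixed"` in between. The thresholds
#' are configurable; the ratio alone cannot capture every probe's
#' behaviour (methionine runs stay apparently zero-order down to
#' pc0 ~ o2_0), so measured kinetic orders take precedence when known.
#'
#' @param conditions an [experiment_conditions()] object.
#' @param zero_ratio ratio above which zero-order is expected (default 5).
#' @param first_ratio ratio below which first-order is expected
#'   (default 1.25).
#' @return one of `"zero"`, `"first"`, `"mixed"`.
#' @export
classify_regime <- function(conditions, zero_ratio = 5, first_ratio = 1.25) {
  stopifnot(zero_ratio > first_ratio)
  ratio <- conditions$pc0 / conditions$o2_0
  if (ratio >= zero_ratio) "zero"
  else if (ratio <= first_ratio) "first"
  else "mixed"
}

#' Fit a zero- or first-order rate to an O2 time series
#'
#' Zero-order: OLS slope of `[O2]` vs time (rate in M s^-1). First-order:
#' OLS slope of `ln [O2]` vs time (rate constant in s^-1). `order =
#' "auto"` picks the order with the higher r-squared. Rates are reported
#' as positive loss rates with a 95% confidence half-width (t, n - 2 df).
#'
#' @param times strictly increasing time vector (s).
#' @param o2 O2 concentrations (M), same length, >= 3 points.
#' @param order `"zero"`, `"first"` or `"auto"`.
#' @return list of class `"rate_fit"`: `order`, `rate`, `ci95`,
#'   `r_squared`, `fit`.
#' @export
fit_rate <- function(times, o2, order = c("auto", "zero", "first")) {
  order <- match.arg(order)
  stopifnot(length(times) == length(o2), length(times) >= 3L)
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")

  fit_one <- function(y) {
    fit <- stats::lm(y ~ times)
    s <- suppressWarnings(summary(fit))
    list(rate = -unname(stats::coef(fit)["times"]),
         ci95 = unname(stats::qt(0.975, df = length(times) - 2L) *
                         s$coefficients["times", "Std. Error"]),
         r_squared = s$r.squared, fit = fit)
  }

  zero <- fit_one(o2)
  first <- if (all(o2 > 0)) fit_one(log(o2)) else NULL
  res <- switch(order,
    zero = c(zero, order = "zero"),
    first = {
      if (is.null(first)) stop("first-order fit requires all concentrations > 0")
      c(first, order = "first")
    },
    auto = {
      if (!is.null(first) && first$r_squared > zero$r_squared) {
        c(first, order = "first")
      } else {
        c(zero, order = "zero")
      }
    }
  )
  structure(res[c("order", "rate", "ci95", "r_squared", "fit")],
            class = "rate_fit")
}

#' Regression of zero-order rates against the commitment term
#'
#' Under the pre-equilibrium rate law, apparent zero-order O2 loss rates
#' across experiments sharing one light condition are linear in the
#' kinetic term `1/(1 + k2/(k3 [PC])) = c/(1 + c)`; the slope of the OLS
#' regression estimates the singlet-oxygen formation rate
#' `rf * f_delta`.
#'
#' @param commitments dimensionless commitment factors (>= 2 points).
#' @param rates zero-order O2 loss rates (M s^-1), same length.
#' @return list with `slope` (M s^-1, the 1O2 formation rate estimate),
#'   `intercept`, `r_squared`, and the `lm` fit.
#' @export
rate_commitment_regression <- function(commitments, rates) {
  stopifnot(length(commitments) == length(rates))
  if (length(commitments) < 2L) stop("need at least 2 points")
  x <- commitments / (1 + commitments)
  if (length(unique(x)) < 2L) stop("degenerate input: all kinetic terms equal")
  fit <- stats::lm(rates ~ x)
  r2 <- if (length(rates) >= 3L) suppressWarnings(summary(fit))$r.squared else 1
  list(slope = unname(stats::coef(fit)["x"]),
       intercept = unname(stats::coef(fit)["(Intercept)"]),
       r_squared = r2, fit = fit)
}
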