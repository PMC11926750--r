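#' Convert an enrichment factor to an apparent kinetic isotope effect
#'
#' The isotopic enrichment factor epsilon (permil) of a kinetic process and
#' the apparent 18O kinetic isotope effect (the molecule-averaged ratio of
#' light to heavy observed rate constants, 16k_obs/18k_obs) are related by
#' `AKIE = 1 / (1 + epsilon/1000)`. Negative epsilon (heavy isotopologue
#' reacts more slowly) gives AKIE > 1.
#'
#' @param epsilon enrichment factor in permil; must exceed -1000.
#' @param ci95 optional 95% confidence half-width of `epsilon` (permil);
#'   propagated to first order as `ci95/1000 / (1 + epsilon/1000)^2`.
#' @return A list of class `"akie"` with elements `akie` and `ci95`
#'   (`NA` when no uncertainty was supplied).
#' @seealso [akie_to_epsilon()] for the exact inverse.
#' @export
#' @examples
#' epsilon_to_akie(-25.2)$akie   # 1.0259
epsilon_to_akie <- function(epsilon, ci95 = NA_real_) {
  stopifnot(is.numeric(epsilon), length(epsilon) == 1L, is.finite(epsilon))
  if (epsilon <= -1000) {
    stop("epsilon must be > -1000 permil (isotope ratio must stay positive)")
  }
  akie <- 1 / (1 + epsilon / 1000)
  ci <- if (is.na(ci95)) NA_real_ else (ci95 / 1000) / (1 + epsilon / 1000)^2
  structure(list(akie = akie, ci95 = ci), class = "akie")
}

#' Convert an apparent kinetic isotope effect to an enrichment factor
#'
#' Exact inverse of [epsilon_to_akie()]: `epsilon = (1/AKIE - 1) * 1000`.
#'
#' @param akie dimensionless apparent KIE, strictly positive.
#' @param ci95 optional 95% half-width of `akie`, propagated to first order.
#' @return A list of class `"enrichment"` with elements `epsilon` (permil)
#'   and `ci95`.
#' @export
akie_to_epsilon <- function(akie, ci95 = NA_real_) {
  stopifnot(is.numeric(akie), length(akie) == 1L, is.finite(akie))
  if (akie <= 0) stop("akie must be strictly positive")
  epsilon <- (1 / akie - 1) * 1000
  ci <- if (is.na(ci95)) NA_real_ else 1000 * ci95 / akie^2
  structure(list(epsilon = epsilon, ci95 = ci), class = "enrichment")
}

#' Evaluate the Rayleigh fractionation model
#'
#' Closed-system Rayleigh relation for the residual reactant:
#' `delta = (delta0 + 1000) * f^(epsilon/1000) - 1000`, with `f` the
#' fraction of O2 remaining. The exact form is used, not the linearised
#' `delta - delta0 ~ epsilon * ln f` approximation.
#'
#' @param delta0 initial delta-18O (permil, vs VSMOW).
#' @param epsilon enrichment factor (permil).
#' @param f fraction of substrate remaining, in (0, 1]; vectorised.
#' @return delta-18O of the remaining pool (permil).
#' @export
#' @examples
#' rayleigh_delta(23.6, -25.34, 0.13)  # ~78 permil after 87% consumption
rayleigh_delta <- function(delta0, epsilon, f) {
  stopifnot(is.numeric(f), all(is.finite(f)))
  if (delta0 <= -1000) stop("delta0 must be > -1000 permil")
  if (epsilon <= -1000) stop("epsilon must be > -1000 permil")
  if (any(f <= 0) || any(f > 1)) stop("f must lie in (0, 1]")
  (delta0 + 1000) * f^(epsilon / 1000) - 1000
}

#' Fit a Rayleigh regression for the enrichment factor
#'
#' Ordinary least-squares regression of `1000 * ln((delta + 1000) /
#' (delta0 + 1000))` against `ln(f)`; the slope is the enrichment factor
#' epsilon in permil. The regression is unweighted and carries a free
#' intercept (it is not forced through the origin). The 95% confidence
#' half-width of the slope uses the t distribution with n - 2 degrees of
#' freedom and is `NA` for n = 2 (exact two-point line).
#'
#' @param f numeric vector of fractions remaining, each in (0, 1], at
#'   least two distinct values.
#' @param delta numeric vector of delta-18O values (permil), same length.
#' @param delta0 initial delta-18O. Default `NULL` takes the observation
#'   at the largest `f` (the earliest sample).
#' @return An object of class `"rayleigh_fit"`: a list with `epsilon`,
#'   `ci95`, `delta0`, `n_points`, `r_squared`, and the underlying `lm`
#'   fit in `$fit`.
#' @export
fit_rayleigh <- function(f, delta, delta0 = NULL) {
  stopifnot(is.numeric(f), is.numeric(delta), length(f) == length(delta))
  if (length(unique(f)) < 2L) {
    stop("need at least 2 points with distinct f to fit a Rayleigh regression")
  }
  if (any(f <= 0) || any(f > 1)) stop("all f must lie in (0, 1]")
  if (any(delta <= -1000)) stop("all delta must be > -1000 permil")
  if (is.null(delta0)) delta0 <- delta[which.max(f)]
  if (delta0 <= -1000) stop("delta0 must be > -1000 permil")

  y <- 1000 * log((delta + 1000) / (delta0 + 1000))
  x <- log(f)
  fit <- stats::lm(y ~ x)
  n <- length(f)
  epsilon <- unname(stats::coef(fit)["x"])
  ci95 <- if (n >= 3L) {
    se <- suppressWarnings(summary(fit))$coefficients["x", "Std. Error"]
    unname(stats::qt(0.975, df = n - 2L) * se)
  } else {
    NA_real_
  }
  r2 <- if (n >= 3L) suppressWarnings(summary(fit))$r.squared else 1
  structure(
    list(epsilon = epsilon, ci95 = ci95, delta0 = delta0,
         n_points = n, r_squared = r2, fit = fit),
    class = "rayleigh_fit"
  )
}

#' @export
print.rayleigh_fit <- function(x, ...) {
  cat(sprintf("Rayleigh fit: epsilon = %.4f permil (95%% CI +/- %s), n = %d, r^2 = %.4f\n",
              x$epsilon,
              if (is.na(x$ci95)) "NA" else sprintf("%.4f", x$ci95),
              x$n_points, x$r_squared))
  invisible(x)
}

#' Read (f, delta18O) measurement points from CSV
#'
#' Expects a header row with at least columns `f` and `delta18O_permil`
#' (an optional `sd_permil` column is carried through). Values use the
#' decimal point, permil units.
#'
#' @param path path to a CSV file.
#' @return data.frame with columns `f`, `delta18O_permil` and, when
#'   present, `sd_permil`.
#' @export
read_rayleigh_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("f", "delta18O_permil")
  if (!all(need %in% names(d))) {
    stop("CSV must contain columns: ", paste(need, collapse = ", "))
  }
  d
}
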