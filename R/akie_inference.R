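#' Assemble an AKIE-vs-commitment series from experiment rows
#'
#' Converts per-experiment enrichment factors to apparent KIEs
#' ([epsilon_to_akie()]) and pairs them with forward commitments. The
#' printed `commitment` column is used when present (it is a measured
#' input); otherwise the commitment is computed from the probe's
#' `k3_over_k2` constant and `pc_mM`. Rows whose commitment is
#' inconsistent with the probe's other rows (deviation > 3x from the
#' per-probe median k3/k2) are excluded with a warning unless
#' `include_flagged = TRUE`.
#'
#' @param table data.frame with columns `probe`, `pc_mM`, `epsilon` and
#'   optionally `epsilon_ci`, `commitment`, `entry`.
#' @param k3_over_k2 named vector of per-probe k3/k2 ratios (M^-1); used
#'   when the table has no `commitment` column.
#' @param include_flagged keep rows flagged as inconsistent.
#' @return data.frame of class `"commitment_series"` with columns
#'   `entry`, `probe`, `commitment`, `akie`, `akie_ci95`.
#' @export
build_series <- function(table, k3_over_k2 = K3_OVER_K2,
                         include_flagged = FALSE) {
  if (nrow(table) == 0L) stop("empty experiment table")
  need <- c("probe", "pc_mM", "epsilon")
  if (!all(need %in% names(table))) {
    stop("table must contain columns: ", paste(need, collapse = ", "))
  }
  if (!"commitment" %in% names(table)) {
    unknown <- setdiff(unique(table$probe), names(k3_over_k2))
    if (length(unknown)) {
      stop("no k3/k2 constant for probe(s): ", paste(unknown, collapse = ", "),
           "; supply k3_over_k2")
    }
    table$commitment <- k3_over_k2[table$probe] * table$pc_mM / 1000
  }
  keep <- rep(TRUE, nrow(table))
  if (!include_flagged && nrow(table) >= 2L) {
    flagged <- flag_inconsistent_commitment(table)
    if (any(flagged)) {
      warning("excluding ", sum(flagged),
              " row(s) with commitment inconsistent with the probe's other rows",
              if ("entry" %in% names(table))
                paste0(" (entry ", paste(table$entry[flagged], collapse = ", "), ")")
              else "")
      keep <- !flagged
    }
  }
  table <- table[keep, , drop = FALSE]
  conv <- lapply(seq_len(nrow(table)), function(i) {
    epsilon_to_akie(table$epsilon[i],
                    if ("epsilon_ci" %in% names(table)) table$epsilon_ci[i]
                    else NA_real_)
  })
  out <- data.frame(
    entry = if ("entry" %in% names(table)) table$entry else seq_len(nrow(table)),
    probe = table$probe,
    commitment = table$commitment,
    akie = vapply(conv, `[[`, numeric(1), "akie"),
    akie_ci95 = vapply(conv, `[[`, numeric(1), "ci95"),
    stringsAsFactors = FALSE
  )
  class(out) <- c("commitment_series", "data.frame")
  out
}

#' Estimate the intrinsic KIE3 from an AKIE-vs-commitment series
#'
#' Fits the pre-equilibrium model [akie_model()] with `KIE1` and `EIE1`
#' held fixed (default 1, per the argument that O2 activation to 1O2
#' involves negligible O-bonding change). Two estimators are provided:
#'
#' * `"weighted_ls"` — the model is linear in KIE3, so the fit is a
#'   weighted least-squares regression of `AKIE_i - KIE1 * c_i/(1+c_i)`
#'   on `EIE1/(1+c_i)` without intercept, weights `1/ci95_i^2`; 95% CI
#'   from the regression standard error (t, n - 1 df).
#' * `"per_point_inversion_mean"` — [invert_akie_for_kie3()] applied to
#'   each point, reporting the mean and its t-based 95% CI.
#'
#' @param series a `commitment_series` from [build_series()], or any
#'   data.frame with `commitment`, `akie` and optionally `akie_ci95`.
#' @param kie1,eie1 fixed isotope effects of the reversible step.
#' @param method estimator; see Details.
#' @return list of class `"kie3_fit"`: `kie3_hat`, `ci95`, `method`,
#'   `residuals` (observed - modelled AKIE per entry), `n`.
#' @export
fit_kie3 <- function(series, kie1 = 1, eie1 = 1,
                     method = c("weighted_ls", "per_point_inversion_mean")) {
  method <- match.arg(method)
  if (nrow(series) < 1L) stop("series must contain at least one entry")
  c_i <- series$commitment
  akie_i <- series$akie
  n <- length(akie_i)

  if (method == "per_point_inversion_mean") {
    k3_i <- invert_akie_for_kie3(akie_i, c_i, kie1, eie1)
    kie3_hat <- mean(k3_i)
    ci95 <- if (n >= 2L) {
      stats::qt(0.975, df = n - 1L) * stats::sd(k3_i) / sqrt(n)
    } else NA_real_
  } else {
    w <- if ("akie_ci95" %in% names(series)) 1 / series$akie_ci95^2 else rep(1, n)
    if (any(!is.finite(w)) || all(w == 0)) {
      warning("undefined or zero weights; falling back to unweighted fit")
      w <- rep(1, n)
    }
    y <- akie_i - kie1 * c_i / (1 + c_i)
    x <- eie1 / (1 + c_i)
    fit <- stats::lm(y ~ 0 + x, weights = w)
    kie3_hat <- unname(stats::coef(fit)["x"])
    ci95 <- if (n >= 2L) {
      unname(stats::qt(0.975, df = n - 1L) *
               suppressWarnings(summary(fit))$coefficients["x", "Std. Error"])
    } else NA_real_
  }
  eff <- isotope_effects(kie3 = kie3_hat, kie1 = kie1, kie2 = kie1 / eie1)
  res <- akie_i - akie_model(c_i, eff)
  structure(list(kie3_hat = kie3_hat, ci95 = ci95, method = method,
                 residuals = stats::setNames(res, series$entry), n = n),
            class = "kie3_fit")
}

#' @export
print.kie3_fit <- function(x, ...) {
  cat(sprintf("Intrinsic KIE3 = %.4f (95%% CI +/- %s), %s over %d entries\n",
              x$kie3_hat,
              if (is.na(x$ci95)) "NA" else sprintf("%.4f", x$ci95),
              x$method, x$n))
  invisible(x)
}

#' Predict the AKIE-vs-commitment masking curve
#'
#' Evaluates [akie_model()] on a commitment grid, e.g. for plotting the
#' masking curve through observed apparent KIEs.
#'
#' @param kie3 intrinsic KIE3.
#' @param c_grid commitment values, >= 0.
#' @param kie1,eie1 fixed isotope effects of the reversible step.
#' @return data.frame with columns `commitment` and `akie`.
#' @export
predict_curve <- function(kie3, c_grid, kie1 = 1, eie1 = 1) {
  eff <- isotope_effects(kie3 = kie3, kie1 = kie1, kie2 = kie1 / eie1)
  data.frame(commitment = c_grid, akie = akie_model(c_grid, eff))
}
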