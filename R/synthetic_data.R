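#' Measurement noise model for synthetic data
#'
#' @param sigma_o2 Gaussian noise on O2 concentrations (uM); default 2,
#'   the scale implied by the replicate scatter of the compiled rate
#'   measurements.
#' @param sigma_delta Gaussian noise on delta-18O (permil); default 0.5,
#'   mid-range of the per-experiment measurement errors.
#' @param seed integer seed; all generators are bit-reproducible for a
#'   fixed seed. `NULL` leaves the RNG state untouched.
#' @return list of class `"noise_model"`.
#' @export
noise_model <- function(sigma_o2 = 2, sigma_delta = 0.5, seed = NULL) {
  if (sigma_o2 < 0 || sigma_delta < 0) stop("sigmas must be >= 0")
  structure(list(sigma_o2 = sigma_o2, sigma_delta = sigma_delta, seed = seed),
            class = "noise_model")
}

.seed_rng <- function(noise) {
  if (!is.null(noise$seed)) set.seed(noise$seed)
}

#' Generate a synthetic irradiation-experiment measurement table
#'
#' Forward-simulates the isotopologue ODE for one set of conditions and
#' samples `n_reactors` closed reactors irradiated for different times:
#' sampling times are geometrically spaced in fraction-remaining between
#' `f_start` and `f_final` (experiments were run until 50-90% of the
#' initial O2 was consumed), plus the unirradiated t = 0 reactor.
#' Independent Gaussian noise is added to O2 (uM) and delta-18O per the
#' noise model. If the trajectory never reaches 50% consumption within
#' the experiment duration (e.g. sub-stoichiometric probe with 1:1
#' consumption), a warning is issued and the available range is sampled.
#'
#' @param conditions an [experiment_conditions()] object.
#' @param params a [kinetic_params()] object.
#' @param effects an [isotope_effects()] object.
#' @param noise a [noise_model()].
#' @param n_reactors number of sampled reactors (>= 2), excluding t = 0.
#' @param delta0 true initial delta-18O (permil).
#' @param deplete_pc consume the probe 1:1 with O2 (used for runs where
#'   probe and O2 concentrations are comparable).
#' @param f_start,f_final fraction-remaining range to sample.
#' @return data.frame with columns `time_s`, `o2_uM`, `f`,
#'   `delta18O_permil` (noisy measurements) and the true values in
#'   `o2_uM_true`, `delta_true`.
#' @export
generate_experiment <- function(conditions, params, effects, noise,
                                n_reactors = 8L, delta0 = 23.6,
                                deplete_pc = FALSE,
                                f_start = 0.95, f_final = 0.15) {
  if (n_reactors < 2L) stop("n_reactors must be >= 2")
  .seed_rng(noise)
  traj <- simulate_experiment(conditions, params, effects, delta0 = delta0,
                              n_steps = 400L, deplete_pc = deplete_pc,
                              f_floor = min(f_final * 0.9, 0.05))
  f_min <- min(traj$f)
  if (f_min > 0.5) {
    warning(sprintf(
      "trajectory only reaches f = %.2f (< 50%% consumption) within duration; sampling available range",
      f_min))
  }
  f_lo <- max(f_final, f_min * 1.001)
  f_hi <- min(f_start, max(traj$f[-1]))
  f_grid <- exp(seq(log(f_hi), log(f_lo), length.out = n_reactors))
  # f is strictly decreasing in time; interpolate sampling times on f
  t_grid <- stats::approx(traj$f, traj$time_s, xout = f_grid)$y
  d_grid <- stats::approx(traj$f, traj$delta18O_permil, xout = f_grid)$y
  o2_true <- c(conditions$o2_0, f_grid * conditions$o2_0) * 1e6
  d_true <- c(delta0, d_grid)
  tt <- c(0, t_grid)
  n <- length(tt)
  out <- data.frame(
    time_s = tt,
    o2_uM = o2_true + stats::rnorm(n, 0, noise$sigma_o2),
    f = NA_real_,
    delta18O_permil = d_true + stats::rnorm(n, 0, noise$sigma_delta),
    o2_uM_true = o2_true,
    delta_true = d_true
  )
  out$f <- out$o2_uM / out$o2_uM[1]
  out
}

#' Generate a synthetic control-experiment trace
#'
#' Control reactors (no sensitizer, no probe, or dark) show at most a few
#' percent O2 loss and a delta-18O drift bounded by the O2
#' dissolution equilibrium fractionation. When the noise model is active,
#' the total O2 loss is drawn uniformly from 2-6% of the initial
#' concentration and the total delta drift uniformly from +/- 0.7 permil,
#' applied as linear trends; with both sigmas zero the traces are flat.
#' The printed control bounds (final O2 >= 94% of initial, |delta drift|
#' <= 0.7 permil) hold for every seed by construction.
#'
#' @param kind `"no_sensitizer"`, `"no_probe"` or `"dark"`.
#' @param noise a [noise_model()].
#' @param n_points number of time points.
#' @param o2_0 initial O2 (M); delta0 initial delta-18O (permil).
#' @param delta0 initial delta-18O (permil).
#' @param duration total irradiation time (s).
#' @return data.frame with `kind`, `time_s`, `o2_uM`, `f`,
#'   `delta18O_permil`.
#' @export
generate_controls <- function(kind = c("no_sensitizer", "no_probe", "dark"),
                              noise = noise_model(), n_points = 8L,
                              o2_0 = 2.7e-4, delta0 = 23.6,
                              duration = 14400) {
  kind <- match.arg(kind)
  .seed_rng(noise)
  tt <- seq(0, duration, length.out = n_points)
  if (noise$sigma_o2 == 0 && noise$sigma_delta == 0) {
    loss <- 0; drift <- 0
  } else {
    loss <- stats::runif(1, 0.02, 0.06)
    drift <- stats::runif(1, -0.7, 0.7)
  }
  frac <- tt / duration
  o2 <- o2_0 * (1 - loss * frac) * 1e6
  data.frame(kind = kind, time_s = tt, o2_uM = o2, f = o2 / o2[1],
             delta18O_permil = delta0 + drift * frac)
}

#' Generate a raw IRMS sequence with injected instrument artifacts
#'
#' Builds a measurement sequence the way a daily run is assembled — a
#' reference-gas block of varied peak amplitudes at the start, then
#' blanks, dilute air standards spread evenly across the run, and the
#' samples — and applies the given artifacts in the forward direction so
#' that [correct_sequence()] can invert them: an instrument scale offset
#' (the negative of the calibration offset), linear drift in sequence
#' position, linear amplitude dependence (linearity), and blank
#' admixture by isotope mass balance on samples and standards.
#'
#' @param true_deltas true sample delta-18O values (permil); >= 1.
#' @param artifacts list with `blank_amplitude`, `blank_delta`,
#'   `linearity_slope` (permil per amplitude unit), `drift_slope`
#'   (permil per position), `calibration_offset` (permil). Missing
#'   entries default to 0.
#' @param noise a [noise_model()]; `sigma_delta` is added to every raw
#'   delta.
#' @param n_air number of air standards (>= 3).
#' @param n_blanks number of blanks (>= 2).
#' @param air_true true air-standard delta (permil).
#' @param refgas_delta true reference-gas delta (permil).
#' @return an [irms_sequence()] with a `true_delta` column (`NA` for
#'   blanks and refgas).
#' @export
generate_irms_sequence <- function(true_deltas, artifacts = list(),
                                   noise = noise_model(sigma_delta = 0),
                                   n_air = 3L, n_blanks = 2L,
                                   air_true = DELTA18O_AIR_O2,
                                   refgas_delta = 10) {
  if (length(true_deltas) < 1L) stop("need at least one sample")
  if (n_air < 3L || n_blanks < 2L) stop("need >= 3 air standards and >= 2 blanks")
  .seed_rng(noise)
  a <- function(x) if (is.null(artifacts[[x]])) 0 else artifacts[[x]]
  blank_a <- a("blank_amplitude"); blank_d <- a("blank_delta")
  lin <- a("linearity_slope"); drift <- a("drift_slope")
  cal <- a("calibration_offset")

  # refgas block: amplitudes symmetric about the block centre so the
  # position-amplitude covariance vanishes and drift cannot alias into
  # the fitted linearity slope
  ref_amp <- c(2, 4, 8, 8, 4, 2)
  n_ref <- length(ref_amp)
  n_s <- length(true_deltas)

  kind <- c(rep("refgas", n_ref), rep("blank", n_blanks),
            rep("sample", n_s), rep("standard_air", n_air))
  true <- c(rep(refgas_delta, n_ref), rep(NA_real_, n_blanks),
            true_deltas, rep(air_true, n_air))
  amp_true <- c(ref_amp, rep(blank_a, n_blanks),
                seq(3, 8, length.out = n_s), rep(5, n_air))

  # interleave: refgas block first, then blanks/airs spread among samples
  body_idx <- order(c(seq(0.5, n_s + 0.5, length.out = n_blanks),
                      seq_len(n_s),
                      seq(1, n_s, length.out = n_air) + 0.25))
  body <- (n_ref + 1):length(kind)
  kind[body] <- kind[body][body_idx]
  true[body] <- true[body][body_idx]
  amp_true[body] <- amp_true[body][body_idx]
  position <- seq_along(kind)

  injected <- kind %in% c("sample", "standard_air")
  amp_meas <- amp_true + ifelse(injected, blank_a, 0)

  d <- true - cal + drift * position + lin * amp_meas
  d[injected] <- (amp_true[injected] * d[injected] +
                    blank_a * blank_d) / amp_meas[injected]
  d[kind == "blank"] <- blank_d
  d <- d + stats::rnorm(length(d), 0, noise$sigma_delta)

  out <- irms_sequence(id = sprintf("%s_%02d", kind, position),
                       kind = kind, amplitude = amp_meas,
                       raw_delta = d, position = position)
  out$true_delta <- true[order(position)]
  out
}

#' Scenario suite mirroring the compiled experiment table
#'
#' Builds the full 21-experiment suite: per entry, the experimental
#' conditions (probe, concentrations, light condition), the kinetic
#' parameters with the singlet-oxygen formation rate `rf * f_delta`
#' back-solved from the reported O2 disappearance rate (zero-order:
#' `rate * (1 + c)/c`; first-order: `k * o2_0 * (1 + c)/c` at t = 0),
#' and the true isotope effects assigned by probe chemistry
#' (cycloaddition KIE3 = 1.028 for FFA/His/Tyr, persulfoxide 1.031 for
#' Met; KIE1 = KIE2 = 1).
#'
#' @param o2_0 initial dissolved O2 (M) shared by all entries.
#' @param f_delta assumed singlet-oxygen yield used to split the
#'   back-solved `rf * f_delta` product.
#' @return list of 21 scenarios, each a list with `entry`, `conditions`,
#'   `params`, `effects`, `kinetic_order`, `commitment`, `epsilon`,
#'   `consistent`.
#' @export
scenario_table1 <- function(o2_0 = 2.7e-4, f_delta = 0.75) {
  tab <- experiment_table()
  lapply(seq_len(nrow(tab)), function(i) {
    row <- tab[i, ]
    c_i <- row$commitment
    rate0 <- if (row$kinetic_order == "zero") {
      row$rate * 1e-6                      # uM/s -> M/s
    } else {
      row$rate * 1e-3 * o2_0               # 1e-3/s pseudo-first-order
    }
    rffd <- rate0 * (1 + c_i) / c_i
    k3 <- K3_OVER_K2[[row$probe]] * K2_SINGLET_O2
    duration <- 2.5 * 0.87 * o2_0 / rate0
    list(
      entry = row$entry,
      conditions = experiment_conditions(
        probe_id = row$probe, pc0 = row$pc_mM / 1000,
        rb0 = row$rb_uM * 1e-6, light_factor = 1,
        o2_0 = o2_0, duration = duration),
      params = kinetic_params(k2 = K2_SINGLET_O2, k3 = k3,
                              kq = KQ_TRIPLET_O2,
                              rf = rffd / f_delta, f_delta = f_delta),
      effects = isotope_effects(kie3 = .probe_kie3(row$probe)),
      kinetic_order = row$kinetic_order,
      commitment = c_i,
      epsilon = row$epsilon,
      consistent = row$consistent
    )
  })
}
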