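#' Per-step isotope effects of the pre-equilibrium scheme
#'
#' Kinetic isotope effects (light-over-heavy rate-constant ratios) of the
#' three elementary steps — 1O2 formation (`kie1`), 1O2 deactivation
#' (`kie2`), irreversible 1O2 + probe reaction (`kie3`) — and the
#' equilibrium isotope effect of the reversible formation step,
#' constrained to `eie1 = kie1 / kie2`. Heavy-isotopologue rate constants
#' are `18k = 16k / KIE`, so KIE > 1 means the heavy isotopologue reacts
#' more slowly.
#'
#' @param kie1,kie2,kie3 dimensionless KIEs, all > 0. O2 activation to
#'   1O2 involves minimal bonding change, so `kie1` and `kie2` default
#'   to 1.
#' @return list of class `"isotope_effects"` with `kie1`, `kie2`, `kie3`
#'   and the derived `eie1`.
#' @export
isotope_effects <- function(kie3, kie1 = 1, kie2 = 1) {
  vals <- c(kie1 = kie1, kie2 = kie2, kie3 = kie3)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all isotope effects must be finite and > 0")
  }
  structure(list(kie1 = kie1, kie2 = kie2, kie3 = kie3,
                 eie1 = kie1 / kie2),
            class = "isotope_effects")
}

#' Closed-form apparent KIE of the pre-equilibrium scheme
#'
#' The apparent 18O-KIE of overall O2 consumption is a commitment-weighted
#' blend of the elementary-step isotope effects:
#' `AKIE = (EIE1 * KIE3 + KIE1 * c) / (1 + c)`,
#' where `c = k3[PC]/k2` is the forward commitment. At `c = 0` the full
#' intrinsic effect `EIE1 * KIE3` is expressed; at large `c` the forward
#' reaction out-competes 1O2 decay and the AKIE collapses to `KIE1`
#' (isotope effect fully masked when `KIE1 = 1`).
#'
#' @param c commitment factor(s), >= 0; vectorised.
#' @param effects an [isotope_effects()] object.
#' @return dimensionless apparent KIE(s).
#' @export
#' @examples
#' akie_model(0.077, isotope_effects(kie3 = 1.028))  # 1.0260
akie_model <- function(c, effects) {
  if (any(c < 0)) stop("commitment must be >= 0")
  (effects$eie1 * effects$kie3 + effects$kie1 * c) / (1 + c)
}

#' Invert the pre-equilibrium AKIE model for the intrinsic KIE3
#'
#' Exact algebraic inverse of [akie_model()]:
#' `KIE3 = (AKIE * (1 + c) - KIE1 * c) / EIE1`.
#'
#' @param akie observed apparent KIE(s).
#' @param c commitment factor(s), >= 0.
#' @param kie1 KIE of 1O2 formation (default 1).
#' @param eie1 EIE of the reversible formation step (default 1), > 0.
#' @return intrinsic KIE3 value(s).
#' @export
invert_akie_for_kie3 <- function(akie, c, kie1 = 1, eie1 = 1) {
  if (eie1 <= 0) stop("eie1 must be > 0")
  if (any(c < 0)) stop("commitment must be >= 0")
  (akie * (1 + c) - kie1 * c) / eie1
}

# ODE right-hand side for the two-isotopologue system.
# State: l = [16O16O], h = [18O16O], pc = [PC]; each isotopologue is
# consumed at the singlet-oxygen formation rate scaled by its mole
# fraction and its own commitment term (k1i = k1/KIE1, k2i = k2/KIE2,
# k3i = k3/KIE3 for the heavy species).
.isotopologue_rhs <- function(t, y, p) {
  l <- y[1]; h <- y[2]; pc <- max(y[3], 0)
  tot <- l + h
  cl <- 1 / (1 + p$k2 / (p$k3 * pc))
  ch <- 1 / (1 + (p$k2 / p$kie2) / ((p$k3 / p$kie3) * pc))
  dl <- -p$rffd * (l / tot) * cl
  dh <- -(p$rffd / p$kie1) * (h / tot) * ch
  dpc <- if (p$deplete) dl + dh else 0
  list(c(dl, dh, dpc))
}

#' Simulate isotopologue-resolved O2 consumption
#'
#' Integrates the consumption of the two most abundant O2 isotopologues,
#' 16O16O and 18O16O, under the pre-equilibrium scheme with the
#' steady-state substitutions applied (no explicit triplet or 1O2 state
#' variables — the substitution is exact at this level). Each
#' isotopologue carries its own rate constants `k1/KIE1`, `k2/KIE2`,
#' `k3/KIE3` (light species: all KIE = 1). With `deplete_pc = TRUE` the
#' probe is consumed 1:1 with total O2; otherwise `[PC]` (and hence the
#' commitment) stays constant. 18O18O is neglected (abundance ~4e-6) and
#' the delta series is carried on the isotopologue ratio
#' `[18O16O]/(2 [16O16O])` (see [isotopologue_init()]).
#'
#' Integration uses `deSolve::lsodar` with rtol 1e-10 and atol 1e-15 M,
#' stopping early if total O2 falls to `f_floor` of its initial value
#' (the zero-order regime would otherwise drive concentrations negative).
#'
#' @param conditions an [experiment_conditions()] object.
#' @param params a [kinetic_params()] object.
#' @param effects an [isotope_effects()] object.
#' @param delta0 initial delta-18O of dissolved O2 (permil vs VSMOW).
#' @param n_steps number of output points (>= 2).
#' @param deplete_pc logical; consume the probe compound 1:1 with O2.
#' @param f_floor stop integration when f reaches this value (default
#'   0.01).
#' @return data.frame of class `"isotopologue_trajectory"` with columns
#'   `time_s`, `light`, `heavy`, `pc` (M), `o2` (total, M), `f` and
#'   `delta18O_permil`.
#' @export
simulate_experiment <- function(conditions, params, effects, delta0 = 23.6,
                                n_steps = 100L, deplete_pc = FALSE,
                                f_floor = 0.01) {
  stopifnot(inherits(conditions, "experiment_conditions"),
            inherits(params, "kinetic_params"),
            inherits(effects, "isotope_effects"))
  if (n_steps < 2L) stop("n_steps must be >= 2")
  if (conditions$pc0 <= 0) stop("simulation requires pc0 > 0")

  init <- isotopologue_init(conditions$o2_0, delta0)
  y0 <- c(l = init$light, h = init$heavy, pc = conditions$pc0)
  p <- list(rffd = params$rf * params$f_delta * conditions$light_factor,
            k2 = params$k2, k3 = params$k3,
            kie1 = effects$kie1, kie2 = effects$kie2, kie3 = effects$kie3,
            deplete = deplete_pc)
  times <- seq(0, conditions$duration, length.out = n_steps)
  floor_total <- f_floor * conditions$o2_0
  root <- function(t, y, p) (y[1] + y[2]) - floor_total

  sol <- deSolve::lsodar(y0, times, .isotopologue_rhs, p,
                         rtol = 1e-10, atol = 1e-15, rootfunc = root)
  sol <- as.data.frame(sol)
  if (any(sol$l < 0 | sol$h < 0 | sol$pc < -1e-12)) {
    stop("integration error: negative concentration encountered; ",
         "reduce duration or raise f_floor")
  }
  tot <- sol$l + sol$h
  out <- data.frame(
    time_s = sol$time,
    light = sol$l,
    heavy = sol$h,
    pc = sol$pc,
    o2 = tot,
    f = tot / conditions$o2_0,
    delta18O_permil = ratio_to_delta(sol$h / (2 * sol$l))
  )
  class(out) <- c("isotopologue_trajectory", "data.frame")
  out
}

#' Initial isotopologue concentrations from total O2 and delta-18O
#'
#' delta-18O of O2 is carried on the isotopologue ratio
#' `r = [18O16O] / (2 [16O16O])` normalised to the VSMOW 18O/16O ratio —
#' the quantity a 34/32 ion-current measurement delivers (the factor 2
#' cancels between sample and reference). With 18O18O neglected
#' (abundance ~4e-6) this equals the atom ratio to first order and
#' inverts exactly for given total O2.
#'
#' @param o2_total total O2 concentration (M).
#' @param delta0 delta-18O (permil vs VSMOW).
#' @return list with `light` and `heavy` concentrations (M).
#' @export
isotopologue_init <- function(o2_total, delta0) {
  if (o2_total <= 0) stop("o2_total must be > 0")
  r <- delta_to_ratio(delta0)
  light <- o2_total / (1 + 2 * r)
  list(light = light, heavy = o2_total - light)
}

#' @rdname isotopologue_init
#' @param ratio isotopologue ratio(s) `heavy / (2 * light)`.
#' @export
ratio_to_delta <- function(ratio) (ratio / R_VSMOW - 1) * 1000

#' @rdname isotopologue_init
#' @param delta delta-18O value(s) in permil.
#' @export
delta_to_ratio <- function(delta) {
  if (any(delta <= -1000)) stop("delta must be > -1000 permil")
  R_VSMOW * (1 + delta / 1000)
}

#' Instantaneous apparent KIE along a simulated trajectory
#'
#' Ratio of the instantaneous apparent rate constants of the light and
#' heavy isotopologues, `(d ln[16O16O]/dt) / (d ln[18O16O]/dt)`,
#' estimated by central differences at an interior output point. For a
#' constant-commitment run this equals the closed-form [akie_model()]
#' value; when the probe depletes, the commitment falls and the
#' instantaneous AKIE rises toward `EIE1 * KIE3`.
#'
#' @param traj an `isotopologue_trajectory` from [simulate_experiment()].
#' @param index interior row index (2 .. nrow - 1).
#' @return dimensionless instantaneous AKIE.
#' @export
instantaneous_akie <- function(traj, index) {
  n <- nrow(traj)
  if (index <= 1L || index >= n) {
    stop("index must be an interior point (2 .. nrow - 1)")
  }
  i0 <- index - 1L; i1 <- index + 1L
  dln_l <- log(traj$light[i1]) - log(traj$light[i0])
  dln_h <- log(traj$heavy[i1]) - log(traj$heavy[i0])
  dln_l / dln_h
}

#' Write a simulated trajectory to CSV
#'
#' Columns: `time_s`, `o2_uM`, `pc_uM`, `f`, `delta18O_permil`.
#'
#' @param traj an `isotopologue_trajectory`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  utils::write.csv(
    data.frame(time_s = traj$time_s,
               o2_uM = traj$o2 * 1e6,
               pc_uM = traj$pc * 1e6,
               f = traj$f,
               delta18O_permil = traj$delta18O_permil),
    path, row.names = FALSE)
  invisible(path)
}
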