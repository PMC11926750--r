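#' Physical and kinetic constants
#'
#' Named constants used throughout the package. All are literature or
#' back-derived values and every function that consumes them accepts a
#' user override.
#'
#' @details
#' * `R_VSMOW` — absolute 18O/16O atom ratio of Vienna Standard Mean Ocean
#'   Water, 0.0020052. Only relative ratios affect enrichment factors and
#'   KIEs; the absolute value matters solely for isotopologue
#'   initialisation.
#' * `DELTA18O_AIR_O2` — delta-18O of O2 in ambient air on the VSMOW scale,
#'   23.8 permil; the one-point calibration anchor for IRMS sequences.
#' * `K2_SINGLET_O2` — first-order deactivation rate constant of singlet
#'   oxygen in water, 2.5e5 s^-1 (reciprocal of the ~4 us 1O2 lifetime).
#' * `KQ_TRIPLET_O2` — second-order quenching constant of the sensitizer
#'   triplet state by dissolved O2, 1e9 M^-1 s^-1 (diffusion-limited
#'   order of magnitude; observables depend only on the product of the
#'   triplet formation rate and the 1O2 yield, not on kq itself).
#' * `K3_OVER_K2` — per-probe ratio of the second-order 1O2 + probe rate
#'   constant to k2, in M^-1, back-derived as the median of the printed
#'   commitment-to-concentration ratios of each probe compound:
#'   furfuryl alcohol (FFA) 480, histidine (His) 253, tyrosine (Tyr) 32,
#'   methionine (Met) 63.
#' * `KIE3_PRESETS` — intrinsic 18O kinetic isotope effects of the
#'   irreversible 1O2 + probe step: 1.028 for the cycloaddition pathway
#'   (FFA, His, Tyr; 1O2 attack on furan/imidazole/phenol moieties) and
#'   1.031 for the persulfoxide pathway (Met; single S-O bond formation).
#'
#' @format Named numeric scalars / vectors.
#' @name photokie-constants
NULL

#' @rdname photokie-constants
#' @export
R_VSMOW <- 0.0020052

#' @rdname photokie-constants
#' @export
DELTA18O_AIR_O2 <- 23.8

#' @rdname photokie-constants
#' @export
K2_SINGLET_O2 <- 2.5e5

#' @rdname photokie-constants
#' @export
KQ_TRIPLET_O2 <- 1e9

#' @rdname photokie-constants
#' @export
K3_OVER_K2 <- c(FFA = 480, His = 253, Tyr = 32, Met = 63)

#' @rdname photokie-constants
#' @export
KIE3_PRESETS <- c(cycloaddition = 1.028, persulfoxide = 1.031)

# persulfoxide chemistry applies to methionine only
.probe_kie3 <- function(probe) {
  ifelse(probe == "Met", KIE3_PRESETS[["persulfoxide"]],
         KIE3_PRESETS[["cycloaddition"]])
}
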