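---
title: "Oxygen isotope fractionation through photochemical singlet-oxygen pathways: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Oxygen isotope fractionation through photochemical singlet-oxygen pathways}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(photokie)
```

## The problem

Dissolved O2 in sunlit surface waters is consumed in part through
singlet oxygen (^1^O2): a light-excited sensitizer triplet (in the
laboratory, rose bengal; in nature, chromophoric dissolved organic
matter) transfers energy to ground-state O2, and the resulting ^1^O2
either decays back to O2 or reacts irreversibly with electron-rich
organic moieties. Because the forward reaction and the decay compete,
the ^18^O/^16^O fractionation observed on the residual dissolved O2 is
not a fixed signature: it is the intrinsic isotope effect of the
irreversible step, *masked* to a degree set by how committed ^1^O2 is to
reacting forward. photokie implements the full analysis chain for this
system: Rayleigh regression of enrichment factors, the pre-equilibrium
kinetic and isotope model, forward isotopologue simulation, inference of
intrinsic isotope effects, and the raw IRMS data-correction chain.

## Kinetic model

The reaction scheme is

$$\mathrm{O_2} \xrightleftharpoons[k_2]{k_1 [\mathrm{^3RB^*}]}
  {}^1\mathrm{O_2} \xrightarrow{k_3 [\mathrm{PC}]} \text{products},$$

with `k1 = f_delta * kq` (energy transfer from the sensitizer triplet,
yield `f_delta`), `k2` the first-order ^1^O2 deactivation in water, and
`k3` the second-order rate constant of the probe compound (PC). With O2
as the dominant triplet quencher, `[3RB*]_ss = rf / (kq [O2])`, and
substituting both steady states gives an O2 loss rate independent of
`[O2]`:

$$-\frac{d[\mathrm{O_2}]}{dt} =
  \frac{r_f\, f_\Delta}{1 + k_2 / (k_3 [\mathrm{PC}])}.$$

Probe in excess therefore gives zero-order kinetics with the plateau
rate equal to the ^1^O2 formation rate `rf * f_delta`; a probe
concentration comparable to O2 gives pseudo-first-order behaviour as
`[PC]` depletes. The dimensionless **commitment**
`c = k3 [PC] / k2` — the forward-to-decay ratio of ^1^O2, the direct
analogue of forward commitment to catalysis in enzyme kinetics — is the
single control variable of both the kinetics and the isotope effects.

## Isotope model

Fractionation on the residual O2 pool is quantified by the Rayleigh
relation; `fit_rayleigh()` regresses
`1000 ln((delta + 1000)/(delta0 + 1000))` on `ln f` (exact form, not the
linearised difference approximation) and reports the slope as the
enrichment factor epsilon in permil, with a t-based 95% CI. Epsilon maps
to the molecule-averaged apparent kinetic isotope effect by
`AKIE = 1/(1 + epsilon/1000)` (`epsilon_to_akie()`); the compiled
experiment pairs verify that no additional per-atom factor applies.

Writing per-isotopologue rate constants `18k = 16k / KIE` for each
elementary step, the ratio of the apparent rate constants of
^16^O^16^O and ^18^O^16^O collapses to the pre-equilibrium expression

$$\mathrm{AKIE}(c) = \frac{\mathrm{EIE_1\, KIE_3} + \mathrm{KIE_1}\, c}{1 + c},$$

implemented in `akie_model()`. Its limits carry the physics: at `c -> 0`
the intrinsic effect `EIE1 * KIE3` is fully expressed; at large `c`
every ^1^O2 formed reacts forward and the AKIE collapses to `KIE1`
(~1, since O2 activation to ^1^O2 barely changes O bonding). The
`invert_akie_for_kie3()` inverse is exact, and the two-isotopologue ODE
in `simulate_experiment()` reproduces the closed form to better than
1e-6 at constant commitment — a deliberate dual route (ODE vs algebra)
used throughout the tests.

## Parameters and defaults

| Parameter | Default | Units | Why |
|---|---|---|---|
| `k2` | 2.5e5 | s^-1 | reciprocal ^1^O2 lifetime in H2O (~4 us) |
| `k3/k2` | FFA 480, His 253, Tyr 32, Met 63 | M^-1 | median of the per-probe commitment/concentration ratios of the compiled experiments |
| `kq` | 1e9 | M^-1 s^-1 | diffusion-limited order of magnitude; observables depend only on `rf * f_delta` |
| `f_delta` | 0.75 | – | typical sensitizer ^1^O2 yield; only the product `rf * f_delta` matters |
| `KIE3` presets | 1.028 / 1.031 | – | cycloaddition (furan/imidazole/phenol) vs persulfoxide (methionine) pathways |
| `KIE1`, `KIE2`, `EIE1` | 1 | – | negligible O-bonding change on ^1^O2 formation/decay |
| noise defaults | 2 uM, 0.5 permil | | replicate-scatter scale of the compiled measurements |

`rf` and `f_delta` are not separable from O2 loss data; the product is
treated as one "light condition" parameter. `rate_commitment_regression()`
estimates it as the slope of zero-order rates against `c/(1+c)`, exactly
how the linear correlation across same-light experiments is interpreted;
the scenario suite instead back-solves it per entry from the reported
rate so each simulated experiment matches its measured speed.

## Delta-value convention

delta-18O of O2 is carried on the isotopologue ratio
`[18O16O] / (2 [16O16O])` normalised to the VSMOW ^18^O/^16^O ratio
(0.0020052). This is the quantity a 34/32 ion-current measurement
delivers, and it makes the Rayleigh slope of a constant-commitment
simulation agree with `akie_to_epsilon(akie_model(c))` to better than
0.01 permil. Defining delta on the atom ratio `h/(2l + h)` instead
introduces a systematic `(1 - R) ~ 0.2%` shrinkage of fitted slopes
(0.05 permil at epsilon = -25 permil) because the denominator itself
fractionates; we therefore do not use it. ^18^O^18^O (abundance ~4e-6)
is neglected, matching the two-isotopologue treatment.

## Numerical choices

- **ODE integration**: `deSolve::lsodar`, rtol 1e-10, atol 1e-15 M —
  required so the instantaneous-AKIE/closed-form equivalence holds at
  1e-6. A root function stops integration when total O2 reaches a
  configurable floor (default 1% of initial), since the zero-order
  regime would otherwise drive concentrations negative.
- **Instantaneous AKIE**: ratio of central differences of the log
  isotopologue concentrations. Because `ln h` is globally linear in
  `ln l` at constant commitment, the estimator is exact there up to
  integrator error; during probe depletion it is a local approximation.
- **Regressions**: unweighted OLS with a free intercept for Rayleigh
  fits (whether the original regressions weighted by measurement error
  is not stated; OLS is the documented choice), `delta0` taken from the
  earliest (largest-f) observation unless supplied. Two-point fits are
  exact with an undefined CI.
- **KIE3 estimation**: the masking curves for the reported 1.028/1.031
  may have been drawn rather than formally fitted, so `fit_kie3()`
  reports two estimators side by side — a weighted least-squares fit
  (exploiting that the model is linear in KIE3) and the mean of exact
  per-point inversions. Both are exact on noiseless model data.
- **Kinetic-regime heuristic**: zero-order expected for
  `pc0 >= 5 o2_0`, first-order for `pc0 <= 1.25 o2_0` (the 0.30 mM
  histidine experiment at `o2_0 = 0.27 mM` was first-order, so the
  boundary sits above 1). The ratio alone cannot reproduce every
  observed order — 0.3 mM methionine stayed apparently zero-order at the
  same ratio — so the scenario suite carries the observed orders as
  ground truth and the classifier remains a labelled heuristic.
- **Entry-19 rule**: any row whose implied `k3/k2` deviates more than
  3x from its probe's median is flagged, warned about, and excluded from
  inference by default (`include_flagged = TRUE` overrides). The 1.2 mM
  methionine row's printed commitment of 0.77 (vs ~0.077 implied by its
  siblings) is the motivating case; it is never silently corrected.

## IRMS correction chain

`correct_sequence()` applies, in this fixed order: blank subtraction by
isotope mass balance (peak area proportional to O2 amount), instrument
linearity (OLS slope of reference-gas delta vs amplitude, reference-gas
pulses carry no blank), instrument drift (OLS slope of
linearity-corrected air-standard deltas vs sequence position, pooled),
and a one-point calibration anchoring the mean air standard to
23.8 permil, the delta-18O of O2 in ambient air. Linearity and drift are
modelled as linear — the minimal forms consistent with "change with
signal size / over time". The synthetic sequence generator places the
reference-gas block at the start with amplitudes symmetric about the
block centre, so positional drift cannot alias into the fitted
linearity slope; noise-free artifact injection then inverts to machine
precision, and the tests require < 0.05 permil RMS.

## What the synthetic data do and do not emulate

`scenario_table1()` reconstructs all 21 experimental conditions;
`generate_experiment()` samples 6–10 reactors at geometrically spaced
fractions remaining (runs targeted 50–90% O2 consumption; exact
irradiation grids were not reported, so geometric spacing is a
documented stand-in) with independent Gaussian noise;
`generate_controls()` draws O2 losses within the reported 2–6% control
envelope and delta drifts within ±0.7 permil. The generators reproduce
the statistical structure of the measurements — not their physics
beyond the pre-equilibrium model: no sensitizer photobleaching, no
variable ^1^O2 steady state across experiments (a hypothesised source
of the observed mid-commitment AKIE scatter), no temperature dependence,
no headspace re-equilibration, and a fixed 1:1 PC:O2 stoichiometry.
Consequently, passing round-trip tests demonstrates internal
consistency of the estimators under the stated model, not that real
experiments are free of the model's simplifications. A visible example:
the mid-commitment histidine experiments sit up to ~0.007 AKIE units
above the masking curve — more than the ~0.003 the pre-equilibrium
model rationalises — and the simulator intentionally does not reproduce
that scatter. Sub-stoichiometric probe runs (e.g. 0.15 mM probe vs
0.27 mM O2) cannot reach deep O2 consumption under strict 1:1
stoichiometry; the generator warns and returns the reachable range.

## Problem sizes

Test and script runs use 30–400 ODE output points per trajectory,
8-point Rayleigh/AKIE series, 500 synthetic series for the KIE3
coverage study, 1000 replicates for the epsilon coverage study, and
50–100 seeds for the IRMS and control round trips — sizes at which every
estimator's sampling behaviour is already stable.

## Known limitations

- Triple-oxygen (^17^O) systematics are out of scope.
- One-electron superoxide pathways are represented only as part of the
  generic irreversible ^1^O2 sink, not modelled separately.
- `k3/k2` constants are back-derived from the compiled experiments, not
  independently measured here; they are user-overridable everywhere.
- The kinetic-regime classifier is a concentration-ratio heuristic and
  will mislabel probes with atypical effective kinetics.
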