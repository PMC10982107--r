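---
title: "Isotope pairing analysis of N2O and N2 isotopologues: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Isotope pairing analysis of N2O and N2 isotopologues: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(n2opair)
```

## The measurement and the model

A sealed-vial ¹⁵N tracer incubation runs three nitrogen-transforming
processes at once:

* **anammox** — NH₄⁺ + NO₂⁻ → N₂, pairing one nitrite N with one
  ammonium N;
* **denitrification to N₂O** — two nitrite N per N₂O molecule;
* **N₂O consumption** — reduction of N₂O (both the nitrite-derived and
  the spiked, unlabelled pool) to N₂.

With the nitrite pool labelled at fraction *F* and ammonium unlabelled,
random pairing makes the isotopologue composition of each product a
binomial fingerprint of its source. Drawing two atoms from the nitrite
pool gives heavy (⁴⁶N₂O → ³⁰N₂) with probability *F*², mixed (⁴⁵N₂O →
²⁹N₂) with 2*F*(1 − *F*), light with (1 − *F*)²; anammox pairs give ²⁹N₂
with probability *F*. `pairing_probabilities()` and
`forward_species_rates()` implement this forward map. Summed over the six
species the consumption terms cancel, so total gas-N production equals
anammox + N₂O production — a closure the test suite checks over random
rate draws.

The inversion runs the other way: fit an ordinary least-squares slope
*V*ₒᵦₛ to each of ²⁹N₂, ³⁰N₂, ⁴⁴N₂O and ⁴⁶N₂O over the 4–15 h window
(`fit_slope()`, endpoints inclusive; the first hours are excluded as an
equilibration transient), normalise to mg N per g biomass per hour
(0.028 mg N per µmol of a two-N molecule), and apply

* production = (*V*₃₀ + *V*₄₆) / *F*²,
* consumption = *V*₃₀ / *F*² − *V*₄₄,
* anammox = (*V*₂₉ − 2 *V*₃₀ (1 − *F*) / *F*) / *F*.

The production equation groups (*V*₃₀ + *V*₄₆) before the *F*⁻² scaling:
³⁰N₂ is reduced ⁴⁶N₂O, so their slope sum is the total heavy-pathway
production rate, and only this grouping inverts the forward model
exactly. The anammox equation subtracts the denitrification contribution
to ²⁹N₂ (2*F*(1 − *F*)/*F*² of the ³⁰N₂-equivalent flux) before dividing
by *F*.

### The (1 − F)² consumption correction

Denitrification also produces a little **unlabelled** ⁴⁴N₂O — a fraction
(1 − *F*)² ≈ 0.04 % at *F* = 0.98 — which leaks into the ⁴⁴N₂O slope and
biases the plain consumption equation by (P − Cₙ)(1 − *F*)². This term is
exactly identifiable from the observed ⁴⁶N₂O slope, so
`estimate_activities(correct_44n2o_bias = TRUE)` (the default) adds
(1 − *F*)²/*F*² · *V*₄₆ to the consumption estimate. The correction
vanishes at *F* = 1 and is ~10⁻⁵ mg N g⁻¹ h⁻¹ at realistic rates — far
below replicate scatter — but it makes the simulate → estimate round trip
exact to floating-point precision, which is what the package's
oracle-equivalence tests assert. `n2o_consumption_activity()` without the
optional `v_obs_46n2o` argument applies the uncorrected textbook form.

## The synthetic vial generator

`simulate_vial()` exists so the whole pipeline can be validated without
any external data. It emulates the standard assay: a 30-mL vial with
15 mL of medium (40 mg N L⁻¹ ¹⁵NO₂⁻ at *F* = 0.98, 40 mg N L⁻¹
unlabelled NH₄⁺), ~0.3 g of dewatered biomass, an unlabelled ⁴⁴N₂O spike,
30 °C, triplicates, and multiplicative GC-MS noise on the headspace
readings.

Parameters that matter, with defaults and rationale:

| parameter | default | why |
|---|---|---|
| `f_label` | 0.98 | labelling grade of commercial ¹⁵N-nitrite stocks |
| `no2_mg_n_l`, `nh4_mg_n_l` | 40, 40 | assay substrate loading |
| `n2o_added_umol` | 5 µmol | large enough to dominate the N₂O pool (the spike is ~10× the N₂O produced in 15 h), small enough that its full consumption stays feasible |
| `mlvss_fraction` | 0.10 | volatile-solids content of a wet dewatered pellet; see below |
| `sampling_times` | 0, 2, 4, 6, 9, 12, 15 h | five points inside the 4–15 h fit window |
| `noise_cv` | 0.02 | typical GC-MS repeatability |
| `dt` | 0.01 h | Euler step bound |

**The MLVSS basis.** Biomass-specific activities are conventionally per g
of volatile suspended solids, while the inoculum is weighed as a wet
dewatered pellet. A wet pellet is mostly water: taking its catalytic
MLVSS mass as `biomass_g * mlvss_fraction` (0.3 g × 0.10 = 0.03 g) makes
the assay self-consistent — at activities around 0.9 mg N g⁻¹ h⁻¹ the
finite nitrite, ammonium and N₂O pools then last the full 15 h, which is
exactly what an observed linear 4–15 h window implies. Had the full 0.3 g
been catalytic, the 0.6 mg of nitrite-N would be exhausted near 4 h and
no linear window could exist. The same mass is used in simulation and in
slope normalisation, so recovery accuracy does not depend on the chosen
fraction; only pool-drawdown realism does. The fraction is configurable
for sensitivity analyses.

**Integration.** Zero-order kinetics make every trajectory piecewise
linear, so the Euler scheme with production and consumption applied as
successive half-steps is exact up to floating point while substrate
lasts. When a pool would go negative within a step, the responsible
rates are scaled down proportionally (shared nitrite is split between
anammox and denitrification by their demands), the step completes with
exact mass balance, and the run is flagged `exhausted` with a warning.
Total nitrogen (substrates + 2 × gas molecules) is conserved to better
than 10⁻⁹ relative in every mode — a property test in the suite.

**Consumption allocation.** Source-proportional mode (default) removes
nitrite-derived N₂O in the binomial proportions it was produced in — the
assumption under which the inversion equations are exact.
Pool-proportional mode removes isotopologues in proportion to the
instantaneous pool composition, which is the more agnostic physical
picture. A useful analytic fact, verified by the recovery tests: with the
⁴⁶/⁴⁵/⁴⁴ pools starting empty, pool-proportional consumption preserves
the ⁴⁵:⁴⁶ ratio at its binomial value for all time, so production and
anammox estimates remain exact, and with the ⁴⁶-correction the
consumption estimate does too. The inversion is therefore robust to this
modelling choice under the assay's conditions, not merely "within 10 %".

**Noise model.** Reported headspace amounts are multiplied by independent
Gaussian factors (mean 1, SD `noise_cv`), censored at zero; dissolved
amounts are carried noise-free, mimicking an assay in which only the
headspace is measured. Replicates share one true trajectory and differ
only in noise. The generator does **not** emulate biofilm diffusion
gradients, gas-transfer kinetics (Henry equilibrium is instantaneous),
growth during the assay, isotope fractionation, or drift in *F* as
nitrite is consumed — passing tests show the estimator is correct under
its own assumptions and robust to the allocation choice, not that real
vials satisfy those assumptions.

## Gas–liquid partitioning

All phase splits use dimensionless Henry constants
H_cc = C_liquid/C_gas, derived from reference solubilities at 25 °C with
van 't Hoff temperature correction (`henry_reference()`: N₂O
0.025 mol L⁻¹ atm⁻¹, 2700 K; N₂ 6.4 × 10⁻⁴ mol L⁻¹ atm⁻¹, 1300 K; Sander
2015 compilation), giving H_cc ≈ 0.61 at 25 °C and 0.54 at 30 °C for
N₂O. Salinity and pressure corrections are omitted (freshwater medium,
~1 atm) — a documented limitation. The dissolved-N₂O assay
(`dissolved_n2o()`) inverts the mass balance of a 1-mL aliquot
equilibrated under 12 mL of N₂: C_original = C_gas (V_gas + H_cc
V_liquid)/V_liquid, linear in the reading and exactly invertible.

Slope fitting defaults to **total vial amounts** reconstructed from the
measured headspace (headspace × (1 + H_cc V_l/V_g)) rather than
headspace-only amounts: totals make the inversion's mass balance exact,
while `phase = "headspace"` is retained as a sensitivity mode (it
understates every rate by the species' headspace fraction, ~1.5 % for N₂
and ~35 % for N₂O in the default geometry).

## Statistics and degenerate inputs

Replicates aggregate as arithmetic mean ± sample SD (n − 1). Group
comparisons use Welch's unequal-variance t-test with Welch–Satterthwaite
degrees of freedom; its type-I error at n = 3 per group is checked by
simulation in the test suite. Degenerate cases follow fixed conventions:
two zero-variance groups give p = 1 (equal means) or p = 0 (different
means) with a `degenerate` flag; negative activity estimates are
reported unclamped with a `negative_flag`, since they are informative
about noise or assumption violations; stoichiometric ratios are `NA` with
a flag when net ammonium consumption is non-positive; slope fits require
at least three in-window points and positive time variance.

The reactor generator draws each day's concentrations as independent
Gaussians censored at zero, so `sd = 0` reproduces the means exactly and
the censoring bias is negligible whenever the mean exceeds about two
SDs. Reference anammox stoichiometric ratios (1.32 nitrite consumed and
0.26 nitrate produced per ammonium) are configuration constants from the
anammox literature, not fitted quantities.

## Problem sizes used in validation

The shipped tests and the acceptance script validate at the scale the
assay itself uses: triplicate vials with seven sampling times, 100
random rate draws for noise-free oracle equivalence, 200 seeded noisy
runs for recovery-under-noise coverage, 500 noise realisations for
slope-SE calibration, and 1000 null simulations for Welch-test
calibration. These sizes keep the Monte-Carlo error of every pass-rate
check comfortably inside its acceptance margin while the default test
run stays fast.

## Known limitations

* The inversion assumes a constant label fraction; real incubations
  dilute the ¹⁵N pool slightly as unlabelled N cycles, an effect the
  generator also neglects.
* ⁴⁵N₂O and ²⁸N₂ are modelled but not used by the inversion; the
  ⁴⁵/⁴⁶ ratio (2(1 − F)/F under binomial pairing) is available as a
  consistency diagnostic, not enforced as a constraint.
* Michaelis–Menten saturation is not modelled; the first-order
  consumption mode is a bounded-pool approximation only.
* The dissolved-N₂O assay assumes complete equilibration and no leakage
  during sampling.
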