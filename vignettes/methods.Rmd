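---
title: "Models and methods behind vactrace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind vactrace}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vactrace)
```

`vactrace` implements the complete quantitative chain of a vacuolar
patch-clamp investigation of nitrate-permeable anion channels: solution design,
electrochemistry, synthetic trace generation and single-channel /
whole-vacuole current analysis. This vignette records the models, the
defaults, and the design decisions — especially where the underlying
experimental literature leaves a choice open.

## Conventions and units

Throughout the package: voltages in mV, currents in pA, conductances in
pS, concentrations in mM (solutions) or M (equilibrium solver internals),
time in s. The membrane voltage is **cytoplasm minus vacuole** and positive
current is cation flux from cytoplasm into the vacuole (the Bertl
convention for endomembranes); inward anion current through the channels
studied here therefore appears at negative voltages as negative current.
The default temperature is 295.15 K (22 °C, the culture growth
temperature; recording temperature is taken to be the same).

## Solutions and activities

A solution is a table of ionic species with totals, charges, mobilities
and ion-size parameters, plus pH and temperature. Recipes written as salt
lists (`solution_from_salts()`) are expanded assuming full dissociation of
NaNO₃, HNO₃, HCl, CaCl₂ and MgCl₂. Two modelling points deserve note:

* **BTP (bis-tris propane) is treated as a diprotic base** with pKa 9.0
  and 6.8 (both configurable). The recipes pair ~200 mM strong acid with
  100–160 mM BTP; only with both protonation sites does the buffer carry
  the ≈1.4 charges per molecule needed to balance the anions
  (electroneutrality within ~10 %). A single-site model would halve the
  ionic strength and distort every downstream activity correction.
* **EGTA is carried as a divalent anion** for ionic-strength purposes: all
  of its dominant forms near pH 7 (H₂EGTA²⁻, CaEGTA²⁻, MgEGTA²⁻) carry
  charge −2, so no self-consistent iteration is needed.

Single-ion activity coefficients offer two standard dilute-solution
models. The **extended Debye–Hückel form with Kielland ion-size
parameters** is the default wherever reversal potentials are computed: it
is the form used throughout the junction-potential and selectivity
literature, and at the ~0.2–0.3 M ionic strengths of these recipes it
reproduces the expected ~7 mV activity correction of a tenfold nitrate
gradient, where the size-free Davies form over-corrects by several mV. The
**Davies equation** (0.3·I variant) is retained as `method = "davies"`.
Note a mathematical caveat: the Davies bracket √I/(1+√I) − 0.3·I peaks
near I ≈ 0.39 M, so γ(I) is only monotone below that; both models warn
above 0.7 M.

## Reversal potentials and selectivity

`nernst_potential()` is the activity-corrected Nernst equation in the sign
convention above. `ghk_reversal_potential()` implements the GHK voltage
equation restricted to **monovalent anions** — the divalent cations in
these recipes (Ca²⁺, Mg²⁺) are not reported as permeant and enter only
through the ionic strength. With one permeant species GHK reduces
algebraically to Nernst; the test suite checks this identity to 10⁻⁹ mV.
`fit_permeability_ratio()` inverts the two-anion equation by bisection on
log₁₀(r) until the reproduced reversal potential is within 0.01 mV. All
chloride in the system — including the 8 mM contributed by CaCl₂/MgCl₂ on
the nominally "nitrate" side — enters the GHK sums; dropping it shifts the
fitted NO₃⁻/Cl⁻ ratio by ~2 %.

`henderson_junction_potential()` estimates junction potentials with the
Henderson equation from limiting equivalent conductances (25 °C table
values; only ratios matter). BTP has no measured mobility, so it is
assigned the Tris value — documented in `ion_reference()` and overridable
per solution. Junction potentials here are *estimates*; experimental
practice measures them, and junction-shifted protocol grids (e.g.
−94…+86 mV) are kept exactly as recorded, never re-interpolated.

## Ca/Mg-EGTA equilibria

`solve_equilibrium()` solves the coupled mass-action/mass-balance system
for free Ca²⁺, free Mg²⁺ and free EGTA with the four protonation states
and the CaEGTA, CaHEGTA, MgEGTA, MgHEGTA complexes, at clamped pH (every
recipe is pH-buffered, so no proton balance is solved). The solver is
damped Newton iteration on log-concentrations (cap 200 iterations) and
refuses to return if any mass balance misses by more than 10⁻⁹ M.

The shipped reference constants (`egta_constants()`) are the
Martell–Smith critical values at 0.1 M and 20 °C — pKa 9.47 / 8.85 /
2.66 / 2.00; log K 10.86 (CaEGTA), 5.33 (CaHEGTA), 5.21 (MgEGTA), 3.37
(MgHEGTA) — the lineage used by the MaxChelator family of buffer
calculators. Adjustment to working conditions follows that family's
scheme:

* metal-complex constants are corrected for ionic strength with a
  Davies-type term (0.25 linear coefficient, the value used by the
  Chelator program line) and charge-product exponents (16 for M²⁺+L⁴⁻,
  12 for M²⁺+HL³⁻), and for temperature by van't Hoff with ΔH = −33.3
  kJ/mol (CaEGTA, exothermic) and +21.2 kJ/mol (MgEGTA, endothermic);
* protonation constants are mixed-mode values (determined with a glass
  electrode), so the **meter pH is used with them directly**, without a
  single-ion H⁺ activity conversion.

This combination was chosen once, at design time, by checking candidate
published schemes against the five buffer design points printed in the
recipes of the emulated experiments (totals of 2.08/1.84/1.04 mM CaCl₂ for
100/10/1 µM free Ca²⁺ and 10.44/2.11 mM MgCl₂ for 10/2 mM free Mg²⁺);
the scheme above reproduces all five within ~10 %, while fuller
thermodynamic treatments (activity-scale pH plus Davies-shifted pKa)
drift 30–60 % low on the most sensitive designs. Free Ca²⁺ near the
Ca/EGTA equivalence point is proportional to 1/K′ and therefore
exquisitely sensitive to the constant vintage; disagreements at this level
between buffer programs are well documented. `design_total_for_target_free()`
inverts the solver by monotone root-finding on the added salt (carrying
the chloride counter-ion so the designed recipe's ionic strength is the
one actually produced), to 0.1 % of the target.

DTT, HEPES, TRIS, MES and BTP are treated as non-chelating for Ca/Mg; no
ATP/BAPTA/citrate ligands are modelled.

## The synthetic-data generator

`simulate_patch_current()` is the ground-truth source for every analysis
test. Design choices:

* **Two-state gating** (C↔O, rates α, β). The emulated recordings
  constrain only the stationary open probability and unitary current, not
  dwell-time structure, so absolute rates are free parameters: the default
  closing rate is 40 s⁻¹ (mean open time 25 ms, comfortably above the
  2 kHz filter rise time) and α is derived from the requested Po.
  Ligand conditions (Ca²⁺, Mg²⁺, pH) are represented as alternative
  (α, β) presets, not mechanistic binding schemes. Optional voltage
  dependence enters as a Boltzmann factor on α/β.
* **Event-driven simulation**: exponential dwell times drawn exactly,
  then sample-and-hold discretisation at the sampling rate — no
  per-sample Bernoulli bias. A warning is raised if mean dwells fall
  below two sampling intervals (aliasing).
* **Linear chord current** i(V) = g·(V − E_rev): conductances in this
  preparation are reported as current/voltage ratios, so no GHK flux
  rectification is simulated.
* **Noise and filtering**: Gaussian noise (default sd 0.5 pA) is added
  before a causal 4-pole Bessel-type low-pass (2 kHz at 10 kHz sampling
  by default — the recording settings emulated). The digital filter is
  the bilinear transform, with prewarping, of the analog 4th-order Bessel
  prototype whose poles are computed from the reversed Bessel polynomial
  and 3 dB-normalised numerically; DC gain is exactly 1, so plateau
  levels are preserved.
* **Reproducibility**: a seed is mandatory; sweep k of a protocol uses
  seed + 1000·k so any single sweep can be regenerated in isolation.

What the generator does **not** emulate: capacitive transients, leak and
seal conductance, 1/f and excess open-channel noise, subconductance
levels, rundown, or multi-state kinetics. Tests passing on these
synthetic traces therefore validate the estimators under ideal
stationarity assumptions; on real recordings, baseline drift and leak
would first have to be handled upstream.

## Amplitude histograms and mixture fits

`build_amplitude_histogram()` bins samples at 0.1 pA by default and, for
protocol sweeps, uses only the quasi-stationary test-segment samples
(discarding the first 5 ms after each step — ten filter time constants).
Counts are conserved exactly and histograms of concatenated traces add.

`fit_peak_mixture()` is a least-squares sum-of-Gaussians fit to the
binned counts, in the spirit of the GRAMS-style peak fitting used for
such data, with three stabilising choices that proved necessary:

1. **Shared peak width.** All components share one sd; the smallest peaks
   (e.g. the four-channels-open level at Po ≈ 0.2, expected occupancy
   0.2 %) carry too few samples to support their own width.
2. **A fitted flat pedestal.** Low-pass-filtered gating transitions leave
   ~1 % of samples *between* levels. Without a pedestal, model selection
   buys spurious components to fit that bridge density — components that
   can out-weigh a genuine high-open level.
3. **Poisson weighting.** Each bin contributes (obs − fit)²/max(obs, 1),
   the χ² statistic. Unweighted fits let the shape misfit of the dominant
   peaks (~10⁴-count bins) drown the entire signal of a ~70-count peak.

The component count K is chosen by BIC (χ² + p·ln n) over K = 1 …
max_channels + 1, capped at the number of local maxima of the smoothed
histogram (peaks are only placed where the data show a mode, as an
analyst would place them; transition bridges are monotone and contribute
none), ties broken toward fewer components. After selection, an interior
component with less than 0.2× the area of both neighbours is rejected:
the level occupancies of N independent identical channels are binomial,
hence unimodal in k, so such a component cannot be a gating level.

The **baseline peak** is identified geometrically: all open levels lie on
one side of the baseline, so the baseline is one of the two outermost
components — the one whose opposite extreme carries the smaller area.
This is robust both to leak offsets (unlike "nearest zero") and to
multi-channel patches where the one-open level is more probable than
all-closed (which defeats "the modal current" as a baseline criterion —
at N = 4, Po = 0.21 the one-open probability is 0.414 against 0.389
closed). `"mode"` and `"zero"` remain available options.

From the fitted mixture: Po = Σk·A_k/(N·ΣA_k) (`open_probability()`),
i.e. NPo normalised per channel under channel independence — whether
multi-channel patches should be reported as NPo or NPo/N is not
standardised, so the normalisation is explicit and N defaults to the
maximum simultaneous open level observed. The unitary current is the mean
adjacent peak spacing signed away from baseline, and the conductance is
the chord g = i/V at the most extreme applied voltage (the I/V curves of
these channels are nonlinear, making slope conductances misleading).

## Whole-vacuole analysis

`steady_state_current()` averages the final 10 % of the 3 s test pulse by
default (the averaging window used in the emulated experiments is unreported; the
last 10 % sits well past the slow activation seen in the recordings).
Current densities use a membrane area from either the optical diameter
(sphere, πd²) or capacitance at 10 mF m⁻² — which sizing the original
experiments used is unreported, so both are provided. `aggregate_jv()`
averages across vacuoles only on exactly matching voltage grids.

## Pipeline and reproducibility

`run_pipeline()` ties the stages together from a YAML config (seed
mandatory, all defaults echoed into the report) and writes every
intermediate artifact — traces with JSON sidecars, histograms, mixture
fits, I/V tables and `report.json`. Reports are byte-identical across
runs with the same seed. Traces round-trip through CSV at full binary
precision (`%.17g`). The package's function surface *is* its command-line
interface: each stage is a plain function over data frames, and
`scripts/acceptance.R` shows the intended scripted use.

## Problem sizes in the tests

The test suite simulates 30 s of 10 kHz data per headline
parameter-recovery condition (the duration at which the Monte-Carlo
standard error of a Po ≈ 0.4 estimate falls near 0.02 with 40 s⁻¹
closing rates) and 4–20 s for property checks; the shipped demo config
uses 8 s analysis recordings. Mass-balance and GHK–Nernst equivalence
properties run over hundreds of randomised inputs under fixed seeds.

## Known limitations

* Free-ion predictions inherit the constant-vintage uncertainty of EGTA
  equilibria; near the equivalence point different published sets differ
  by factors of 2–3 in free Ca²⁺.
* Junction potentials are Henderson estimates with an approximated BTP
  mobility, not measurements.
* The GHK module is monovalent-anion-only by design; no Pitzer/SIT
  activity models, no temperature-dependent mobilities.
* The mixture analysis assumes identical independent channels with a
  single conductance class; subconductance states or heterogeneous
  patches violate its binomial pruning assumption.
* Reversal-potential estimation interpolates linearly and needs a sign
  change in the sampled I/V range; strongly rectifying whole-vacuole
  curves may not provide one (the estimator then errors rather than
  extrapolating).
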