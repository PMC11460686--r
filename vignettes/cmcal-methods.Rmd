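---
title: "Calibrating cell-specific iPSC-CM models: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrating cell-specific iPSC-CM models: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Induced pluripotent stem cell-derived cardiomyocytes (iPSC-CMs) are
immature, usually spontaneously beating cardiac cells whose
electrophysiological phenotype varies strongly between donors, cell
lines, and differentiation protocols. A single "average" mathematical
model cannot represent this variability. `cmcal` builds *digital twins*
of iPSC-CM preparations: it tunes the maximal-conductance parameters of
an iPSC-CM electrophysiology model until the model reproduces a specific
preparation's action potential (AP) and calcium transient (CaT)
waveforms, and then uses the calibrated model to predict that
preparation's responses to unseen perturbations — most importantly its
arrhythmia susceptibility under I~Kr~ block.

Because optical voltage- and calcium-dye recordings are far easier to
acquire at scale than patch clamp, the pipeline is designed around
*normalized* traces: each recorded segment is scaled to span [0, 1],
exactly what a relative-fluorescence readout provides. The central
question the package's experiments answer is whether such amplitude-free
data, collected under a small number of varied culture conditions,
constrain the conductances well enough to make cell-specific predictions.

# The model core

The ordinary-differential-equation core follows the Kernik iPSC-CM
formulation: 22 state variables — membrane potential, intracellular and
sarcoplasmic-reticulum (SR) calcium, intracellular Na^+^ and K^+^, and
the gating variables of I~Na~, I~CaL~ (with calcium-dependent
inactivation), I~CaT~, I~to~, I~Kr~, I~Ks~, I~f~, plus a Shannon-type
three-state SR release gate. Voltage-gated activation/inactivation uses
the generalized two-exponential rate form
$\alpha = x_1 e^{V/x_2}$, $\beta = x_3 e^{V/x_4}$ with the steady-state
constraint $x_3 = x_5 x_1$, $x_4 = (1/x_2 + 1/x_6)^{-1}$, so
$x_\infty = \alpha/(\alpha+\beta)$ and $\tau = 1/(\alpha+\beta) + c$.
Pumps, exchanger and background currents use the ten Tusscher
formulations rescaled for the iPSC phenotype; I~CaL~ carries Ca^2+^,
Na^+^ and K^+^ with Shannon permeability ratios.

The package's baseline parameterization was fixed once, against the
published baseline phenotype of this model class: maximum diastolic
potential near −76 mV, upstroke velocity ≈ 30 mV/ms, diastolic
Ca~i~ ≈ 0.1 µM, and a spontaneous rate inside the 0.3–1.0 Hz
automaticity band of cultured iPSC-CMs. With all multipliers at 1 the
shipped model beats spontaneously at ≈ 0.96 Hz with APD~90~ ≈ 465 ms.
These constants are part of the package; they are never refit by the
calibration machinery.

Sixteen dimensionless multipliers scale the maximal
conductances/fluxes:
`g_Na, g_f, g_CaL, g_CaT, g_to, g_Kr, g_Ks, g_K1, g_NaK, g_NaCa, g_PCa,
g_bNa, g_bCa, g_up, g_leak, g_rel`.
An all-ones `conductance_set()` reproduces the baseline model exactly;
channel block by a fraction $b$ multiplies the targeted parameter by
$(1-b)$ through a fixed current-name registry.

## Numerical choices

* **Solver.** LSODA (stiff/non-stiff switching) with `rtol = 1e-6` and
  per-state absolute tolerances: 1e-4 for V, 1e-8 for concentrations,
  1e-6 for gates. Dense output is taken from the solver interpolant on
  the requested grid (default 0.1 ms), never by forcing step size.
* **Stimulus.** Pacing pulses (default 60 pA/pF, 1 ms, first pulse at
  `t = period`) are additive inward current, integrated piecewise so the
  adaptive solver can never step over a pulse.
* **Failures.** An integration that does not complete, produces
  non-finite states, or leaves |V| > 200 mV returns a *flagged failed
  trace*; the calibration fitness maps it to a sentinel penalty (10^6^)
  instead of crashing. Population draws far from baseline make such
  candidates routine.
* **Degenerate inputs.** The GHK-type I~CaL~ driving terms are guarded
  at V = 0; normalization of a constant (non-beating) segment is an
  explicit error; APD of a non-repolarizing beat is `NA`, reported but
  never silently dropped.
* **Initial state.** The canonical starting point is the final
  *diastolic* state (maximum diastolic potential) of a 10-minute
  unpaced baseline run in 151/1.8/5.4 mM Na/Ca/K — computed once per
  session by `initial_state()` and cacheable to JSON.

# Protocols and the fluorescence surrogate

A `condition()` is a milieu + pacing + block + duration; a `protocol()`
is an ordered list of conditions with full state carry-over (all state
variables, including ion concentrations, survive a milieu switch — only
external parameters change). Each condition's *trailing window* (default
5 s at 0.1 ms) is the recorded segment, matching steady-state optical
acquisitions.

The canonical library reconstructs 19 conditions from three families —
buffer Ca^2+^ ∈ {1.0, 1.8, 2.5} mM, pacing ∈ {spontaneous, 1, 1.25,
1.5, 2} Hz, I~CaL~ block ∈ {25%, 50%} — plus mixtures; condition 19 is
the physiological, unperturbed baseline. The *optimized* calibration
protocol is the 3-condition sequence (1) 1.0 mM Ca^2+^ spontaneous →
(2) 1.8 mM spontaneous → (3) 1.8 mM, 1.25 Hz pacing + 25% I~CaL~ block.

Min–max normalization is the sole fluorescence forward model:
`normalize_traces()` scales each condition's V and Ca independently to
[0, 1] ("per-segment"), treating every recording as an independent
acquisition; a "global" mode is available for sensitivity checks. No
optical blurring, photobleaching or motion artifact is modelled, so
tests passing on normalized synthetic data show that *amplitude loss*
does not break calibration — not that the pipeline is robust to every
optical artifact.

# The in-silico dataset generator

`draw_multipliers(n, spread = 0.2)` draws each multiplier as
$e^z$, $z \sim N(0, 0.2)$ — the population-of-models convention with
median multiplier exactly 1 (mean ≈ 1.02). The natural-log reading of
"spread 0.2" is the package's choice; a log2 variant is exposed because
the two conventions differ only by a scale factor of log(2). Cells are
simulated under the unperturbed baseline and kept when their spontaneous
rate lies in the closed band [0.3, 1.0] Hz; four randomly selected
survivors (documented seed) form the dataset, simulated under all 19
conditions with raw and normalized copies derived from identical
simulations.

# Feature extraction and arrhythmia labels

Beats are upstrokes where the smoothed dV/dt exceeds 10% of its window
maximum, with a 200 ms lockout; the same rule serves normalized traces.
APD~f~ runs from the upstroke to the linearly interpolated crossing of
`peak − f·amplitude`. Amplitudes are peak minus preceding diastolic
minimum, per signal.

The classifier returns the first matching label in the priority order
**cessation > afterdepolarization > alternans > tachycardia > irregular
> none**, with all thresholds in `arrhythmia_config()`:

* *cessation*: fewer than 2 beats, or all amplitudes < 10% of a known
  baseline amplitude;
* *afterdepolarization* (EAD/DAD combined): a re-depolarization ≥ 5% of
  the beat amplitude between peak and next upstroke **that falls again
  by at least half its rise** — the fall requirement separates genuine
  afterdepolarization bumps from the smooth diastolic depolarization
  that every spontaneous iPSC-CM shows;
* *alternans*: ≥ 4 consecutive beats whose APD~90~ differences alternate
  in sign, each > 5% of the mean APD~90~;
* *tachycardia*: rate > max(2 Hz, 2 × baseline rate);
* *irregular* (single-cell surrogate for torsadogenic dynamics):
  inter-beat-interval coefficient of variation > 0.2.

These detection rules and numbers are package choices; the reported
block-tolerance thresholds therefore come with a classifier-sensitivity
companion (see the acceptance script), which re-scans with a stricter
afterdepolarization threshold.

# Genetic-algorithm calibration

Genes are log2 multipliers of the free parameters (default all 16),
bounded to [−3.32, 3.32] (0.1×–10×). Defaults: population 200, 20
generations, size-2 tournament selection, uniform crossover (p = 0.5
per gene), Gaussian mutation in log2 space with a geometrically
annealed step (σ = 0.2 at the first generation down to 0.05 at the
last — a fixed large step explores well but never refines, and at small
generation budgets it dominates the run-to-run scatter of the fitted
values), per-gene mutation rate 0.3, elitism top 5%, sentinel fitness
10^6^. The initial population is drawn log2-normal around baseline
(σ = 1, clamped to the bounds), the same kind of random
conductance-scale-factor population the method simulates — a uniform
draw over the full 0.1×–10× box mostly produces non-beating cells and
wastes the evaluation budget (uniform initialization remains available).
These search settings are package defaults chosen from common GA
practice for conductance fitting; they are exposed in `ga_config()` and
recorded with every run.

Fitness is the sum over segments of the point-wise mean squared error
between candidate and target, V and Ca weighted so both signals
constrain the fit: on normalized data both live on [0, 1] and are
summed as-is, while on raw data each calcium segment's MSE is weighted
by (voltage range / calcium range)² — plain summed MSE in physical
units (mV versus mM) would let the calcium term (∼10⁻⁸ mM²) vanish
against the voltage term and silently drop the calcium constraint.
`trace_fitness()` itself defaults to the plain unweighted sum. Because
spontaneous segments have arbitrary phase, the candidate is first
beat-aligned to the target by a circular shift at the first upstroke
(configurable: none | first-upstroke | cross-correlation). A failed or
non-beating candidate against a beating target scores the sentinel.

Candidate simulations can use a reduced per-condition pre-equilibration
(`condition_duration_ms`); targets for reduced-cost experiments are
generated with the same setting so candidate and target see identical
protocols. Repeated runs (`calibrate_ensemble()`, default 10) differ
only by seed and initial population; the per-parameter sample standard
deviation of log2(fitted/true) across runs is the *calibration spread*,
and |log2(fitted/true)| is the *calibration error*.

# Evaluation

* `predict_response()` simulates a fitted cell under a perturbation that
  was never part of calibration (default 30% I~Kr~ block; 30% or 15%
  I~K1~ block are supported alternatives).
* `prediction_scores()` reports trace MSE (same definition as the
  fitness), the percent error of amplitude-normalized APD~90~ under
  block, and the percent error of the amplitude-normalized APD~90~
  change (block − baseline).
* `ikr_block_threshold()` scans block levels upward (default 1% steps,
  5-minute pre-equilibration per level from the cell's baseline state,
  last 30 s classified) and returns the first arrhythmic level; cells
  clean up to 100% are "tolerant". An exhaustive mode evaluates every
  level and is used to cross-check the ascending scan.
* `sensitivity_regression()` regresses z-scored (log-transformed where
  positive) phenotype outputs on z-scored log2 multipliers by ordinary
  least squares. Duration phenotypes are measured under 1.5 Hz overdrive
  pacing (`population_phenotypes(pacing_hz = 1.5)`): on spontaneous
  cells a depolarizing conductance shortens APD~90~ indirectly by
  accelerating the rate, which would mask its direct repolarization
  effect — the classic rate confound of automatic cells. OLS rather than partial least squares is the package's
  choice: with populations an order of magnitude larger than the 16
  parameters and an orthogonal-by-construction design, the coefficients
  are directly comparable; `regression = "pls"` would add nothing but a
  dependency.

# In-vitro preprocessing

Optical recordings (typically 125 samples/s) pass through a fixed
pipeline: (1) baseline-drift estimation by grayscale erosion — a moving
minimum whose window defaults to 1.5 × the median beat interval, wide
enough that the baseline tracks drift but never the AP itself — and
subtraction; (2) 5-sample median filtering; (3) linear resampling onto
the 0.1 ms pipeline grid; (4) min–max normalization. The in-vitro
workflow (`run_invitro_calibration()`) fits the three recorded
conditions (1.0 mM Ca + 1 Hz, 1.8 mM + 1 Hz, 1.8 mM + 1.25 Hz),
holds out 1.0 mM + 2 Hz, and reports hold-out prediction scores.

# Problem sizes used by the shipped experiments

The package's test suite and `scripts/acceptance.R` run everything at
reduced, documented sizes chosen so a complete desk run finishes in
minutes while preserving each experiment's logic: GA recovery uses one
synthetic cell, 4 free parameters (g~Kr~, g~CaL~, g~Na~, g~K1~),
population 50, 10 generations, and 60 s per-condition pre-equilibration
(targets generated with the same setting); the sensitivity regression
uses 300 cells with 60 s pre-equilibration and a 10 s analysis window;
block-threshold scans in the scripted experiments use 5% steps with
60 s pre-equilibration and a 30 s classified window. Full-scale
defaults (5-minute conditions, 1% threshold steps, population 200, 20
generations, 10-run ensembles) remain the function defaults.

# Known limitations

* The conductance multipliers are the only fitted quantities; channel
  kinetics (time constants, half-activation voltages) are fixed, so a
  preparation whose variability is kinetic rather than conductance-based
  will calibrate imperfectly.
* Single-cell surrogates only: no tissue-level propagation, no
  fibroblast coupling, no temperature dependence.
* The fluorescence surrogate is pure normalization; dye kinetics and
  photobleaching are not modelled.
* Low-sensitivity parameters (background conductances, SR leak, g~rel~,
  g~Ks~) are weakly constrained by any trace-matching protocol; their
  fitted values should be read as nuisance parameters, not biology.
* Arrhythmia labels depend on the stated detection thresholds; the
  acceptance script quantifies how the block-tolerance extremes move
  under a stricter afterdepolarization rule.
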