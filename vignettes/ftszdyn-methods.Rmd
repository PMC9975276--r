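---
title: "Models and methods behind ftszdyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ftszdyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ftszdyn)
```

ftszdyn implements the quantitative layer of the standard FtsZ assembly
assays: coupled-enzyme GTPase kinetics, GTP-depletion prediction,
90° light-scattering (LS) trace metrics, two-binding-state FRAP fitting,
and sedimentation statistics. This vignette records the models, their
assumptions, and the numerical choices, so a reader can judge what the
package's tests do and do not demonstrate.

## GTPase kinetics

The regenerative coupled assay couples every GTP hydrolysed to the
oxidation of one NADH via pyruvate kinase / lactate dehydrogenase, so at
constant GTP the absorbance at 340 nm declines linearly and the velocity is

$$v \;=\; \frac{-\,\mathrm{slope}(A_{340}\ \text{vs}\ t)\times 60}
{\varepsilon \cdot \ell}\times 10^{6}\quad[\mu M\ \mathrm{min}^{-1}],$$

with the NADH extinction coefficient $\varepsilon$ (default
6220 M⁻¹cm⁻¹) and path length $\ell$ (default 0.56 cm, the effective depth
of 200 µl in a 96-well plate). Both are exposed as arguments of
`velocity_from_trace()` because the conversion depends on the instrument
and plate geometry. Velocities are clamped at zero — the coupled assay
cannot report negative hydrolysis — and slopes at the level of
floating-point residue on flat traces are snapped to exactly zero so that
below-`Cc` wells report zero velocity rather than ~1e-15.

Because hydrolysis requires oligomerization, velocity versus FtsZ
concentration is linear above a critical concentration $C_c$ and zero
below it. `fit_kinetics()` regresses the points with detectable activity
(velocity above `min_velocity`, default 0) by ordinary least squares; the
slope is the GTPase activity $a$ (GTP min⁻¹ FtsZ⁻¹) and $C_c = -b/a$ is
the extrapolated x-intercept. The `Cc` standard error comes from the
delta method over the slope/intercept covariance. An explicit
`conc_range` override supports assays where the linear range is chosen by
eye. For coassembly mixtures, `mixture_activity()` is the same regression
but exists to enforce the convention that mixtures are parameterised by
*total* FtsZ concentration. Replicate assays are fitted individually and
pooled by `pool_kinetic_fits()` as mean ± between-fit SD.

The published velocity unit for this assay is ambiguous between
µmol min⁻¹ and µM min⁻¹; the package standardises on µM min⁻¹ (the plotted
unit), which with the fixed 200 µl reaction volume differs only by that
constant volume and leaves $a$ and $C_c$ unchanged.

## GTP depletion prediction

Only the protein above $C_c$ contributes to hydrolysis, so with starting
GTP $G$ (µM) the pool is predicted to empty at

$$t_{dep} \;=\; \frac{G}{(C - C_c)\, a} \times 60 \quad[\mathrm{s}].$$

`depletion_time()` reports the time truncated (floored) to whole seconds,
keeping the raw value; the convention is a `rounding` toggle
(`"floor"`/`"round"`/`"none"`) since either reading is defensible for
reported integer seconds. Reactions at or below $C_c$ have no defined
prediction (`ftszdyn_undefined_prediction`); in batch tables
(`depletion_table()`) such rows yield `NA` so concentration series remain
computable. A reaction with zero GTP returns a depletion time of 0 s.
The model assumes constant activity until exhaustion — no product
(GDP) inhibition and no substrate-depletion curvature — which is exactly
the assumption under which the printed predictions are made.

## Light scattering

LS reports polymerization plus bundling in arbitrary units; metrics are
never converted to polymer mass.

- `normalize_trace()` subtracts the mean of a pre-addition baseline
  window (≥ 3 points) and stores the baseline and its SD.
- `initial_rate()` fits a least-squares line from signal start until the
  trace first reaches `fit_fraction` (default 0.5) of its maximum. The
  half-max default is a robust, parameter-light reading of "initial
  rate"; as `fit_fraction` → 0 the estimate approaches the true initial
  slope ($A k$ for a saturating exponential). The fitted window is
  recorded for transparency, since the window convention used for any
  particular published figure is rarely stated. Traces whose maximum
  stays below a noise floor (5 × baseline SD) return rate 0 with a
  `no_assembly` flag.
- `detect_onset()` calls disassembly only when the smoothed trace
  (centered moving average, default 5 samples) drops below
  `(1 - drop_fraction)` of its maximum (default 10%) and stays there for
  at least `smooth_window` samples — so monotone traces and brief dips
  never fire. The onset *location* is a least-squares
  plateau-then-decline breakpoint fit on the raw trace, run twice: a
  global pass between the smoothed maximum and the sustained drop, then
  a local refinement with a short (25-sample) plateau side — the plateau
  is only approximately flat while assembly still saturates — and a long
  (200-sample) decay side for leverage on the decline slope. On a
  noiseless kinked trace the breakpoint coincides with the argmax of the
  trace; unlike the argmax, it remains well-determined when assembly
  saturates long before disassembly, where the peak region is a plateau
  and an argmax under noise wanders along it. The window geometry was
  fixed by a design sweep over noiseless and noisy synthetic traces
  before the test suite was frozen.
- `classify_onset()` compares the onset with the raw (unrounded)
  predicted depletion time: `before`, `after`, `no_disassembly` (no
  onset), or `no_prediction` (no defined depletion, e.g. at or below
  $C_c$). Reaction labels, when present on both sides, must agree.

## FRAP

Recovery traces are double-normalized
(`normalize_frap()`): background is subtracted from the bleach and
reference channels frame-by-frame, their ratio corrects for acquisition
bleaching, and division by the prebleach mean sets the prebleach level to
1. The exact arithmetic of "background-corrected, reference-normalized"
varies between labs; this standard double normalization is invariant to
adding a constant to all channels, and degenerate frames
(reference ≤ background) raise a classed error rather than producing
infinities.

`fit_frap()` fits the two-binding-state reaction-kinetics model

$$\mathrm{FRAP}(t) = (1-r)\left(1 - C_{eq1} e^{-k_{off1} t}
 - C_{eq2} e^{-k_{off2} t}\right)$$

to the postbleach points (t = 0 at the first postbleach frame; the
~20 ms bleach is instantaneous relative to 10 s sampling). $C_{eq1}$,
$C_{eq2}$ are bound fractions, $k_{off1} \ge k_{off2}$ dissociation rate
constants (ordering enforced by swapping), and $r$ captures incomplete
recovery: the plateau is $1-r$ and percent recovery $100(1-r)$.
Numerically the problem is reparameterised as
$C_{eq1} = s w$, $C_{eq2} = s(1-w)$ with $s, w \in [0,1]$, turning the
constraint $C_{eq1}+C_{eq2}\le 1$ into box bounds, and rate constants are
fitted on the log scale within [1e-6, 10] s⁻¹. Because the
bi-exponential surface is ill-conditioned when the rates are close, the
Levenberg–Marquardt solver (`minpack.lm::nls.lm`, ftol = ptol = 1e-13) is
multistarted (default 20: one data-driven start plus seeded random
starts) and the lowest-RSS solution returned. Flags: `at_bounds` (any
parameter at a box bound), `degenerate` ($r > 0.99$: no measurable
recovery, rate constants not interpretable). If the optimum has
$k_{off1}/k_{off2} < 2$ the two states are weakly identifiable and a
reduced single-state fit is attached as `$single_state`. The fit reports
`max_abs_residual` so the "all points within 0.05 normalized units"
quality check can be applied; both the fitted plateau and the last
measured point are available, with the plateau treated as the primary
percent-recovery estimate.

## Sedimentation

`pellet_fraction()` is pellet/(pellet + supernatant) from densitometry —
scale-invariant, with a classed error when both densities are zero. A
recorded total-lane density is used only for QC: a warning fires when
pellet + supernatant deviates from it by more than 25%.
`compare_conditions()` runs a two-sided unpaired t test on the fractions;
the pooled-variance Student test is the default (the plain reading of
"unpaired t test"), with Welch behind `var_equal = FALSE`, and two-sided
because sidedness is rarely stated. Zero-variance groups are handled by
an epsilon guard: identical groups give t = 0, p = 1; separated constant
groups give a vanishing p instead of an error. Mixed-protein pellets that
co-migrate on the gel cannot be resolved per protein; fractions are
per-lane totals.

## The synthetic-data generator

`ground_truth()` collects every generative parameter; all randomness
flows through one explicit integer seed (identical seeds give
bit-identical data). Defaults are the study conditions of the
cyanobacterial FtsZ system the package models: activity
0.59 GTP min⁻¹ FtsZ⁻¹, $C_c$ 2.12 µM, protein titrations 2–14 µM,
50 µM GTP.

- GTPase traces: exactly linear A340 decline with slope
  $-v\,\varepsilon\,\ell \times 10^{-6}/60$ per second, clipped at zero
  absorbance, plus Gaussian noise (default sd 0.002 absorbance units).
- LS traces: saturating-exponential rise
  $I(t) = A(1-e^{-kt})$ with $A$ linear in $(C - C_c)$ above $C_c$
  (default 25 a.u. µM⁻¹ — arbitrary instrument units — and
  $k = 0.02$ s⁻¹, reaching plateau within a few hundred seconds as rapid
  assembly does), zero below $C_c$; optional disassembly from a set
  onset, linear by default (full decay over ~1000 s) or exponential;
  Gaussian noise default sd 2 a.u. The paper-level trace shape is not
  parameterised anywhere, so the saturating exponential is simply the
  least structured monotone form with an amplitude and a rate; the true
  onset is stored in trace metadata as the recovery target.
- FRAP traces: the two-state model rescaled to raw units between a
  background and a prebleach level, with noise expressed in normalized
  units (default sd 0.01) on the bleach channel and a tenth of that on
  the bright, flat reference and background channels.
- Sedimentation: replicate pellet fractions drawn Gaussian around the
  condition means, truncated to [0, 1].

Instrument noise magnitudes are not published for any of these assays;
the defaults above were chosen once as realistic for the respective
instruments and are fully configurable. For test surfaces the package
uses sd 1 a.u. LS noise against the ~147 a.u. default amplitude
(0.7% of signal) as "moderate".

What the generator does *not* emulate: coupled-enzyme lag phases and
substrate-depletion curvature in GTPase traces; bundling-versus-
polymerization structure, drift, or spikes in LS; diffusion-limited
recovery, acquisition photobleaching, or ROI-size effects in FRAP;
gel-loading correlations in densitometry. Passing parameter-recovery
tests therefore demonstrates correctness of the estimators under the
stated models, not robustness to every artefact of real instrument data.

## Test problem sizes

The suite exercises: exact noiseless round trips (generator → estimator)
for kinetics and FRAP; 200-replicate noisy $C_c$ recovery (velocity noise
sd 0.05 µM/min over 7 concentrations); 100-seed noisy FRAP refits
(31 frames, sd 0.01 normalized units, 10 starts each); 100 synthetic LS
traces (dt = 2 s, onsets 300–888 s) for onset localisation and
before/after classification; and closed-form oracles for the depletion
times and the sedimentation t test. These sizes give stable pass/fail
behaviour for the stochastic surfaces while keeping the default test run
fast.

## Known limitations

- The kinetic regression assumes a sharp transition at $C_c$; shallow
  curvature near the transition biases the x-intercept.
- Depletion predictions ignore GDP accumulation, which is known to
  hasten disassembly of some FtsZs; predictions are upper bounds in that
  sense.
- The LS onset estimator assumes one sustained decline; oscillating or
  re-assembling traces report only the first qualifying onset.
- The FRAP model is reaction-dominant; if recovery is partly
  diffusion-limited the fitted rate constants are effective, not
  molecular, parameters.
- With closely spaced rate constants the two FRAP states are weakly
  identifiable: inspect the `single_state` reduction and the `at_bounds`
  flag before interpreting $k_{off}$ values.
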