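---
title: "Cross-task selectivity analysis: model, design choices, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-task selectivity analysis: model, design choices, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neurocpd)
```

This vignette is the package's account of its statistical model, the
design decisions that were genuinely open, and what the validation on
synthetic data does and does not establish.

## The task structure and why it shapes the statistics

Both task variants share one trial skeleton: the animal presses a hold
button (trial time 0), holds for 1 s, sees a first cue for 0.5 s, waits
through a variable 1–1.5 s delay, and responds within 1 s of the go
signal. Four trial labels describe each trial:

* **tactics** — pro-reach (reach toward the visuospatial cue) or
  anti-reach (away from it), instructed by cue colour: cyan and green
  mean pro, blue and red mean anti;
* **cue position** — which button is illuminated (left/right);
* **action** — the executed reach (left/right);
* **cue colour** — the specific colour among the four.

On correct trials the labels are not free: action equals cue position
under pro-reach and its opposite under anti-reach, and colour determines
tactics two-to-one. These dependencies are the crux of the encoding
model. With ±1 contrasts (`PRO`, `RIGHT`, and the first colour of each
pair coded +1):

* the action contrast satisfies `c_A = c_T * c_P` exactly — action is
  the tactics × position interaction contrast. It is estimable alongside
  tactics and position precisely when all four tactics × position cells
  are populated; with trials from a single tactics level it collapses
  onto the position column and `encode_design()` refuses the fit with a
  rank diagnostic rather than silently dropping a column.
* a four-level colour factor spans the tactics contrast (cyan+green vs
  blue+red *is* tactics), which would force the tactics partial sum of
  squares — and hence its CPD — to zero identically. Colour therefore
  enters as a two-level *shade* contrast nested within the trial's
  tactics level (cyan vs green, blue vs red). The raw four-level coding
  is kept behind `color_coding = "levels"` only so that the
  rank-deficiency it causes can be demonstrated and tested.

This is the only coding under which per-factor effects of all four
labels are simultaneously computable, which is what the cross-task
comparison requires.

## Nested-model ANOVA and the coefficient of partial determination

Firing rate is the dependent variable throughout, modelled by ordinary
least squares on the contrast columns. For each factor `X`, the drop-one
comparison of the full model against the model without `X`'s column
gives

* `F(X) = ((SSE_partial − SSE_full) / df_X) / (SSE_full / df_res)` with
  p from the F distribution, and
* `CPD(X) = (SSE_partial − SSE_full) / SSE_partial`,

the fraction of rate variance uniquely attributable to `X`. CPD is
stored as a fraction in [0, 1]; reports multiply by 100 only where a
column is explicitly labelled a percentage. Because the contrasts are
orthogonal in balanced designs, the drop-one (partial) sums of squares
coincide with classical type-III sums there; in unbalanced data the
drop-one definition is primary because it is what the CPD formula is
defined from.

Degenerate fits — zero residual variance, as with a noise-free coder or
an all-zero rate vector — are flagged rather than assigned a p-value
from a zero-denominator F: p is set to 0 when the omitted factor still
carries signal (`SSE_partial > 0`) and to `NA` when both models fit
perfectly. The `degenerate` column makes these rows visible downstream.

## Time-resolved profiles

`align_and_bin()` computes the instantaneous firing rate as the spike
count in a 200 ms window divided by its width, stepped every 20 ms
(both configurable). Three numerical conventions matter:

* **Windows are centred** on grid times by default (`anchor = "center"`);
  the alternative left-edge anchoring is a configuration switch. Centred
  windows make the latency of significance onsets symmetric around a
  true rate step, at the cost of smearing any effect by ±width/2.
* **Intervals are half-open** `[lo, hi)`, so abutting windows tile time
  exactly: summed counts over a disjoint tiling equal the interval's
  total spike count (a tested invariant).
* **Windows extending past the recorded trial span**
  (`[hold_onset, hold_release]`) are masked `NA` for that trial rather
  than zero-filled; each window's model is fitted on its complete trials
  only, and the per-window trial count is reported. This keeps
  go-aligned profiles honest when reaction times vary across trials.

Per-window significance is evaluated at α = 0.05 without correction
across windows, matching the conventional presentation of such
selectivity traces; a Benjamini–Hochberg option and a
minimum-consecutive-windows mask are available but off by default. All
four factors are evaluated at every window, including windows before
the second cue reveals a label to the animal: pre-revelation
selectivity for an unrevealed factor is interpretable as anticipation
(or chance at the nominal rate), and the window times make the
revelation structure explicit to the reader.

## Response-period classification

The cross-task question is answered in the response period — the 300 ms
before hold release, the one epoch in which both task variants have
revealed all information. Movement onset is identified with hold
release: the recorded release of the hold button is the observable
event closest to movement initiation in this data model, and the
simulator uses the same definition, so analysis and generation agree.
The response-period model uses tactics, cue position and action (no
colour term: with only 300 ms of data per trial, the shade contrast
would dilute power for the factors the classification is about, and the
classification analysis is defined over these three factors).

A neuron is selective for a factor in a task if p < 0.01 (strict
inequality) in that task's response-period ANOVA. The two task flags
yield four categories (only tactics-precued, only location-precued,
both, none); population summaries report exclusive counts, the
task-specific fraction, and integer percentages rounded half away from
zero. With zero selective neurons the fraction is reported as missing,
never as 0. A pooled ANOVA adding the task-type contrast over both
tasks' response-period rates flags neurons whose firing depends on
which task variant is being performed.

Neurons enter the analysis only if each of the four tactics ×
cue-position cells of each task holds at least five correct trials in
which the neuron was recorded. The inclusion-cell definition is the
minimal determinant set — requiring five trials per colour × position ×
task cell (8 cells per task) is a stricter reading; it is available via
`cells = "tactics_position_color"` but not the default. Recording
coverage is operationalised as spike presence (a trial counts for a
neuron if the neuron has at least one spike in it), the only coverage
signal a plain spike table carries; truly silent neurons are therefore
excluded, which is conservative.

## The synthetic-data generator

The simulator emulates exactly the study conditions the analysis
expects: balanced trials over tactics × position × colour-shade cells in
both tasks, hold 1 s, cue 0.5 s, delay uniform on 1–1.5 s, and reaction
times uniform on 0.2–0.6 s (the task only bounds them by 1 s; 0.2–0.6 s
is a realistic primate reaching range and keeps the response epoch
strictly inside the trial). Each neuron's intensity is piecewise
constant over the four epochs (pre-cue, post-cue, delay, response):
baseline plus, per applicable gain, `gain × contrast` for the trial's
level of the gained factor, clipped at zero. A gain `g` therefore
produces a `2g` difference in cell means. Piecewise-constant intensities
were chosen over smooth kernels deliberately: they exercise every
downstream statistic while keeping analytic expectations (means, SEs,
PSTH plateaus) available for exact tests.

Spiking is inhomogeneous Poisson by default; a gamma-renewal option
(shape κ, implemented by time-rescaling a unit-rate gamma renewal
process through the cumulative intensity) provides sub-Poisson
regularity when wanted. Population composition defaults are the
recovery conditions used throughout validation: baseline 20 spikes/s,
planted response-epoch gain equal to baseline, 80% of neurons selective
for one factor, and a task-specific fraction of 0.8 among them. A
single seed drives everything; each neuron's spikes come from a
substream derived from the seed and the neuron index, so sessions are
bit-reproducible and stable under changes in neuron count order.

What the generator does **not** emulate: smooth rate dynamics and
transients, spike-history effects (refractoriness beyond the gamma
option), correlated variability across neurons or trials, error-trial
dynamics (error trials, if requested, simply flip the action and are
marked incorrect), drift across a session, and any areal differences —
area labels on synthetic neurons are labels only. Consequently, passing
validation on synthetic data establishes the *statistical machinery*
(calibration, recovery, invariances), not that real pmPFC data meet the
model's assumptions; with real recordings the Poisson-like variance
assumption and the absence of slow drift are the points to check first.

## Validation design and problem sizes

The test suite validates each stage against independent oracles and
known truth:

* the nested ANOVA, CPD and KS statistic are compared with brute-force
  implementations (explicit normal equations; direct ECDF scan) to
  1e-8 relative tolerance on 100 random balanced designs of 8–64
  trials;
* type-I error of the window-wise test (α = 0.05, four disjoint delay
  windows) and the response-period test (α = 0.01) is measured over
  2000 simulated null neurons of 80 trials each and required to sit
  inside the 99% binomial confidence band; the null rate of the BOTH
  category is checked against α²;
* parameter recovery runs 250 planted coders at gain = baseline =
  20 spikes/s with 40 correct trials per cell and requires ≥0.9
  sensitivity for one-task coders and recovery of the planted
  task-specific fraction 0.8 within ±0.05.

These sizes give Monte-Carlo standard errors comfortably below the
tolerances they are checked against (e.g. SE ≈ 0.0022 for a 0.01 rate
at n = 2000) while keeping the whole suite to a few minutes on one CPU.

## Known limitations

* The per-window tests are marginal; no family-wise control is applied
  by default across windows, neurons or factors, mirroring common
  practice for selectivity traces. The BH option exists for users who
  need it.
* CPD compares nested least-squares fits of *rates*; for very low
  counts (≪1 spike per window) the Gaussian working model is coarse and
  a count GLM would be preferable. At the firing rates and window
  widths validated here the F test is well calibrated.
* The inclusion rule depends on spike presence as a recording proxy;
  sessions with explicit per-trial recording masks would need that
  information to be expressed as spike rows or by pre-filtering trials.
* `crosstask_f_comparison()` treats the two f-value samples as paired
  per neuron for the reduced-selectivity count but uses the unpaired
  two-sample KS test for the distributional comparison, which is the
  conventional choice for this contrast.
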