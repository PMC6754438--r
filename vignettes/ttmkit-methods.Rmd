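---
title: "Triple transient analysis and hypothesis-based MOA scoring: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Triple transient analysis and hypothesis-based MOA scoring: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ttmkit)
```

## The measurement problem

Cardioactive drugs change contraction through distinct arms of
excitation-contraction (EC) coupling: ion-channel block reshapes the
action potential (AP), calcium handling changes the cytosolic calcium
transient (Ca), and myofilament-directed compounds act on contraction
(Co) with little upstream signature. Measuring only one of the three
transients therefore cannot separate, say, a myosin activator from a
calcium-loading inotrope. `ttmkit` analyses simultaneous optical
recordings of all three transients from paced hiPSC-CM monolayers: each
recording is reduced to ten kinetic parameters (four AP, three Ca, three
Co), and the drug-induced change pattern across all ten is matched
against a table of mechanism-of-action (MOA) hypotheses by a
probability-score algorithm referenced to vehicle measurements.

## Data model and ingest

The acquisition hardware cycles three excitation wavelengths at 1000
frames/s, so the raw movie interleaves the three channels
frame-by-frame. `demultiplex()` assigns frame *i* to channel
`(i - 1) mod 3` of the declared interleave order, giving three stacks at
333.33 frames/s each (a trailing incomplete cycle is dropped).
`intensity_trace()` reduces each stack to the ROI-mean intensity per
frame; the membrane-label channel doubles as the motion-artifact (MA)
reference and, via `contraction_trace()`, as the contraction readout.

`contraction_trace()` is deliberately minimal: the mean absolute pixel
difference of each frame against a fixed reference frame. It is a
monotone motion surrogate — zero for a motionless recording, increasing
with displacement — not a validated contraction-amplitude algorithm
(no registration, no motion vectors, no drift handling). Downstream
stages only require a contraction-shaped trace with onset, peak and
relaxation, which this supplies.

## Cleaning chain

`clean_trace()` applies, in fixed order:

1. **Ratiometric MA correction** (AP, Ca): the membrane label is
   co-localised with the voltage dye, so contraction modulates all
   fluorescence channels by a common multiplicative factor; dividing by
   the mean-normalised MA trace removes it. Division is the standard
   ratiometric form; a constant MA trace is a no-op.
2. **Inversion** (AP only): the voltage dye dims on depolarisation, so
   the optical AP is reflected about its mid-range, `(max + min) - x`,
   which restores an upright AP while keeping the trace positive for the
   next step. The simulator emits APs reflected about the template
   mid-range so this recovers the true pulse exactly in the noise-free
   limit.
3. **Pseudo-ratio dF/F_min** (AP, Ca): `(F - F_min) / F_min`,
   dimensionless, minimum exactly zero, invariant to detector gain.
4. **2-frame trailing moving average** — minimal smoothing at the ~3 ms
   per-channel sample period; the trailing (causal) form with prefix
   shortening preserves trace length and never advances onsets.
5. **Event detection**: pacing is fixed at 1.2 Hz, so beats are located
   by their half-amplitude rising crossings (with a half-period
   refractory), and each onset is the preceding 10%-amplitude rising
   crossing. A pure onset-threshold detector proved fragile in testing:
   the AP hovers at the 10% level around APD90, and photometric noise
   there produces spurious crossings. The inter-marker spacing must
   match the pacing period within 10%; recordings failing this
   pacing-consistency check are rejected whole (the conservative reading
   of the quality rule — a drifting recording is not trusted
   beat-by-beat).
6. **Event averaging**: the first five complete events, aligned at
   onset, are averaged pointwise into one representative beat. Each
   event window spans one pacing period starting 5% of a period before
   the onset, so a pre-upstroke baseline segment survives averaging.

Contraction traces skip steps 1–3 and are filtered and event-averaged
identically. All thresholds (onset fraction 0.1, inter-peak tolerance
0.1, pre-window 0.05, events 5, window 2) live in `cleaning_config()`.

## Kinetic quantification

From each averaged beat, `beat_kinetics()` measures with linear
interpolation between samples:

* **AP**: amplitude (peak minus pre-upstroke median baseline), 10–90%
  upstroke time, APD at 90% repolarisation (APD90 is the field-standard
  reading of "AP duration"; the level is configurable), and
  triangulation = APD90 − APD30, the positive repolarisation-shape
  measure. APD is referenced to activation, the 50%-amplitude upstroke
  crossing.
* **Ca / Co**: amplitude, onset(10%)-to-peak time, and the 50%-decay
  (relaxation) time from the peak; the decay level is configurable
  (50/90), with 50% the default so that an exponential decay with
  constant τ reads out τ·ln 2.

A flat or unmeasurable channel flags the whole record unusable rather
than raising, so screening runs drop and log bad areas. Each area's
post-incubation record is divided fieldwise by its own baseline record
(`normalize_to_baseline()`) — fold changes remove the large
between-sample variation of absolute hiPSC-CM kinetics; a ratio rather
than a difference keeps all ten parameters on one dimensionless scale.
Areas average into wells, wells into conditions
(`aggregate_kinetics()`).

## Probability scoring

The vehicle (solvent-only) wells define the null population. For each
kinetic parameter a Gaussian `N(mean, sd)` is fitted; for a normalised
value `x`,

* `PS_=(x) = 10 · exp(−(x − mean)² / (2·sd²))` — the vehicle density
  rescaled to peak at 10,
* `PS_↑(x) = 0` below the mean, `10 − PS_=(x)` at or above it,
* `PS_↓(x)` the mirror below the mean,

so the three scores partition 10 at every `x`. Hypothesis-table cells
expecting "any effect but e" (NOT cells, used for heterogeneous drug
classes) score `10 − PS_e(x)`, the exact complement under the partition
identity. Per MOA column the ten cell scores are summed — 0 to 100 —
and the hypothesis with the highest total is the assigned MOA
(`assign_moa()`; exact ties are flagged and listed, not silently
broken). Channel-subset scoring (`AP`, `Ca`, `Co`, capped at 40/30/30)
implements the single-modality ablation comparison; the AP rows of the
no-effect and myosin columns are identical, so the AP subset provably
cannot separate those two classes.

Two scoring choices deserve emphasis:

* **Reference spread.** The vehicle Gaussians are fitted, by default, on
  the individual vehicle measurements — the area-level normalised
  records (15 values with the default 5 wells × 3 areas) — rather than
  on the 5 well means (`vehicle_level = "well"` forces the latter). An
  SD estimated from 5 values has a standard error of ~35% of itself;
  in simulation that instability produced spurious |z| > 3 excursions
  and misassigned null drugs in a third of runs, while
  measurement-level fitting is both more stable and more conservative
  (it includes area-level noise in the spread). An `sd_mode = "sem"`
  switch divides the spread by √n for users who read the reference as
  the uncertainty of the vehicle mean.
* **Vehicle self-scoring.** The value scored for a drug condition is the
  across-well mean at that concentration. For the vehicle condition
  itself that mean equals the fitted mean by construction, so the
  vehicle is instead scored leave-current-well-out: each held-out
  well's complement mean is scored and the totals averaged — an
  informative self-consistency check rather than a guaranteed 100.

## The synthetic-data generator

`simulate_experiment()` generates fully labelled plates mirroring the
screening design: five concentrations plus vehicle (configurable), five
wells per condition, three areas per well, each area recorded at
baseline and after incubation, 7 s per recording at 1.2 Hz pacing and
333.33 samples/s per channel. Waveforms are phenomenological — a
piecewise-linear AP pulse constructed so that measured APD30/APD90 equal
their targets exactly under the package's own measurement geometry, and
rise-plus-exponential-decay Ca/Co transients — because the classifier
consumes only the ten kinetic parameters; no ion-channel biophysics is
modelled, and no claim of electrophysiological realism is made. Default
shape parameters (AP APD30/90 = 200/350 ms, rise 10 ms; Ca rise 90 ms,
τ = 120 ms; Co rise 120 ms, τ = 130 ms; onset delays 60/80/90 ms) were
chosen once to resemble averaged optical hiPSC-CM transients while
decaying fully within the 833 ms pacing period (residual < 0.5% of
amplitude, keeping baseline estimation unbiased).

Perturbations follow the hypothesis table: a drug's MOA column maps to
multiplicative factors `1 ± magnitude` on the ten kinetic parameters
(the AP duration/triangulation pair is solved jointly into APD30/APD90
targets). NOT cells draw one admissible direction at random — once per
drug, exported as ground truth — honouring the "might be expected"
semantics and stressing the scorer. Effect magnitude scales along
concentration with a Hill curve (EC50 at the middle concentration,
coefficient 1.5). Biological structure is multiplicative lognormal:
well-level variability (CV 5%), area-level variability (CV 2.5%), and a
baseline-to-post drift per area (CV 3%) — the time-dependent effect
that motivates vehicle referencing. Photometric noise is additive
Gaussian at 5% of each channel's amplitude; the contraction-driven
motion artifact modulates AP, Ca and the membrane label by a common
factor (default depth 5%) that the ratiometric step removes. All
randomness flows from one integer seed; a fixed seed reproduces the
dataset bit-for-bit.

What the generator does **not** emulate: beat-to-beat variability and
arrhythmic events (EADs, alternans), spatial heterogeneity within an
area, photobleaching and baseline drift within a recording,
non-multiplicative (additive or saturating) dye artifacts, and real
MUSCLEMOTION output. Passing recovery tests therefore demonstrates
internal consistency of the pipeline and scorer under the stated noise
model, not performance on laboratory recordings.

## Numerical choices and degenerate inputs

* Interpolation is linear everywhere; time parameters are exact for
  piecewise-linear inputs and accurate to within one sample (~3 ms)
  otherwise.
* `delta_f_over_f()` and `ratiometric_correct()` refuse non-positive
  inputs (offset correction is upstream's job) rather than silently
  producing signs.
* Degenerate baselines (any non-positive parameter) reject the record;
  an all-unusable aggregate raises; a zero vehicle SD raises — scoring
  against a degenerate null is meaningless.
* Ties in `assign_moa()` use an epsilon of 1e-6, i.e. exact-tie
  detection only.
* Problem sizes in the test suite: classifier recovery runs 6 MOA
  categories × 10 seeds with three concentrations plus vehicle at the
  full 5 wells × 3 areas design; deterministic recovery uses a grid of
  three values per shape parameter. These sizes give stable pass/fail
  behaviour at desk scale.

## Known limitations

* The contraction quantifier is a stand-in (see above); absolute Co
  amplitudes are in arbitrary motion units and only meaningful as fold
  changes.
* The hypothesis set covers six contractile MOA classes; mixed-MOA
  compounds (e.g. PDE inhibitors that also sensitise myofilaments) have
  no dedicated column and will be assigned the closest single class.
* Scoring assumes an approximately Gaussian vehicle population of
  normalised values; heavy-tailed vehicle noise inflates NOT-cell and
  directional scores.
* No frequency correction is attempted: pacing is fixed by design, and
  kinetic parameters are only comparable at one pacing rate.
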