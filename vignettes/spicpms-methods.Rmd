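---
title: "Methods: single-particle ICP-MS data reduction in spicpms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-particle ICP-MS data reduction in spicpms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spicpms)
```

## The measurement model

In single-particle ICP-MS a suspension is diluted until nanoparticles
reach the plasma one at a time. The detector then sees two superimposed
signals in a time-resolved acquisition: a continuous baseline from the
dissolved fraction of the element, and short ion bursts — one per particle
— whose integrated intensity is proportional to the particle's analyte
mass. At the 100 µs dwell time used here a burst (a few hundred µs of ion
cloud) spans several consecutive dwells, so an "event" is a run of dwells,
not a single reading.

Everything downstream rests on three calibration constants:

* the **ionic response slope** `s` (cps per µg/L), from ordinary least
  squares on a dissolved standard series;
* the **sample uptake rate** `Q_sam` (L/s), measured gravimetrically
  (water density taken as 1.000 g/mL);
* the **transport efficiency** `η`, the fraction of aspirated suspension
  that reaches the plasma.

A dissolved standard at concentration `C` delivers `C·Q_sam·η` µg/s to the
plasma and reads `s·C` cps, so the instrument counts `s/(Q_sam·η)` counts
per µg of analyte *in the plasma*. This single conversion factor gives
both directions of the particle-size calibration:

* a reference particle of known mass `m_ref` (50 nm Au,
  ρ = 19.30 g/cm³) integrates to `Ī_ref = m_ref·s/(Q_sam·η)` counts, hence
  `η = m_ref·s/(Ī_ref·Q_sam)` (the particle-size method);
* an unknown event of integrated, baseline-corrected counts `I` carries
  `m = I·Q_sam·η/s` µg, and the spherical-equivalent diameter follows from
  the compact-sphere model `d = (6m/(π·ρ·X))^{1/3}`, where `X` is the mass
  fraction of the measured element in the particle (1 for a bare
  zero-valent iron core; an oxide shell would lower it).

All internal quantities use one canonical unit system — seconds, litres,
grams, micrograms of analyte, nanometres, integer counts per dwell, cps —
and unit conversion happens only in the I/O layer. This is deliberate:
the field mixes mL/min, µs, µg/L and nm, and a single canon prevents
silent factor errors.

## Baseline, threshold, events

The discrimination threshold is `I_thresh = I_b + 5σ_b`. The raw trace
moments are contaminated by particle pulses, so `estimate_baseline()`
purges them iteratively: compute mean and SD of the retained dwells, drop
dwells above mean + 5 SD, repeat to a fixed point (at most 20 iterations,
relative tolerance 1e-6). The 5σ multiplier keeps the per-dwell false
positive probability near `P(Z > 5) ≈ 2.9e-7` — about 0.34 spurious events
per 1.2 × 10⁶-dwell acquisition for Gaussian noise — while missing few
true events.

Numerical choices worth stating:

* Events require counts **strictly greater** than `I_thresh`; ties fall to
  baseline, which makes the degenerate zero-variance case (threshold equal
  to a constant trace) deterministic.
* Baseline correction subtracts `I_b` per member dwell, so longer events
  receive proportionally larger corrections.
* `detect_events()` does not merge across sub-threshold gaps by default
  (`gap_tolerance = 0`), but the pipeline wrapper `analyze_timescan()`
  uses `gap_tolerance = 1`: a multi-dwell pulse crosses the threshold
  through a noisy transition zone on each flank, and a single dip there
  would otherwise split one particle into a main event plus a tiny
  satellite, inflating event counts and dragging size medians down. One
  dwell is the smallest bridge that fixes this without merging genuinely
  separate particles at realistic occupancies.
* `coincidence_check()` reports the fraction of dwells inside events and
  flags above 5%. Coincidences are flagged, never deconvolved.

A genuine limitation in the discrete regime: for a Poisson baseline the
5σ rule is calibrated against a Gaussian tail, and for small means the
skewed Poisson tail yields noticeably more false positives (about 24 per
1.2e6 dwells at a mean of 5 counts/dwell, about 3 at a mean of 50). Below
a mean of ~1 count/dwell the threshold falls under a single count and the
rule degenerates entirely. The package reports what the rule gives;
choosing a different multiplier is exposed everywhere the threshold is
used.

## Concentrations and the size detection limit

Each detected event is one particle that survived nebulisation, so the
analysed suspension holds `N = n_events/(η·Q_sam·t)` particles per litre.
Multiplying by the dilution factor gives the concentration in the original
extract; scaling by extract volume (default 8.5 mL, a typical enzymatic
digest) over tissue mass (default 0.015 g) gives particles per gram of
tissue, and the same bookkeeping applied to the summed event masses gives
the particulate mass concentration in ng/g. The dissolved concentration is
read off the baseline: `C = (I_b/t_dwell − intercept)/s`, floored at zero
with a warning (the calibration intercept serves as blank correction).

The size detection limit uses the 3σ decision convention on the
counts-per-mass response:

LOD_size = (6·3σ_B / (π·ρ·X·K_ICPMS·K_M))^{1/3},
  K_ICPMS·K_M = R/(K_intr·C_M),  K_intr = η·Q_sam.

Two deliberate asymmetries are surfaced rather than hidden:

* the LOD uses 3σ while event detection uses 5σ — both multipliers are
  configurable, and the dual-route identity
  `size_lod(σ_B) ≡ mass_to_diameter(3σ_B/K_product)` is enforced by test
  to machine precision;
* σ_B is put on the **event-integral basis** by scaling the per-dwell
  baseline SD by √(pulse dwells) (default 3), since a detection decision
  compares an integral over the pulse, not a single dwell. Whether one
  reports per-dwell or per-event σ_B changes the LOD by √3 ≈ 1.2×; the
  basis used here is documented and adjustable via `lod_pulse_dwells`.

The detection-efficiency factor `K_ICPMS` never appears alone in this
pipeline; only the product `K_ICPMS·K_M` is measurable from a dissolved
standard. `element_factor_km()` exposes `K_M = A·N_Av/M_M` so a user who
wants `K_ICPMS` can divide it out.

## What the synthetic generator emulates

`simulate_timescan()` produces traces with known ground truth so that
every stage can be validated closed-loop:

* **Arrivals**: Poisson with expectation
  `λ = N·η·Q_sam·t`, positions uniform over the acquisition.
* **Sizes**: lognormal (median, gsd), optionally a two-component mixture
  for agglomerate populations.
* **Pulse shape**: a discretised Gaussian with FWHM `pulse_width`
  (default 300 µs ≈ 3 dwells), since real single-particle plasma pulses
  last a few hundred µs; this forces the detector to handle split events,
  the defining complication of microsecond dwells. The pulse duration of
  any given instrument is a free parameter here, not a measured value.
* **Baseline**: mean `s·C_diss·t_dwell` counts per dwell with Poisson
  noise by default (counting statistics); a `gaussian(σ)` option exists so
  the 5σ false-positive rate can be checked against the analytic Gaussian
  value.
* Pulse and baseline are summed per dwell and rounded **once** (not
  rounded separately), and a coincidence guard refuses configurations
  whose expected dwell occupancy exceeds 5%, mirroring the dilution
  practice of real acquisitions.

Defaults describe a realistic operating point: 7 × 10⁶ particles/L
(≈ 370 events in 120 s at η = 0.075 and 0.35 mL/min), median 59 nm,
gsd 1.3, 0.5 µg/L dissolved iron, ionic slope 10⁶ cps/(µg/L).

What the generator does **not** model: droplet transport and ionisation
physics (η and `s` are taken as given), reaction-cell chemistry,
multi-element particles, and any kinetics of dissolution or agglomeration
— the fresh/aged scenario fixtures are endpoint states, not trajectories.
A green closed-loop test therefore establishes that the arithmetic chain
inverts its own stated statistical model, not that the model captures any
particular instrument.

## Scenario fixtures

`generate_scenario_suite()` encodes the three fates of a suspension
incubated in a growth medium:

* **stable** — fresh median 59 nm, aged 61 nm, no dissolved background;
* **dissolution_agglomeration** — fresh 55 nm single mode; aged keeps a
  reduced primary mode plus an agglomerate mode at 150 nm (gsd 1.25) whose
  number fraction is solved numerically so the pooled aged median is
  exactly 81 nm (≈ 0.46), over an elevated dissolved background;
* **fast_dissolution** — aged arrivals reduced to a handful of events
  (λ ≈ 6) over a dominant dissolved background.

The dissolved levels are chosen once, with the discreteness limitation
above in mind: fresh and stable runs use 0 µg/L (their "no significant
background" state; any small nonzero value would put the 5σ threshold
below one count at these particulate levels and flood the trace with
discreteness false positives), while the aged dissolution fixtures use
0.3 and 0.5 µg/L — baseline means of 30–50 counts/dwell, where the
Poisson tail above 5σ contributes fewer than five spurious events per
trace.

## Mixture fitting and the transformation classifier

Size distributions are fitted by maximum likelihood on the log scale
(median = exp(mean of logs), gsd = exp(MLE SD of logs)); the histogram
(Freedman–Diaconis bins) is attached for plotting only and plays no part
in estimation — binning-free estimation is reproducible where
histogram-curve fitting is not. Agglomerate detection fits k = 1 and
k = 2 lognormal mixtures by EM and selects k by BIC, the parsimonious
choice at the few hundred events of a typical run. The EM restarts are
deterministic quantile splits of the data (10 cut points), so the fit is
bit-reproducible without touching the RNG; component SDs are floored at
1e-4 on the log scale to keep the likelihood bounded.

`classify_transformation()` turns fresh/aged evidence into flags with
fully exposed thresholds (`transformation_thresholds()`):

| rule | default | rationale |
|---|---|---|
| agglomeration: heavy-mode weight | ≥ 10% | a genuine second mode, not a tail artefact |
| agglomeration: mode separation | ≥ 1.5× | k = 2 fits that split one mode in two are not agglomeration |
| agglomeration: median shift | > +15% | well above the ±2–4% sampling spread of a 300-event median |
| partial dissolution: dissolved-fraction rise | > 10 points | clearly beyond baseline-estimation error |
| partial dissolution: event-count ratio | < 0.7 | a 30% particle loss at matched dilution |
| fast dissolution: count ratio and dissolved fraction | < 10% and > 50% | few surviving particles in a dominated background |
| size-evidence guard `min_events` | 50 | with fewer aged events the sample median is too noisy to support any size claim |

The `min_events` guard matters in practice: a fast-dissolution aged run
has ~6 events, whose sample median scatters by ±15% around the true
value, enough to trip the median-shift rule spuriously. With the guard,
size-based rules abstain and the verdict rests on counts and dissolved
fraction. "stable" is the absence of every other flag, and missing
evidence is reported in the verdict's note rather than guessed at.

Group comparisons (e.g. diameters across treatments) use classical
one-way fixed-effects ANOVA at α = 0.05.

## Known limitations

* Coincident particles are flagged via occupancy, not resolved; number
  concentrations at high occupancy are biased low and event masses high.
* The 5σ/3σ conventions are inherited, not optimal; in the low-mean
  Poisson regime the false-positive rate exceeds the Gaussian figure, and
  near-threshold events bias small-particle masses upward.
* The transport-efficiency closed loop validates the particle-size method
  against the generator's own delivery model; systematic effects real
  nebulisers show (size-dependent transport, matrix effects) are outside
  the model.
* Scenario fixtures are endpoint states with stated anchor medians; they
  validate the classifier's decision rules, not any dissolution kinetics.
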