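---
title: "Impedimetric migration monitoring: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Impedimetric migration monitoring: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(migrEIS)
```

## The assay

A 3D micro-tumor spheroid (100–500 µm) is placed at the centre of a well
carrying a 6 × 7 grid of 100 µm gold microelectrodes at 300 µm pitch
(42 electrodes per well; nine wells per chip, 378 electrodes in total,
monitoring area 1.5 mm × 1.8 mm). Impedance magnitude spectra |Z|(f) are
swept from 5 kHz to 5 MHz (41 log-spaced points, 10 mV) on every
electrode over 144 h. Cells migrating out of the spheroid reach
electrodes one by one; the per-electrode *relative impedance*

$$\mathrm{RI}(f) = \frac{|Z|_\text{cells}(f) - |Z|_\text{cell-free}(f)}
 {|Z|_\text{cell-free}(f)} \times 100\,\%$$

isolates the cell signal. Its spectral maximum is the working quantity:
the *frequency* of the maximum sits in the 100–300 kHz band typical of
adherent-cell sensing, and its *amplitude* scales with the cell
amount/density on the electrode. Two per-well time courses summarise a
run:

* **covered electrodes** — the count of electrodes whose maximum
  relative impedance reaches a detection threshold (migration axis), and
* **median maximum relative impedance** over the covered electrodes
  (cell-amount/proliferation axis).

Plotting one against the other and cutting both axes gives the
four-quadrant discrimination of migration versus proliferation
(Q1 low/low, Q2 low migration/high proliferation, Q3 high/high, Q4 high
migration/low proliferation), with proliferation-suppressed (mitomycin C
treated) spheroids as the reference for the "low proliferation" side.
For automatic classification, the covered-electrode count and the median
maximum relative impedance at six time points (24–144 h in 24 h steps)
form a 12-parameter feature vector per well; features are z-scored,
reduced to three principal components, and clustered by fuzzy c-means
with four clusters, matching the four reference groups.

## Electrode forward model

No instrument data accompany the assay description, so the package
renders synthetic recordings through a minimal lumped-element model of a
partially covered microelectrode:

$$Z(f,\theta) = R_\mathrm{sol}
  + \frac{1}{Q\,(i\,2\pi f)^{n}}
  + \theta\,\frac{R_\mathrm{cell}}{1 + i\,2\pi f\,R_\mathrm{cell} C_\mathrm{cell}}$$

a series solution resistance, a constant-phase element for the
electrode–electrolyte double layer, and a parallel-RC cell branch scaled
by the covered-area fraction θ ∈ [0, 1]. Both branches have
non-negative real and non-positive imaginary parts, so |Z| — and with it
the relative impedance at any frequency — is non-decreasing in θ, and
θ = 0 reproduces the cell-free baseline exactly.

Defaults (`circuit_params()`):

| parameter | default | meaning |
|---|---|---|
| `R_sol` | 1500 Ω | spreading/solution resistance of a 100 µm electrode |
| `Q_cpe` | 2.5 nS·sⁿ | CPE magnitude (double layer, ~nF scale) |
| `n_cpe` | 0.9 | CPE exponent, slightly non-ideal gold/SU-8 interface |
| `R_cell` | 8 kΩ | cell-layer resistance at full coverage |
| `C_cell` | 80 pF | cell-layer capacitance at full coverage |

These values place the full-coverage relative-impedance maximum near
200 kHz — inside the 137–275 kHz band where spheroid and cell-layer
maxima are observed — with a saturated amplitude of roughly 290 %.
The amplitude scale was chosen against the *per-well median* traces of
the assay, which reach ~270 % on the array: a single saturated electrode
must be able to produce values of that order, and the 110 %
proliferation cut of the quadrant scheme must be reachable. (The
frequently quoted "tens of percent" spheroid maxima come from the
microcavity characterisation geometry, which is not what this forward
model describes.) With the default cell footprint, one adherent cell on
an electrode (θ ≈ 0.05) yields a maximum of about 15 %, just above the
10 % detection threshold — single migrating cells are detectable, as
intended for the assay. Absolute ohm scales are otherwise
unconstrained by the source material and were chosen for plausibility;
only the relative impedance matters downstream.

## The spheroid-egress simulator

`simulate_agents()` is an agent-based stand-in for the instrument data:

* **Emission.** Cells leave the spheroid rim (radius 300 µm, which puts
  6 central electrodes under the body, matching the 3–6 initially
  covered electrodes seen in the assay) as a Poisson process at
  `egress_rate_per_h`, heading radially outward.
* **Motility.** A persistent random walk: per 0.5 h step the heading
  turns by a wrapped-normal angle calibrated so that the one-hour
  direction correlation equals `persistence`, and the step speed is an
  independent truncated-normal draw. Agents are confined to the well
  (radius 3.2 mm, 96-well scale) by clamping.
* **Proliferation.** Each agent divides with probability
  `rate × dt` per step; daughters appear one cell diameter (10 µm) from
  the mother with a random heading — proliferation densifies the
  existing spread rather than extending it, which is exactly what the
  cell-amount read-out is meant to pick up. `mitomycin = TRUE` forces
  the division rate to zero.
* **Spheroid body.** A static disc: electrodes within
  `spheroid_radius + electrode radius` of the centre hold θ = 1 until
  `disassembly_time_h` (finite only for the fast phenotype, whose
  spheroids fully disassemble by 48 h; emission also stops then).

`coverage_series()` converts agent positions to per-electrode coverage,
θ = min(1, footprint × agents-in-disc / electrode area) with a 400 µm²
cell footprint, and `render_recording()` applies the forward model plus
multiplicative lognormal measurement noise with relative standard
deviation 1 % (mean exactly 1; baselines are rendered noise-free by
default so that the no-cell relative impedance is identically zero —
`noisy_baseline = TRUE` disables this).

### Phenotype presets

The three migration phenotypes are pinned to the endpoint
covered-electrode fractions that define them: the fast phenotype covers
essentially all 42 electrodes by 96 h (spheroid disassembly at 48 h),
the intermediate one more than 60 % of electrodes at 144 h, and the slow
one about 35 % at 144 h. Within those constraints the parameters were
fixed once as:

| preset | egress (cells/h) | speed (µm/h) | persistence | division (1/h) | disassembly |
|---|---|---|---|---|---|
| fast | 16 | 25 ± 8 | 0.85 | 0.025 | 48 h |
| intermediate | 3.5 | 9.5 ± 3.4 | 0.80 | 0.032 | — |
| slow | 3 | 5.5 ± 2.0 | 0.70 | 0.040 | — |

Mitomycin variants differ *only* by a zero division rate. The division
rates are deliberately high enough that proliferative densification is
clearly expressed on the covered electrodes within the 144 h window:
untreated wells saturate their agent-electrode medians by the late time
points while treated wells stay at single-cell signal levels. That is
what makes the four reference groups the tight, well-separated clusters
the classifier is specified against, and it mirrors the reference
behaviour of the assay (treated wells end with low medians and roughly
half the covered electrodes of their untreated counterparts).

## Analysis conventions and numerical choices

* **Maximum extraction.** Argmax over the sampled 41-point grid, no
  smoothing or interpolation (41 log-spaced points are sparse; any
  smoother would be an uncontrolled choice). Ties break toward the
  lower frequency.
* **Coverage threshold.** Default 10 % maximum relative impedance,
  inclusive boundary. The detection criterion is not documented for the
  original assay; 10 % sits an order of magnitude above the 1 % noise
  floor and below the smallest single-cell signal the default forward
  model produces (~15 %) and the smallest reported spheroid maxima
  (~15 %). It is exposed everywhere as a parameter.
* **Medians over covered electrodes only**, `NA` (never 0) when nothing
  is covered. Electrodes already covered at the t = 0 measurement are
  additionally excluded from the median (not from the count): they sit
  under the spheroid body and report the 3D culture, not migrated
  cells. Without this exclusion the median of a slowly spreading well
  is clamped at the saturated-electrode amplitude and the
  proliferation axis carries no information; with it, the median traces
  reproduce the characteristic assay patterns (slowly rising medians
  for proliferating slow lines, flat low medians under mitomycin).
  Recordings without a t = 0 sweep are summarised without exclusion.
  `exclude_spheroid = FALSE` restores the plain median.
* **Quadrant thresholds.** The reference assay determined its cuts
  manually; `calibrate_thresholds()` automates this as the midpoint of
  group means of the *endpoint* (last time point) values — covered
  count between low/high-migration references, median between
  suppressed/proliferating references — because the scheme explicitly
  targets late time points. With no references the documented cuts
  (20 electrodes, 110 %) are the fallback. Boundaries are inclusive on
  the "high" side.
* **Features.** 12-vector of covered counts then medians at 24, 48, 72,
  96, 120, 144 h (the assay states six time points without listing
  them; the six daily sweeps after attachment are the natural choice).
  Missing medians are imputed with 0 — a well with no covered,
  non-body electrode genuinely carries no migrated-cell signal — and
  flagged.
* **Standardisation.** Per-feature z-score before PCA: counts (0–42)
  and medians (0–290 %) live on incommensurate scales. Zero-variance
  features are dropped with a warning.
* **Fuzzy c-means.** Standard alternating updates with fuzzifier
  m = 2, convergence when the largest membership change is below 1e-6
  (at most 300 iterations), best of 20 seeded restarts by objective.
  The objective is verified non-increasing on every fit. Memberships
  are computed from distance *ratios*, which is stable for fuzzifiers
  arbitrarily close to 1 (used by the hard-assignment oracle tests) and
  returns exact unit membership for a point on a centre.
  Out-of-sample wells are standardised and projected with the training
  parameters and scored against the fixed centres; hard labels take the
  maximal membership, ties toward the lower cluster index.
* **Determinism.** Every stochastic routine takes an explicit seed and
  restores the caller's RNG state; identical inputs and seeds give
  byte-identical runs, recordings and reports.

## What the simulator does and does not emulate

The generator reproduces the *structure* of the assay data — per-well,
per-electrode, per-time spectra against cell-free baselines, three
migration phenotypes with and without proliferation suppression — and
the endpoint coverage fractions that define the phenotypes. It does not
model cell–cell adhesion or contact inhibition, chemotaxis, the
extracellular-matrix resistance that lifts high-frequency impedance in
dense 3D cultures, spheroid swelling, cell death, or electrode-to-
electrode fabrication variability; trajectories are 2D and agents are
points. Passing tests therefore demonstrate that the analysis pipeline
recovers known ground truth under the stated acquisition geometry and
noise — not that the classifier would separate arbitrary real cell
lines, whose feature distributions may overlap far more than the
calibrated presets do.

## Problem sizes

The test suite and the acceptance script run entirely from synthetic
data generated at run time: endpoint-coverage checks average 20
independent wells per preset; phenotype-recovery fits use 30 wells per
reference group (120 wells); closed-form walk and noise checks use a
few thousand agents and 150 replicate spectra. A full single-well
simulation (144 h at 0.5 h steps, rendered at seven daily sweeps)
takes well under a second; the complete suite runs in a few minutes on
one core.

## Known limitations

* Only |Z| is modelled and analysed; phase information, which real
  instruments record, is discarded by design.
* The equivalent circuit is a forward model for rendering, not a
  fitting model; `migrEIS` deliberately offers no circuit fitting to
  measured spectra.
* The covered/uncovered decision is a single global threshold; per-
  electrode baselines drifting over 144 h (not simulated) would require
  a time-local reference.
* Quadrant calibration uses endpoint values only; wells that cross the
  cuts transiently (e.g. the early attachment/disintegration phase,
  which the assay itself flags as uninformative for proliferation) are
  classified by where they end, not by their path.
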