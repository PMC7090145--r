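---
title: "Methods: timing the salt-induced C3-to-CAM transition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: timing the salt-induced C3-to-CAM transition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(camphen)
```

`camphen` packages the measurement chain used to time the transition of
salt-stressed ice plant (*Mesembryanthemum crystallinum*) seedlings from
C3 photosynthesis to crassulacean acid metabolism (CAM). This vignette
documents the models, the tunable parameters, the design of the
synthetic-data generator, and the limits of what the synthetic tests can
show about real plants.

## Image-based leaf area

Leaf area is a pure pixel ratio: with a 1 cm^2 black reference square in
the frame on the plant's plane,

$$A \,[\mathrm{cm^2}] = \frac{N_\text{green}}{N_\text{ref}}.$$

Because both counts scale with the square of the resolution, the ratio is
invariant to uniform rescaling, and no lens or perspective model is
needed (or attempted) as long as the reference is coplanar with the
foliage.

A pixel counts as *leaf* when `G >= min_green` and `G - R >= margin_r`
and `G - B >= margin_b` on 8-bit channels (defaults 60/20/20); as
*reference black* when all channels are at most `black_max` (default 60).
The reference is the largest 4-connected black component; 4-connectivity
is deliberately conservative against diagonal noise bridges. A
bounding-box fill ratio below 0.85 rejects shadow-like or ragged
components (overridable with `force = TRUE`); note that a perfectly
straight one-pixel line has fill ratio 1 and is not caught by this guard
— it exists to reject oblique streaks and blotches. Specular or
bladder-cell glitter on real ice-plant leaves can fail the green rule;
the thresholds are exposed precisely so users can recalibrate them on
their own camera and lighting.

## Growth model

Whole-plant leaf area over days after treatment $D$ follows

$$A(D) = a_1\,(r_1^{\,D+\tau} - 1), \qquad D \le D_0,$$
$$A(D) = a_1\,(r_1^{\,D+\tau} - 1) - a_2\,(r_2^{\,D + o} - 1), \qquad D > D_0,$$

with germination offset $\tau = 21$ d (the bracket vanishes at
$D = -\tau$, i.e. area zero at germination) and treatment breakpoint
$D_0 = 0$. The salt-term clocking $o$ is a genuine modelling choice: with
$o = \tau$ the second term is enormous already at $D = 0^+$, making the
curve discontinuous and negative within a few days — incompatible with
the positive measured areas it is meant to describe. The package
therefore defaults to $o = 0$ (salt effect clocked from the treatment
day, continuous at the breakpoint) and keeps $o = \tau$ available as an
explicit option (`salt_offset("printed")`), which errors on negative
predicted areas rather than returning them.

Fitting minimises vertical least squares — "minimum distance" between
simulated and acquired data is read as ordinary RSS, not orthogonal
distance — with a Nelder–Mead simplex on log-transformed parameters
$(\log a, \log(r-1))$, which enforces $a > 0$, $r > 1$ without
constraints. The start point is a log-linear regression of $\log A$ on
$D + \tau$ over the upper half of the data (where the $-1$ is
negligible); up to 10 deterministic restarts guard against simplex
stagnation. The fitting domain defaults to $D \in [-21, 14]$: below
$-\tau$ the model is undefined, and 14 days is the monitored treatment
window. On noiseless model-generated data the fit recovers parameters to
better than 0.1% relative error; with 1 cm^2 daily noise the rate factor
is still recovered to about 1% (median over seeds).

Divergence between groups is scanned on integer days (matching the daily
photography) for the first $D > D_0$ with
$A_c(D) - A_s(D) > 0.05\,A_c(D)$; on the study's parameter values this
gives day 4 — growth separates before any gas-exchange signature.

## Diel gas exchange and CAM onset

Traces are 30-s samples of net assimilation $A_\text{net}$
(umol m^-2 s^-1) under a 12/12 h photoperiod, lights-on at the start of
each day. Summaries partition every sample into exactly one (day, phase)
cell; **a night belongs to the day it begins in**, so "day 8's night" is
the dark period following day 8's light period. Gaps larger than twice
the median sampling interval are a hard error, not an interpolation.

CAM onset is operationalised as the first day whose nightly mean
$A_\text{net}$ reaches a threshold, default **-0.1 umol m^-2 s^-1**:
tolerant of "almost zero" nocturnal exchange while cleanly rejecting the
C3 respiratory baseline near -1. Raising the threshold can only delay
the detected onset (a tested monotonicity property).

Anticipation transients are measured across the light edges: the mean of
the last 15 min of dark against the first 15 min of light (and the
mirror at lights-off). Fifteen minutes (30 samples at 30 s) is wide
enough to be noise-stable and narrow enough to isolate the transient. A
morning edge spanning from below -2 to above +2 umol m^-2 s^-1 is
flagged "CAM-like" — stomata closing before dawn and the decarboxylation
burst at lights-on.

## Stomatal statistics

Apertures (inner-pore width, um) are observed at 4 pm and 4 am. A stoma
counts as open at or above **1.4 um** — the midpoint between the
observed closed ceiling (1.1 um) and open floor (1.7 um); the original
classification was visual, so the numeric threshold is exposed. The open
proportion is exact count division, and the inversion day is the first
day with mean 4 am aperture above the 4 pm mean. Standard errors are
sample SD / sqrt(n) throughout, matching the error bars convention.

## Physiological indices

The relative water content formula used and reported by the study,
$RWC = 100\,(FW - DW)/(TW - FW)$, differs from the conventional
$100\,(FW - DW)/(TW - DW)$: its denominator is the *water deficit* at
sampling, not the total water capacity, so values above 100% are
possible. The study's form is the default (its reported 62.5–80% series
only makes sense under it); `formula = "standard"` selects the
conventional form, and the choice is recorded in the output metadata.

MDA is computed in the assay's native unit,
$6.45\,OD_{532} - 0.56\,OD_{450}$ umol L^-1, and converted to
nmol g^-1 fresh weight through explicit volume bookkeeping
(`mda_per_gram()`): assay volume x (extract/aliquot scale-up) / tissue
mass, defaulting to the protocol's 0.2 g in 3 mL TCA with a 2 mL aliquot
in a 4 mL assay — a factor of 30 at those defaults. Whether the original
report used exactly this bookkeeping is not stated; every volume is a
parameter so any interpretation is expressible. Negative MDA values are
flagged with a warning, never clipped.

Index series are computed replicate-wise (index of each replicate's raw
values, then aggregated) — not the index of averaged inputs, which would
bias the nonlinear RWC.

## Group statistics

Per-day comparisons use a two-sided Student's t-test. The pooled
(equal-variance) variant is the default since the original analysis
specified "Student's t-test" without qualification; Welch is a flag.
Stars follow strict inequalities: `**` for p < 0.01, `*` for p < 0.05,
none otherwise — p = 0.05 exactly earns no star. No multiple-testing
correction is applied (matching the per-figure convention); the output
notes this.

## The synthetic-data generator

No raw measurements were deposited with the study, so the generator is a
first-class, tested module that emulates the *described* data under the
stated conditions; its defaults are the study conditions, not tuning
knobs.

- **Leaf scenes**: green ellipses and a black square on white,
  rasterised to *pixel-exact* areas (per-blob counts apportioned by
  largest remainder, each blob taking exactly its count of
  nearest-by-elliptical-distance pixels). Colour jitter (<= 20 levels on
  green, <= 10 on black) exercises the thresholds without defeating the
  defaults.
- **Diel traces**: control days are a half-sine hump from 6.5 to
  10.5 umol m^-2 s^-1 — the published description constrains only the
  range 6.0–12.0, so the smoothest waveform inside it is used — with
  nights at -1.0 and Gaussian noise sd 0.3 (no variance was reported;
  0.3 keeps the maximum sample below 12.0 with ~5 sigma margin over a
  14-day trace, and per-sample dips below 6.0 at the hump's edges are
  possible by construction, so range conformance is asserted on phase
  means). Salt traces ramp the nightly mean linearly from -1.0 (ramp
  start, day 6) to -0.05 at day 8 and +0.3 after, while the daytime hump
  decays to a shallow CAM-state parabola dipping below zero
  mid-afternoon. Nightly base levels are solved so the realised night
  mean *including* the injected 15-min dawn/dusk excursions (flat
  windows at +-2.5) equals the ramp target exactly in expectation —
  detection margins are then ~6 sigma, so the detected onset equals the
  generator's transition day at any seed.
- **Stomata**: apertures uniform within the observed open (1.7–3.0 um)
  and closed (0.7–1.1 um) ranges (no distribution was stated); 150
  stomata per timepoint; 80% of stomata in the phase-appropriate state.
  Salt tables swap the phase pattern from inversion day 7.
- **Physiology**: index *targets* (succulence 0.12 -> 0.16 g cm^-2 over
  days 0–5, to 0.18 under salt by day 11; RWC 62.5 -> 80%; MDA ~1.15
  nmol/g control, +0.55–0.8 under salt from day 7) are perturbed with
  replicate noise and inverted through the index formulas to raw
  weights and absorbances, guaranteeing DW < FW < TW. Four biological
  replicates per day.

All generators are seeded, bit-reproducible, restore the caller's RNG
state, and attach their latent truth (true areas, transition days, index
trajectories) so downstream estimators can be scored.

**What passing tests do and do not show.** The synthetic data reproduce
the *described statistics* of the measurements — ranges, trajectories,
transition days — not their full physiology: no temperature or VPD
effects, no transpiration channel, no instrument drift or leaf occlusion,
uniform rather than empirical aperture distributions, and independent
Gaussian noise rather than autocorrelated instrument noise. Detector
performance on this data demonstrates correctness of the computations,
not field robustness.

## Problem sizes and numerics

Simulations default to the study's own scales — 14 days at 2880
samples/day (40,320 samples per trace), 150 stomata per timepoint, 4
replicates — and the full test suite and acceptance script run these
sizes directly; nothing is scaled down. Optimiser tolerance is 1e-12
relative on RSS with at most 10 restarts. Ties in pixel rasterisation
break by row-major order; equal 4 am / 4 pm aperture means do *not*
count as inversion (strict inequality); day-boundary indexing uses
floor(time/86400).

## Known limitations

- The renderer's colour palette is far cleaner than field photographs;
  real-image use requires threshold recalibration and likely white
  balancing upstream.
- The growth model is purely descriptive (no carbon balance), and
  per-plant mixed effects are out of scope.
- `detect_inversion` requires both timepoints on every scanned day and
  does not interpolate missing cells.
- The CAM-onset and inversion detectors return *first-passage* days; a
  transient artefact crossing the threshold on an early day would be
  reported. On real traces, inspect the nightly-mean series the report
  carries alongside the day index.
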