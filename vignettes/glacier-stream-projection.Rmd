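---
title: "Projecting salmon-accessible streams exposed by glacier retreat"
author: "glacierStreams"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Projecting salmon-accessible streams exposed by glacier retreat}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glacierStreams)
```

## The question and the model

As mountain glaciers retreat they uncover river channels that did not
exist as fish habitat before. Whether Pacific salmon can ever use a newly
exposed channel depends on two things the terrain alone determines: can
adults swim to it (no stretch of the route from the sea is steeper than
their migration limit), and is the channel itself large and gentle enough
to support spawning and juvenile rearing. `glacierStreams` chains the
standard terrain-analysis steps that answer those questions into one
tested pipeline:

1. **Drainage.** Depressions in the elevation grid are filled to spill
   level; every cell then drains to its steepest-descent 8-neighbor (D8);
   flow accumulation counts the cells draining through each cell.
2. **Streams.** Cells with accumulation ≥ a support threshold form the
   stream network, split into reaches at confluences and Strahler-ordered.
3. **Segments and gradients.** Reaches are cut into ~500 m segments;
   the gradient of a segment is the absolute elevation difference between
   its two endpoints divided by its along-path length.
4. **Accessibility.** Starting at the river mouth, segments are accessible
   while every segment passed is *strictly below* the migration gradient
   threshold — 10 % (conservative) or 15 % (inclusive). One steeper
   segment bars everything upstream; glaciers whose ice the accessible
   network reaches are "accessible glaciers".
5. **Futures.** Beneath accessible glaciers the ice-surface DEM is
   replaced by reconstructed bedrock (surface − ice thickness) and the
   whole drainage chain is re-run; the future network is classified with
   the same contiguity rule, plus the habitat criteria: Strahler order ≥ 2
   and gradient ≤ 2 % (with the 10 % threshold) or ≤ 4 % (with 15 %).
6. **Timing.** Annual ice-extent schedules per glacier and ensemble member
   give every future segment an exposure year; stream-km totals are
   reported for decadal-mean benchmark extents centred on 2050 and 2100
   and for complete deglaciation.
7. **Uncertainty.** Three components combined by root sum of squares:
   the ensemble spread across members, a ±25.9 % systematic ice-thickness
   perturbation (full re-run), and a segment-length sensitivity (full
   re-runs at 250, 400, 600 and 750 m).

The package's central assumption is shared with the approach it
implements: only stream gradient and order decide habitat. Width,
discharge, temperature, sediment, and the lag before a raw proglacial
channel stabilises into usable habitat are all outside the model; exposure
is treated as instantaneous availability.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `supportThreshold` | 50 | cells | stream initiation; the underlying study does not report its value, so this is a package choice — large enough that hillslope cells never register as streams on the synthetic landscapes |
| `targetLength` | 500 | m | the gradient-analysis scale; segments of a reach are `ceiling(L/target)` near-equal pieces, never spanning a junction |
| `accessThresholds` | 0.10, 0.15 | fraction | conservative and inclusive adult migration limits; strict inequality, so a tie at exactly the threshold is a barrier |
| `habitatGradientMax` | 0.02, 0.04 | fraction | spawning/rearing ceilings paired with the thresholds; closed interval ("0–2 %" includes 2 %) |
| `minOrder` | 2 | — | habitat spans second- to fourth-order streams; first-order streams are accessible but not counted as habitat |
| `thicknessPerturbation` | 0.259 | fraction | the stated uncertainty of modelled ice thickness; the sensitivity runs scale all thicknesses by 1 ± 0.259 |
| `sensitivityLengths` | 250, 400, 600, 750 | m | alternative segmentation scales; the extremes define the segment-length sigma |
| `benchmarkYears`, `benchmarkWindow` | 2050/2100, 10 | yr | decadal-mean benchmark extents |
| `adjacencyRadius` | 60 | m | secondary glacier-contact tolerance (2 cells at 30 m) |
| `snapTolerance` | 100 | m | fish-presence points farther than this from any stream are excluded |

## Numerical and semantic choices

Several points are genuinely open in a verbal description of this
procedure; the package fixes them as follows, and the test suite pins each
one down.

* **Flat resolution and tie-breaks.** Depression filling is priority-flood
  to spill elevation (no breaching), with FIFO ordering among equal
  elevations so filled flats are conquered breadth-first from their spill
  point; a flat cell's direction falls back to its flood parent, which
  guarantees an acyclic field. Steepest-descent ties break to a fixed
  neighbor scan order (E, SE, S, SW, W, NW, N, NE). Runs are therefore
  bit-reproducible.
* **Nodata is a barrier.** Cells enclosed by nodata cannot drain to the
  boundary; they are reported and excluded rather than guessed at.
* **Segments never span junctions.** Reaches are cut at confluences before
  length subdivision; cut points snap to cell boundaries, so segment
  lengths tile each reach exactly and the total network length is
  conserved at every target length (the basis of the segment-length
  sensitivity).
* **Gradient uses |Δz| over along-path length** (diagonal steps count
  √2 × cell size), not straight-line distance — and the absolute value
  matters because bedrock-derived profiles need not be monotone.
* **Glacier contact.** Ice removal happens at whole-segment granularity,
  so the truncated endpoint of the segment straddling an ice margin can
  sit hundreds of metres below the outline. A glacier therefore counts as
  accessible when a segment overlapping its footprint drains directly
  into a kept accessible segment (the accessible network reaches the
  ice); a tip-to-outline distance test at `adjacencyRadius` is kept as a
  secondary criterion for ice abutting the network without overlapping a
  segment.
* **Future networks are derived on the full grid**, with thickness
  subtracted only over accessible glaciers and all other terrain frozen.
  This joins future reaches to the present network exactly where the
  truncated network ended (no artificial boundary seam) and — deliberately
  — computes Strahler orders on the combined drainage, so a future trunk
  continuing a large present river is not reset to order 1. Overdeepenings
  in the reconstructed bedrock are filled like any other depression; the
  package does not model proglacial lakes.
* **Exposure requires the whole path to be ice-free.** A partially exposed
  segment contributes no fractional kilometres. The "10-year average" of a
  set-valued extent is operationalised per cell: covered in the benchmark
  iff covered in ≥ 50 % of the window's annual masks. For monotone
  schedules this is equivalent to `exposureYear < centerYear`. Complete
  deglaciation is evaluated analytically as the empty mask.
* **Uncertainty collapse.** The two-sided sensitivity deltas are collapsed
  to one sigma as the mean of their absolute values, applied to the
  ensemble-mean kilometres; the ensemble uses the sample (n−1) standard
  deviation. Error bars are symmetric mean ± σ_total.
* **Threshold-verification statistic.** The maximum gradient crossed from
  outlet to observation is reported with both tail fractions (share below
  10 %/15 % and share at or above 10 %), because the verbal phrasing of
  the statistic is readable in either direction; quartiles use the
  sort-based inverse-ECDF definition.

## What the synthetic landscapes emulate — and what they do not

`landscapeSpec()` plants a dendritic channel network (main stem,
diagonal tributaries, sub-tributaries) with exact construction slopes
(1.5 % main stem, 3 % tributaries, 4 % sub-tributaries); the terrain is
the lower envelope of cones rising from the channel profiles at the
cross-valley hillslope (0.35), plus power-law roughness, clipped to nodata
beyond a watershed half-width — the same clip a real DEM gets at a basin
boundary. The mask tapers to a narrow collar at each channel head so
headwater drainage enters from the side slopes; without that, the
convergent cap beyond each head spawns radial rills that inflate Strahler
orders above the planted topology. Four glaciers cover headwater branch
complexes with smooth thickness fields (parabolic along- and cross-flow
tapers, zero at the margins) in four bedrock styles: gentle, icefall step
(~25 % ramp under the ice), hanging (~30 % headwall below the terminus —
inaccessible at both thresholds), and gate (~12 % approach — gained only
at 15 %). Ramp slopes are capped below the hillslope because an envelope
of hillslope cones cannot contain anything steeper; a small planted gully
anchors a junction at each ramp base, where the valley side slopes
converge anyway, so reach splits are deterministic. Retreat schedules melt
cells terminus-upward at a member-specific rate (five members share
seed-derived multipliers across scenarios, so the fast scenario strictly
outpaces the moderate one), giving closed-form exposure years
`start + ceiling(d / rate)`.

With roughness amplitude 0 the landscape is analytically controlled: a
1-D emulation on the planted profiles (reach splitting at junctions,
initiation from cone-geometry drainage counts, near-equal segmentation,
the same contiguity/order/gradient rules) yields a ground-truth manifest
entirely independent of the raster pipeline, and the end-to-end run is
required to recover its accessible and habitat kilometres within 5 %
(observed: under 2 %). Passing on these landscapes shows the chain of
rules is implemented correctly; it does *not* show the rules describe real
terrain. Real DEMs have correlated noise, braided and low-relief reaches
where D8 is a poor router, ice-surface artefacts, and bedrock errors that
are spatially structured rather than a uniform ±25.9 % — none of which the
generator reproduces. With nonzero roughness the landscapes exercise the
pipeline stochastically (monotonicity and ordering properties hold on
every seed) but short reaches near junctions can then carry
noise-dominated gradients, which is also why the benchmark quantities in
`scripts/acceptance.R` are computed on the smooth landscape.

## Problem sizes

The default landscape is 400 × 400 cells at 30 m (12 × 12 km) with four
glaciers — large enough for order-4 networks and seconds-scale runs.
Property tests sweep twenty 140 × 140 landscapes; oracle tests use 12 × 12
grids against brute-force graph searches and 50 random reach trees against
the recursive Strahler definition. A full `runPipeline()` with both
sensitivity analyses takes a few seconds on one core.

## Known limitations

* D8 single-flow-direction routing only; no D∞/MFD, no DEM reconditioning
  against mapped hydrography.
* Barrier semantics are segment-level: a 500 m segment under 10 % may
  still hide a waterfall, and one over 10 % may be passable. The
  segment-length sensitivity brackets, but does not remove, this
  imprecision.
* Retreat schedules are extent-only inputs (terminus raising); the package
  deliberately contains no mass-balance or ice-dynamics model.
* Exposure is availability, not suitability: channel stabilisation,
  sediment and temperature evolution are out of scope, as are outburst
  floods, landslides and river piracy.
* Habitat is gradient × order only; no width, confinement or discharge
  attributes exist anywhere in the data model.
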