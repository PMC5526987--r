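---
title: "Quantifying DNA halos: measurement model and design notes"
author: "haloquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying DNA halos: measurement model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(haloquant)
```

## The assay and what is being measured

In the maximum fluorescence halo radius (MFHR) assay, histones are
salt-extracted from nuclei so that chromatin loops unfold and diffuse
outward, while loop bases remain anchored to the extraction-resistant
nuclear matrix (NM). A stained preparation shows a bright, dense **residual
nucleus (RN)** surrounded by a dimmer, diffuse **halo** of expanded loops.
The mean halo radius is a proxy for average chromatin-loop extension, and
its change under perturbation (oncogene expression, cell-line differences)
reports on the stability of DNA–NM attachment.

`haloquant` quantifies 8-bit fluorescence micrographs of such preparations.
Everything rests on two intensity boundaries per cell:

* the **RN edge**, taken at `localMax - rnOffset`, where `localMax` is the
  brightest pixel of that cell's object. Tying the RN threshold to the
  per-cell maximum makes the edge robust to the wide brightness range seen
  across a population;
* the **outer halo edge**, at either a fixed 8-bit level (absolute mode,
  e.g. 15, which confidently includes the outermost loop DNA) or at
  `localMax - outerValue` (relative mode, e.g. 180), which couples the
  outer edge to RN intensity and is what makes time-decay measurable.

The shorthand `x55/15` means `rnOffset = 55` with absolute outer threshold
15; `x75/x180` means `rnOffset = 75` with relative outer offset 180.

Regions are segmented as 8-connected components of pixels at or above the
threshold, anchored at the object's maximum pixel, so RN and outer regions
are linked by construction (the outer component contains the RN seed).
Areas convert to radii by the equal-area-circle rule \(r = \sqrt{A/\pi}\),
and the halo radius is the difference `outerRadius - rnRadius`. The
equal-area convention is the one consistent with polygon-area visual
estimates ([polygonRadius()]), which integrate shape irregularity the same
way.

## Stability classes

Populations produce two broad phenotypes: cells with a defined RN
(class I) and cells whose RN is too ill-defined to segment (class II).
Class I is split by RN brightness: **Ia** (bright) when strictly more than
half of the RN pixels exceed intensity 220, otherwise **Ib** (pale). The
classifier (`classifyField()`) segments the RN with its own offset
(`RNx55/RN220`, `RNx75/RN220`), mirroring the fact that the classification
variants are named independently of the sizing variants.

Two deliberate tie-breaks make the rule total and deterministic:

* a bright fraction of exactly 0.5 is **Ib** — Ia requires a strict
  majority;
* "above 220" is strict (`> 220`), so pixels at exactly the cut do not
  count as bright.

Class II is defined operationally as RN measurement failure
(`status == "rn_fail"`): either the RN threshold is unreachable
(`localMax - rnOffset < 1`) or the RN region is smaller than
`minObjectArea`.

## Halo decay over time

Imaging itself damages the DNA: under continued exposure the halo loses
intensity until, with a relative outer threshold, the outer edge can no
longer be measured (`localMax - outerValue < 1`) and the cell *fails* to
return a value. `decayRecord()` measures a timed series (typically 7
frames, 0–60 s at 10 s intervals), tracks the cell, and reports the time
of the first failing frame. Cells measurable at every frame are censored
and assigned the sentinel fail time of 70 s; `survivingFraction()` counts
censored cells as surviving at every observed time, and
`meanTimeToDecay()` averages fail times with the sentinel included —
deliberately *not* a Kaplan–Meier estimator, but the raw-percentage and
sentinel-mean convention of the assay itself.

Decisions taken where the procedure was open:

* **first-failure rule** — a frame that is measurable again after an
  earlier failure does not reset the clock; scanning stops at the first
  failure;
* **tracking** — the object nearest the previous frame's centroid, with a
  50 px displacement gate; in the first frame, the object nearest the
  image centre (series image individual cells, so this is a tie-break more
  than a tracker). A vanished or out-of-gate object counts as failure at
  that frame, with a diagnostic note kept in the record;
* decay analysis refuses absolute-outer configs, since failure is defined
  by the relative threshold becoming unreachable.

## Calibration

`calibrateRnOffset()` reproduces the threshold-selection procedure: for
each candidate offset the training images are measured, each field's mean
RN radius is expressed as a percent of the visually estimated radius for
that field (per-pair percent, then mean — matching how mean-percent bars
are computed), and the offset whose mean percent is closest to 100 wins;
ties go to the smaller offset. `percentOfReference()` implements the same
comparison for marker-based exposure calibration; choosing a physical
exposure time is a bench activity and out of scope. `twoSampleT()` is the
equal-variance Student's t (the convention used with these data), with
stars at 0.05 / 0.005 / 0.0005 and explicit handling of the
zero-variance degenerate case.

## The phantom generator as analytic oracle

`renderField()` draws each phantom from a radial model: a flat core at
`peak` intensity out to `rnRadius`, then a Gaussian tail
\(I(r) = b + (p-b)\,e^{-((r-r_\mathrm{RN})/s)^2}\) over background \(b\).
The Gaussian tail is chosen because it resembles the bright-core /
shallow-tail profiles seen in line scans across processed nuclei **and**
gives a closed-form crossing radius for any threshold \(t \in (b, p]\):

\[ r(t) = r_\mathrm{RN} + s\sqrt{\ln\frac{p-b}{t-b}}, \]

(`crossingRadius()`), which is what turns rendered images into ground
truth for the whole measurement pipeline. With `plateau = FALSE` the core
is a pure Gaussian peak — equivalent to \(r_\mathrm{RN} = 0\) in the same
formula. Noise is additive Gaussian, clipped to [0, 255] and rounded
(a simple stand-in for camera noise; when phantoms in a field declare
different `noiseSd`, the largest is applied to the whole frame, since
noise is physically a field property). Overlapping phantoms are rejected
because the max-composition would make the per-phantom crossing radii
ill-defined. `renderTimeSeries()` decays the intensity excess
exponentially and reports the first frame at which the rendered
(integer) peak makes a relative outer threshold unreachable, so decay
timing can be checked frame-exactly.

What the generator does **not** emulate: non-circular and lobed halos,
intensity gradients across the field, debris and overlapping cells,
Poisson photon statistics, chromatic aberration. Passing the recovery
suites therefore demonstrates correctness of the measurement logic on the
stated model, not robustness to every real-world artefact — threshold
configuration on real data should still be validated against a visual
training set via `calibrateRnOffset()`.

## Parameters, defaults and numerical choices

| parameter | default | meaning |
|---|---|---|
| `rnOffset` | 55 | RN threshold below local max (`x55`); 75 for the relative-outer setting |
| `outerMode`/`outerValue` | absolute / 15 | outer edge level; relative 180 or 240 for decay work |
| `seedThreshold` | 15 | candidate detection level — the most permissive outer level, so detection never misses a measurable halo |
| `minObjectArea` | 500 px | debris filter at full 1388×1040 frame scale; the validation suites use 100 px, matched to their 10–40 px RN radii |
| `borderPolicy` | exclude_touching | border-clipped objects would bias radii low |
| `maximaMode` | object | per-object maxima; per-image mode is kept as a fidelity switch |
| `brightCut` / `brightFractionCut` | 220 / 0.5 | class Ia rule |
| censor sentinel | 70 s | fail time assigned to series measurable at 60 s |
| tracking gate | 50 px | maximum frame-to-frame centroid displacement |

Numerical conventions: region membership is `>= threshold` (closed lower
bound); connectivity is 8-way (diagonal contact merges); thresholds are
clipped at 1 because a threshold of 0 would select the entire frame; the
segmentation seed is the topmost-then-leftmost maximum pixel, making all
tie-breaks deterministic; images deeper than 8 bits are rejected rather
than rescaled because every threshold is defined on the 0–255 scale.
For sane configurations the RN threshold exceeds the outer threshold and
the RN region nests inside the outer region; if a configuration violates
this (e.g. a very dim object under an absolute outer threshold), the
package warns once per field and measures anyway.

## Problem sizes used in validation

The test and acceptance suites run on synthetic frames of roughly 200–600
px per side with RN radii 10–40 px and halo extents 20–80 px beyond the
RN — the same geometry as full-size micrographs at a quarter the field of
view, chosen to keep the suites quick while leaving every radius large
against the 1 px recovery tolerance. Recovery is validated on 50
noise-free and 50 noisy (σ = 5) fields, classification on 200 phantoms
with programmed classes (brightness margins ≥ 10 intensity units from the
220 cut), decay on 32 series with analytically known crossing frames, and
calibration on 20 independently seeded training sets.

## Known limitations

* Halo radii assume near-circular halos; strongly lobed halos are
  summarised by their equal-area radius, which understates anisotropy.
* Touching cells whose outer regions merge at a permissive absolute
  threshold are linked to a single outer component; the RN measurements
  remain separate, but outer areas are then shared and halo radii
  unreliable — fields should be imaged sparsely, as the assay prescribes.
* The classifier reuses the measurement machinery, so very small bright
  RNs (< `minObjectArea`) classify as II by construction.
* No sub-pixel edge localisation: the method is pure intensity
  thresholding, and measured radii carry ± half-pixel rasterisation
  error.
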