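---
title: "Lesion overlays, subtraction maps and indirect disconnection: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lesion overlays, subtraction maps and indirect disconnection: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lesionmap)
```

## The analysis

`lesionmap` implements a descriptive lesion-symptom mapping workflow for
two cohorts of stroke survivors, each given as one binary lesion mask per
subject on a shared voxel grid (NIfTI-1, with the affine mapping 0-based
voxel indices to world mm). The chain is:

1. **Overlay.** Voxelwise count of lesioned subjects, and the proportion
   map obtained by dividing by the cohort size.
2. **Common lesion.** The case cohort's proportion map thresholded at 0.80:
   the territory lesioned in at least 80% of cases.
3. **Subtraction.** Case proportions minus control proportions, thresholded
   at the difference between the two cohorts' global proportion maxima
   (the max-difference rule) and binarized. The data-driven threshold
   compensates for the control cohort's generally lower overlap; a fixed
   cutoff would either admit vascular-territory voxels common to any left
   hemisphere stroke or discard genuinely case-specific ones.
4. **Parcel overlap.** For each parcel of a labeled atlas, the percent of
   the parcel's voxels inside a binary map.
5. **Indirect disconnection.** For each bundle of a normative streamline
   atlas, the percent of streamlines intersecting a binary map.

Both binary maps (common lesion and binarized subtraction map) are pushed
through both quantifiers, so the regional and tract-level readouts can be
compared like-for-like.

The workflow is deliberately non-inferential: no voxelwise tests, no
permutation correction, no smoothing, no cluster-extent filtering. It
answers "where do the cohorts' lesions concentrate and differ", not "is
the difference significant".

## Conventions and numerical choices

- **Thresholds are inclusive** (`>=`), both for the 0.80 common-lesion rule
  and for the binarization of the subtraction map: a voxel exactly at the
  cutoff survives. With realistic cohort sizes the boundary case is real —
  at n = 39 the attainable fractions bracket 0.80 as 31/39 ≈ 0.795 and
  32/39 ≈ 0.821 — so the choice is observable and must be fixed.
- **Proportions are exact rationals.** Counts are tallied as integers and
  divided once, so every proportion is an exact integer multiple of 1/n and
  thresholds compare against these exact values, never against rounded
  percentages. This also removes float accumulation from the sum.
- **Grid compatibility** requires equal shapes and affines agreeing
  entrywise within 1e-5 (absolute). The tolerance absorbs serialization
  noise in NIfTI headers without masking genuine misregistration, which at
  1-2 mm voxel sizes appears in the affine at far larger magnitudes.
- **Resampling is nearest neighbour only**, for masks and label volumes
  alike: each target voxel centre is mapped through the target affine and
  the inverse source affine and rounded to the nearest source index
  (half-to-even, R's `round`); out-of-view voxels get 0. Any interpolating
  scheme would create non-binary mask values or invented labels. Identity
  resampling is exactly a no-op.
- **Binarization at load**: input masks are nominally binary but often
  carry interpolation residue; voxels strictly above a configurable
  threshold (default 0, i.e. any nonzero value) become 1.
- **Streamline-mask intersection** samples the polyline at steps of half
  the minimum voxel edge (subdividing each segment) and assigns each sample
  to its nearest voxel index. The step bound guarantees that a straight
  segment cannot cross a one-voxel-thick lesion between two samples; finer
  steps only add cost.
- **Deterministic table order**: overlap tables sort by descending percent
  with ascending label as tie-break; disconnection tables by descending
  index with bundle name as tie-break. CSV outputs carry each percentage
  twice — one decimal for display, `%.17g` for exact round-trips.
- The max-difference rule can return a **negative threshold** when the
  control cohort overlaps more; this is permitted (the rule is well defined
  there) but flagged with a warning, since it usually indicates swapped
  cohorts.

## Design decisions that were genuinely open

- **Direction of the overlap percentage.** "Percent of overlap with each
  parcel" could be parcel-normalized or lesion-normalized. We normalize by
  the parcel: near-ceiling values for small regions engulfed by a large
  lesion are only meaningful under parcel normalization, and that is the
  reading consistent with reported near-100% values for small insular
  parcels. Background (label 0) is not a parcel and gets no row; labels
  named in the lookup but absent from the volume get a 0% row, so a
  standard atlas lookup always yields a complete table.
- **Disconnection index definition.** We count streamlines with any lesion
  contact, as a percentage of the bundle (the convention of the established
  lesion-quantification toolkits). A minimum-overlap-length variant would
  need an arbitrary length parameter and cannot reproduce clean 100%/0%
  endpoints on planted geometry.
- **Threshold on counts vs rounded percentages.** The 80% rule is applied
  to the exact rational proportions with `>=`; applying it to rounded
  percentages would silently shift the boundary at small n.
- **Parcel-to-parcel disconnection matrices** are out of scope: only
  tract-level indices are produced.

## What the synthetic generator emulates — and what it does not

`make_cohort()` draws, per subject and in a fixed order (three normal
deviates for the centre jitter, one for the radius, one uniform deviate
for the core-hit Bernoulli), a spherical lesion around a core territory,
unioned with the core with probability `core_hit_rate`. The two stock
specifications encode the study contrast the pipeline is built for:

- `broca_like_spec()`: n = 39, `core_hit_rate = 1`, radius 37.6 ± 6 mm
  (a mean volume of ≈223 cc), centre scatter 8 mm — large, spatially
  concentrated lesions that always cover the core.
- `wnl_like_spec()`: n = 41, `core_hit_rate = 0`, radius 24.3 ± 8.5 mm
  (≈60 cc), centre scatter 25 mm — smaller, scattered lesions that never
  cover the core.

The radii are the sphere-equivalents of the target mean volumes; the sd
values propagate the corresponding volume spreads through the cube-root;
radii are truncated below at 1 mm and spheres at the grid bounds. The
default grid is 64³ voxels at 2 mm isotropic, centred on the origin —
small enough that a full cohort generates in well under a second, large
enough for nontrivial parcellations and corridors. `make_parcellation()`
produces a Voronoi partition around seeded sites (ties to the lower
label); `make_tract_atlas()` emits bundles as corridor polylines densified
to one-voxel steps with a per-streamline rigid Gaussian offset. All
generators are pure functions of (spec, seed); ground truth (core voxels,
per-subject parameters) is returned and serialized alongside the data.

What this does **not** emulate: vascular-territory anatomy (lesions are
spheres, not middle-cerebral-artery shapes), lesion tracing noise,
normalization error, cortical-surface geometry of real parcellations, or
curved tract anatomy. Passing tests therefore demonstrate that the
*pipeline arithmetic and geometry* are correct and that planted structure
is recovered end-to-end; they say nothing about the anatomical validity of
any real-data result.

## Problem sizes and verification strategy

The test suite verifies each operation against independent brute-force
oracles (triple-loop voxel tallies, analytic line-slab traversal) on
10³-voxel grids across 100 random cohorts, checks the published worked
arithmetic (0.7 − 0.1 = 0.6; maxima 0.97 and 0.42 giving a 0.55 threshold
applied inclusively), and runs the planted-structure recovery scenario at
the full default conditions (64³ grid, 39 + 41 subjects). Monotonicity
suites (threshold nesting, overlap and disconnection growth under lesion
growth, range invariants) run across 20 seeds. These sizes keep the whole
suite around ten seconds while leaving no operation tested only at toy
scale.

## Limitations

- Only nearest-neighbour resampling is offered; volumes must already be
  co-registrable by an affine (no nonlinear normalization).
- Streamline files are read in the TCK format and a plain JSON dialect;
  the legacy TRK format, whose coordinate conventions vary by producer,
  is not parsed — convert to TCK or JSON first.
- The subtraction analysis is descriptive; absence of a voxel from the
  binarized map is not evidence of no difference.
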