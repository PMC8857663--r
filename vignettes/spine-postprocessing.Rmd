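---
title: "Refining, labeling and evaluating vertebra segmentations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Refining, labeling and evaluating vertebra segmentations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spineseg)
```

## The problem

Convolutional networks that delineate vertebral bodies on CT emit two kinds
of hard labelmaps: a *binary* segmentation (vertebra vs background) and a
*level-coded* segmentation in which each voxel carries an anatomical level
(T1–T12, L1–L5; 17 classes plus background). Neither output is directly
usable for radiotherapy planning: adjacent vertebrae may be fused into one
region, small spurious islands appear, and a single segmentation error can
shift every level label below it by one. `spineseg` implements the
downstream half of that workflow — everything between the network's argmax
and the clinical report:

1. **Refinement** of the binary segmentation into separated vertebra
   instances (`refine_binary()`).
2. **Level assignment** by consensus anchoring and craniocaudal propagation,
   via the *sequential* approach (geometry from the binary map, levels from
   the level map) or the *combined* approach (one level map supplies both)
   (`sequential_approach()`, `combined_approach()`).
3. **Evaluation**: per-vertebra Dice and Hausdorff distance, labeling
   accuracy, offset-by-one attribution, paired statistics, and a blinded
   subjective review protocol.
4. A **synthetic spine phantom generator** with a controllable
   network-failure model, so the whole pipeline is testable without
   clinical scans or trained weights.

## Data model and conventions

Volumes and labelmaps are plain 3-D arrays with voxel spacing in mm
(`volume3d()`, `labelmap3d()`), read and written as NIfTI-1. Axis 3 is the
craniocaudal axis with increasing index = superior; images must be
reoriented to this convention on load. Voxel indices are treated as points
at `index * spacing`, so all distances are physical. Instance ids run 1..n
from cranial to caudal, which makes level codes increase with instance id.

Preprocessing follows the workflow's contract: resampling to 1 mm isotropic
voxels (trilinear for intensities, nearest-neighbor for labelmaps — labels
are never blended) and window normalization onto \[-0.5, 1.5\]. The
normalization window is not part of the published contract, only the output
range; we expose it as a parameter with default (-1000, 1000) HU, a
symmetric window spanning air to dense bone, and clip outside values.

## Refinement

`refine_binary()` composes four steps: connected components (26-neighborhood
by default — fusions leak through face *and* diagonal contacts), candidate
filtering, watershed splitting, and a second filtering pass over the split
parts. The detection criteria are of three kinds — region size, position
relative to the spine axis, and inter-region distance along that axis — but
their numeric thresholds are not published, so they are explicit,
configurable reconstructions (`refine_config()`):

* plausible body volume 5–120 cm³ (an adult vertebral body is ~10–20 cm³;
  the wide band only rejects debris and giant merged blobs);
* edge-contacting instances are exempt from the minimum down to a quarter
  of it, because partially visible vertebrae at scan edges are legitimately
  small;
* centroids more than 25 mm lateral to a smooth spine axis (quadratic
  least-squares curve of x and y against z through the size-passing
  candidates) are removed; with fewer than three candidates the axis is
  unidentifiable and this filter is skipped;
* an instance is a fusion suspect when its craniocaudal extent exceeds
  1.6 × the expected body height (default 28 mm).

Suspects are split by a marker-controlled watershed on the negated interior
Euclidean distance transform. Markers are per-slice distance maxima after
suppression of peaks closer than 0.8 × expected height craniocaudally, ties
broken by greater distance then lower slice index — one deterministic
marker per body center. The flood is a priority queue with FIFO
tie-breaking, so the partition is exact and reproducible: the parts' union
equals the suspect voxel-for-voxel. A suspect with a single distance peak
(e.g. one genuinely tall blob) is passed through with a logged warning
rather than force-split.

Because post-processing can also *cause* errors (an unrepaired merge
shifts every downstream label), every destructive action — removal, split —
is logged with voxel counts in the segmentation's `$log`, and the pipeline
embeds that log in its JSON run report.

## Level assignment

For each refined instance the level prediction is reduced to its modal
nonzero level and a consensus fraction (modal voxels / overlapping nonzero
voxels). Instances at or above the 0.95 consensus threshold are *anchors*
and keep their level; every other instance gets the level implied by
counting positions from its nearest anchor along the craniocaudal order.
This counting interpretation is what makes the characteristic failure mode
mechanical: if two vertebrae merge into one instance, every vertebra on one
side ends up off by exactly one level.

Two choices here are ours, as the published description is silent:

* **Anchor conflicts.** When equidistant anchors imply different levels for
  an instance, the higher-confidence anchor wins, ties going to the more
  superior one; every overridden implication is logged. A global
  reconciliation scheme would be possible but harder to audit.
* **No anchors.** An input whose every instance is below threshold fails
  loudly (`propagate_labels()` errors) instead of guessing. Propagation
  past T1 or L5 is likewise an error, and a non-monotone assignment (only
  possible with a wrong anchor) triggers a warning plus a log entry.

## Evaluation

`dice()` is exact voxel counting (defined as 1 for two empty sets).
`hausdorff()` is the classical maximum over surface voxels (foreground
voxels with a background 6-neighbor; grid-boundary voxels count as
surface), computed from exact anisotropic Euclidean distance transforms;
whether the original evaluation used the maximum or a percentile variant is
unstated, so the 95th-percentile variant is available via `percentile =`
but is not the default.

`match_and_score()` matches each fully visible ground-truth vertebra to the
predicted instance of maximal overlap (ties by centroid distance — the
matching rule is also unpublished) and scores geometry label-blind. Offset
attribution is operationalized as: maximal runs of ≥ 2 consecutive
mismatches sharing one signed offset, adjacent to a merge or a missing
match; the causal rows themselves are not offset-eligible. Those rows keep
their geometric Dice/HD "as if correctly labeled"; an unmatched vertebra
scores Dice 0 with HD flagged missing rather than invented.

Statistics: labeling accuracy carries a Wilson interval; paired Dice/HD
comparisons use the Wilcoxon signed-rank test with Pratt zero handling by
default (`zero_policy = "wilcoxon"` defers to `stats::wilcox.test()`, which
the Pratt path reproduces exactly when no zeros or ties are present);
review tables use chi-squared tests with Yates correction on 2×2 tables.
All of these policies are unstated in the original description and are
therefore explicit, configurable defaults here.

The blinded review protocol (`build_review_session()`) draws, per level,
three human-sourced and three automatic-sourced slices, permutes them with
a seeded RNG, and keeps the blinding key in a separate file; ratings use
the 4-point scale (1 = large obvious errors … 4 = precise) with clinical
acceptability defined as rating ≥ 3.

## The phantom generator and what it does (not) show

`generate_phantom()` builds the study regime the workflow targets: a
craniocaudal stack of ≥ 5 vertebral-body-like blobs. Bodies are
superellipsoids (exponent 4 — squat rounded boxes, which is what makes the
interior distance transform bimodal across a fusion, unlike spheres), with
semi-axes 14 × 12 × 13 mm (~14 cm³), 4 mm disc gaps, a mild sinusoidal
lateral curvature (≤ 2 mm), and an intensity model of soft tissue
(~40 HU) / trabecular interior (~200 HU) / cortical shell (~700 HU) plus
Gaussian noise (σ = 15 HU). `partial_at_edges` truncates the top body to a
sub-minimum cap to exercise the edge exemption. All randomness flows from
one integer seed; identical specs give bit-identical phantoms.

`corrupt_prediction()` emulates the network failure modes the refinement
must fix: cylindrical fusion bridges (3 mm radius) across the disc gap,
EDT-threshold boundary erosion/dilation, superior-slab level mislabeling
with a chosen mixing fraction, spurious small islands, and per-instance
dropout. On a 1 mm grid a hard labelmap is invariant to sub-voxel
morphological perturbation, so boundary noise below 1 mm is exactly
identity — tests that need real geometric damage use ≥ 2 mm.

What passing phantom tests shows: the refinement, propagation, offset
bookkeeping and review protocol behave mechanically as specified, at
realistic sizes and failure rates. What it does not show: performance on
real CT — phantoms have no vertebral arches, ribs, metastatic lesions,
fractures, contrast variation or scanner artefacts, and the corruption
model is far simpler than real network error structure. Headline clinical
numbers therefore cannot be reproduced here; the package's tests are
property-based instead.

Under label-only corruption the sequential and combined approaches coincide
by construction (relabeling does not change level-map geometry), so the
divergence tests also corrupt level-map *geometry*, where the combined
approach — whose segmentation comes from that map — genuinely degrades
while the sequential approach is untouched.

## Problem sizes and numerical choices

The test-suite and acceptance-script studies use 5–17 vertebrae per
phantom, 10–50 phantoms per property, and 50–200 review sessions; these
sizes give stable proportions while keeping a full run in a few minutes on
one core. Distance transforms are exact (Felzenszwalb lower-envelope, fp
error ~1e-12 mm); the watershed and component labeling are integer-exact
and deterministic; ties anywhere (modal level, matching, markers) break
toward the lower code / more superior position, and all such policies are
noted in the function documentation.

## Worked example

```{r example, eval = FALSE}
library(spineseg)

ph <- generate_phantom(phantom_spec(n_vertebrae = 5, first_level = "T9",
                                    seed = 7))
pred <- corrupt_prediction(ph$instances, ph$levels,
                           corruption_spec(fuse_pairs = list(c(2, 3)),
                                           seed = 8))
lseg <- sequential_approach(pred$binary, pred$level)
m <- match_and_score(lseg, ph$instances, ph$levels)
labeling_accuracy(m)
glance(m)
autoplot(m)
```

## Known limitations

* Thoracolumbar only (T1–L5); cervical levels and the sacrum are out of
  scope, as is DICOM/RT-STRUCT I/O.
* Inputs are hard labelmaps; soft (probabilistic) network outputs are not
  consumed.
* The refinement thresholds are reconstructions of unpublished criteria;
  they are defaults to be tuned per cohort, not validated clinical
  constants.
* Orientation handling trusts the NIfTI header spacing and the documented
  axis convention; no automatic reorientation is performed.
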