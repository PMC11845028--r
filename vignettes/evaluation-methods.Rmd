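---
title: "Evaluating multi-animal pose tracking: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating multi-animal pose tracking: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vmtrack)
```

This vignette explains the models and procedures behind `vmtrack`, the
assumptions they rest on, the parameters that matter, and the design
choices made where the conventions of the field left the question open.

## The evaluation problem

Multi-animal pose trackers output, per video frame, one 2-D pixel
coordinate per (individual, body part), possibly missing. Given a
manually annotated ground truth (GT) for a scene of consecutive frames,
the task is to say *how* the tracking failed, not just how much: a
prediction can be absent, slightly off, on the right body part of the
wrong animal, on the wrong body part, or nowhere near anything — and its
identity can silently change between frames. These failure modes have
very different downstream consequences (a 12-pixel localization error is
benign for behavior classification; an identity swap is not), so the
framework keeps them separate end to end.

## Identity pairing

Before keypoints can be scored, predicted identity labels must be put in
correspondence with GT labels. The cost of pairing predicted individual
$i$ with GT individual $j$ is the mean Euclidean distance over all
(frame, body part) cells where both are observed; the minimum-total-cost
one-to-one assignment is found with the Hungarian algorithm. Two design
choices deserve note:

* **Scene-global, not per-frame.** A single mapping is used for the whole
  scene. Re-pairing per frame would silently absorb exactly the identity
  switches the evaluation exists to expose.
* **Mean, not sum, over co-observed cells.** Summing would penalize pairs
  with more co-observed cells; the mean is invariant to how much of the
  scene the pair co-covers. Pairs with *no* co-observed cells get a cost
  one larger than any observed cost, so they are chosen only when forced.
  (How missing cells enter the pairing distance is not fixed by
  convention; this is the package's decision and it is stable under any
  relabeling of predicted individuals — a property the test suite checks.)

Ties are broken toward the smallest predicted index, then the smallest GT
index, by a lexicographic refinement pass over optimal assignments, so
results are fully deterministic. With unequal counts the smaller side is
fully assigned and surplus predicted individuals are simply never scored
as anyone's prediction.

## The verdict taxonomy

Every annotated GT cell (individual $j$, body part $b$, frame $f$)
receives exactly one verdict at threshold $\tau$ (default 10 px,
comparisons inclusive — "within $\tau$" means $d \le \tau$; the boundary
case has probability zero for continuous coordinates and is documented
rather than agonized over):

1. prediction missing → **FN**;
2. within $\tau$ of the *corresponding* GT keypoint → **MATCH**, even if
   another GT keypoint is nearer — correspondence takes priority;
3. otherwise, the nearest GT keypoint within $\tau$ decides:
   same body part → **ID-mismatch FP**; different body part →
   **bodypart-mismatch FP**; distance ties break by (identity index,
   body-part index);
4. within $\tau$ of nothing → **deviating FP**.

Because every cell gets exactly one verdict, Match + FN + FP counts equal
the GT count and the three FP subtypes sum to the FP count — both hold
*exactly*, and the suite asserts them on a thousand randomized scenes.
The implementation is vectorized per frame; an independent naive
nested-loop reimplementation in the test helpers re-derives every verdict
on randomized scenes and must agree cell for cell.

**Identity switches.** For each (GT individual, body part) series over
consecutive frames, a cell whose prediction landed on some GT keypoint
(MATCH or either non-deviating FP) is flagged when its matched identity
differs from the most recent earlier matched identity, skipping FN and
deviating frames in between — a switch that "hides" behind a dropout is
still caught when the track resurfaces on the wrong animal. The first
identified frame of a series is never a switch, and scenes with
non-consecutive frames refuse switch evaluation rather than producing
wrong counts.

**Denominators.** GT-based percentages (Tgt match, FN, FP, subtypes,
switches) divide by the annotated GT count; prediction-based percentages
(Pred match, Bodypart match) divide by the non-missing prediction count.
When FN = 0 the two match rates coincide. RMSE is taken over all
non-missing predictions whose corresponding GT is annotated — matches
*and* FP subtypes — using the distance to the corresponding GT keypoint;
a `rmse_matches_only` flag restricts it to matches, since conventions
differ on whether grossly wrong predictions belong in a localization
error. GT is assumed fully annotated (occluded parts annotated by
estimation); unannotated GT cells are excluded from both the GT count
and the RMSE set.

**Centroids.** The centroid variant condenses a whole animal to the mean
of its designated torso keypoints (a single available keypoint is itself
the centroid; none available is a centroid FN) and scores it against the
three mid-body-axis GT points at a larger threshold (default 20 px,
reflecting that a multi-keypoint average and a body-axis point are not
the same object). Body-part categories, switches and RMSE are undefined
for centroids and deliberately not reported.

## Virtual-marker accuracy

A virtual marker matches its animal's identity when it lies within 10 px
of *any* GT keypoint of the same animal — markers are identity cues, not
body-part estimates, so any on-body location counts. A missing marker
counts as a mismatch in the identity-matched rate (denominator
2 × animals × frames): a marker that should exist and does not is an
identity-information failure. The six-way per-animal-frame pattern
(Match/Partial/No-match × Two/One VM, Missing) is symmetric in the two
markers. The marker-to-animal correspondence is declared explicitly
(default: label order); it is identity information by construction, not
something to re-infer.

## Group metrics

* **Chain-spacing variance.** With keypoints annotated equidistantly
  along the body axis, the population variance of the $(n-1)$ adjacent
  distances is zero for perfect tracking; it needs at least three
  observed chain points and is missing otherwise.
* **Outlier frames.** The fence is Q3 + 1.5 IQR of a *pooled* reference
  (all compared conditions together), with type-7 linear-interpolation
  quantiles. Only the upper fence is used: small variance is good, only
  large variance signals failure. The quantile type is a package decision
  — "the IQR method" underdetermines it.
* **Headings and schooling.** The heading is the `atan2` angle of the
  vector from the second keypoint to the head. Image y points down, but
  every downstream quantity is a *difference* of angles, which is
  invariant to that flip, so no axis correction is applied — this avoids
  a whole class of silent convention bugs. Schooling synchrony is the
  mean of $\cos(\theta_i - \theta_j)$ over unordered pairs (equivalently
  a rescaling of the squared resultant length; the pairwise form is kept
  because its closed forms are easy to test: $n$ aligned fish give
  exactly 1, one reversed fish gives
  $(\binom{n-1}{2} - (n-1))/\binom{n}{2}$). Frame-to-frame heading
  changes are wrapped to [0°, 180°] before the >90° flip count, so
  350°→10° is a 20° change, not 340°.
* **Pose similarity.** Each individual-frame yields the matrix of all
  pairwise keypoint distances with the observed upper triangle z-scored
  to mean 0, SD 1. Standardization makes the matrix exactly invariant to
  rigid motion *and* uniform scaling, so dancers of different apparent
  size are comparable; the precise normalization is not a community
  standard, and z-scoring was chosen for that invariance. Degenerate
  poses (all distances equal, detected with a relative tolerance against
  floating-point ties) are an error, not a silent zero-division. The
  between-individual RMSD over co-present upper-triangle entries is a
  pseudometric; the per-frame mean over all pairs summarizes group
  similarity.
* **Stray-keypoint overlap.** The fraction of frames where two
  individuals' same-named keypoints sit strictly closer than 10 px,
  excluding frames with either missing. Strict `<` is used (the two
  plausible conventions differ only on a measure-zero boundary).

## The synthetic-data generator

The simulator is first-class, tested code: it produces the study
conditions every evaluation operation is validated under.

* **Geometry.** Each animal is a straight chain of `n_keypoints` at
  exactly `spacing` px, laid backward from the head along the current
  heading — so adjacent-distance variance is zero by construction, the
  property the fish metrics assume. Defaults mirror the canonical
  setups: 10 animals × 5 keypoints in a 1228 × 1030 arena (a fish
  school), with mouse-like scenes (3–5 animals × 6 keypoints, 150–300
  consecutive frames at 30 fps) used throughout the tests.
* **Motion.** Headings follow a wrapped-Gaussian random walk
  (`turn_sd` = 0.25 rad/frame) with Gaussian speed clipped at zero
  (4 ± 2 px/frame) and reflective boundaries at a full chain-length
  margin, which keeps every keypoint inside the arena. No published
  motion model is being imitated; the walk is the simplest process that
  yields plausible body-axis locomotion.
* **Feasibility.** The arena must exceed *twice* the chain length in each
  dimension: the head keeps a chain-length margin from every wall, and
  with less room no start position exists.
* **Error model.** Applied in a fixed order — jitter, body-part swaps,
  deviating displacements, FN deletions, identity-swap episodes — with a
  cell receiving at most one of {deviating, FN}, so the error log is an
  unambiguous per-cell ground truth. Deviating displacements are drawn at
  ≥ `displacement_min` in a uniform direction *and re-drawn until they
  clear the match threshold around every GT keypoint of the frame*;
  without that clearance a displaced point could alias onto another
  animal and the log would stop predicting the verdicts exactly.
  `displacement_min` must strictly exceed the threshold for the same
  reason. Trajectory and error seeds are independent, so one ground
  truth can be degraded many ways for paired designs.
* **What it does and does not emulate.** The generator reproduces the
  *phenomenology* of tracking errors (dropouts, displaced detections,
  part confusion, identity swaps) with known bookkeeping. It does not
  model occlusion geometry, appearance, social interaction, or the
  spatially correlated failures real networks produce. Passing tests
  therefore certify the *evaluation machinery* — that the metrics
  measure what they claim on known inputs — not any claim about how a
  particular tracker performs on real video.

Two closed forms anchor the calibration: with jitter-only degradation at
SD $\sigma$ per coordinate, the prediction–GT distance is Rayleigh, so
the match probability is $1 - \exp(-\tau^2/2\sigma^2)$ (0.8647 at
$\sigma = 5$, $\tau = 10$) and RMSE converges to $\sigma\sqrt{2}$
(7.071 px). The acceptance checks hold the observed rate inside a
3-sigma binomial band at ≥ 20,000 keypoints and RMSE within 2%.

## Numerical and interface choices

* Coordinates are image pixels, origin top-left, x right, y down; frames
  are 0-based in files and 1-based inside R (the CSV writer emits
  0-based indices). Missing keypoints are NaN/empty-cell both-or-neither;
  half-missing cells on read are demoted to missing with a warning.
* Time→frame conversion selects the frames whose timestamp
  $(\text{frame})/\text{fps}$ (0-based) lies inside $[t_0, t_1]$:
  first = ⌈$t_0$·fps⌉, last = ⌊$t_1$·fps⌋, so 3.33–6.66 s at 30 fps is
  0-based frames 100–199.
* Rendering rounds marker centers to integer pixels and draws without
  anti-aliasing, so tests can assert exact pixel values; palettes are
  explicit RGB lists (the viewers' "standard"/"gray"/"rainbow" palettes
  are approximations, since their exact RGB values are not published).
  Output goes to in-memory frames or lossless PNG sequences; lossy video
  codecs are out of scope.
* The CSV dialects are fully supported; HDF5 variants of the same tables
  are not read (no suitable reader among the package's dependencies),
  which matters only for workflows that never export CSV.
* Problem sizes in the tests and acceptance script (up to 10 animals ×
  6 keypoints × 400 frames, 1,000 random matrices/scenes per property)
  were chosen as the smallest sizes at which the binomial bands and
  exhaustive oracles are meaningful.

## Known limitations

* The taxonomy scores predictions only through the lens of annotated GT
  cells; extra detections with no annotated counterpart (e.g. a surplus
  predicted individual) are excluded rather than counted as a separate
  false-detection class.
* Scene-global pairing assumes one dominant identity correspondence per
  scene; a tracker that is wrong about identities for most of a scene
  will be paired by its majority behavior.
* The switch detector's carry-forward rule reaches back arbitrarily far
  across FN/deviating gaps; extremely fragmented tracks can attribute a
  switch to a long-past identity, which is the documented intent but can
  surprise on scenes with very low detection rates.
* `id_matched_vm_pct` deliberately counts absent markers against the
  rate; studies that want presence-conditional accuracy should read the
  pattern proportions instead.
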