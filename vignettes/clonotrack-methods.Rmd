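---
title: "ClonoTrack: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ClonoTrack: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ClonoTrack)
```

## The counting problem

A colony-forming assay imaged as a brightfield Z-stack shows every object
— single cell, cluster (2–14 cells) or colony (≥ 15 cells) — on several
focal planes at once, sharp near its own focal depth and increasingly
blurred away from it. Counting objects per slice therefore overcounts;
merging detections purely by (x, y) position undercounts, because
colonies at different depths can overlap laterally. ClonoTrack treats the
Z axis the way multi-object tracking treats time: per-slice detections
are associated into identity-preserving trajectories, and each 2.5D
object is counted once.

Two modelling commitments follow from the optics:

* **Hierarchical classes with a max rule.** Out-of-focus objects cannot
  be classified reliably, so they carry the class `candidate`. The class
  of a finished track is the *maximum* of its per-slice classes under
  `candidate < cell < cluster < colony`; a single sharp slice therefore
  determines the object's class. `classifyTrack()` implements exactly
  this rule. A track that is candidate on every slice stays `candidate`
  and is excluded from the biological counts (`countObjects()` reports it
  separately).
* **Cell-count partition.** The class partition must be total, so 1 cell
  = `cell`, 2–14 = `cluster`, 15 and above = `colony`. Common usage
  leaves the value 15 ambiguous ("2–14" clusters vs "more than 15"
  colonies); assigning 15 to `colony` closes the gap with the smaller of
  the two possible changes.

## Synthetic scenes: what they emulate, and what they do not

`sceneConfig()` / `sampleScene()` / `renderStack()` generate the study
conditions end to end. Defaults: 19 slices at 30 µm spacing (570 µm of
gel), 512×512 px at 1.5 µm/px, 5 cells + 3 clusters + 2 colonies per
field, single-cell radius 5 µm with object area proportional to cell
count (`radius = 5·sqrt(n)` µm, so blob area measures cell-equivalents),
depth of field ±20 µm, candidate visibility to ±90 µm, minimum
edge-to-edge separation 25 µm. Cluster sizes are drawn from 3–12 cells
and colony sizes from 18–60: within their class definitions but clear of
the 1/2 and 14/15 decision boundaries, where a pixel-level area estimate
legitimately cannot decide class membership.

Rendering uses a radial Gaussian edge profile: an object of in-focus
radius $r$ viewed at defocus $\Delta z$ is drawn as an intensity deficit
$A \,\Phi\!\big((r-d)/\sigma\big)$ at distance $d$ from its centre, with
edge softness $\sigma = \sigma_0 + k\,|\Delta z|$ (defaults
$\sigma_0 = 1$ µm, $k = 0.12$) and contrast attenuation
$A = A_0 \exp(-(\Delta z/z_c)^2)$. This is the closed-form profile of a
Gaussian-blurred disk edge, rendered directly instead of convolving an
explicit kernel; it is cheaper, exactly deterministic, and preserves the
property the pipeline relies on (edge sharpness decreasing monotonically
with defocus). Per-slice positional drift is a seeded random walk applied
identically to the rendered image and the ground-truth boxes. Additive
Gaussian noise comes last, from an independent seeded stream.

Ground-truth labels follow the annotation practice of such assays: the
true class within the depth of field, `candidate` between the depth of
field and the candidate depth, no box beyond. Ground-truth box half-width
is $r + \sigma(\Delta z)$ — the ~16% contrast contour — so boxes grow
with blur the way a human annotator's would.

What the generator does **not** emulate: point-spread-function physics,
phase-contrast halos, uneven illumination, debris, touching or merging
colonies, and annotation noise. Tests that pass on these scenes show that
the pipeline's logic is correct under its stated assumptions, not that a
classical detector matches a trained network on real microscopy; the
detector interface exists precisely so a stronger model can be swapped in.

## The classical reference detector

`detectSlice()` runs: background flattening (darkness = median −
intensity), Otsu (or fixed) thresholding, connected components of at
least `minArea` px², then a per-component refinement around the local
contrast peak $M$: the bounding box is the connected region above
$0.16\,M$ and the reported area is the pixel count above $0.5\,M$. For a
blurred disk the half-contrast level set sits at the original disk edge,
so this area is nearly blur-invariant — the key to classifying by size
across focal planes. The refinement window grows adaptively until the
$0.16\,M$ contour is fully contained; a truncated window was the one
observed failure mode (it inflates the focus score of dim, strongly
defocused blobs).

The focus score is the peak gradient magnitude of the 3×3-mean-smoothed
patch divided by its intensity range: 0 for flat patches, invariant to
intensity offsets, monotone decreasing in blur. For this profile the
score of an edge of softness $\sigma$ px has the closed form
$(\Phi(2/\sigma) + \Phi(1/\sigma) - 1)/3$ (`focusThresholdFor()`), which
converts the scene's blur model into a focus threshold.
`detectorConfigForScene()` places that threshold at the predicted
sharpness of an object defocused by $0.8 \times$ the depth of field. The
slack is deliberately below 1: measured areas inflate with blur, so near
the depth-of-field boundary a `candidate` label (which defers
classification to a sharper slice) is safer than a true-class label —
and with 30 µm slice spacing and a 20 µm depth of field, every object
has at least one slice within 15 µm of its focal plane where it scores
sharp. Detection confidence is the bounded product of the focus margin
$f/(f+\theta)$ and the size margin (distance of `area/cellArea` from the
nearest class boundary), clipped strictly below 1.

## Tracking along Z

`trackStack()` performs two-stage association per slice: detections with
confidence ≥ `highConf` (0.35) are matched to open tracks by exact
minimum-cost assignment on 1 − IoU, accepting pairs with IoU ≥
`matchIouHigh`; leftover tracks then see the low-confidence detections
(≥ `lowConf` = 0.05) at the stricter `matchIouLow` = 0.4. Unmatched
high-confidence detections open new tracks; a track missing for more
than `maxGap` = 3 slices is finished, and within the gap it can be
re-identified. There is no Kalman filter: the predicted box is the last
observed box, because drift along Z has no velocity structure — a motion
model can be added behind `associateDetections()` without touching the
interface.

`matchIouHigh` defaults to 0.15, more permissive than a temporal tracker
would use, for a geometric reason: a defocusing object's box grows by
roughly one blur sigma per slice, and two concentric boxes of half-widths
$h_1 < h_2$ have IoU $(h_1/h_2)^2$ — for a single cell stepping 30 µm
out of focus this ratio is ≈ 0.15–0.4. A tight gate fragments the
blurred tails of a trajectory into separate candidate tracks (harmless
for counting, but noisy in identity metrics); 0.15 absorbs the scale
change while remaining far stricter than chance overlap between objects
separated by 25 µm.

The assignment itself is a Jonker–Volgenant shortest-augmenting-path
solver written for this package (`solveAssignment()`), since no linear
assignment solver is available among the package's dependencies. It is
exact; the test suite checks it against exhaustive permutation search on
all instances up to 6×6. Determinism under permutation of input
detections is obtained by canonicalizing each slice's detections
(decreasing confidence, then position) before association.

## Evaluation metrics

* **IDF1/IDP/IDR** (`idMeasures()`): one global bipartite matching
  between whole ground-truth and predicted trajectories maximizing
  total frames matched at IoU ≥ 0.5; IDTP is that optimum. The suite
  verifies the optimum against brute-force enumeration of all pairings
  and against an independent Python implementation built on
  `scipy.optimize.linear_sum_assignment`.
* **Coverage and ID switches** (`clearMatching()`): CLEAR-style
  sequential per-slice matching that prefers the previous slice's
  assignment before re-matching the remainder optimally. Coverage uses
  the standard boundaries — ≥ 80% mostly tracked, ≤ 20% mostly lost —
  chosen because the verbal definitions ("more than 80%", "less than
  20%") leave the boundary values themselves open and these are the
  conventions of the established MOT toolchain.
* **AP50/mAP50** (`averagePrecision()`): confidence-ranked greedy
  matching, all-point interpolated precision–recall integration
  (the interpolation rule is not dictated by any source; all-point is the
  modern default), mAP as the unweighted mean over classes with
  ground-truth instances. The confusion matrix routes each detection to
  its best-IoU ground-truth box of any class, or background.
* **Summaries** (`summarizeScores()`): benchmark-style "Average" rows are
  arithmetic means of the per-dataset columns; tracked-share percentages
  are computed from the *averaged counts* (100·mean(MT)/mean(n)), which
  is the convention that reproduces published summary percentages,
  rather than averaging per-dataset percentages. Score columns are
  reported both unrounded and rounded (half-up, 3 decimals; percentages
  1 decimal), because printed tables round but downstream arithmetic
  should not. One known wrinkle: a mostly-lost share computed from
  averaged counts can differ by one final-digit unit from
  100 − MT% − PT%; both are derivable from the summary row, and the
  package emits the count-derived value.
* **Objective** (`trackingObjective()`): IDF1 × (MT+PT)/n, the joint
  detection-and-tracking objective; `tuneParameters()` is a seeded
  uniform random search over box constraints, returning the argmax and
  full history, with the backend deliberately pluggable.

## Dose-response analysis

Responses are clusters+colonies totals normalized to the mean of the
vehicle (DMSO) control (`normalizeToControl()`), so the control maps to
1.0 and the IC50 crossing level for the linear fallback is 0.5 on that
scale (both the scale and the level are explicit arguments, since
normalization to percent is equally common). The 4PL uses the
log10-concentration, base-10 Hill parameterization
$y = b + (t-b)/(1+10^{(\log IC_{50}-x)h})$ familiar from Prism-style
analyses; with this sign convention inhibition curves have $h < 0$ (the
curve falls with concentration), and the self-starting values pick the
sign of $h$ from the data's slope. Fitting is plain Levenberg–Marquardt
least squares on the residual function (no robustification — nothing in
the assay motivates outlier down-weighting); convergence is flagged, and
`selectAndFit()` falls back to ordinary least squares on
log10-concentration when fewer than 4 distinct concentrations are
available or the sigmoid fit fails. Parameters are unconstrained by
default; top/bottom constraints can be imposed through `init` if a
design warrants them.

Monte-Carlo behaviour at the reference design (5-point 1:5 dilution
series, triplicates, 5% response noise): the 2-fold recovery criterion is
met in ≈ 99–100 of 100 seeded replicates, with median
$|\Delta \log_{10} IC_{50}|$ ≈ 0.04.

## Growth simulation

`simulateGrowth()` evolves each object's cell count by per-cell Bernoulli
divisions in 1-hour steps with probability
$p = \text{baseRate}\,(1 - \text{inhibition}(c))$. The default base rate
$2^{1/12}-1$ gives a 12 h doubling time, under which one seeded cell is
expected to cross the 15-cell colony threshold around 60 h — the onset
timing typical of these cultures. No growth law is claimed beyond this
qualitative target; the model is the simplest seeded branching process
with the two required monotonicities (arrest at full inhibition,
stochastically fewer cells at higher inhibition).

## Quantification conventions

* Plating efficiency supports both denominators in use — cells seeded
  into the well, or single cells actually observed at the start
  timepoint — via `denominator_mode`; the default is `observed_start`,
  which is the quantity an automated per-ROI workflow can actually
  measure. The mode is carried in the output so the two are never
  silently conflated.
* SEM with a single replicate is reported as 0 with a
  `single_replicate` flag rather than NA, keeping downstream tables
  rectangular while making the degenerate case visible.
* Per-ROI counts can be aggregated by summation or averaging upstream of
  `platingEfficiency()`; the package computes per-ROI rows and leaves
  the aggregation explicit in user code.
* Stack height is `nSlices × spacing` (one spacing per slice), the
  convention used in the assay descriptions this package targets.

## Problem sizes and determinism

Every stochastic operation takes a seed and isolates its RNG state from
the caller. The test and reproduction workloads are sized for a desk
machine: end-to-end scenes of 10 objects on 512×512×19 stacks (~2 s
each), 10-stack perfect-input identity checks, 20–22 randomized metric
scenarios against two independent oracles, 100-replicate dose-response
recovery, and exhaustive assignment verification to 6×6. These sizes
were chosen to exercise every code path with comfortable margins rather
than to benchmark throughput.

## Known limitations

* The classical detector assumes dark, roughly isotropic blobs on a
  brighter background and a known cell-equivalent area; it is a
  reference implementation and an adapter target, not a competitor to a
  trained network on real images.
* Area-based classification near class boundaries (2 cells, 15 cells) is
  intrinsically uncertain at pixel resolution; the synthetic defaults
  avoid the boundaries, real data will not.
* Identity metrics assume one box per object per slice; instance masks
  and fragmented/merged detections beyond box overlap are out of scope.
* Lineage tracking across timepoints (which cell became which colony) is
  not attempted; timepoints are analysed as independent stacks.
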