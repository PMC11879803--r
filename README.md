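# ClonoTrack

Automated quantification of clonogenic colony-forming assays (CFA) from
brightfield Z-stacks, in R.

A CFA measures the ability of single cells — here, B-ALL leukemia cells
grown in a semi-solid 3D matrix — to expand into colonies. Imaging the
culture as a Z-stack (many focal planes through the gel) captures colonies
growing at different depths, but the same object then appears, blurred to
varying degrees, on several slices. ClonoTrack solves the resulting
counting problem with a detection-plus-tracking pipeline:

1. **Per-slice detection** — objects on each 2D slice are localized and
   classified into four hierarchical classes: `candidate` (out of focus,
   not yet classifiable) < `cell` (single cell) < `cluster` (2–14 cells)
   < `colony` (≥ 15 cells). A classical blob detector (background
   flattening, Otsu threshold, blur-invariant half-contrast area, focus
   scoring) is built in; any detector honouring the same
   image → detections contract (e.g. a neural network whose output is read
   from YOLO-style files) can substitute it.
2. **Z-axis multi-object tracking** — per-slice detections are merged into
   unique 2.5D objects by two-stage IoU association (high-confidence
   detections first, ByteTrack/BoT-SORT style) with an exact minimum-cost
   assignment per stage and gap tolerance along Z. Each track is
   classified by the *maximum* class observed along its trajectory, so one
   sharp slice suffices to classify an object that is blurred everywhere
   else.
3. **Assay read-outs** — unique-object counts per stack, replicate
   time series (mean ± SEM), plating efficiency
   `PE = 100 · colonies_end / cells_start`, survival fraction
   `SF = colonies_treated / (cells_seeded · PE)`, and IC50 estimation by a
   four-parameter logistic fit
   `y = bottom + (top − bottom) / (1 + 10^((logIC50 − x)·hill))` on
   x = log10 concentration (Levenberg–Marquardt, linear-regression
   fallback).
4. **Evaluation** — identity-based tracking metrics (IDF1/IDP/IDR via a
   globally optimal trajectory matching), mostly/partially-tracked and
   mostly-lost coverage, ID switches, per-class AP50/mAP50 with a
   confusion matrix, benchmark-table summaries, and a seeded random-search
   harness whose objective is IDF1 × (fraction of objects tracked).
5. **Synthetic data** — a fully seeded generator of 3D scenes, defocus
   -blurred Z-stack renders, ground-truth annotations (in-focus true class,
   out-of-focus `candidate`), stochastic clonal growth under drug
   inhibition, and dose-response tables, so the entire pipeline runs and
   is tested without any microscopy data.

## Worked example

```r
library(ClonoTrack)

cfg <- sceneConfig(seed = 7)          # 19 slices x 30 um; 5 cells, 3 clusters, 2 colonies
sc  <- sampleScene(cfg)               # ground-truth objects + annotations
stk <- renderStack(sc)                # defocus-blurred Z-stack (512 x 512 x 19)

det    <- detectStack(stk, detectorConfigForScene(cfg))
tracks <- trackStack(det, trackerConfig())
cnt    <- countObjects(classifyTracks(tracks),
                       well = "A1", roi = "1", timepoint = 96)
cnt
#>   well roi timepoint n_cells n_clusters n_colonies n_candidates
#> 1   A1   1        96       5          3          2            0

platingEfficiency(cnt$n_colonies,
                  cnt$n_cells + cnt$n_clusters + cnt$n_colonies)
#>   pe_percent colonies_end denominator denominator_mode
#> 1         20            2          10   observed_start
```

The counts equal the simulated census exactly: every object was merged
into one track and classified from its sharpest slice. A dose-response
fit on simulated assay data:

```r
tab <- simulateDoseResponse(list(top = 1, bottom = 0,
                                 logIC50 = log10(20), hill = -1),
                            concentrations = 500 / 5^(0:4),  # 1:5 series
                            nRep = 3, noiseSd = 0.05, seed = 7)
selectAndFit(tab)
#> DoseResponseFit [fourPL]
#>   top = 1.0798, bottom = 0.029937, logIC50 = 1.204, hill = -0.71089
#>   IC50 = 15.99 nM,  r^2 = 0.9794
```

The recovered IC50 (16 nM) sits within 2-fold of the simulated truth
(20 nM), the accuracy the package's acceptance suite requires in ≥ 95% of
replicates at this design (5-point 1:5 dilutions, triplicates, 5% noise).

A command-line wrapper is included for shell use:

```sh
Rscript inst/cli/clonotrack.R run-all --seed 7 --out results/demo
```

which chains simulate → detect → track → count → evaluate and writes
counts, MOT-format tracks, scores and a run log.

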