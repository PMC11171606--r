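---
title: "Density-map tumor cellularity estimation: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Density-map tumor cellularity estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(cellularity)
```

This vignette is the package's account of its science: what is modeled,
which knobs matter, what the synthetic data does and does not emulate,
and where design was genuinely open.

## The quantity of interest

The tumor content ratio of a region is `TCR = 100 * t / (t + n)` where
`t` and `n` count tumor and non-tumor cells; indistinguishable cells
(`i`) — crushed, necrotic, degenerated or otherwise unclassifiable — are
excluded from both numerator and denominator, exactly as pathologists
exclude them from visual estimates. `tcr()` refuses a zero denominator
rather than returning a conventional value: a region without countable
t/n cells has no TCR.

## Gold-standard aggregation

Three annotators independently mark every cell center. Two ingredients
turn this into one label set:

1. **Distance grouping** (`group_annotations()`): annotators are
   processed in a fixed order and their cells in row-major scan order.
   Each unconsumed cell seeds a group and pulls in the nearest
   unconsumed cell of each *other* annotator within 4 µm (pairwise from
   the seed, not a bound on group diameter); ties at exactly equal
   distance go to the lower scan index. Points farther than the radius
   stay separate. This greedy procedure is deterministic and consumes
   every cell exactly once. Order can matter only in dense, ambiguous
   configurations; on instances whose true cells are separated by more
   than twice the radius the grouping is provably order-independent,
   and a test verifies this. The synthetic generator's 3 µm minimum
   spacing keeps 4 µm matching mostly unambiguous by construction.
2. **Majority rule** (`aggregate_label()`): unanimous groups keep their
   label; 2-vs-1 majorities win; three mutually different labels give
   `i`; two-member disagreements give `i`; single-member groups are
   discarded (tallied, never entering TCR).

## The density-map model

A compact U-Net (`unet_init()`) maps an RGB patch to two same-size maps
— non-tumor and tumor — through `depth` encoder stages of two 3×3
convolution + batch-norm + ReLU layers with 2×2 max pooling, a
bottleneck, and mirrored decoder stages with nearest-neighbor upsampling
and skip concatenation, ending in a 1×1 convolution with two output
channels. Zero padding keeps the maps registered to the input, which is
what makes the downstream peak arithmetic trivial; the classic
crop-and-shrink U-Net variant would complicate coordinate bookkeeping
for no benefit at these patch sizes. Channel widths double per stage
from `base_ch`; the widths are deliberately configurable because the
appropriate capacity differs by orders of magnitude between a desk-scale
synthetic study and a clinical deployment.

Targets (`render_targets()`) are unit-amplitude isotropic Gaussians at
annotated cell centers, max-combined where peaks overlap so values stay
in [0, 1]; `i` cells are drawn in neither map, making them unannotated
background — the model is never asked to classify what the annotators
could not. Training minimizes the sigmoid binary cross-entropy averaged
over all pixels of both maps, optimized by Adam, with early stopping on
a validation loss that has not improved for `patience_epochs` epochs and
the best-validation checkpoint returned.

Parameters that matter:

* `target_sigma_px` (default 3 px ≈ 2 µm at the 0.6667 µm/px working
  resolution): must stay well below the 4 µm matching radius so a
  detected mode pixel cannot drift outside its cell's matching
  neighborhood. Larger sigmas merge neighboring peaks; smaller ones
  starve the loss of positive pixels.
* `patch_px` (default 300): the model's field of view. All
  convolutions are local, so the patch mainly controls how much context
  the classifier sees. Must be divisible by `2^depth`.
* `learning_rate` (default 1e-4) and `examples_per_epoch` (default
  4000): the documented full-scale protocol. The desk-scale preset
  (`desk_train_config()`: 64 px patches, base width 8, 240
  examples/epoch, lr 1e-3) trades capacity for single-CPU runtimes of
  about a minute per model; the wider learning rate compensates for the
  much smaller per-epoch budget.
* Gaussian peaks are truncated at 4 SD when rendered (error ≤ e^-8);
  `trunc_sigma = Inf` renders exactly.

## Detection and classification

The two maps are combined by a pointwise max; peaks are pixels strictly
greater than all eight neighbors (plateaus are not peaks — "higher
than" is read strictly, so constant regions yield nothing) with value at
least the detection threshold. The threshold is tuned by sequential
domain reduction (`tune_threshold()`): evaluate the pooled 4 µm matching
F1 on an 11-point grid over [0, 1], shrink the domain about the argmax
by 0.5, repeat for 3 rounds. The grid/round/shrink values are package
choices; the procedure is deterministic and a test checks it hits the
argmax of unimodal curves at final-grid resolution. Local maxima are
extracted once at threshold zero and filtered per candidate threshold,
which is arithmetic-identical to re-running the detector.

Each peak is classified by a softmax over the raw (normal, tumor) map
values at the peak pixel — no temperature, and exact ties break toward
non-tumor, a conservative and documented convention. Whole-ROI
prediction tiles the image with overlapping patches (overlap 50 px, or a
quarter patch when patches are smaller), averages the maps over
overlaps, and removes seam duplicates by 2 µm non-maximum suppression.

`tcr_ai()` implements the matched definition: detections classified
tumor *and* matched to gold tumor cells against detections classified
non-tumor *and* matched to gold non-tumor cells; predictions matched to
`i` cells are discarded for comparability with visual estimates. The
unmatched-inclusive deployment variant (`tcr_predictions()`) — all
detections, no gold needed — is provided separately and clearly flagged.

## Evaluation

Matching is a maximum-cardinality, minimum-total-distance assignment
among prediction–label pairs within 4 µm, solved exactly via a shortest
augmenting path LSAP solver on an augmented square cost matrix (dummy
rows/columns price being unmatched; out-of-radius pairs are forbidden).
Greedy matching was rejected because it can strand matchable points; an
exhaustive enumeration oracle guards all small cases in the tests.

The extended confusion matrix tallies matched pairs by label (n/t/i) ×
prediction (n/t) plus unmatched labels and predictions per class.
Indistinguishable cells *are* matchable and count on the label side of
detection F1 (they are real detectable cells even if unclassifiable);
`include_icells = FALSE` is available where a detection-only view of
classified cells is wanted. Sensitivity/specificity come in matched-only
and all-cells modes, and per-ROI averages are reported alongside pooled
counts because the two genuinely differ on heterogeneous cohorts.

## Cohort statistics

Per-ROI visual error is the mean over available evaluators of
|estimate − TCR_GS| (evaluators may be missing per ROI and are simply
skipped); the overall visual MAE is the mean over ROIs. The written-out
unnormalized per-ROI sum exists behind `per_roi_sum = TRUE`, but the
normalized form is the one consistent with per-evaluator site tables and
is the default. AI MAE is the mean over ROIs of |TCR_AI − TCR_GS|.

The paired signed-rank test uses Pratt's treatment of zero differences
(zeros rank, then drop from the statistic) — zero AI-vs-visual error
differences carry information and discarding them (the default
elsewhere) inflates significance on coarse 5%-gridded estimates. For up
to 25 non-zero pairs the p-value is computed from the exact conditional
distribution of the statistic given the observed (possibly tied) ranks,
by direct convolution; beyond that, a normal approximation with zero and
tie variance corrections and continuity correction. Kendall's tau-b and
its p-value are delegated to `stats::cor.test()`.

The site dependency index of an evaluator is the range (max − min) of
its per-site MAEs; site summary rows use the sample SD across
pathologists (the AI column is excluded from those summaries). The
published per-site grid reproduces its printed mean ± SD values under
the sample-SD convention, which settled that choice.

## The synthetic cohort

`generate_tile()` renders anti-aliased elliptical nuclei on a smooth
value-noise eosin background: tumor nuclei large (2.6–3.6 µm semi-major
axis), dark, elongated and clustered into nests; non-tumor nuclei small
(1.3–1.9 µm), round, lighter, dispersed; indistinguishable cells
intermediate in every respect so they are not trivially classifiable.
Centers keep a 3 µm minimum spacing by rejection sampling with an
explicit capacity error. Coordinates are microns from the tile's
top-left corner; pixel (r, c) is centered at ((c−0.5)·mpp, (r−0.5)·mpp).
Identical specs (including seed) are bit-identical.

Simulated annotators drop each cell with `miss_prob`, jitter positions
with an isotropic Gaussian, and corrupt labels to `i` or by t↔n flips;
defaults (0.5 µm jitter, 3% miss, 5% flip, 5% to-indistinguishable) are
in the range where majority aggregation recovers truth almost
everywhere, which is the regime exhaustive double-reading aims for.
Simulated visual estimates add evaluator bias (SD 6), per-site evaluator
bias (SD 6) and per-ROI noise (SD 11), then round to 5% increments —
chosen once to produce visual MAEs in the low teens, the magnitude
reported for real pathologists. Site profiles are deterministic
photometric shifts (H&E stain axes, RGB offset, gamma, brightness); the
stain basis is the standard hematoxylin/eosin optical-density matrix,
and "fraction of range" for stain shifts means a fraction of log10(256)
OD units.

What the generator does **not** emulate: nucleus texture and chromatin
patterns, overlapping/touching nuclei, tissue architecture (stroma,
glands, necrosis, keratinization), and staining heterogeneity within a
tile. Passing tests therefore demonstrate that the pipeline's machinery
— aggregation rules, loss, matching, statistics, domain-shift direction
— is correct, not that the model reaches any particular accuracy on
clinical slides.

## Desk-scale study design

The experiment harness and the in-repo checks run at deliberately small
problem sizes chosen once: 128×128 px tiles (≈85 µm, ~30–70 cells at
realistic density), 4 sites × 5 tiles for the leave-one-site-out
experiment, 64 px patches, base width 8, and 16 training epochs for the
experiment (training-loss diagnostics showed clear underfitting at 8).
The parameter-recovery check trains without augmentation — it measures
whether the detector recovers what the renderer drew — while the
robustness check compares augmented against plain training on
stain-shifted sites, where augmentation is the treatment under study.
Augmentation strengths, site-shift magnitudes and all seeds are fixed in
the code; nothing is adapted to individual runs.

## Numerical choices and degenerate inputs

* BCE uses the log-sum-exp stable form; gradients are exact and checked
  against numerical differentiation.
* Batch-norm uses batch statistics in training (momentum 0.1 running
  updates) and running statistics in evaluation, making evaluation
  deterministic for repeated inputs.
* Max-pooling ties resolve to the first candidate in scan order;
  softmax classification ties resolve to non-tumor; peak plateaus are
  discarded; LSAP penalties (10^5 per unmatched point) dominate any
  feasible total distance, enforcing cardinality-before-distance.
* Undefined quantities raise errors rather than returning sentinels:
  TCR with an empty denominator, sensitivity/specificity with empty
  margins, SDI with fewer than two sites. ROI-level averages exclude
  and report undefined ROIs.
* All randomness funnels through explicit integer seeds; derived seeds
  stay below 2^31.

## Known limitations

The renderer's two classes are separable by size and intensity almost
by construction, so classification accuracy on synthetic tiles
overstates clinical difficulty. The U-Net here is far smaller than a
clinical-scale model and the desk protocol trains on a handful of tiles;
the harness exists to exercise the protocol, not to produce deployable
weights. Greedy gold-standard grouping can depend on annotator order in
pathologically dense configurations. The signed-rank normal
approximation is used above 25 non-zero pairs; its continuity correction
is standard but approximate.
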