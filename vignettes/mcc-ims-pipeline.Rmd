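---
title: "From raw MCC-IMS measurements to disease classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From raw MCC-IMS measurements to disease classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imspeak)
```

## The problem

Multi-capillary column ion mobility spectrometry (MCC-IMS) resolves the
volatile organic compounds in a breath sample along two axes: retention
time in the capillary column (seconds) and inverse reduced mobility 1/K0 in
the drift tube (Vs/cm2). One measurement is therefore a dense 2D intensity
matrix, and a clinical study is a set of such matrices with case/control
labels. Getting from raw matrices to a disease classifier requires three
steps, each with several competing algorithms:

1. **Peak picking** — locate analyte signals within a single matrix;
2. **Peak clustering** — decide which peaks from different measurements are
   the same analyte, producing *consensus peaks* that act as features;
3. **Classification** — learn and evaluate a case/control rule on the
   resulting measurements x features intensity table.

imspeak implements this pipeline end to end, together with a benchmarking
layer (repeated stratified nested cross-validation, AUC, rank-sum
comparison across datasets) and a synthetic cohort generator with full
ground truth, so that every stage can be validated without access to
clinical data.

## Data model

An `ims_measurement` stores the intensity matrix with both axes in physical
units; all public coordinates in the package are physical (seconds,
Vs/cm2), never grid indices, because clustering across measurements with
different grids is only meaningful in physical coordinates. Peak lists,
consensus sets, feature matrices and CV results are tibbles, so the whole
pipeline composes with ordinary dplyr verbs; `tidy()`, `glance()` and
`autoplot()` methods cover the result objects. Zero-sized grids are
rejected everywhere: an empty spectrum has no meaning.

The on-disk format is deliberately minimal: a delimited grid with the 1/K0
axis in the header row, the retention-time axis in the first column, and
`#`-prefixed metadata lines. Files with descending axes or transposed
orientation are normalised on read.

## Preprocessing

**Noise model.** The background level of a matrix is estimated as
`median + k * MAD` (MAD scaled by 1.4826). Most cells in an MCC-IMS matrix
are background, so this robust pair is unaffected by the few analyte
peaks; `k = 3` by default, the conventional three-sigma rule.

**RIP compensation.** The reactant ion peak (RIP) is an intense artifact
band from the ionised carrier gas, constant in drift position across all
retention times. Because it spans entire columns, it dominates the
column-wise median intensity, while genuine analyte peaks — localised in
retention time — barely move a column median. `compensate_rip()` exploits
exactly this: a RIP is declared only when the largest column median exceeds
the typical (median) column median by a dominance factor (default 5), so
RIP-free matrices pass through untouched. The band is then the contiguous
run of columns around that maximum whose medians stay above a small
fraction (default 2%) of it. The low cutoff is important: the band has a
smooth cross-profile, and a higher cutoff leaves its flanks behind as
retention-invariant stripes at a substantial fraction of the RIP amplitude
— bright enough that every picker would report them as peaks. Within the
band, the column-wise 25th percentile (a robust per-column baseline across
retention time) is subtracted and clamped at zero, which removes the
retention-invariant artifact without erasing analyte peaks riding on it;
columns outside the band are untouched. The detected band is carried on
the measurement and masked from peak candidacy downstream, since the RIP is
an artifact, not an analyte. Applying the compensation twice changes
nothing beyond the noise spread (the dominance guard fails on the already
compensated matrix).

**Smoothing.** `smooth_savgol()` applies a Savitzky-Golay (local
polynomial least squares) kernel separably along both axes. The kernel is
computed from the design matrix of the local fit, so the filter is exactly
linear, preserves constants, and reproduces polynomial surfaces up to its
order on interior cells. Borders use nearest-edge replication — a
deliberate choice, because extrapolating polynomials at the border
introduces spurious curvature that the curvature-based picker would then
detect. Defaults: window 9 cells, order 2.

Whether the original instruments' software subtracted the RIP before or
after smoothing is not documented anywhere we could find; the pipeline
here runs RIP compensation first, then smoothing, and both stages are
independently callable so the order can be changed.

## Peak picking

All pickers return peaks whose positions lie on the measurement grid and
whose intensity is the (preprocessed) matrix value at that cell.

**Local maxima (LM).** A cell is a candidate when its intensity exceeds a
threshold *and strictly* exceeds all eight neighbours; exact-tie plateaus
produce no candidate (the strict reading avoids duplicate candidates on
flat tops). Candidates within 3 grid cells (Chebyshev) of each other are
then joined by the same weighted cluster-editing solver used for
cross-measurement clustering, and each clique is represented by its
highest-intensity cell. The default threshold is the matrix's noise level.

**SGLTR.** Curvature is measured as the negated Laplacian — minus the sum
of unmixed second derivatives along both axes — approximated by
Savitzky-Golay second-derivative filters (a peak apex has strongly negative
second derivatives, so the response is positive there; on a quadratic bowl
of unit curvature per axis the interior response is exactly 4 in cell
units). Peak regions are 8-connected components of cells whose curvature
response exceeds the response's own noise level *and* whose intensity
exceeds the intensity noise level; 8-connectivity keeps diagonal ridges
connected. Regions smaller than `min_region` cells (default 2) are
discarded: an isolated single-cell exceedance is a noise blip, not a
credible 2D peak. Each region yields a peak at its maximum-intensity cell
with the region bounding box.

**PDSA.** Spectra are processed row by row, as an online device would see
them. Sliding windows (default 5 cells) are scored by their intensity sum;
a window is kept as a segment when its score is a strict local maximum
over one-cell shifts and exceeds `window x noise level`, and among
overlapping segments in a row only the best scorer survives. Segments in
adjacent rows are chained when their drift intervals overlap by at least
half a window (the published merging criteria are in software we do not
have; the overlap rule is this package's documented stand-in, and the
fraction is configurable). Each chain gives one peak at its
maximum-intensity cell.

On noise-free synthetic data the estimated noise level degenerates to
zero; the pickers accept an explicit `floor` for that situation rather
than silently treating the whole matrix as signal.

## Peak clustering

Distances between peaks from different measurements are measured in a
normalised coordinate system (`peak_scaling()`): 1/K0 differences divided
by `tol_ik0` (default 0.003 Vs/cm2) and retention-time differences by
`tol_rt_abs + tol_rt_rel * mean rt` (defaults 3 s and 1%), the relative
term reflecting that retention-time spread grows along the column. A
normalised distance of 1 means "one tolerance ellipse apart". These
tolerances are study-dependent and deliberately configurable everywhere.

**Grid squares (GS)** partitions the plane into rectangles (anchored at
the minimum observed position, so binning is reproducible); every
rectangle with at least `min_count` peaks becomes a consensus peak at the
average member position.

**DBSCAN** is implemented from the density-reachability definition, with
one determinism refinement: peaks are processed in sorted order
(measurement id, rt, 1/K0), so border points reachable from several
clusters always join the earliest-formed one. The test suite verifies the
partition against a literal brute-force closure implementation on random
instances.

**Cluster editing (CE)** gives each peak pair the weight
`sim_threshold - distance` and partitions the peaks into cliques at
minimum total absolute weight of deleted positive and inserted negative
edges. Connected components of the positive graph are solved
independently (an optimal solution never joins elements of different
components). Components up to `exact_limit = 12` peaks are solved exactly
by branch-and-bound over set partitions, seeded with a greedy solution for
pruning; larger components fall back to the greedy heuristic (iteratively
merge the pair of cliques with the largest positive inter-clique weight).
Twelve is the limit where exhaustive verification is still desk-tractable
(Bell(12) is about 4.2 million partitions).

**EM with merging** models peak positions as a mixture of axis-aligned
Gaussians with *known, fixed* standard deviations per axis — the
generative picture being that each analyte's peaks jitter around a true
position with instrument-specific spread. Only means and mixture weights
are updated. Components are seeded deterministically from a coarse
grid-squares pass (cell size twice the sigma per dimension, `min_count`
1), which makes the fit independent of peak order; the number of clusters
is then found by the merging step inside each iteration: components whose
sigma-normalised mean separation falls below `merge_dist` are merged
(weights summed, means weight-averaged). The default `merge_dist = 4`
reflects an identifiability argument: components closer than a few sigma
cannot be told apart given the assumed jitter (a single Gaussian cloud
happily supports two stable components ~2 sigma apart, and lone fringe
points hold small components ~3 sigma out), while distinct analytes in
practice sit tens of sigma apart. The log-likelihood is non-decreasing
between merges (each merge itself may drop it); the iteration stops when
no merge occurred and the log-likelihood change falls below `tol`.

## Features

The intensity of consensus peak *j* in measurement *i* is taken from the
peak of measurement *i* closest to the consensus position, provided the
normalised distance is at most `assign_radius` (default 1, the tolerance
ellipse). Entries with no peak in range are 0: the absence of a detected
signal is physically a zero analyte response, and a zero also keeps the
matrix complete for classifiers that cannot handle missingness.

## Evaluation

**Cross-validation.** `run_cv()` repeats a stratified 10-fold CV 50 times
by default. Stratification keeps per-fold class proportions within one
sample of exact proportionality, with leftover samples dealt to the
currently smallest folds so overall fold sizes also differ by at most one.
Classifiers with a tuning grid get a nested inner stratified 10-fold CV on
each outer training set; the grid point with the best mean inner AUC is
refitted on the full outer training set. Out-of-fold case scores are
pooled across the 10 outer folds into **one AUC per repetition** — with
only 3-4 positives in a fold, per-fold AUCs are too unstable to average,
while the pooled estimate uses every sample exactly once. An optional
`row_hook` records which rows each fold's tuning/training touched, so
leakage of outer test rows into tuning is checkable mechanically (and is
checked in the test suite).

**Classifiers.** Six standard algorithms: linear and radial SVM (e1071),
k-nearest-neighbours (class), a classification tree (rpart), gradient
boosted trees (xgboost; binomial deviance, 50% subsampling per tree), and
a random forest (randomForest; 500 trees, `floor(sqrt(p))` candidate
variables per split, no tuning). Tuning grids are conventional ranges
(SVM cost 0.1-100, RBF gamma scaled by 1/p, k in 1-15, tree complexity
0.001-0.1, boosting trees/depth/shrinkage) and fully configurable.

**AUC** is computed in its Mann-Whitney form with midranks, so ties count
one half and the value is invariant under monotone transforms of the
scores.

**Rank sums.** To compare pipelines across several datasets, per-dataset
median AUCs are converted to ranks (competition ranking: tied values share
the minimum rank, the next distinct value skips — the convention that
matches published rank tables of this kind) and summed; lower is better.
`mean_rank_sum()` normalises a combination's ranks across the six
classifiers by the best achievable sum, giving 1 when one clustering
method wins under every classifier.

**Design enumeration.** The benchmark's method registry declares six
pickers, five combinable clusterers, the combined manual VisualNow
procedure, and six classifiers, with two feasibility rules (VisualNow's
automated clustering only accepts its own picker's output; the manual
procedure cannot be mixed with automated steps). `enumerate_design()`
derives the 26 picker x clusterer combinations (25 automated) and 156
pipelines (150 automated) from those rules. Methods whose models live in
other publications or in commercial software (PME, OPME, both VisualNow
entries) are declared but not implemented; asking for them produces a
clear error rather than a silent substitute.

## The synthetic cohort generator

`generate_cohort()` emulates a two-class breath study: a shared set of
true analyte positions, drawn uniformly over the usable plane with a
minimum pairwise separation (default 8 normalised units, so distinct
analytes are resolvable by construction); per-measurement realisations
with Gaussian positional jitter (defaults 0.001 Vs/cm2, 1 s), dropout
(default 10%), and lognormal amplitudes (median about 20x the noise sd);
differential peaks whose amplitude is multiplied by `effect_size` (default
2) in cases; a RIP band (centred at 12% of the 1/K0 axis, near the
low-mobility end where it physically occurs) with a Gaussian cross-profile;
optional exponential retention-time tailing of the peak shape; and
additive Gaussian noise clamped at zero. The default grid is 600 x 400
cells over 0-300 s and 0.4-1.0 Vs/cm2, and default group sizes are 30+30 —
desk-scale approximations of routine clinical MCC-IMS geometry, with
per-measurement peak counts (20-25 after dropout) inside the 10-60 range
typical of such studies. Everything is a deterministic function of the
spec's seed.

What the generator does *not* emulate: real ion chemistry (competitive
ionisation, humidity and temperature effects), intensity drift between
sessions, correlated noise, or peaks overlapping closer than the grid can
resolve (it warns when asked for those). Passing tests on synthetic
cohorts therefore demonstrates algorithmic correctness under the stated
model, not instrument-level fidelity.

`truth_match()` scores detections against ground truth by greedy
one-to-one matching in ascending distance; an empty detection set reports
precision 1 with an explicit `zero_support` flag rather than 0/0.

## Numerical and degenerate-input choices

- Savitzky-Golay windows must be odd and larger than the polynomial order;
  violations are errors, not silent adjustments.
- `estimate_noise()` on a constant matrix returns spread 0; pickers
  running on noise-free data should pass an explicit `floor`.
- DBSCAN neighbourhoods include the point itself when counting `min_pts`.
- CE branch-and-bound prunes on the running cost against the greedy
  incumbent; equal-cost optima may differ from the enumeration oracle as
  partitions, but never in cost.
- EM drops components that end up with no assigned peak; non-convergence
  at `max_iter` warns and returns the current state.
- Feature ids are position-sorted (`F001`, `F002`, ...) so output is
  stable across runs and peak orderings.
- All stochastic stages (fold assignment, the generator, repetition seeds
  `base_seed + r`) derive from explicit seeds; re-runs are bit-identical.

## Validation strategy and problem sizes

The test suite validates each stage against an independent oracle:
analytic polynomial surfaces for the filters, brute-force
density-reachability for DBSCAN (instances up to 20 peaks), full
set-partition enumeration for cluster editing (8-peak instances, Bell(8) =
4140 partitions), parameter recovery for EM (100 two-cloud instances of 30
points each), exact recall/precision for all three pickers on noise-free
well-separated synthetic measurements, separable and permutation-null
cohorts for the CV machinery (the null draws a fresh label permutation per
repetition, so its median concentrates at chance level), and an
end-to-end run of the best automated pipeline (SGLTR picking, DBSCAN
clustering, random forest) on the default 30+30 cohort with 10 CV
repetitions. These sizes were chosen as the smallest instances that still
discriminate a correct implementation from a subtly wrong one.
`scripts/acceptance.R` recomputes the same quantities from scratch for any
seed.

## Known limitations

- The peak-shape model is axis-aligned Gaussian (optionally rt-tailed);
  real IMS peaks can be skewed in drift too.
- PDSA's cross-row merging rule is a documented stand-in for criteria
  published elsewhere.
- No intensity normalisation across measurements is applied; if an
  instrument drifts between sessions, that has to be handled upstream.
- The cluster-editing heuristic for components above `exact_limit` has no
  optimality guarantee (the exact solver covers the sizes where
  verification is feasible).
- With DBSCAN's permissive defaults (`min_pts = 3` across 60
  measurements), sporadic noise detections can form extra low-support
  consensus features; they carry little class signal and the random forest
  tolerates them, but stricter `min_pts` or a support filter is advisable
  when a compact feature set matters.
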