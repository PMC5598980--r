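# imspeak

Automated analysis of multi-capillary column ion mobility spectrometry
(MCC-IMS) breath measurements: from raw 2D intensity matrices to a
cross-validated disease classifier, with every intermediate step exposed,
tested, and benchmarkable.

Breath volatilomics screens for disease by measuring volatile organic
compounds in exhaled air. An MCC-IMS measurement is a dense matrix of
signal intensities over retention time (s) and inverse reduced mobility
1/K0 (Vs/cm2). Turning a cohort of such matrices into a classifier takes
three steps, each with competing algorithms:

1. **Peak picking** on single measurements — implemented: local maxima
   (LM), the Savitzky-Golay Laplace-operator filter thresholding-regions
   method (SGLTR), and peak detection by slope analysis (PDSA);
2. **Peak clustering** across measurements into *consensus peaks* —
   implemented: grid squares (GS), DBSCAN, weighted cluster editing (CE,
   exact by branch-and-bound up to 12-peak components), and a
   fixed-variance EM mixture with component merging;
3. **Classification** of the measurements x consensus-peaks feature matrix
   — six classifiers (linear/RBF SVM, kNN, classification tree, gradient
   boosting, random forest) under repeated stratified 10-fold
   cross-validation with nested hyperparameter tuning, scored by the
   Mann-Whitney AUC, and compared across datasets by rank sums.

The AUC is the probability that a random case scores above a random
control: `AUC = (#concordant pairs + 0.5 #ties) / (n_case * n_control)`.
Pipelines are ranked per dataset by median AUC over 50 CV repetitions and
compared by the sum of their ranks across datasets.

A synthetic cohort generator (`generate_cohort()`) emulates two-class
studies — jittered Gaussian peaks, dropout, lognormal intensities,
class-differential effects, a reactant-ion-peak (RIP) artifact band, and
detector noise — with complete ground truth, so the full pipeline is
testable without clinical data. A method registry also declares the
non-redistributable methods of the original benchmark (PME, OPME,
VisualNow automated/manual), so the design space enumerates to its full
26 picker x clusterer combinations and 156 pipelines (150 fully
automated).

## Worked example

```r
library(imspeak)

spec <- cohort_spec(n_case = 15, n_control = 15,
                    grid = list(n_rt = 300, n_ik0 = 200,
                                rt_range = c(0, 300), ik0_range = c(0.4, 1.0)),
                    n_shared_peaks = 12, n_diff_peaks = 3, seed = 42)
cohort <- generate_cohort(spec)
cohort
#> <ims_cohort> 15 case + 15 control measurements, 15 true peaks (3 differential)
#>   grid 300 rt x 200 ik0

peaks <- pick_peaks(cohort$measurements, method = "sgltr")   # RIP-compensate, smooth, pick
clusters <- cluster_dbscan(peaks)
clusters
#> <ims_clusters> dbscan: 29 consensus peaks from 849 peaks (442 noise)

truth_match(clusters, cohort)      # consensus vs planted ground truth
#>   recall precision  rmse n_matched n_truth n_detected zero_support
#> 1      1     0.517 0.274        15      15         29 FALSE

fm <- build_feature_matrix(clusters, peaks, cohort$labels)
cv <- run_cv(fm, classifier_spec("rf"), cv_plan(repetitions = 10, seed = 1))
glance(cv)
#>   classifier k_folds repetitions median_auc iqr_auc
#> 1 rf              10          10      0.924  0.0144
```

Reading the numbers: all 15 planted analytes are recovered as consensus
peaks (recall 1) with mean position error about a quarter of the
tolerance ellipse; DBSCAN's permissive defaults additionally admit 14
low-support noise clusters (precision 0.52), which carry no class signal.
The random forest on the resulting feature table separates cases from
controls with a median AUC of 0.92 across ten repeated 10-fold CVs —
driven by the three planted differential peaks (twofold intensity change).

`autoplot()` works on measurements (heatmaps), cluster results and CV
results; `tidy()`/`glance()` return tibbles. A thin command-line
front-end wraps the same functions:

```sh
Rscript inst/cli/imspeak.R simulate --spec spec.yaml -o cohort/
Rscript inst/cli/imspeak.R pick --method sgltr cohort/M*.csv -o peaks.csv
Rscript inst/cli/imspeak.R cluster --method dbscan peaks.csv -o consensus.csv
Rscript inst/cli/imspeak.R featurize consensus.csv peaks.csv --labels cohort/labels.csv -o features.csv
Rscript inst/cli/imspeak.R evaluate features.csv --clf rf --reps 50 --seed 17 -o cv.json
```

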