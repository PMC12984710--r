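# octits

Iterative teacher-student (ITS) semi-supervised learning for three-class
retinal OCT B-scan classification — **normal / drusen / CNV** — with the full
experimental harness such a study needs, and a synthetic OCT-phantom cohort
generator so everything runs at desk scale with no external data.

## Who this is for

Researchers studying **label-scarce medical image classification**: how fast
does a supervised model degrade as the labeled fraction of a training archive
shrinks to 70 / 50 / 20 / 5%, and how much of that loss can confidence-filtered
self-training recover? The package gives you the complete, leakage-audited
pipeline: cohort structure, patient-wise splits, training protocol,
pseudo-labeling loop, and multiclass evaluation.

## The method

Self-training with a confidence-based reliability check, iterated:

1. Train a **teacher** on the labeled pool (class-weighted cross-entropy,
   Adam, LR-reduction-on-plateau, early stopping, best-epoch checkpoint).
2. Predict class probabilities `p(c | x)` for every unlabeled image. Each
   prediction becomes a **pseudo-label** `argmax_c p(c | x)` with
   **confidence** `max_c p(c | x)`.
3. Keep pseudo-labels with confidence `>= τ` (the sweep grid is
   τ ∈ {0, 0.90, 0.95, 0.99}; `>=` makes τ = 0 "accept all").
4. Train a fresh **student** on labeled ∪ accepted pseudo-labeled images,
   class weights `w_c = N/(3 N_c)` recomputed on the union.
5. Promote the student to teacher and repeat, re-predicting the whole
   unlabeled pool each iteration; report the iteration with the best
   *validation* accuracy.

Splits are **patient-wise** (all images of a patient in one partition), the
test set is constant across every experiment of a replicate, and labeled
subsets are selected by whole volumes, stratified by class and *nested*
across fractions (5% ⊂ 20% ⊂ 50% ⊂ 70%).

## Worked example

A 150-patient phantom cohort with 20% of training volumes labeled, then three
teacher→student iterations at confidence threshold 0.95 (a few minutes on one
CPU):

```r
library(octits)

cohort <- generate_cohort(phantom_spec(n_patients = 150, seed = 7))
cohort
#> <oct_cohort> 5392 B-scans, 150 patients, 180 volumes
#> normal drusen    cnv
#>   2915   1583    894

split <- patient_wise_split(cohort, fractions = c(0.64, 0.17, 0.19), seed = 7)
split <- subset_labels(split, cohort, labeled_fraction = 0.2, seed = 7)
split
#> <cohort_split> train 3442 (labeled 693 / unlabeled 2749), val 912, test 1038

tcfg <- train_config(max_epochs = 25, early_stop_patience = 6,
                     lr_reduce_patience = 3, seed = 7)
res <- run_its(cohort, split, tcfg,
               its_config(confidence_threshold = 0.95, max_iterations = 3))
res
#> <its_result> 3 iteration(s), best 2
#>   iteration n_accepted n_rejected purity val_accuracy test_accuracy
#>       <int>      <int>      <int>  <dbl>        <dbl>         <dbl>
#> 1         1        295       2454  0.759        0.754         0.828
#> 2         2        856       1893  0.738        0.757         0.822
#> 3         3        968       1781  0.753        0.696         0.782
#> supervised baseline: val 0.7555 test 0.8314
```

Reading this: the teacher accepted 295 of 2749 unlabeled images at τ = 0.95 in
iteration 1 (purity: 76% of accepted pseudo-labels match the hidden truth —
measurable because phantoms carry ground truth), grew that to 856 in iteration
2, and validation accuracy declined at iteration 3 so iteration 2 is reported.
In this single replicate the ITS result happens to sit just below the
supervised baseline on the *test* set — individual seeds vary in both
directions; the package's sweep machinery exists precisely to average such
replicates (see below). Across seeds the mean gain is modest at the 20%
fraction and largest and most consistent in the scarcest (5%) regime.

Evaluation of the selected model:

```r
ev <- evaluate_model(res$model, cohort_images(cohort, split$test_ids),
                     cohort_labels(cohort, split$test_ids))
ev$confusion
#>         predicted
#> truth    normal drusen cnv
#>   normal    491     83   0
#>   drusen     69    132   0
#>   cnv        15     18 230
ev$metrics
#> <metrics_report> accuracy 0.8218 | macro P 0.8068 R 0.7955 F1 0.7987
ev$roc
#> <roc_result> per-class AUC: normal 0.9076, drusen 0.8810, cnv 0.9913 | micro 0.9401 | macro 0.9271
```

Drusen is the hardest class — its subtle band deformations overlap with
normal variation — exactly the error structure one expects clinically.

Full sweeps (label fractions × thresholds × modes × seeds) run through
`experiment_plan()` / `run_plan()` / `summarize_sweep()`.

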