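---
title: "Iterative teacher-student self-training for OCT classification: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Iterative teacher-student self-training for OCT classification: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem and the method

Labeled retinal OCT archives are expensive to build: a grader must review an
entire scan volume before any of its B-scans can carry a diagnosis. Unlabeled
scans, by contrast, accumulate for free during routine screening. `octits`
implements the standard remedy in its simplest robust form, confidence-filtered
self-training, for the three-class problem *normal / drusen / CNV*:

1. Train a **teacher** classifier on the labeled pool with class-weighted
   categorical cross-entropy.
2. Predict class probabilities for every unlabeled image. The **confidence**
   of a prediction is its maximum softmax probability; the **pseudo-label** is
   the argmax.
3. A **reliability check** keeps only pseudo-labels with confidence at or
   above a threshold $\tau$ (acceptance uses $\ge$, so $\tau = 0$ accepts the
   whole pool).
4. Train a fresh **student** on the union of the labeled pool (true labels)
   and the accepted pseudo-labeled images (hard labels, full sample weight by
   default), with class weights recomputed on the union.
5. **Iterate**: the student becomes the next teacher, the *entire* unlabeled
   pool is re-predicted, and the accepted set is rebuilt from scratch.

The threshold trades pseudo-label quantity against quality: low $\tau$ floods
the student with data but also with label noise; high $\tau$ keeps the labels
clean but few. The sweep grid used throughout (0, 0.90, 0.95, 0.99) brackets
this trade-off.

Several points were genuinely open and are fixed here as package design
choices:

* **Confidence definition.** Maximum softmax probability — the conventional
  reading of a "classification score". No calibration is applied.
* **Acceptance uses $\ge$, not $>$.** This makes $\tau = 0$ mean "accept
  everything", which the 0% point of the sweep grid requires.
* **Hard pseudo-labels.** Accepted images enter the student set as
  categorical labels, not soft distributions, because they are appended to
  the labeled dataset on equal footing.
* **Re-prediction, not accumulation.** Pseudo-labels are never sticky; every
  iteration routes the full unlabeled pool through the newest teacher. This
  avoids freezing an early teacher's mistakes into the training set.
* **Fresh students.** Each student is initialized from scratch
  (`clone_untrained()`), not warm-started from the teacher, limiting
  confirmation-bias accumulation.
* **Stopping.** At most `max_iterations` (default 4) promotions, with an
  optional early stop when validation accuracy drops below the previous
  iteration's; excessive pseudo-labeling shows diminishing returns and can
  overfit. The reported model is the iteration with the best *validation*
  (never test) accuracy.

## Experimental-design layer

**Patient-wise splits.** All images of a patient land in exactly one of
train/validation/test, so near-duplicate B-scans of one eye can never straddle
the evaluation boundary. Patients are shuffled by seed, ordered largest image
count first, and greedily assigned to the split with the largest remaining
image-count deficit; realized fractions land within a few percent of the
targets (the default 0.64/0.17/0.19 mirrors a typical archive's split). The
assignment is a pure function of (cohort, fractions, seed), so the test set
stays constant across every experiment of a replicate.

**Label-fraction subsetting.** The labeled/unlabeled partition of the
training split operates on whole volumes — a clinician labels a volume, not a
slice — and is driven by one seeded per-class volume permutation interleaved
across classes. Consequences: the labeled class mix tracks the training mix,
and for a fixed seed the subsets are *nested* (5% ⊂ 20% ⊂ 50% ⊂ 70%), making
the label-fraction sweep monotone in information. Nesting is a package
decision, not a property inherited from any external protocol. If a fraction
is so small that a class loses all labeled volumes, a note is recorded in the
split's provenance and that class receives weight 0 — the run proceeds, as it
must for a 5% sweep on a small cohort.

**Class imbalance** is handled by loss weighting, $w_c = N/(3 N_c)$, rather
than oversampling: weighting composes cleanly with pseudo-labels (weights are
simply recomputed on the union each iteration).

## Training protocol

Any backbone registered by name can be trained under the same protocol
(`train_config()`): minibatch Adam (initial learning rate 0.001, batch 64),
weighted categorical cross-entropy, learning rate reduced by a factor of 0.1
after 10 epochs without validation-loss improvement, early stopping after 15
such epochs, up to 100 epochs, and restoration of the best-validation-loss
checkpoint. An "improvement" means a validation-loss decrease of at least
`min_delta` (default 1e-4); the checkpoint itself uses strict improvement, so
the returned model always attains the minimum recorded validation loss.
Fitting is a pure function of (data, config): initialization, shuffling and
augmentation draw from one seeded stream.

**Reference backbone.** The reference classifier is a deliberately small
model: images are bilinearly downsampled to 24×24, standardized per image,
flattened, and passed through one hidden layer of 64 ReLU units into a 3-way
softmax (~37k parameters). This is not a state-of-the-art OCT classifier and
is not meant to be one; it is the smallest model that learns the phantom task
well (≥85% test accuracy on a fully labeled 150-patient cohort within 25
epochs on one CPU) while leaving the label-scarcity regime visible. The
backbone contract (`fit` / `predict_proba` / `clone_untrained`) is the
integration point for heavier architectures; a linear-softmax backbone is
registered as a second instance, and a convolutional network with pretrained
weights would slot in the same way where such a runtime is available.

**Augmentation.** `augment_config()` applies, in fixed order, random crop
(scale 0.85–1.0, resized back), horizontal flip (p = 0.5), rotation (±15°),
and affine translation (±10%) + shear (±10°), with bilinear resampling on a
reflection-padded canvas so no dark corners leak augmentation state into the
features. Magnitude defaults are package choices, set small enough to
preserve the band/lesion anatomy that defines the classes. Augmentation is
applied to training inputs only — never validation or test — and the training
history records which ids were augmented so the audit is assertable. The
phantom experiments below run without augmentation: the generator's own
nuisance variation already supplies the diversity augmentation would add, and
this keeps each of the several dozen training runs in the sweeps to seconds.

## The phantom generator

`generate_cohort()` emulates the *structure* of a clinical OCT archive so
every pipeline stage is testable without external data:

* hierarchy: patients → volumes (25% of patients contribute a second,
  independently labelled volume — both eyes scanned) → ~30 B-scans per
  volume, with the class label assigned at volume level and inherited by
  B-scans;
* class mix at volume level: 0.51 / 0.30 / 0.19 for normal / drusen / CNV;
* images: three bright horizontal bands (stylized retinal layers) on a dark
  background; *drusen* deforms the lowest band with 1–5 small upward domes;
  *CNV* adds one large bright blob beneath a locally attenuated, sagging
  band; additive Gaussian noise (default sd 0.05 on a [0,1] scale);
* nuisance structure: band pose, width and brightness vary per scan, and
  bright non-diagnostic spots appear *above* the band stack in every class,
  so a classifier must localize pathology relative to the bands rather than
  track overall brightness;
* within-volume correlation: B-scans of one volume share a latent geometry
  draw with per-scan jitter, as adjacent slices of a real volume do. The
  effective sample size is therefore closer to the number of volumes than
  the number of images — this is what makes the 5% regime genuinely hard and
  patient-wise splitting a real constraint.

Class structure is recoverable without learning: a two-feature hand-written
statistic (ridge-deviation energy of the lowest band; mean intensity in a
window beneath it) classifies phantoms with ≈99% accuracy at noise 0.05
(`classify_by_statistics()`). What the phantom does **not** model: OCT
speckle statistics, curvature and layer segmentation, device variation,
grader noise. Passing results here demonstrate the *pipeline logic* —
leakage-free splitting, filter behavior, trend directions — not clinical
performance.

## Problem sizes and numerical choices

The packaged experiments and tests run at desk scale, chosen as the smallest
sizes at which the studied effects are clearly visible: 150-patient cohorts
(~5,500 B-scans of 32×32 px), five seed replicates, 25-epoch training with
early-stop patience 6 and LR patience 3, and up to 3 ITS iterations. Under
these conditions the supervised learning curve spans roughly 94% (full
labels) down to 45% (5% labels), and ITS at threshold 0.95 recovers accuracy
at the 20% and 5% fractions, with the largest and most consistent paired
gains in the scarcest regime (the 20% gain is smaller and varies in sign
across individual seeds) — the qualitative pattern the method is designed to
produce. Degenerate inputs are handled explicitly: constant images normalize
to zeros (with a warning), zero-count classes get weight 0 and metric 0 (with
warnings), an empty unlabeled pool degrades ITS to a single supervised run,
and probability ties break in the fixed class order normal < drusen < CNV.

ROC analysis groups tied scores into single operating points, which makes
each one-vs-rest AUC exactly the pairwise Mann–Whitney probability; the
macro-average ROC is computed exactly on the union of all per-class
false-positive-rate breakpoints (no interpolation grid). Because the single
precision/recall/F1 summary of a 3-class problem depends on the averaging
convention, reports carry *both* macro and support-weighted averages, with
macro as the default in summaries.

## Known limitations

* The reference backbone sees 24×24 downsamples; phantom pathology is
  rendered large enough to survive this, real pathology often would not.
* Self-training inherits teacher bias: when the teacher is near chance (deep
  5% regime on an unlucky seed), accepted pseudo-labels can be impure and an
  iteration can hurt — visible in per-seed sweep rows, and the reason the
  loop selects its reported iteration on validation accuracy.
* Purity is measurable only in phantom mode, where hidden truth exists; on
  real data the same column is `NA`.
* No consistency regularization, EMA teachers, or soft labels — the method
  is deliberately pure confidence-filtered self-training.
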