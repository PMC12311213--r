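---
title: "Predicting axillary lymph node metastasis with patient-graph convolutional networks: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{lymphgraph methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The clinical problem

Axillary lymph node metastasis (ALNM) drives staging and surgical planning
in breast cancer, but its reference standards — sentinel node biopsy and
axillary dissection — are invasive. A noninvasive preoperative predictor
built from routine B-mode ultrasound would spare node-negative patients
unnecessary axillary surgery. `lymphgraph` implements such a predictor as a
pipeline: deep features extracted from the lesion region of an ultrasound
image, aggressive feature selection, and transductive classification on a
patient-similarity graph with a graph convolutional network (GCN).

The package is written for three-cohort studies: one training cohort and
two external validation cohorts, each from a different hospital. Each
cohort becomes its own graph; no edge ever crosses cohorts.

## Pipeline stages

1. **Preprocessing** (`preprocess_image()`): grayscale conversion (Rec.709
   luminance), crop to the lesion bounding box expanded by a margin
   (default 8 px) so peritumoural tissue is retained, aspect-preserving
   resize of the longer side to 224 px with symmetric padding of the
   shorter side, and — for the training cohort only — seeded augmentation
   (flips, random crop, rotation). Augmenting a validation image is an
   error, enforced in code.
2. **Feature extraction** (`extract_features()`): a pluggable backbone
   maps each 224×224 image to a fixed-width feature vector. The reference
   backbone (`resnet50_backbone()`) is a 50-layer residual network
   (bottleneck blocks 3-4-6-3) with the classification head removed; its
   globally pooled final activation has width 2048. Pretrained weights are
   a drop-in option, never a requirement: the package's tests and
   simulations use either a randomly initialized reference backbone (for
   the dimensionality contract) or synthetic feature tables.
   `fine_tune()` trains a temporary binary softmax head on the backbone's
   features (cross-entropy, Adam, learning rate 1e-4, batch 32, 200
   epochs) and removes it again.
3. **Feature selection** (`select_features()`): standardization fitted on
   the training cohort; a Spearman redundancy filter that removes one
   member of every pair with \(|\rho| > 0.85\); then recursive feature
   elimination with a linear SVM (\(C = 1\)), scored by 10-fold stratified
   cross-validated accuracy, never keeping fewer than 3 features. The
   frozen result (scaler statistics + column indices) is applied to the
   validation cohorts without touching their labels.
4. **Graph construction** (`assemble_graph()`): patients are nodes;
   an edge joins two patients of the same cohort when the cosine
   similarity of their selected-feature vectors reaches a threshold.
   Four thresholds (0.60, 0.70, 0.80, 0.95) define four competing models.
5. **GCN** (`gcn_train()`, `gcn_predict()`): two graph-convolution layers
   with ReLU, dropout, and a dense softmax head, trained with Adam.
6. **Evaluation** (`diagnostic_report()`, `delong_test()`,
   `decision_curve()`, `agreement_matrix()`, `rm_anova()`).

## The model

With \(A\) the 0/1 adjacency matrix, \(\tilde A = A + I\) and
\(\tilde D = \mathrm{diag}(\tilde A \mathbf 1)\), the propagation matrix is

\[\hat P = \tilde D^{-1/2} \tilde A \tilde D^{-1/2},\]

and the network computes

\[H^{(1)} = \mathrm{ReLU}(\hat P X W^{(0)}), \quad
  H^{(2)} = \mathrm{ReLU}(\hat P H^{(1)} W^{(1)}), \quad
  Z = \mathrm{softmax}(H^{(2)} W^{(fc)}),\]

with dropout applied to \(H^{(2)}\) during training. Self-loops guarantee
\(\tilde D\) is invertible, so isolated patients are retained (their
propagation row is a standard basis vector) and every patient receives a
prediction — only connected components are worth plotting, but all nodes
must be classified. \(\hat P\) is symmetric with spectral radius exactly 1
(verified numerically in the tests).

## Training protocol and its two deliberate choices

Defaults in `gcn_config()`: hidden widths 64/32, dropout 0.5, Adam with
learning rate 1e-4, batch size 32, at most 500 epochs, Glorot-uniform
initialization, patience 50. The published protocol this follows states a
batch size without saying how a batch interacts with single-graph
transductive training. Two choices needed making:

**Batching.** A "batch" here is a subset of labeled training nodes: each
Adam step runs a full-graph forward pass but computes the cross-entropy on
32 shuffled training nodes; one epoch sweeps all training nodes. This is
exactly what mini-batch loss masking does in standard GCN toolkits, and it
keeps the number of optimizer updates per epoch (\(\lceil n/32\rceil\))
consistent with the stated batch size. `batch_size = Inf` gives classical
full-batch training (one update per epoch) for comparison.

**Early stopping.** Stopping on the loss of an *external* validation
cohort leaks model-selection information. The default instead holds out a
stratified internal mask of training nodes (15%) and stops when its loss
has not improved for `patience` epochs, restoring the best-mask-loss
parameters. `early_stop_fraction = 0` disables the guard and trains for
the full epoch budget.

These two protocols answer different questions, and the package's own
validation uses both. With the guard on, the model is scored honestly on
external cohorts. With the guard off and the full 500-epoch budget, the
model can drive training accuracy into the saturated regime (≈ 0.99+ on
the simulated study, threshold 0.95) — the regime three-cohort
deep-radiomics studies typically report for their training set. On
leakage-free data these two outcomes cannot be produced by a single run:
held-out early stopping restores pre-overfitting weights, whose training
accuracy sits near the Bayes ceiling (≈ 0.89 at the default simulation
settings). Saturated training metrics *together with* held-out early
stopping are only possible when the features were themselves fitted to the
training labels (as happens when a backbone is fine-tuned on the same
patients), which is precisely the kind of optimistic training-set metric
an external validation exists to discount.

## The synthetic study

The original cohorts are private, so `make_study_cohorts()` draws
surrogate cohorts with the published geometry: 621/112/87 patients,
metastasis prevalences 0.346/0.402/0.402, 2048 features per patient, all
three cohorts from one generative model.

The generative family is class-conditional equal-covariance Gaussians: 10
informative columns whose class means differ by
\(\Delta/\sqrt{10}\) each (joint Mahalanobis separation \(\Delta = 2\) by
default), 20 redundant columns, and pure-noise remainder. The family was
chosen for one reason: its Bayes-optimal AUC is the closed form
\(\Phi(\Delta/\sqrt 2)\) (≈ 0.921 at \(\Delta = 2\)), giving every
downstream claim an analytic reference. A redundant column is a signed
linear copy of an informative partner plus Gaussian noise calibrated
through \(\rho_{\text{Pearson}} = 2\sin(\pi\rho_{\text{Spearman}}/6)\) so
the pair's Spearman correlation hits its target (0.95 by default, above
the 0.85 filter cutoff) in expectation; monotone (linear) coupling makes
Spearman and Pearson agree, matching the filter's rank-based criterion.
Copies are planted at larger column indices than their sources, the way
derived features follow their sources in a feature table, so the filter's
deterministic drop-the-later-column rule removes the copy and keeps the
source. An optional `mean_shift` knob emulates mild cohort shift; it
defaults to 0 because the study this mirrors reports modest external
divergence without quantifying it.

What the generator deliberately does **not** model: clinicopathological
covariates (receptor status, grade, BI-RADS), vendor-specific ultrasound
physics, correlated noise between non-planted features, and non-Gaussian
deep-feature marginals. Passing tests therefore demonstrate that the
pipeline recovers known signal under its stated assumptions — not that it
would achieve any particular performance on real ultrasound cohorts.

Toy lesion images (`generate_toy_images()`) exist to exercise the image
path end to end: speckle background, one hypoechoic elliptical lesion,
positives larger with irregular (sinusoidally perturbed) margins, tight
0-based half-open bounding boxes.

## Numerical and implementation choices

- **Linear SVM engine.** The elimination path fits hundreds of SVMs on
  matrices up to 621×2048. Refitting with a kernel-recomputing solver at
  every step is the bottleneck, so the package computes the linear Gram
  matrix once, downdates it as features are dropped
  (\(K \leftarrow K - X_{\text{drop}}X_{\text{drop}}^\top\)), and solves
  each C-SVC dual with a compiled SMO routine (second-order working-set
  selection, warm-started from the previous step's solution). The solver
  is validated against libsvm in the test suite: weight vectors correlate
  above 0.999 (up to the sign convention of which class is "+1") and
  decision values agree.
- **RFECV semantics.** One elimination path is scored by stratified
  10-fold CV at each recorded feature count; the optimum resolves ties
  toward fewer features. Elimination drops 64 columns per round while more
  than 256 remain, then one at a time — the final selected set near the
  optimum is unaffected by the coarse early phase, and `rfe_step = 1`
  restores a pure single-step path. When a fixed selected-feature count is
  requested (the default experiment fixes 22, reproducing the published
  table geometry of 22 features + id + class = 24 columns), elimination
  runs straight to that count and only the final set is CV-scored.
- **Ties and degenerate inputs.** Zero-variance columns standardize to
  zero with unit scale and a warning; constant columns rank-correlate as 0
  (kept); zero-norm rows make cosine similarity undefined and raise an
  error naming the patient; empty metric denominators yield `NA`, never
  `NaN`; a DeLong comparison of identical score vectors returns
  \(p = 1\) by convention.
- **Thresholding.** Edge inclusion is `similarity >= threshold`
  (inclusive); negative similarities (possible after standardization) are
  simply sub-threshold — no absolute value is taken.
- **NPV.** The standard definition TN/(TN+FN) is the default. A printed
  variant of the formula that circulates in the literature, FN/(FN+TN),
  is 1 − NPV and is available via `diagnostic_metrics(npv = "as_printed")`
  for auditing published tables; it is not a predictive value.
- **Confidence intervals.** 95% stratified percentile bootstrap (2000
  resamples by default); class counts are preserved in each resample.
  The method is deliberately assumption-light; its coverage for
  sensitivity is checked by simulation in the acceptance tests at the
  pooled external-validation sample size (200 cases).
- **ANOVA across models.** Repeated measures is primary (cases are
  subjects, models the within-subject factor; \(df = (k-1), (k-1)(n-1)\));
  a one-way variant is available because the two are easy to conflate.
  No sphericity correction is applied, matching the uncorrected df
  convention of the tables this reproduces.
- **Determinism.** A single experiment seed fans out to stage seeds via a
  polynomial hash of the stage name (`stage_seed()`), all below \(2^{31}\);
  every stochastic stage consumes only its own stream, so stages can be
  re-run in isolation. The compiled GCN training loop draws its batch
  shuffles and dropout masks from R's RNG, making compiled and reference
  engines separately reproducible (and provably identical in the
  deterministic full-batch regime — a test asserts equality to 1e-10).

## Problem sizes used by the test suite

The suite simulates at the full study geometry (621/112/87 × 2048) for the
recovery checks — five seeds, threshold 0.95, both training protocols —
and at reduced sizes (60–250 patients, 15–100 features) for contract and
property tests, sizes at which every statistical check is already stable.
The calibration simulations use 500 datasets for interval coverage and
1000 null replicates for the DeLong test size.

## Known limitations

- The Gaussian surrogate cannot certify real-world discrimination; it
  certifies correct mechanics and recovery of known signal.
- The reference backbone ships without pretrained weights; users who want
  deep features from real images must supply weights or accept
  random-weight features (useful only for plumbing tests).
- Transductive evaluation means a validation cohort's *features* (not
  labels) participate in its own graph; per-patient streaming prediction
  would require an inductive variant, which is out of scope.
- The DeLong test compares AUCs of models evaluated on the same patients;
  comparing across cohorts is not supported by design.
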