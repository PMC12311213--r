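# lymphgraph

Preoperative prediction of axillary lymph node metastasis (ALNM) in breast
cancer from B-mode ultrasound, using deep image features and a graph
convolutional network (GCN) over patient-similarity graphs.

Sentinel node biopsy and axillary dissection — the reference standards for
nodal staging — are invasive. This package implements, as tested R code, a
noninvasive pipeline for three-cohort (one training, two external
validation) studies:

1. lesion ROI crop (+margin), aspect-preserving resize to 224×224;
2. 2048 deep features per patient from a 50-layer residual backbone with
   the classification head removed (pluggable; pretrained weights optional);
3. standardization → Spearman redundancy filter (|ρ| > 0.85) → recursive
   feature elimination with 10-fold cross-validated linear SVMs (C = 1);
4. one cosine-similarity patient graph per cohort, at thresholds
   0.60/0.70/0.80/0.95;
5. a two-layer GCN
   `Z = softmax( ReLU(P̂ ReLU(P̂ X W⁽⁰⁾) W⁽¹⁾) W⁽ᶠᶜ⁾ )` with
   `P̂ = D̃^(−1/2)(A+I)D̃^(−1/2)`, trained with Adam (lr 1e-4, batch 32,
   ≤500 epochs, early stopping);
6. a full evaluation battery: accuracy/sensitivity/specificity/PPV/NPV/AUC
   with stratified bootstrap CIs, paired DeLong tests, decision-curve
   analysis, inter-model Pearson agreement, repeated-measures ANOVA.

The hospital cohorts such studies use are private, so the package ships a
synthetic-data module (`make_study_cohorts()`) that reproduces the study
geometry — 621/112/87 patients, metastasis prevalences 0.346/0.402/0.402,
2048 features — from class-conditional Gaussians with a *closed-form*
Bayes AUC (`Φ(Δ/√2)`), planted redundant feature pairs, and optional toy
lesion images. Every stage is testable offline with a known right answer.

## Worked example

```r
library(lymphgraph)

cohorts <- make_study_cohorts(seed = 11, class_separation = 2)
cohorts$train
#> <lg_cohort> 621 patients x 2048 features, 218 metastasis-positive (35.1%)
#>   planted: 10 informative, 20 redundant; Bayes AUC 0.921

sel <- select_features(cohorts$train$features, cohorts$train$labels,
                       selection_config(seed = 2), n_features = 22)
length(sel$kept_after_spearman)   # 2028  (20 redundant columns removed)
sum(cohorts$train$truth$informative %in% sel$selected)  # 10 of 10 recovered

nt <- lapply(cohorts, function(co)
  node_table(co$ids, apply_selection(sel, co$features), co$labels))
g_train <- assemble_graph(nt$train, threshold = 0.60)
unlist(graph_summary(g_train))[c("n_nodes", "n_edges")]
#> n_nodes n_edges
#>     621     252

fit <- gcn_train(g_train, cohorts$train$labels, gcn_config(seed = 3))
p_val1 <- gcn_predict(assemble_graph(nt$val1, 0.60), fit)
roc_auc(p_val1, cohorts$val1$labels)$auc
#> [1] 0.906        # generative Bayes optimum: 0.921
```

The numbers mean: the Spearman filter removed exactly the 20 planted
redundant columns, RFE recovered the full informative subspace, and the
trained GCN's external-cohort AUC (0.906) sits close beneath the analytic
ceiling of the generative model (0.921) — the pipeline loses little of the
recoverable signal.

`run_experiment(experiment_config(...))` runs everything (all four
thresholds, reports, DeLong/DCA/ANOVA comparisons, artifact tree with a
digest manifest); `inst/scripts/lymphgraph.R` is a thin command-line front
end over it.

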