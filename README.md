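# hspcflow

Reference-based cell-type annotation and perturbation analysis for
hematopoietic stem/progenitor cell (HSPC) single-cell RNA-seq data.

Early hematopoiesis is a continuum of CD34+ stem and progenitor states.
Aging and myeloid malignancies such as myelodysplastic syndrome perturb that
landscape in three measurable ways: the *composition* of progenitor
compartments shifts, *gene expression dynamics* along differentiation
trajectories change, and the activity of *regulons* (a transcription factor
with its inferred target genes) is rewired. `hspcflow` implements a tested,
reusable pipeline for detecting all three kinds of perturbation against a
labeled reference, together with a synthetic-data module that generates
negative-binomial count matrices with full ground truth (cell types, marker
genes, doublets, mitochondrial content, latent pseudotime with branch
probabilities, regulon activity), so every stage is testable without any
data download.

## The core method

**Classification.** For each of the reference cell types *k* a binary
elastic-net logistic regression is fitted on log-normalized expression over
the highly-variable genes shared by reference and query:

    minimize  -loglik(y, b0 + x'b) + lambda * [ alpha*||b||_1 + (1-alpha)/2 * ||b||_2^2 ]

Positives are all cells of type *k*; negatives are an equal-sized random
draw from the remaining cells; 75% of the pooled set trains the model and
25% validates it. Models are fitted over an alpha grid (1, 0.75, 0.5, 0.25,
0.1) with lambda chosen by 10-fold cross-validation; among candidates using
20–150 variables (window dropped if none qualifies) the winner maximizes
validation AUC, with ties broken by minimum false-positive rate, minimum
false-negative rate, and maximum variable count. The whole procedure is
repeated 10 times; a query cell's probability for type *k* is the mean of
the 10 logistic responses, its label is the argmax type if that probability
exceeds 0.5, and `"not assigned"` otherwise.

**Downstream tests.** Composition shifts use the pooled two-proportion
z-test per cell type with Bonferroni–Holm correction; gene trends are
penalized cubic spline fits of expression on pseudotime with branch
probabilities as observation weights, compared between conditions with a
two-sample Wilcoxon test (tiers `*`/`**`/`***` at Holm-adjusted p < 0.05 /
0.01 / 0.001); regulon AUC activity matrices are batch-centered, binarized
with a two-component Gaussian mixture, summarized as percent-active per
cluster, ranked by the regulon specificity score
`RSS = 1 - sqrt(JSD(activity, cluster indicator))` (Jensen–Shannon
divergence, base 2), and regulon networks are trimmed at the per-regulon
third quartile of edge importance.

## Worked example

```r
library(hspcflow)

cfg <- sim_config(n_types = 4, type_names = c("HSC", "MEP", "GMP", "CLP"),
                  n_genes = 200, markers_per_type = 6, n_dynamic_genes = 8,
                  n_cells_per_donor = 150,
                  donors_per_condition = c(young = 2, elderly = 2),
                  seed = 7)
ref <- generate_reference(cfg)
qry <- generate_query(cfg, ref$truth, effects = list(prop_delta = c(HSC = 0.10)))

fr <- filter_cells(ref$counts, qc_thresholds(mito_max_pct = 10))
fq <- filter_cells(qry$counts, qc_thresholds(mito_max_pct = 10))
nref <- log_normalize(fr$counts); nq <- log_normalize(fq$counts)
feat <- intersect_features(select_hvg(fr$counts, 100), select_hvg(fq$counts, 100))

ens <- train_ensemble(nref, ref$truth$cell_labels[colnames(fr$counts)], feat,
                      elastic_net_spec(alpha_grid = c(1, 0.5), n_repetitions = 2),
                      seed = 3)
ann <- predict(ens, nq)
mean(ann$label == qry$truth$cell_labels[ann$cell_id])
#> [1] 0.9866667
mean(ann$label == "not assigned")
#> [1] 0.006666667
```

98.7% of the 300 query cells recover their simulated identity and 0.7% are
left unassigned — the behavior expected when marker structure is strong
(here a 5-fold marker mean increase). Composition testing on the annotated
query versus the reference then flags the injected +0.10 HSC shift, and the
trend/regulon stages work analogously (see the vignette in `vignettes/`).

A full run of all seven stages (simulate, qc, train, predict, composition,
trends, regulons) with one JSON config and a reproducibility manifest:

```r
run_pipeline(list(outdir = "run1", seed = 1,
                  sim = list(n_types = 4, n_genes = 200),
                  classify = list(n_repetitions = 2)))
```

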