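# wbmir — whole-blood microRNA microarray analysis and diagnostic classification

`wbmir` is an R package for case-control studies that profile microRNA
expression in whole blood on two-color spotted microarrays (sample
channel vs a universal-reference channel, target probes printed in
quadruplicate, probe-less empty spots measuring background). It is
aimed at analysts who need the complete chain from scanner-exported
spot tables to cross-validated diagnostic classifiers, with every
statistical engine implemented as an exported, tested function:

* **Pre-processing** — normexp background correction (Normal + Exponential
  convolution, full maximum likelihood, corrected value
  `E[signal | observed] + offset`), global within-array loess of
  M = log2(sample/reference) on A, between-array quantile normalization
  of the reference channel that preserves every log-ratio, replicate
  summarization (mean if max < 1.5×min, else median), and an
  expressed-probe call against empty-spot levels (>3× on at least a
  quarter of arrays).
* **Differential expression** — empirical-Bayes moderated t
  (`s̃²_g = (d₀s₀² + d·s²_g)/(d₀+d)`, hyperparameters by log-F moment
  matching), Benjamini-Hochberg step-up FDR, Wilcoxon rank-sum
  alternative, linear-scale fold-changes, and cohort summary tests
  (pooled t from raw data or published n/mean/SD; Fisher's exact).
* **Classification** — top-scoring pairs
  (Δᵢⱼ = |P(Xᵢ<Xⱼ|case) − P(Xᵢ<Xⱼ|control)|, rank-invariant,
  deterministic tie-breaks) and linear soft-margin SVM with
  moderated-t feature filtering (≤15 probes) and nested 3-fold cost
  tuning over {0.1,…,50}; leave-one-out and Monte Carlo (36/9 split)
  cross-validation with feature-frequency accounting and a
  training-size sweep.
* **Evaluation** — ROC/AUC (= Mann-Whitney with ties ½), DeLong test
  for correlated AUCs, covariate correlation profiling (|r| > 0.4)
  with analytic and permutation nulls, average-linkage clustering on
  correlation distance with exact optimal leaf ordering, and
  RT-PCR/array concordance statistics.
* **Synthetic data** — a spot-level generator reproducing the study
  conditions (22 cases / 23 controls, ages 70.6±7.7 vs 59.9±9.1,
  1305 probes ×4 + 548 empty spots, fold-changes 0.54–1.59, a planted
  perfectly separating probe pair, age-driven probes, dye bias,
  corrupted spots), so the whole pipeline is testable end to end.

Reference summary tables from the deposited study (GEO accession
GSE27486) ship under `inst/extdata/` for the arithmetic anchor checks.

## Worked example

```r
library(wbmir)

ds <- simulate_dataset(synthetic_config(seed = 1))   # 45 spot tables
em <- build_expression_matrix(ds$spot_tables, ds$panel)
em
#> Expression matrix: 1305 probes x 45 samples; 401 expressed
mean(em$empty_summary)
#> [1] 11.49579

mat <- log2_signal(em, expressed_only = TRUE)
cls <- as.character(class_labels(ds$sheet))

loocv(mat, cls, "tsp")
#> LOOCV with TSP - 45 iterations
#>   accuracy 100.0%  sensitivity 100.0%  specificity 100.0%

mc <- mccv(mat, cls, "tsp", n_iter = 200, seed = 2)
head(mc$feature_frequency, 2)
#> probe_0001 probe_0002
#>        200        200

roc_auc(ds$sheet$age, cls)
#> ROC: AUC = 0.911 (22 cases, 23 controls)
```

Read: 401 of 1305 probes (31%) are called expressed; summarized
empty-spot signals sit near 11; the planted separating pair is found by
every one of the 200 Monte-Carlo classifiers and classifies perfectly
under leave-one-out; and the age difference built into the cohorts is
itself a strong classifier (AUC 0.91 here), which is exactly why the
confounder analyses in `correlate_covariate()` /
`resample_covariate_null()` exist.

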