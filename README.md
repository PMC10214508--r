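# mzclass

Interpretable classification of untargeted metabolomics feature tables.

Case-control metabolomics delivers a subject × feature abundance table —
tens to a few hundred subjects, tens to thousands of chemical features
known only by their m/z — and asks two questions: *can disease status be
predicted from the whole metabolome*, and *which ions carry the signal?*
`mzclass` answers both without any feature preselection, for
bioinformaticians and analytical chemists working on small-cohort
biomarker studies:

- **Resampling evaluation.** Diagnostic performance is estimated by
  Monte-Carlo cross-validation: the cohort is split at random `B` times
  (default 100) into 60% training / 40% test folds; per fold, imputation
  and standardisation are fitted on the training subjects only. Per-fold
  accuracy, precision, sensitivity, specificity, F1, MCC, and
  ROC/PR AUC are aggregated as mean ± sd.
- **Six classifier families** behind one contract: a multilayer
  perceptron (NN), gradient-boosted trees (XGB), random forest (RF),
  ridge logistic regression (LR), SVM, and LDA. Hyperparameters are tuned
  by grid search under shared splits, selecting the highest mean Matthews
  correlation coefficient,

  MCC = (TP·TN − FP·FN) / √((TP+FP)(TP+FN)(TN+FP)(TN+FN)).

- **Shapley feature ranking.** Per fold, test-subject predictions are
  attributed to features by model-agnostic Shapley values (training fold
  as background); the global score of feature *j* is mean |φ_ij| over all
  folds and subjects, with up/down regulation read from the
  abundance-label correlation.
- **Adduct-aware annotation.** m/z features are matched against a local
  compound table via monoisotopic masses under [M+H]⁺, [M+Na]⁺,
  [M+H−H₂O]⁺ or [M−H]⁻ hypotheses within a ppm tolerance (default
  ±20 ppm), with a mass-defect flag for candidate exogenous (e.g.
  fluorinated) compounds.
- **A synthetic-data generator** with planted, directioned biomarkers, so
  the full pipeline is testable end to end.

## Worked example

```r
library(mzclass)

# a synthetic cohort: 80 subjects, 120 features, 8 planted biomarkers
# at threefold abundance shift
ds  <- generate_dataset(synthetic_spec(80, 120, n_informative = 8,
                                       effect_fold = 3, seed = 7))
res <- run_evaluation(ds$table, model_spec("NN"), bootstrap_plan(100, seed = 7),
                      attributions = TRUE, shap_budget = 256)
glance(res)
#> # A tibble: 1 × 10
#>   family n_iterations mcc_mean mcc_sd auc_roc_mean auc_roc_sd auc_pr_mean
#> 1 NN              100    0.697  0.115        0.926     0.0451       0.916
#>   auc_pr_sd accuracy_mean pooled_rsd
#>      0.0586         0.846       9.17
```

The MLP separates cases from controls at mean ROC AUC 0.926 ± 0.045 over
the 100 resampling iterations (mean MCC 0.70; the pooled relative
standard deviation of 9.2% says the metrics are stable across folds).
Ranking features by absolute-averaged Shapley attribution recovers the
planted biomarkers, with the correct shift direction:

```r
rk <- rank_features(aggregate_shap(res$attributions),
                    regulation_direction(ds$table), top_k = 5)
head(tidy(rk), 5)
#>   feature_id shap_score  rank top   direction
#> 1 f0042          0.0411     1 TRUE  down
#> 2 f0098          0.0408     2 TRUE  down
#> 3 f0049          0.0395     3 TRUE  up
#> 4 f0032          0.0392     4 TRUE  up
#> 5 f0089          0.0386     5 TRUE  down
ds$truth$feature_id
#> "f0032" "f0042" "f0049" "f0089" "f0090" "f0098" "f0100" "f0106"
```

All five top-ranked features are planted ones. When feature IDs are m/z
values, the top-ranked ions can be annotated against a compound table:

```r
db <- read_compound_table(system.file("extdata", "compounds_demo.tsv",
                                      package = "mzclass"))
annotate_mz(942.9824, db)
#>   observed_mz compound_id compound_name          adduct  theoretical_mz  ppm
#> 1     942.982 CPD0001     Tris(heptafluorob[...] [M+Na]+        942.966 16.9
```

The observed ion at m/z 942.9824 matches the sodiated fluorinated ester
within the 20 ppm window (+16.9 ppm) and carries a negative mass defect
(−0.018), flagging it as a candidate exogenous synthetic compound.

`run_pipeline(run_config(...))` chains simulate/tune/evaluate/interpret/
annotate and writes metrics, curves, ranking, annotations, a markdown
report and a reproducibility manifest into a run directory;
`inst/scripts/run_mzclass.R` wraps it for the shell.

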