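---
title: "Methods: benchmarking interpretable classifiers on metabolomics feature tables"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: benchmarking interpretable classifiers on metabolomics feature tables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mzclass)
```

## The problem

Untargeted mass-spectrometry metabolomics produces a subject-by-feature
abundance table: tens to a few hundred subjects, tens to thousands of
chemical features identified only by their mass-to-charge ratio (m/z).
Case-control questions on such tables — can disease status be predicted
from the whole metabolome, and which ions carry the signal? — face three
obstacles at once: far more features than subjects, strong correlation
between features (isotopes, adducts, shared pathways), and no external
validation cohort. `mzclass` addresses this setting with four connected
pieces:

1. a resampling evaluation engine that estimates diagnostic performance
   from repeated random 60/40 train/test splits,
2. a six-family classifier zoo behind one train/score contract, tuned by
   mean Matthews correlation coefficient (MCC),
3. model-agnostic Shapley attribution aggregated into a global feature
   ranking, and
4. adduct-aware annotation of m/z features against a local compound table.

A synthetic-data generator with planted biomarkers makes every stage
testable end to end without any cohort download.

## Resampling protocol

The cohort is split `n_iterations` times (default 100) into a training
fold of `floor(0.6 n)` subjects sampled without replacement and a test
fold of the remainder — Monte-Carlo cross-validation. Splits are not
stratified by default; a stratified option exists. Per split, all
preprocessing (median imputation of missing abundances, then per-feature
z-scoring) is fitted on the training fold only, the model is fitted on the
preprocessed training fold, and the test fold is scored. Per-iteration
metrics (accuracy, precision, sensitivity, specificity, F1, MCC, ROC and
PR AUC) are aggregated as mean and sample standard deviation; iterations
where a metric's denominator vanishes (e.g. a single-class test fold under
non-stratified splitting) are excluded from that metric's aggregate and
counted. Training folds with fewer than two subjects of a class cannot be
fitted at all; such iterations are recorded as undefined with a warning.

Two conventions are fixed and documented rather than left implicit: a
score exactly at the 0.5 threshold predicts the positive class, and MCC is
0 when its denominator is 0 (so MCC-based model selection is total). ROC
AUC is the trapezoid over the full threshold sweep and equals the
Mann–Whitney pair statistic with ties counted one half; PR AUC is the
trapezoid over recall of the same sweep (not interpolated average
precision), matching the ROC treatment and keeping both oracle-testable.

Hyperparameter search (`grid_search()`) evaluates every combination of a
finite grid under one shared split sequence — reusing identical splits
across combinations removes split-to-split variance from the comparison —
and selects the highest mean MCC, first combination winning ties. The
packaged default grids enumerate 120–158 combinations for NN, XGB, RF, LR
and SVM, and 12 for LDA.

## The classifier zoo

Six families share the contract `fit_model(spec, x, y)` /
`predict_scores(model, x)` with scores in [0, 1] for the positive class
(label 1 = case throughout):

* **NN** — a multilayer perceptron implemented in the package (plain R,
  BLAS matrix products): default two hidden layers (64, 32), ReLU,
  inverted dropout 0.2, sigmoid output, binary cross-entropy, Adam
  (learning rate 0.01) with decoupled L2 weight decay 1e-4, 200 full-batch
  epochs, He initialisation under a fixed seed. At the cohort sizes this
  package targets a full training run takes well under a second, and
  seeded training is bit-reproducible.
* **XGB** — gradient-boosted trees via `xgboost` (binary logistic
  objective, single thread, seeded).
* **RF** — probability forests via `ranger` (seeded, single thread).
* **LR** — ridge-penalised logistic regression via `glmnet` (fixed
  `lambda`, default 0.01; features are already standardised by the shared
  preprocessing).
* **SVM** — `e1071::svm`; continuous scores are the logistic sigmoid of
  the signed decision margin, which ROC/PR analysis needs, without the
  extra internal cross-validation that Platt calibration would add.
* **LDA** — `MASS::lda` on the non-constant columns, posterior probability
  of the case class.

The MLP is written in the package because no deep-learning backend is part
of the dependency stack; a two-hidden-layer perceptron trained by Adam is
small enough that a dense-matrix implementation is both transparent and
fast at these problem sizes. Defaults (layer sizes, dropout, decay,
epochs) are deliberately ordinary for tabular data of this width and are
all grid-searchable.

## Shapley attribution and feature ranking

Per iteration, the test fold is explained against the training fold as
background: a feature absent from a coalition is replaced by the
corresponding value of a background subject. Two estimators:

* **exact** (p ≤ 12): all 2^p coalitions are enumerated and the coalition
  value is the mean model score over all background rows. This satisfies
  local accuracy (base value plus attribution row sum equals the model
  score) to machine precision and serves as the oracle in the tests.
* **sampling**: a permutation-walk estimator. Each walk draws one feature
  permutation and one background row, then flips features from background
  to instance values in permutation order; each score change is one
  marginal-contribution sample. A walk costs p + 1 model evaluations, so a
  budget of `b` coalition evaluations per instance buys `ceiling(b/(p+1))`
  walks (at least one). All walk states are scored in one batched
  prediction call, which keeps wide tables fast.

Explaining the *test* fold avoids attributing memorised training points;
over 100 iterations every subject is explained many times, so the
aggregate covers all subjects in expectation. The global score of a
feature is the mean of absolute attributions over all iterations and
explained subjects (`mean |phi|`). The alternative reduction `|mean phi|`
cancels opposing effects and is available as an explicit option but is not
the default. Regulation direction is deliberately *not* taken from the
attribution sign: it is the sign of the Pearson correlation between
abundance and label, which is model-free and matches how up/down
regulation is read in practice. Ranking ties break by feature position,
stably.

With the default budget of 128 coalition evaluations per instance a wide
table gets one walk per explained subject — individually noisy, but the
ranking averages thousands of walks across iterations and subjects, and
the planted-biomarker recovery test below shows the aggregate is reliable.
For p ≤ 12 the exact method is used automatically.

## Annotation of m/z features

Feature IDs that parse as m/z values are matched against a local compound
table (TSV: id, name, formula) by computing each compound's monoisotopic
mass from tabulated most-abundant-isotope masses and each adduct
hypothesis's theoretical m/z. Supported adducts are protonation
(+1.007276 Da), sodiation (+22.989221 Da), protonation with water loss
(−17.003289 Da) and deprotonation (−1.007276 Da); the electron mass is
included — at a 20 ppm tolerance on small ions it is borderline material
and exactness is cheap. The ppm error is computed on the m/z scale, one
fixed convention. Matches within ±20 ppm (default) are returned sorted by
absolute ppm error, ties by compound id; tightening the tolerance can
only remove matches.

The mass defect (distance of m/z to its nearest integer) flags candidate
exogenous synthetic compounds: CHNO-dominated endogenous metabolites drift
*positive* with mass, so a strongly negative defect at high mass is
anomalous — typical of per-/polyfluoroalkyl substances. The flag fires
when the defect falls below −0.0015 Da per 100 Da of m/z. This slope is a
package choice (the concept does not come with a standard cut-off): it is
calibrated so that a heavily fluorinated ion near 943 Da with defect
about −0.018 is flagged while near-zero defects at any mass are not, and
it is a plain argument for users who prefer a different rule.

## The synthetic-data generator

`generate_dataset()` emulates the data shapes of small case-control
metabolomics cohorts (tens of subjects, tens to thousands of features,
balanced or imbalanced): abundances are log-normal (per-feature baseline
log-mean ~ N(10, 1.5), subject-level log-sd `noise_sigma`, default 0.5 —
i.e. roughly ±65% multiplicative noise, ordinary for untargeted data);
features within a declared block share a latent subject factor with
loading `sqrt(rho)` so within-block log-abundance correlation converges to
`rho`; planted informative features shift the case-class log-mean by
±log(effect_fold) with alternating signs, so both up- and down-regulated
markers exist and direction recovery is testable; missing cells are placed
uniformly at random. Everything is reproducible from one seed.

What the generator does *not* emulate: retention-time structure, isotope
and adduct peak families derived from the same analyte, batch effects and
instrument drift, intensity-dependent missingness, and heavy-tailed
contamination. Passing tests on this generator therefore demonstrate that
the pipeline's machinery is correct and unbiased, not that any particular
real cohort is classifiable.

## Verification scales and protocol choices

The package's own test suite runs every stage at sizes chosen to finish
promptly while keeping the statistical checks meaningful; the heavier,
statistically load-bearing checks are:

* **Permutation control**: a signal-bearing cohort (n = 74, p = 200, 10
  planted features, twofold effect) with labels permuted, evaluated by the
  100-iteration NN protocol. One permutation replicate's mean accuracy is
  itself a random variable with a standard deviation near 0.045, because
  all 100 iterations share the single permuted labeling — empirically
  replicate means range from about 0.41 to 0.53 across permutations, for
  linear and nonlinear models alike. The control therefore averages five
  independent permutation replicates and takes a t-interval over replicate
  means; the naive per-iteration interval would be several times too
  narrow and would reject a sound pipeline on many single draws.
* **Planted-biomarker recovery**: n = 80, p = 500, 10 planted features at
  twofold effect inside correlated blocks (rho = 0.3, blocks of 20), 100
  NN iterations with a Shapley budget of 1024 coalition evaluations per
  instance (two walks); at least 8 of the 10 planted features must appear
  in the top 10 and every recovered feature's direction must match its
  planted sign.
* **Interaction benchmark**: on an XOR-style dataset whose label depends
  only on a product of two features, the MLP's mean ROC AUC must exceed
  that of LDA and of a linear SVM by at least 0.1 — linear models cannot
  represent the interaction.

## Known limitations

* The evaluation protocol estimates out-of-fold performance on the *same*
  cohort; it does not substitute for external validation.
* Non-stratified 60/40 splitting of very small or very imbalanced cohorts
  produces degenerate folds; they are handled (undefined metrics, logged),
  but strongly imbalanced cohorts should use `stratified = TRUE`.
* The sampled Shapley estimator assumes feature independence in its
  background replacement, as marginal-expectation Shapley always does;
  attributions within strongly correlated blocks spread credit across the
  block.
* Annotation is mass-matching only: isomers are returned as co-matches and
  never disambiguated, and without MS/MS or retention information a match
  is a hypothesis, not an identification.
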