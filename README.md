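# mycog

Scores and classifiers for detecting cognitive impairment (CI) from brief
multi-instrument cognitive batteries. The package targets the analysis
design of an 86-patient primary-care screening study: per-patient binary
item responses from five instruments — DCCS (cognitive flexibility, 30
items), PSM (episodic memory, 12), ARW (inhibitory control, 50), MFS
(working memory, 30), NSM (processing speed, 144) — plus total response
times, demographics, and a clinical 0/1 impairment label.

At its core is a **higher-order two-parameter logistic IRT model** fitted
by MCMC (`hoirt()`):

    P(y_ij = 1 | θ) = logit⁻¹{ a_j (θ_{i,d(j)} − b_j) },
    θ_{i,d} = λ_d θ_{i,g} + ε_{i,d},   ε_{i,d} ~ N(0, 1 − λ_d²),
    θ_g ~ N(0, 1)

Each item measures one content domain; domain abilities load on one
general factor. The EAP of θ_g is the overall screening score (SSHO2D for
the two-instrument DCCS+PSM battery). Around the model the package
provides:

* classical scores and the five published **composite scores**
  (OLS-on-label + logistic transform, `fit_composite()` /
  `apply_composite()`, published coefficients via
  `load_composite_fixture()`);
* fixed-cut classification and an exhaustive **mismatch-minimizing cut
  search** (`cut_rule()`, `search_optimal_cut()`);
* a **classifier benchmark**: sixteen feature spaces, seven models with
  their hyperparameter grids, stratified 80/20 splits (86 → 68/18),
  5-fold CV grid search, confusion-matrix metrics/QWK/AUC, and a
  100-round **bootstrap evaluation** (`bootstrap_evaluate()`);
* a **synthetic cohort generator** reproducing the study's statistical
  structure (22 % prevalence, 1 SD ability deficit, age–impairment
  correlation 0.27, published response-time moments, monotone MFS/NSM
  missingness) so everything is testable without data access
  (`generate_cohort()`, `make_benchmark_fixture()`);
* the study's published per-patient score table as a checksummed fixture
  (`load_printed_fixture()`), and a pipeline driver (`run_pipeline()`,
  `verify_against_paper()`).

See the methods vignette (`vignettes/mycog-methods.Rmd`) for the model,
estimation, protocol conventions and limitations.

## Worked example

Applying the published SSHO2D cut to the published per-patient scores,
searching for the optimal cut, and bootstrapping a random forest on
{SSHO2D, age}:

```r
library(mycog)
fx <- load_printed_fixture()           # 86 patients, 19 impaired

pred <- classify_by_cut(fx$ssho2d, cut_rule(-0.026, "below"))
count_mismatches(pred, fx$impaired)
#> [1] 14

opt <- search_optimal_cut(fx$ssho2d, fx$impaired)
opt$rule; opt$mismatches
#> Cut rule: impaired if score < 0.012
#> [1] 13

x <- build_feature_matrix(fx, "F15")   # {age, ssho2d}
bootstrap_evaluate(x, fx$impaired, "RF", B = 25, seed = 1)
#> Bootstrap evaluation: RF - 25 replications (seed 1)
#>              mean    sd used skipped
#> precision   0.779 0.251   25       0
#> recall      0.678 0.314   25       0
#> accuracy    0.876 0.079   25       0
#> specificity 0.926 0.084   25       0
#> f_score     0.699 0.197   24       1
#> qwk         0.601 0.273   25       0
#> auc         0.883 0.175   25       0
```

The fixed −0.026 cut misclassifies 14 of 86 patients and the best
achievable single cut still misses 13, while the bootstrap random forest
on the same score plus age classifies far better — the package's central
substantive result: a learned classifier on the two-instrument IRT score
and age beats any fixed cutoff. (Bootstrap replications share duplicated
patients across the train/test split, so these means measure protocol
stability, not out-of-sample error.)

A full synthetic run, from item responses to bootstrap tables:

```r
cfg <- pipeline_config(
  input = list(type = "synthetic", sim = cohort_sim_config(n = 86, seed = 1)),
  hoirt = list(n_iter = 800L, n_burn = 300L))
run_pipeline(cfg, out_dir = "out")     # cohort/scores/cuts/benchmark CSVs
```

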