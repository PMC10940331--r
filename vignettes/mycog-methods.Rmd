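---
title: "Screening scores for cognitive impairment: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening scores for cognitive impairment: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mycog)
```

## The screening problem

Brief tablet/smartphone cognitive batteries are attractive for primary-care
detection of cognitive impairment (CI) in older adults. The data this
package works with are per-patient binary item responses from five
instruments — DCCS (cognitive flexibility, 30 items), PSM (episodic memory,
12 items), ARW (inhibitory control, 50 items), MFS (working memory, 30
items) and NSM (processing speed, 144 items) — plus total response times
for the three timed instruments, demographics, and a 0/1 impairment label
from clinical records. The question is how to turn 266 item responses into
one or a few scores that separate impaired from normal cognition, and
whether a fixed score cutoff or a machine-learned classifier does that
better.

The package ships a checksummed transcription of the per-patient published
score table of an 86-patient study of this design
(`load_printed_fixture()`: 19 impaired, 67 normal), which anchors the
exactly reproducible results: linear-cut mismatch counts and the bootstrap
classifier benchmark.

## The higher-order 2PL model

`hoirt()` fits the hierarchical item response model

$$P(y_{ij}=1\mid\theta) = \mathrm{logit}^{-1}\!\left\{a_j\,(\theta_{i,d(j)}-b_j)\right\},
\qquad
\theta_{i,d} = \lambda_d\,\theta_{i,g} + \varepsilon_{i,d},$$

with $\varepsilon_{i,d}\sim N(0,1-\lambda_d^2)$ and
$\theta_g \sim N(0,1)$. Each item $j$ measures one content domain $d(j)$
with discrimination $a_j>0$ and difficulty $b_j$; the domain abilities load
on a single general factor through $\lambda_d\in(0,1)$. Two
identification choices matter:

* **unit marginal variance** — $\mathrm{Var}(\theta_d)=\lambda_d^2+(1-\lambda_d^2)=1$,
  which fixes the latent scale without constraining items;
* **positive loadings** — $\lambda_d>0$ resolves the reflection invariance.

No 1.7 scaling constant is used. The posterior mean (EAP) of $\theta_g$ is
the overall screening score: `ssho2d` when the model is fitted to the
two-instrument battery {DCCS, PSM}, `ssho` for all five instruments;
domain EAPs (`d2_dccs`, `d2_psm`, `d5_*`) come along for free
(`eap_scores()`).

### Estimation

A Metropolis-within-Gibbs sampler is used: the general abilities have an
exact normal full conditional and are Gibbs-drawn; domain abilities, item
parameters (on $\log a$ and $b$) and loadings use Gaussian random-walk
proposals. Priors are weakly informative:
$\log a \sim N(0, 0.5^2)$, $b \sim N(0, 2^2)$, $\lambda_d \sim U(0,1)$.
Step sizes adapt every 50 iterations during burn-in toward a 20–50 %
acceptance rate and are frozen afterwards, so the post-burn-in chain is a
fixed-kernel Markov chain; defaults are 5000 iterations, 2000 burn-in,
thin 1. Chains are bit-reproducible under a fixed seed. Missing responses
(MFS/NSM stopping rules, treated as missing at random) are skipped in the
likelihood; NSM's 90-second speeding is deliberately not modelled —
unattempted items are missing, not wrong.

### What two domains can and cannot identify

With only two domains the covariance of $(\theta_1,\theta_2)$ depends on
the loadings only through the product $\lambda_1\lambda_2$, so the
individual loadings are informed mainly by their priors. This is a
structural property of two-indicator factor models, not a sampler defect.
Its practical consequence: domain EAPs are recovered very well (simulation
correlation with truth ≈ 0.9 at 20 items/domain), while the general-factor
EAP has a ceiling. At the simulation design used in the recovery tests
(two domains of 20 items, $a\sim U(0.8,2)$, $b\sim U(-2,2)$,
$\lambda=(0.7,0.8)$, $n=500$), an exact nested-quadrature EAP at the *true*
parameters correlates with the true $\theta_g$ at only ≈ 0.81; with
$\theta_d$ known perfectly the algebraic ceiling is
$\sqrt{w/(1+w)}=0.856$, $w=\sum_d \lambda_d^2/(1-\lambda_d^2)$. Any
monotone use of the score downstream (cuts, classifiers) is unaffected,
because those layers are invariant to monotone rescaling.

## Classical and composite scores

`classical_scores()` computes number-correct per instrument and, for the
timed instruments, the accuracy rate = number correct / total response
time (1/seconds); DCCS and ARW enter composites through their rates. The
five composite models combine small feature sets
(`load_composite_fixture()` for the published coefficients,
`fit_composite()` to refit on a cohort):

| model | features |
|---|---|
| Composite1 | classical scores (rates for DCCS/ARW) |
| Composite2 | five-domain IRT scores + three total RTs |
| Composite3 | ssho2d, dccs2D, psm2D, age |
| Composite4 | ssho2d, dccs2D, psm2D |
| Composite5 | DCCS rate, PSM number-correct, age |

A deliberate quirk is preserved: the linear part is an **ordinary least
squares fit of the 0/1 label** (a linear probability model), with the
logistic transform $\sigma(f)=e^f/(1+e^f)$ applied afterwards — not
logistic regression. The published coefficients and the published
per-patient composite values are mutually consistent only under that
construction. Two published oddities are reproduced as printed rather than
reinterpreted: Composite3's positive overall-score coefficient, and
Composite2's response-time coefficients, whose ≈ 1e-5 magnitudes imply
millisecond inputs — composite models therefore carry an `rt_unit` field
and `apply_composite()` refuses a second-scale bundle for a
millisecond-scale model.

## Cut rules and the optimal-cut search

A `cut_rule()` is a threshold plus an explicit direction
(impaired-if-below for ability-like scores, impaired-if-above for
risk-like probabilities); inequalities are strict, which is exactly what
reproduces the published predicted-label columns including boundary
patients (a Composite5 of 0.92 is predicted normal at cut 0.925).
`search_optimal_cut()` evaluates every midpoint of consecutive sorted
unique scores plus below-minimum/above-maximum sentinels, in both
directions; ties prefer impaired-if-below, then the smallest threshold,
making the search deterministic. The sentinels guarantee the optimum never
exceeds min(#impaired, #normal). Only the mismatch *count* is treated as
reproducible — the published cut values themselves may be grid points
rather than midpoints.

## The classifier benchmark

Sixteen feature spaces (`feature_spaces()`, F1–F16) combine IRT scores,
classical scores, response times, composites and integer-coded
demographics; F13/F14 use the five-domain single-instrument scores,
matching the registry's score notation. Seven classifiers are available
(`model_spec()`): radial SVC (C ∈ {1,10,50,100}), L2 logistic regression
(20 log-spaced strengths in [0.01,5]), decision tree (7 depths spanning
3–30), KNN (k ∈ {3,5,7,9} — a minimal symmetric default, recorded in the
grid), random forest (10 tree counts spanning 10–500), gradient boosting
(10/30/50 trees) and a neural network. The neural network is a
single-hidden-layer perceptron (nnet backend) with a grid over hidden
size {150, 120} and weight decay {0.01, 0.3, 1} and internally
standardized inputs; it stands in the benchmark where a deeper
multi-layer perceptron would otherwise appear, the rest of the layer
being backend-agnostic.

Protocol conventions, each of which materially affects reported numbers:

* **split** — stratified, test size $\lceil 0.2n\rceil$ (86 → 68/18),
  per-class counts by largest remainder; seeded and reproducible.
* **selection** — stratified 5-fold CV on the training portion, best mean
  validation *accuracy*, ties broken by grid order, refit on the full
  training portion.
* **metrics** — positive class = impaired: precision TP/(TP+FP), recall
  TP/(TP+FN), specificity TN/(TN+FP), F = 2PR/(P+R); zero-denominator
  ratios are reported as undefined (`NA`), never as 0. A
  class-frequency-weighted variant (under which precision = recall =
  accuracy for binary data) is computed alongside, since published
  all-data tables follow that convention while the bootstrap headline
  numbers follow the per-positive-class one.
* **QWK** — Cohen's kappa with quadratic weights, which for binary labels
  equals unweighted kappa.
* **AUC** — pairwise concordance with ties counted ½, computed by the
  rank identity; probability scores are used where the classifier
  provides them.

## Bootstrap evaluation

`bootstrap_evaluate()` repeats, B = 100 times by default: resample the n
patients with replacement (same sample size), stratified 80/20 split *of
the resample*, grid-search-train on the 80 %, evaluate on the 20 %.
Because resamples contain duplicates, the same patient can appear on both
sides of the split; that leakage is intrinsic to the protocol and the
summary should be read as a stability measure, not out-of-sample error —
it is also why the bootstrap means exceed honest test-split estimates.
Metrics undefined in a replication (e.g. no predicted positives) are
skipped and the skip count reported. Replication seeds are derived from
the master seed, so the whole procedure is reproducible end-to-end.

## The synthetic cohort generator

`generate_cohort()` exists so every stage is testable without any data
download. It emulates, by construction:

* 22 % impairment prevalence (label-first: the label is drawn, then the
  ability shifted — prevalence and effect size stay independently
  controllable);
* a 1 SD general-ability deficit in the impaired group, marginal mean 0;
* ages 67–93, truncated normal around 76 (SD 6), tied to the impairment
  propensity by a Gaussian copula calibrated to a 0.27 point-biserial
  age–impairment correlation;
* lognormal total response times moment-matched to the published
  means/SDs (ARW 47.421/11.619 s, DCCS 36.049/14.909 s, PSM 73/34 s);
* monotone MFS/NSM missingness via a per-patient stopping point, ramping
  linearly to 50 % (MFS) and 90 % (NSM) at the last item — the NSM ramp
  reflects that most of its 144 speeded items go unattempted;
* demographics drawn from the published category frequencies, special
  codes ("D", 777) included.

The default item bank draws $a\sim\mathrm{LogNormal}(0,0.5)$,
$b\sim N(0,1)$, $\lambda_d\sim U(0.5,0.9)$. What the generator does *not*
emulate: the real instruments' empirical difficulty profile (real DCCS
accuracy is near ceiling; the bank's $b\sim N(0,1)$ is more spread),
ability–age dependence beyond the label path, education/income–ability
structure, and item-level response-time processes. Consequently, passing
synthetic tests demonstrates the pipeline's statistical machinery —
recovery, monotonicity, determinism, signal propagation — not clinical
realism of any particular score distribution; composite probabilities on
synthetic cohorts can stray slightly outside the published sample range
precisely because that range is an n = 86 sample extremum.

## Numerical choices and degenerate inputs

* Likelihood cells use the stable form $y\eta-\log(1+e^\eta)$ with
  $\log(1+e^\eta)=\max(\eta,0)+\log(1+e^{-|\eta|})$.
* Ability chains initialize from logit-transformed proportion correct
  (standardized); items from observed difficulty.
* `cronbach_alpha()` drops items containing missing values, then needs at
  least 2 items, 2 persons and positive total variance; otherwise `NA`.
  Single-patient summaries flag all variance statistics undefined.
* Single-feature spaces are handled in the ridge logistic backend by a
  zero-variance padding column (glmnet requires two columns; the pad's
  coefficient is exactly 0).
* `kmeans_elbow()` keeps, for each k, the best of 10 random starts *and*
  a warm start from the previous solution's centers plus its worst-fitted
  point; since Lloyd iterations never increase inertia, the reported
  elbow curve is guaranteed non-increasing in k. k = n with distinct
  points short-circuits to inertia 0.
* Every stochastic routine takes an explicit integer seed; identical
  seed + configuration ⇒ identical output, including byte-identical
  pipeline CSVs.

## Problem sizes used by the test suite

The shipped tests exercise the full pipeline at sizes chosen to make the
statistical assertions sharp while keeping a default run brief: MCMC
recovery at n = 500 patients × 40 items (4000 iterations), generator
moment checks at n = 1000–5000, the bootstrap benchmark at the study's
n = 86 with B = 100, oracle equivalence on 200 random cut instances and
sub-50-point AUC instances, and an end-to-end synthetic pipeline at
n = 86 with 400-iteration chains.

## Known limitations

* Two-domain general-factor recovery has the identifiability ceiling
  described above; published overall scores are reproducible only up to a
  monotone transformation, which is why printed-score checks use the
  packaged fixture rather than refit scores.
* The bootstrap protocol is a reconstruction of an under-specified
  procedure; alternative readings (e.g. training on the full resample and
  scoring all patients) shift the metric means by several points.
* The ANN is single-hidden-layer; deep feedforward/recurrent variants are
  out of scope.
* Polytomous items, differential item functioning, and marginal maximum
  likelihood estimation are out of scope.
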