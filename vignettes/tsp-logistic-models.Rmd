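---
title: "Top-scoring pair logistic models: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Top-scoring pair logistic models: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tsplogit)
```

## The problem

Prognostic models for binary clinical outcomes (here the motivating case is
prostate cancer progression: a *lethal* versus *indolent* course) are
traditionally built from clinical covariates — age, Gleason score, tumor
percentage, ERG fusion status. Adding gene expression has often disappointed,
in part because genes are screened one at a time: a per-gene t-test ranks
genes by marginal mean shift, and many informative expression patterns carry
no marginal shift at all.

`tsplogit` implements the alternative this package is built around: select
*gene pairs* by the rank-based top-scoring pair (TSP) statistic and feed them,
together with clinical covariates, into a logistic regression. The pair
feature is the within-sample ordering event, so the molecular part of the
model is invariant to any monotone per-sample distortion — normalisation,
scanner effects, monotone batch effects — which single-gene expression values
are not.

## The pair statistic

For genes $u, v$ and sample $j$, the indicator $I(x_{uj} < x_{vj})$ is 1 when
gene $u$ is expressed strictly below gene $v$ in that sample; ties count as 0
(the indicator credits the strict ordering only). Within each outcome class
the ordering frequency is

$$p^{(c)}_{uv} = \frac{1}{N_c} \sum_{j \,:\, y_j = c} I(x_{uj} < x_{vj}),
\qquad c \in \{0, 1\},$$

and the pair score is $\Delta_{uv} = |p^{(0)}_{uv} - p^{(1)}_{uv}|$. A
*reversal pair* — one whose ordering flips between classes — approaches
$\Delta = 1$. `score_pairs()` evaluates all $M(M-1)/2$ pairs (a compiled
kernel; the operation is $O(M^2 N)$) and sorts them by $\Delta$.

Decisions the score definition leaves open, and what this package does:

* **Orientation.** Each unordered pair is stored once, oriented so
  $p_0 \ge p_1$: the ordering $x_u < x_v$ is the one more frequent in class
  0, which makes the single-pair decision rule (`tsp_predict()`: predict
  class 0 on seeing that ordering) well defined. With tied expression values
  the two ordered directions can disagree slightly (the "$\ge$" in the tie
  rule is asymmetric); the implementation counts both directions and prefers
  the orientation with $p_0 \ge p_1$, then the larger $\Delta$. Continuous
  data has no ties almost surely, so this matters only for degenerate input.
* **Tie-breaking between equal $\Delta$.** The secondary score is the
  absolute between-class difference of the mean within-sample rank gap of
  the two genes — the usual k-TSP secondary statistic. Remaining ties fall
  back to gene index order, so the ranking is fully deterministic.
* **Multi-pair panels.** `select_pairs(k, disjoint = TRUE)` greedily skips
  pairs sharing a gene with an already selected pair. Disjointness is the
  default because near-duplicate pairs (one strong gene paired with many
  partners) otherwise crowd the panel; the non-disjoint reading is available
  with `disjoint = FALSE`.
* **Scale guard.** For very large gene sets an optional pre-filter
  (`prefilter = "variance"` or `"ttest"`) limits the quadratic enumeration;
  it is off by default so the exhaustive search is what you get unless you
  ask otherwise.

## The logistic layer

Pairs and clinical covariates are combined in an ordinary logit model

$$\log \frac{p_j}{1 - p_j} = \beta_0 + \sum_i \beta_i x_{ij},$$

fitted by maximising the binomial log-likelihood. How a pair enters the
design was a genuinely open choice:

* `indicator` (default): one 0/1 column per pair, the ordering event itself.
  This preserves the TSP method's rank invariance end to end — the fitted
  model depends on the data only through orderings.
* `raw`: the two genes' expression values, two columns per pair, provided
  for comparison; it abandons rank invariance and is flagged in the model
  spec.

The fitter (`fit_logit()`) is iteratively reweighted least squares with
step-halving, so the log-likelihood trace is non-decreasing by construction.
Numerical choices: at most 100 iterations; convergence when every component
of the score vector is below $10^{-8}$; constant columns are dropped with a
warning. Indicator covariates on small folds frequently separate the
classes; divergence (a slope passing $|\beta| > 15$, about an odds ratio of
$3\times10^6$, or a singular step) triggers a refit with a small ridge
penalty $\lambda = 10^{-4}$ on the slopes — never the intercept — and the
fit is flagged `ridge_used`. Clinical covariates are used on their natural
scales: coefficients stay interpretable and the AUC is unaffected by linear
rescaling. Samples missing a *modeled* clinical covariate are dropped
per-model with a message; imputation would add assumptions the data cannot
check.

## Evaluation protocol

`stratified_split()` makes the one-time learning/validation division (class
proportions within one sample of exact in both parts). On the learning set,
`run_cv()` repeats stratified k-fold cross-validation `n_iter` times; the
defaults (100 repetitions of 10 folds) follow the repeated-CV protocol the
package is designed around, and every repetition reruns feature selection
*inside* each training fold — the selection is logged per fold and is a
deterministic function of training-fold data only, which the test suite
verifies by recomputation.

Two per-iteration AUC aggregations are computed:

* `pooled` (default): one AUC from the pooled out-of-fold probabilities of
  the iteration. Folds of ~19 samples give very unstable individual AUCs,
  and pooling is the standard stable choice. Pooling can in principle be
  slightly pessimistic under the null (fold-wise calibration differences
  interact with finite-population class balance), a known property of
  pooled CV predictions; at the sizes used here the null mean measured by
  the test suite is within a few thousandths of 0.5.
* `per_fold`: the mean of the k fold-level AUCs, also recorded per
  iteration, for users who want the other reading.

AUC itself is the Mann–Whitney form: ties contribute one half, which matters
because indicator-encoded models emit few distinct probabilities. The
repeated-CV summary is the mean AUC and a percentile interval (2.5th/97.5th
empirical percentiles of the per-iteration AUCs, linear interpolation); the
interval construction is labelled in the output since other constructions
(normal approximation) exist. No multiplicity correction is applied across
the 16-model grid — model-selection optimism is controlled only by the
held-out validation set, and `finalize_model()` asserts that validation
indices never intersect the learning set.

"Best model" needs a parameterisation rule, because repeated CV produces
1,000 fold-level models: `finalize_model()` picks the spec with the largest
mean CV AUC (ties toward fewer covariates), then re-selects the panel and
refits the coefficients once on the full learning set, reporting the
per-fold selection frequencies alongside. A single deployable model needs
one coefficient vector; the frequencies show how stable the selection was.

The one-gene-at-a-time baseline (`selector = "ttest"`) ranks genes by
two-sided Welch t-tests (unpooled variances — the pooled/unpooled choice is
not dictated by the protocol; Welch is the safer default and is labelled),
enters the top genes as raw expression columns, and spends the same gene
budget as the pair model (`2 * n_pairs` genes) so comparisons are at equal
cost. Zero-variance genes have an undefined statistic and rank last.

## The synthetic generator

`simulate_tsp_dataset()` emulates the shape of the motivating cohort: 281
samples with an unbalanced event fraction (165/281), thousands of null
genes, a handful of planted reversal pairs, and four clinical covariates
with class-linked distributions. Null genes are Gaussian with gene-specific
baseline and spread drawn from ranges typical of log-intensity arrays
(baseline 4–12, SD 0.6–1.4), exchangeable across classes.

The planted-pair construction is the part worth spelling out. A reversal
pair must satisfy two things at once: the ordering indicator is
Bernoulli($q_c$) within class $c$, and each gene's marginal distribution is
*identical* across classes (otherwise a per-gene t-test could see it, and
the pair-versus-single-gene comparison would be confounded). The obvious
construction — draw an ordering coin, then place two exchangeable values in
that order — fails the second requirement: the gene receiving the minimum
with probability $q_c$ has a class-dependent mixture marginal (at
$q_0/q_1 = 0.9/0.1$ the induced mean shift is about $0.9$ SD, easily
visible to a t-test). The generator instead uses a cyclic-shift copula:

$$U \sim \mathrm{Unif}(0,1), \qquad V = (U + 1 - q_c) \bmod 1,$$

mapping both $U$ and $V$ through the same increasing quantile transform
(here Gaussian with the pair's shared baseline and SD). Then $x_u < x_v$
exactly when $U < q_c$ — an exact Bernoulli($q_c$) indicator — while $V$ is
again uniform, so both marginals are the same Gaussian in both classes. The
test suite checks both properties directly (binomial concentration of
$\hat p_0, \hat p_1$; two-sample Kolmogorov–Smirnov between classes). The
boundary $q_c = 1$ uses an infinitesimal shift since a zero shift would tie
the genes (and ties count as 0); $q_c = 0$ works exactly for the same
reason.

Clinical covariates are drawn from class-conditional distributions chosen
once as plausible for an elderly watchful-waiting cohort (no published
estimates exist for the emulated dataset, so these are the package's own
defaults, all overridable): age $\mathcal N(70, 8^2)$ vs
$\mathcal N(74, 7^2)$; Gleason grades 6–9 with probabilities
$(0.45, 0.40, 0.10, 0.05)$ vs $(0.10, 0.35, 0.35, 0.20)$; tumor percentage
$100 \cdot \mathrm{Beta}(2,4)$ vs $100 \cdot \mathrm{Beta}(4,3)$; ERG
fusion Bernoulli(0.30) vs Bernoulli(0.50). Labels are drawn first
(Bernoulli), so class counts vary around their expectation as they would in
a cohort.

What the generator does **not** emulate: probe-level/array-specific noise,
stromal contamination, inter-tumor heterogeneity, correlation among null
genes, or dependence between clinical covariates and expression beyond
their shared class. Passing tests on this generator therefore demonstrate
the machinery (selection, fitting, protocol integrity, calibration) under a
clean reversal signal — not performance on real arrays.

```{r example, eval = FALSE}
sim <- simulate_tsp_dataset(n_samples = 300, n_genes = 500,
                            planted_pairs = data.frame(q0 = 0.9, q1 = 0.1),
                            seed = 1)
scores <- score_pairs(sim$expression, sim$labels)
head(scores)           # the planted pair tops the table

spec <- model_spec("gleason_score", n_pairs = 1, id = "1.3")
cv <- run_cv(sim$expression, sim$clinical, sim$labels, spec,
             n_iter = 100, k = 10, seed = 2)
glance(cv)
autoplot(cv)
```

## Useful closed forms

A single planted pair with flip probabilities $(q_0, q_1)$ and no other
signal gives a binary feature whose ROC has one interior point, so

$$\mathrm{AUC} = q_0(1 - q_1) + \tfrac12\big[q_0 q_1 + (1-q_0)(1-q_1)\big]
= \tfrac12 + \tfrac{q_0 - q_1}{2},$$

e.g. $0.90$ at $(0.9, 0.1)$. The estimated $\hat\Delta$ of a planted pair is
a difference of two binomial proportions, with standard error
$\sqrt{q_0(1-q_0)/n_0 + q_1(1-q_1)/n_1}$; the test suite uses 3-SE bands of
exactly this form wherever it compares estimates to planted truth, and the
same form (halved, by the identity above) for the CV-AUC check.

## Reproducibility and problem sizes

Every stochastic entry point takes a `seed`; `run_cv()` spawns per-iteration
sub-seeds from its master seed so all fold assignments are reproducible and
logged. Identical parameters and seed give bit-identical simulated datasets.

The test suite exercises the protocol at deliberately reduced sizes — CV
with 2–10 repetitions on 150–500 genes and 200–500 samples, recovery and
comparison experiments over 10–20 seeded replicates — chosen so the full
suite documents every claim it makes while running in minutes; the defaults
users get (`n_iter = 100`, `k = 10`, cohort-sized generator) are the
full-scale protocol.

## Known limitations

* The exhaustive pair search is quadratic in genes; at 6,100 genes
  (~18.6M pairs) a scoring pass is feasible but slow inside repeated CV —
  use the pre-filter, or fewer genes, for interactive work.
* The ridge fallback biases separated-fold coefficients toward zero by
  design; predictions (and hence AUC) are barely affected, but flagged
  coefficients should not be interpreted as unpenalised estimates.
* `percentile_ci()` over repeated-CV AUCs quantifies partition-resampling
  variability on one learning set, not sampling variability of the cohort;
  it should not be read as a population confidence interval.
* The t-test baseline implements one-gene-at-a-time selection with a fixed
  gene budget; stepwise model growth over p-value-ordered genes is out of
  scope.
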