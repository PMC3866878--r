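# tsplogit

Top-scoring pair logistic regression for binary phenotype prediction.

## What problem this solves

Clinical prognostic models for binary outcomes — the motivating case is
prostate cancer progression, *lethal* (death within 10 years of diagnosis)
versus *indolent* disease — are built from covariates such as age, Gleason
score, tumor percentage and ERG fusion status. Adding gene expression to such
models has historically helped little, partly because genes are screened one
at a time by per-gene tests, which are blind to expression patterns with no
marginal mean shift.

`tsplogit` implements the alternative: select **gene pairs** with the
rank-based top-scoring pair (TSP) statistic and combine them with clinical
covariates in a logistic regression, evaluated by repeated stratified
cross-validation with AUC-based model selection. For genes *u*, *v* the pair
statistic is

&nbsp;&nbsp;&nbsp;&nbsp;Δ<sub>uv</sub> = | p⁽⁰⁾<sub>uv</sub> − p⁽¹⁾<sub>uv</sub> |,
&nbsp;&nbsp; p⁽ᶜ⁾<sub>uv</sub> = (1/N<sub>c</sub>) Σ<sub>j : y_j = c</sub> I(x<sub>uj</sub> < x<sub>vj</sub>),

the absolute between-class difference in the frequency of the within-sample
ordering *x_u < x_v* (ties count as 0). Selected pairs enter the logit model

&nbsp;&nbsp;&nbsp;&nbsp;log p<sub>j</sub>/(1 − p<sub>j</sub>) = β₀ + Σ<sub>i</sub> β<sub>i</sub> x<sub>ij</sub>

as 0/1 ordering indicators by default, so the molecular part of the model is
invariant to any monotone per-sample transformation of expression. A
one-gene-at-a-time Welch t-test baseline at an equal gene budget, and a
synthetic-data generator that plants reversal pairs with exactly matched
per-gene marginals, complete the toolkit. The methods vignette
(`vignettes/tsp-logistic-models.Rmd`) documents every modelling and numerical
choice.

Intended users: computational biologists evaluating rank-based pair features
against single-gene selection in clinical+expression prognostic models, and
anyone needing a leak-proof repeated-CV harness with in-fold feature
selection.

## Worked example

```r
library(tsplogit)

# 300 genes x 200 samples; one planted reversal pair with ordering
# probabilities (q0, q1) = (0.9, 0.1), i.e. true delta = 0.8
sim <- simulate_tsp_dataset(n_samples = 200, n_genes = 300,
                            planted_pairs = data.frame(q0 = 0.9, q1 = 0.1),
                            seed = 42)

scores <- score_pairs(sim$expression, sim$labels)
head(scores, 3)
#> # A tibble: 3 × 7
#>   gene_u gene_v    p0    p1 delta tiebreak  rank
#>   <chr>  <chr>  <dbl> <dbl> <dbl>    <dbl> <int>
#> 1 g00125 g00022 0.872 0.142 0.731     5.82     1
#> 2 g00233 g00227 0.734 0.462 0.272    27.9      2
#> 3 g00138 g00148 0.734 0.491 0.243    22.2      3
```

The top-ranked pair is the planted one (`sim$truth`: g00125/g00022, true
delta 0.8; the estimate 0.731 reflects sampling noise at n = 200), and it
clears the best null pair by a wide margin. Combine it with the Gleason
score in a logistic model (the "model 1.3" covariate combination):

```r
panel  <- select_pairs(scores, k = 1)
spec   <- model_spec("gleason_score", n_pairs = 1, id = "1.3")
design <- build_design(sim$expression, sim$clinical, panel, spec)
fit    <- fit_logit(design, sim$labels)
tidy(fit)
#> # A tibble: 3 × 5
#>   term          estimate std.error statistic  p.value
#>   <chr>            <dbl>     <dbl>     <dbl>    <dbl>
#> 1 (Intercept)     -5.06      1.72      -2.95 3.21e- 3
#> 2 gleason_score    0.968     0.238      4.06 4.85e- 5
#> 3 tsp1            -3.74      0.458     -8.17 3.17e-16
```

Both covariates carry signal: each extra Gleason grade adds ~0.97 to the
log-odds of the lethal class, and showing the class-0-typical ordering
(`tsp1 = 1`) subtracts 3.74. The honest performance estimate comes from
repeated stratified CV, with the pair re-selected inside every training
fold:

```r
cv <- run_cv(sim$expression, sim$clinical, sim$labels, spec,
             n_iter = 10, k = 10, seed = 43)
cv
#> <tsp_cv> model 1.3 | tsp selector | 10 x 10 -fold
#>   mean AUC 0.914  [0.911, 0.916] (pooled, 95% percentile)
```

`enumerate_model_specs()` builds the full 16-model grid of clinical
covariate subsets, `run_cv_grid()` cross-validates all of them, and
`finalize_model()` picks the best by mean CV AUC, refits on the full
learning set and reports the AUC on a held-out validation split
(`stratified_split()`). `autoplot()` methods and `plot_cv_grid()` /
`plot_pair()` visualise results; `read_expression()` / `read_clinical()`
ingest the tab-delimited / CSV file formats; `inst/cli/tsplr` exposes the
pipeline (`simulate`, `score-pairs`, `fit`, `cv`, `evaluate`) from a shell.

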