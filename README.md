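# tpcmeta

Bayesian meta-analysis of thermal performance curve (TPC) evolution from
experimental thermal-selection studies.

Ectotherm fitness is a unimodal, negatively skewed function of temperature.
Experimental evolution and artificial selection studies measure these
curves before and after selection at a new temperature, which makes the
evolutionary response directly quantifiable: the fitness of the derived
line relative to its ancestor or control, at every assay temperature.
`tpcmeta` is for researchers synthesising such studies. It turns a flat
table of extracted assays into effect sizes with propagated uncertainty,
fits multilevel measurement-error models over the standard analysis
designs, ranks candidate models, decomposes heterogeneity, and screens the
usual failure modes of a meta-analysis (collinear moderators, publication
bias) — with a synthetic experiment generator so the whole pipeline runs
and is tested without external data.

## The model

Relative fitness is computed per reproduction mode
(selection-coefficient formulations):

| mode | effect size | propagated SE |
|---|---|---|
| discrete generations | $f_s/f_a - 1$ | $\|f_s/f_a\|\sqrt{(\delta f_s/f_s)^2 + (\delta f_a/f_a)^2}$ |
| continuous growth | $(f_s - f_a)\,G$ | $\sqrt{\delta f_s^2 + \delta f_a^2}\,G$ |
| binary fission | $(f_s/f_a - 1)\ln 2$ | discrete form $\times \ln 2$ |

Each effect $y_i$ then enters a hierarchical measurement-error model with
known sampling SE $s_i$:

$$y_i \sim \mathcal N(\theta_i, s_i^2),\qquad
\theta_i = \mathbf x_i^\top \boldsymbol\beta + u_{\text{species}(i)} +
u_{\text{study}(i)} \,(+\,u_{\text{tpc}(i)}),\qquad
u_\ell \sim \mathcal N(0, \sigma_\ell^2),$$

with moderators (variation source, generations, relative selection
temperature) and polynomials in the relative assay temperature
$\Delta T$ = assay − selection temperature as fixed effects. Candidate
models are ranked by WAIC; heterogeneity is reported as posterior
$\sigma^2_\ell$ and per-level $I^2$ computed draw-wise with the
Higgins–Thompson typical sampling variance. Sampling runs on JAGS via
`rjags`. See the methods vignette
(`vignettes/tpc-meta-analysis.Rmd`) for the full model, priors and design
choices.

## Worked example

Simulate a warm-selection experiment in which optima shift adaptively
(a niche-shift world), then run the at-selection analysis — the overall
direct response to selection:

```r
library(tpcmeta)

assays <- simulate_experiment(sim_scenario("shift", seed = 2024))
res <- run_analysis(assays, "at_selection",
  iterations = 30000, warmup = 1000, seed = 2024
)

res$ranking
#> # A tibble: 2 × 5
#>   model      waic p_waic delta_waic weight
#>   <chr>     <dbl>  <dbl>      <dbl>  <dbl>
#> 1 intercept -68.3   29.1     0       0.512
#> 2 var       -68.2   29.1     0.0964  0.488

tidy(res$best)
#> # A tibble: 3 × 6
#>   term        estimate std.error conf.low conf.high  rhat
#>   <chr>          <dbl>     <dbl>    <dbl>     <dbl> <dbl>
#> 1 (Intercept)   0.241     0.0512  0.133       0.338  1.00
#> 2 sd_species    0.0945    0.0646  0.00534     0.249  1.01
#> 3 sd_study      0.162     0.0369  0.108       0.250  1.00

res$heterogeneity$summary[, c("level", "I2_mean", "I2_lo", "I2_hi")]
#> # A tibble: 3 × 4
#>   level   I2_mean   I2_lo I2_hi
#>   <chr>     <dbl>   <dbl> <dbl>
#> 1 species    28.1  0.0778  74.8
#> 2 study      68.6 23.3     96.9
#> 3 total      96.7 94.0     98.7

res$bias$verdict
#> [1] "no consistent bias"
```

Reading the output: the posterior median relative fitness at the selection
temperature is 0.24 (95% compatibility interval 0.13–0.34) — selected
lines outperform their ancestors where selection happened, as the shift
scenario builds in. The intercept-only and variation-source models are
indistinguishable by WAIC (ΔWAIC ≈ 0.1). Nearly all variance (97%) is
true between-species/study heterogeneity rather than sampling error, and
the funnel regression finds no SE–effect association.

The other analyses run the same way: `"two_point"` (reaction norms,
$|\Delta T|$ predictor), `"multipoint"` (TPC shape, cubic polynomial in
signed $\Delta T$, where the shift scenario shows fitness lost below and
gained at and above the selection temperature), and
`"hotter_is_better"` (max-vs-max comparison). `autoplot(res$best)` draws
the prediction curve over the data; `autoplot(res$bias)` the funnel.

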