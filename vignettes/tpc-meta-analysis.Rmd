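---
title: "Meta-analysing thermal performance curve evolution with tpcmeta"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Meta-analysing thermal performance curve evolution with tpcmeta}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(tpcmeta)
library(dplyr)
```

## The problem

Ectotherm fitness is a unimodal, negatively skewed function of temperature
— the thermal performance curve (TPC): a gradual rise to an optimum,
followed by a rapid collapse toward a critical maximum. Whether and how
TPCs evolve under thermal selection is a central question for predicting
responses to warming. Experimental evolution and artificial selection
studies answer it directly: they measure fitness of ancestral (or control)
and derived lines across assay temperatures, before and after selection at
a new temperature.

`tpcmeta` implements a complete meta-analytic pipeline for such
experiments: selection-coefficient style effect sizes with propagated
uncertainty, Bayesian multilevel measurement-error models with moderators,
WAIC model ranking, multilevel heterogeneity decomposition, and the
standard screening diagnostics (moderator collinearity, funnel-plot
publication bias). A synthetic experiment generator with the same
hierarchical structure lets every stage run, and be tested, without any
external data.

## Effect sizes

The unit of analysis is *relative fitness* of the derived line against its
ancestor or control at a common assay temperature $T$, computed per
reproduction mode following the selection-coefficient formulations for
discrete generations, continuous growth and binary fission:

* discrete, non-overlapping generations:
  $s(T) = f_s(T) / f_a(T) - 1$;
* continuous growth rates, with generation time $G$:
  $s(T) = \left(f_s(T) - f_a(T)\right) G$ — the multiplication by $G$
  puts studies on different time scales on a common per-generation scale;
* binary fission: $s(T) = \left(f_s(T)/f_a(T) - 1\right)\ln 2$.

Uncertainty is propagated to first order assuming uncorrelated errors in
the two means: for the ratio-based modes
$\delta s = |f_s/f_a| \sqrt{(\delta f_s/f_s)^2 + (\delta f_a/f_a)^2}$
(times $\ln 2$ for fission), and for continuous growth
$\delta s = \sqrt{\delta f_s^2 + \delta f_a^2}\, G$. The first-order
(delta-method) form is accurate to well under 3% whenever the relative
errors $\delta f / f$ stay below about 0.1; the test suite verifies this
against large Monte-Carlo simulations. Reported standard deviations are
converted to standard errors by $\mathrm{sd}/\sqrt{n}$ and 95%
confidence-interval half-widths by division with 1.96.

Ratio-based modes reject negative fitness means (growth rates, clutch
sizes and similar correlates are non-negative); continuous mode accepts
negative rates (declining populations). Three cleaning rules precede
modelling: relative fitness above 20 (an extraction outlier two orders of
magnitude above the typical effect) is removed, as are effects with a zero
or missing standard error, which cannot enter a measurement-error
likelihood.

## The measurement-error meta-analytic model

Each cleaned effect $y_i$ is treated as a noisy measurement of a true
effect with *known* sampling standard error $s_i$:

$$y_i \sim \mathcal{N}(\theta_i,\ s_i^2), \qquad
\theta_i = \mathbf{x}_i^\top \boldsymbol\beta
  + u_{\mathrm{species}(i)} + u_{\mathrm{study}(i)}
  \,(+\, u_{\mathrm{tpc}(i)}), \qquad
u_\ell \sim \mathcal{N}(0, \sigma_\ell^2).$$

This weights effects by study precision. Random intercepts for species and
study identity account for shared biology and within-study replication;
TPC identity is added for the two-point and multipoint analyses so that
independent TPC measurements are not pooled. We deliberately include no
additional residual level beyond the finest grouping: within-TPC residual
heterogeneity is absorbed by $\sigma^2_{\mathrm{tpc}}$ (and by
$\sigma^2_{\mathrm{study}}$ in the at-selection analysis, where each
effect is one TPC's single relevant assay). Phylogeny beyond the species
level is not modelled: with weakly related taxa an explicit phylogenetic
covariance adds nothing identifiable, and it is a documented non-goal.

Priors are vaguely informative on the effect-size scale, where relative
fitness rarely exceeds 2 in magnitude: $\mathcal{N}(0, 1)$ on the
intercept and on coefficients of centred predictors, and
$\mathrm{Exponential}(1)$ on the level standard deviations. Both are
configurable through `meta_model_spec(priors = ...)`, since reasonable
alternatives (half-normal scales, wider coefficient priors) should be easy
to try.

Sampling uses JAGS (Gibbs/slice sampling). Headline analyses use 30 000
iterations with 1000 warmup; because the conditionals of this
normal-normal hierarchy mix quickly, far shorter chains give stable
summaries, and the bundled tests and the acceptance script run at 2000 to
12 000 iterations with 2 or 3 chains. Convergence is monitored by
split-$\hat R$ on every coefficient and level SD; fits with
$\hat R > 1.05$ are flagged in `glance()` and with a warning, never
silently accepted. All sampling is seeded explicitly; a config plus a seed
reproduces a run exactly.

### Fixed-effect designs

Moderators are indicator-coded: variation source (de novo mutation vs
standing genetic variation, reference `standing`), the sign of the
selection temperature relative to the control regime (higher / lower /
equal), and the generation count (centred and scaled; because not all
studies report durations, models containing it are fitted on the reduced
data set and ranked separately — WAIC is only comparable within one data
set). The temperature predictor is the *relative assay temperature*
$\Delta T$ = assay − selection temperature. The multipoint (TPC-shape)
analysis uses raw powers of signed $\Delta T$ up to degree 3; raw rather
than orthogonal polynomials because the intercept is then directly the
effect at the selection temperature, which is the quantity of scientific
interest. The two-point analysis uses $|\Delta T|$, since with two assay
temperatures per TPC only the distance from the selection temperature is
comparable across studies. Interactions are supported only between the
variation-source indicator and the polynomial terms; the candidate sets
actually ranked are main-effects models.

### WAIC

Models are ranked by WAIC computed from the pointwise posterior
log-likelihood with the latent true effects integrated out analytically:
conditioning on the sampled random effects of every level in the design,
$y_i \sim \mathcal{N}(\mathbf{x}_i^\top\boldsymbol\beta_d + \sum_\ell
u_{\ell,d},\ s_i^2)$ per draw $d$. This keeps the pointwise likelihood
stable without storing per-effect latent draws. `waic()` uses log-sum-exp
throughout; ranking reports $\Delta$WAIC and Akaike-style weights
$w_m \propto \exp(-\Delta_m/2)$, and refuses to compare fits made on
different effect subsets.

## The four analyses

`run_analysis()` orchestrates them; each takes an assay table and returns
ranking, best-model summaries, heterogeneity and diagnostics.

1. **At-selection** (`rel_assay_temp == 0`): the overall direct response
   to selection, intercept model with a variation-source variant.
2. **Two-point**: TPCs assayed at exactly two temperatures; predictor
   $|\Delta T|$.
3. **Multipoint**: TPCs with three or more assay temperatures; signed
   polynomial models up to cubic, with variation-source and sign
   variants.
4. **Hotter is better**: for TPCs with more than three assay
   temperatures, the maxima of the two curves are compared directly —
   relative fitness of $\max_T f_s(T)$ vs $\max_T f_a(T)$, with the SE
   propagated from the dispersions at the two argmax points. Ties in a
   maximum resolve to the lower temperature (the conservative choice for
   a hypothesis about heat: it never manufactures a warm shift).

A temperature-equality tolerance of 0.25 °C is used both for
"assayed at the selection temperature" and for the sign moderator:
digitised temperatures carry rounding, and 0.25 °C is well below any
biologically meaningful assay spacing while absorbing one-decimal
rounding. The same reasoning applies to both uses, which is why the sign
comparison is not an exact equality either.

## Heterogeneity

The posterior of each $\sigma^2_\ell$ is summarised directly, and the
sampling-error share is expressed through $I^2$ computed per draw:

$$I^2_\ell = \frac{\sigma^2_\ell}{\sum_m \sigma^2_m + \tilde s^2}
\times 100,$$

with the Higgins–Thompson typical sampling variance
$\tilde s^2 = (k-1)\sum w_i / \left((\sum w_i)^2 - \sum w_i^2\right)$,
$w_i = 1/s_i^2$ (the `metafor` convention; the estimator is configurable
in principle, and collapses to $s^2$ under equal standard errors). Level
contributions add to the total exactly within every draw. Summaries emit
both posterior means and medians with 95% intervals, clearly labelled,
because reporting conventions differ between effects (medians) and $I^2$
(means).

## Diagnostics

*Collinearity.* Binary moderator pairs are screened with the tetrachoric
correlation: the maximum-likelihood correlation of a latent bivariate
standard normal dichotomised at thresholds reproducing the margins. The
bivariate normal CDF is evaluated by numerically integrating the
conditional-normal form (accuracy near $10^{-6}$); the likelihood is
maximised over $\rho \in (-0.999, 0.999)$. Tables with a zero cell sit at
the boundary of the parameter space and return $\pm 1$ with a flag rather
than a continuity-corrected interior value — explicit behaviour over a
silent correction. Binary-continuous pairs use the point-biserial
correlation (the quantity the commonly used software computes under the
name "biserial"; the strict latent-normal biserial estimator is not
implemented, and the divergence is deliberate and documented here). Pairs
with $|r| > 0.7$ are flagged and one representative per cluster retained,
preferring variation source and generations — jointly estimating nearly
collinear moderators is not meaningful.

*Publication bias.* `bias_test()` refits the multilevel model with the
effect's centred standard error added as a fixed moderator (an
Egger-style multilevel regression keeping the main analysis's random
effects). The verdict is "no consistent bias" exactly when the slope's
95% interval covers zero; with no spread in the standard errors the slope
is unidentifiable and said so. Funnel coordinates are returned for
plotting (`autoplot()`).

## The synthetic generator

`simulate_experiment()` emulates the statistical structure of an
extracted assay table, not any particular biology:

* a species → study → TPC → assay-point hierarchy, with ancestor curve
  parameters perturbed at species and study level and a small TPC-level
  performance perturbation, so all three variance components are real;
* unimodal, left-skewed TPCs: Gaussian rise
  $r_{\max} e^{-((T - T_{opt})/(2\sigma_r))^2}$ below the optimum,
  quadratic fall to zero at $T_{\max}$ above it. The analyses never fit
  this form; any continuous, negatively skewed unimodal curve would do,
  and the shape is configurable;
* scenario transformations of the derived curve encoding the classical
  hypotheses (optimum shift; shift plus height gain, "hotter is better";
  width-height trade-off, "generalist-specialist"; widening with
  preserved maximum, "hotter is wider"; and a null);
* heteroscedastic errors from replicate simulation
  ($\mathcal{N}(\text{curve}, \sigma_{noise})$, reported as means with
  sd, se or CI half-width over `replicate_count` replicates), so the
  dispersion-normalisation path is exercised;
* moderators that co-vary realistically: unicellular systems reproduce
  by fission or continuous growth, rely on de novo variation and
  ancestor comparisons, sexual multicellular systems the opposite —
  which reproduces the strong moderator collinearity that motivates the
  screening step; about 12% of studies omit the generation count;
* assay designs mixed as in the literature (roughly 17% selection
  temperature only, 38% two temperatures, 45% multi-temperature).

Defaults (10 species × 2 studies × 2 TPCs, assay offsets −8…+4 °C, +3 °C
warm selection, curve height near 1 with replicate noise 0.05, 5
replicates) give a few hundred assay points across tens of studies — the
same order as a real systematic extraction, with effect sizes and
standard errors on the scale the priors assume.

What the generator does **not** emulate: digitisation error from figure
extraction, non-normal replicate noise, phylogenetic correlation between
species beyond the species level, correlation between the two lines'
errors (propagation assumes independence, as does the extraction), or
selection-biased reporting. Passing tests therefore demonstrate that the
machinery recovers what it assumes, not that those assumptions hold in
any particular literature.

`simulate_effects_direct()` is the generative twin of the fitted model
itself (known $\mu$, $\boldsymbol\beta$, $\sigma_\ell$, heteroscedastic
$s_i$) and is the right tool for parameter-recovery and model-selection
simulations, where generator and model must coincide exactly.

## Numerical and design choices

* Degenerate inputs fail loudly with row identity: zero ancestor fitness
  in ratio modes, missing generation time for continuous reproducers, sd
  dispersion without a replicate count, unknown enum levels.
* Missing values are empty fields / `NA`, never sentinels.
* `normalize_dispersion()` and `apply_exclusions()` are idempotent, so
  pipelines can be re-entered safely.
* The two-point / multipoint split partitions TPCs by their number of
  distinct assay temperatures (exactly 2 vs ≥ 3); the at-selection subset
  cuts across it.
* Problem sizes in the tests and acceptance script (for example 20
  recovery replicates of 200 effects at 2500 iterations, ranking checks
  with 10 replicates of 300 effects) were chosen as the smallest designs
  at which the checked properties are comfortably identified; they are
  package choices, not statements about the machinery's limits.
* Model configurations, rankings and summaries serialise to plain CSV and
  JSON (`run_analysis(outdir = ...)`), with a run log recording seeds and
  settings so every report is regenerable.

## Known limitations

* Prior families are fixed at normal (coefficients) and exponential
  (level SDs); scales are configurable, families are not.
* The general interaction algebra among moderators is limited to
  variation-source × temperature terms.
* Leave-one-out cross-validation, non-normal likelihoods, alternative
  effect sizes (log response ratio, Hedges' g) and frequentist REML
  heterogeneity estimation are out of scope.
* The Egger-style bias model inherits the main analysis's random-effect
  structure; other bias-model variants (e.g. $\sqrt{s_i}$ moderators)
  are not implemented.
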