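---
title: "Bayesian probabilistic recommendation in multi-harvest trials: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian probabilistic recommendation in multi-harvest trials: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(harvestprob)
```

## The problem

A perennial variety trial measures the same plants repeatedly: each of $I$
genotypes is planted in $J$ complete blocks and yields are recorded at $K$
harvests.  Two features dominate such data.  First, genotype performance is
not constant over harvests — the genotype-by-harvest interaction (GHI)
reshuffles rankings from one season to the next.  Second, residual
variability is strongly non-stationary: as trees mature and yields climb,
the residual variance can grow by two or three orders of magnitude.  A
recommendation must therefore address *which genotypes yield most*, *which
fluctuate least*, and *how sure we are* about both — the last point being
exactly what a posterior distribution provides and a point estimate does
not.

## The hierarchical model

`harvestprob` fits, by MCMC, the conditional normal model

$$y_{ijk} \sim N(\mu + g_i + r_j + h_k + gh_{ik} + p_{ij},\ \sigma_{(k)})$$

where $g_i$ is the genotypic effect, $r_j$ the block effect, $h_k$ the
harvest effect, $gh_{ik}$ the interaction and $p_{ij}$ the permanent
environment effect of the plot (a genotype-block combination, constant
across harvests — it captures everything that plot contributes to every
measurement made on it).  Two residual structures are supported:

* **B-ID** — a single residual scale $\sigma$ (homogeneous);
* **B-DG** — one residual scale $\sigma_k$ per harvest (diagonal), the
  structure suited to maturing orchards.

Every effect vector has an exchangeable zero-mean normal prior with its own
scale parameter, and every scale parameter — including the residual
scale(s) and the intercept's — has a half-Cauchy$(0, \varphi)$ hyperprior.
Priors are parameterized by *scale* (standard deviation); variances such as
$\sigma^2_g$ are derived quantities, and that is the scale on which HPD
intervals for variance components are reported.  The global hyperscale is
$\varphi = 10\max(y)$ by default: heavy-tailed enough that the data
dominate, proper enough to keep the posterior well defined.  No sum-to-zero
constraints are imposed; the grand mean absorbs location, weak location
trade-offs are resolved by the hierarchical shrinkage itself, and all
reported genotype *contrasts* are invariant to them.

### Sampling

The sampler is a blocked Gibbs scheme.  Effect blocks ($\mu$, $g$, $r$,
$h$, $gh$, $p$) have conjugate normal full conditionals under any fixed set
of scales, and each half-Cauchy scale is handled by the exact two-level
inverse-gamma representation
$\sigma^2 \mid a \sim \mathrm{IG}(1/2, 1/a)$,
$a \sim \mathrm{IG}(1/2, 1/\varphi^2)$,
which makes every scale update conjugate as well.  The representation is
itself unit-tested against the half-Cauchy law
(`rhalfcauchy_mix()`), the joint density is exposed analytically
(`log_posterior()`) and the sampler is validated against the normal-normal
closed form on the reduced intercept-only model — a genuinely independent
oracle, since the conjugate posterior is computed by formula, not by
sampling.  Defaults mirror common practice for this model class: 4 chains,
4000 iterations each, 50% burn-in, thin 1.  Chains are initialized
overdispersed and all randomness derives from one integer seed, so runs are
exactly reproducible.

## Diagnostics

* **Split $\widehat{R}$** per chain-halving, without rank normalization:
  each chain is split in half, $W$ is the mean within-sequence variance,
  $B = N \cdot \mathrm{Var}(\text{sequence means})$, and
  $\widehat{R} = \sqrt{((N-1)/N \cdot W + B/N)/W}$.  All-constant chains
  make the statistic undefined; the implementation returns `NaN` with a
  warning rather than silently reporting 1, and summary averages skip and
  count such sentinels.
* **WAIC2** with the variance-based effective-parameter penalty:
  $\mathrm{lppd} = \sum_n \log(\frac{1}{S}\sum_s e^{\ell_{sn}})$ (computed
  via log-sum-exp), $p_{\mathrm{WAIC2}} = \sum_n \mathrm{Var}_s(\ell_{sn})$,
  $\mathrm{WAIC2} = -2(\mathrm{lppd} - p_{\mathrm{WAIC2}})$; lower is
  better.  The variance penalty (rather than the mean-based one) is the
  form implied by the "2" suffix.
* **Posterior predictive p-values** for max, min, median, mean and sd, with
  inclusive counting: $p_T = \frac{1}{R}\#\{r : T(y^{rep}_r) \ge T(y)\}$.
  Replicates are drawn by ancestral sampling — residual noise added to the
  linear predictor of distinct retained draws.
* **HPD intervals** as the shortest contiguous window of sorted draws
  holding the requested mass, ties broken to the lowest-starting window
  (cross-checked against `coda::HPDinterval`).

A calibration caveat worth stating plainly: for a *correctly specified*
model, posterior predictive p-values concentrate near 0.5 only for
statistics the model adapts to tightly (mean, sd, median here).  For
extreme order statistics (max, min) the p-value is close to uniformly
distributed across datasets, so individual values near 0.1 or 0.9 for those
two statistics are unremarkable and not evidence of misfit.  The package's
own replicate studies show exactly this pattern, and it bounds what any
"all five p-values near 0.5" expectation can deliver.

## Selection probabilities

All probabilities are counting fractions over the $S$ retained draws —
rational numbers with denominator $S$, reported together with their integer
numerators so exact reproduction is testable.  Per draw $s$:

* rank genotypes by $g_i^{(s)}$; the top $n$ form the superior subset; the
  **probability of superior performance** of genotype $i$ is the fraction
  of draws in which it is a member.  With $n=4$ of 24 genotypes this is the
  16% selection proportion typical of advanced trials; `n_selected` is the
  deliberate knob, and every marginal probability is non-decreasing in it.
* rank genotypes by the per-draw GHI variance
  $\mathrm{var}_k(gh_{ik}^{(s)})$ (divisor $K-1$); the $n$ smallest form
  the stable subset; membership frequency is the **probability of superior
  stability**.
* **pairwise** probabilities count strict wins $g_i^{(s)} > g_{i'}^{(s)}$
  (or strict variance ordering for stability); the diagonal is masked, and
  an entry plus its transpose is 1 absent exact ties.
* **within-harvest** variants rank $g_i^{(s)} + gh_{ik}^{(s)}$ per harvest
  (the harvest main effect is common to all genotypes and cancels in
  ranking).  For within-harvest *stability* the target quantity is a
  dispersion of a single indexed term, which admits no per-draw variance;
  the package uses the squared interaction magnitude $(gh_{ik}^{(s)})^2$ —
  the only per-draw, per-harvest dispersion available — preserving the
  smaller-is-more-stable semantics.  This is a documented interpretive
  choice, not a consensus definition.

Exact ties in any ranking (possible only for degenerate, e.g. hand-built,
draws) are broken by genotype input order: deterministic, documented, and
measure-zero for real MCMC output.  The entire module is verified, draw by
draw, against an independent naive-loop implementation; agreement is exact,
not approximate.

## Frequentist baseline

The F-DG model keeps the same mean structure with block and harvest fixed,
genotype, interaction and plot effects random, and a diagonal per-harvest
residual covariance.  Homogeneous fits use `lme4::lmer`; diagonal fits use
`glmmTMB` with a per-harvest dispersion model; both maximize the restricted
likelihood, and on balanced single-harvest data the REML genotypic variance
reproduces the ANOVA moment estimator $(MS_G - MS_E)/J$ to numerical
accuracy — the module's closed-form oracle.  Random effects are tested by
LRT with a $\chi^2_1$ reference (conservative at the variance boundary; no
mixture correction, matching common practice).  Note that the restricted
log-likelihood is defined only up to a constant depending on the
fixed-effects parameterization: variance components and LRT statistics are
invariant to the contrast choice, the raw log-likelihood is not.

**Persistence.** Per harvest the ideotype is the best genotypic value
$g_{\max,k} = \max_i(\hat g_i + \widehat{gh}_{ik})$; genotype $i$
accumulates $d_i = \sum_k (v_{ik} - g_{\max,k})^2$ and persistence is the
normalized reciprocal $P_i = (d_i + \varepsilon)^{-1} / \sum_{i'} (d_{i'} +
\varepsilon)^{-1}$ with $\varepsilon = 10^{-8}$ guarding the genotype that
*is* the ideotype everywhere ($d_i = 0$).  Using BLUPs of $g_i + gh_{ik}$
as the per-harvest genotypic values is an interpretive choice: a
per-harvest distance only makes sense if the genotypic value varies by
harvest.  The $P_i$ sum to 1 (a ×100 "percent" reading is also reported);
published persistence values on other scales are not comparable without
knowing their normalization, so the package sets no numeric expectation
there.  Persistence deliberately mixes performance and stability — a
genotype stable at a mediocre level sits far from the ideotype — so its
Spearman correlation with the purely dispersion-based Bayesian stability
probability is positive but moderate, strongest when genotypes differ
mainly in their interaction spread.

## The trial simulator

`simulate_trial()` generates the complete crossing from the additive model
with every effect drawn i.i.d. normal at user-specified true variances, and
records all drawn effects in a truth ledger.  The reference regime
(`truth_preset_heterogeneous()`) uses $\sigma^2_g = 2.44$,
$\sigma^2_{gh} = 0.76$, $\sigma^2_p = 0.26$ and per-harvest residual
variances from 0.91 to 492.71 kg²/tree² — magnitudes reported for mature
multi-harvest acid-lime yield trials, spanning the residual explosion that
motivates the diagonal models.  Quantities that are fixed (not estimated)
in that setting needed one-off choices, made once on field-realism grounds:
grand mean 40 kg/tree for mature plot means, block variance 0.5 (complete
blocks on commercial flat ground differ little), harvest variance 100
(seasonal and ontogenetic swings of roughly ±10 kg/tree).  An optional
masking rate drops records after generation to exercise unbalanced fits.

What the simulator deliberately does not emulate: spatial field trend
within blocks, genetic relatedness among candidates (no kinship
covariance), non-normal yield distributions, tree-level variation within
plots (data are generated at plot-mean level, as plot means are what such
trials analyse), serial correlation beyond the permanent plot effect, and
informative missingness.  Passing tests therefore demonstrate correctness
of the machinery and calibration *under the stated generative model*, not
robustness to those real-data departures.

## Numerical choices and problem sizes

* $\varphi$ resolves to $10\max(y)$ at model-build time; degenerate inputs
  (empty tables, missing labels, nonpositive scales) raise errors rather
  than propagate.
* Scale updates never collapse: conditional inverse-gamma shapes are at
  least 1 and scales strictly positive.
* The HPD window uses $\lceil mS \rceil$ spacings, clamped so mass
  $\to 1$ recovers the sample range.
* Validation studies in the test suite use 20 simulated replicates of the
  full 24 × 4 × 12 design with 4000 retained draws per fit (4 chains ×
  2000 iterations, 50% burn-in) — enough for stable coverage and
  model-selection counts while keeping a full run in minutes on one CPU;
  the same study, re-seeded, is what `scripts/acceptance.R` reports.
* Default seed 2015 (the reference trial's planting year) is recorded in
  all outputs; every derived stream (chains, replicates, stages of
  `run_pipeline()`) uses a distinct seed derived from the master seed.

## Known limitations

* The Gibbs sampler exploits conjugacy of the normal likelihood throughout;
  non-normal responses would require a different kernel and are out of
  scope, as are spatial corrections, kinship matrices and random-regression
  (e.g. Legendre polynomial) genotype trajectories.
* Location parameters ($\mu$, $h_k$ means) are only weakly identified and
  mix more slowly than contrasts; convergence summaries for the *scale*
  parameters are the meaningful fit diagnostics, and genotype contrasts are
  unaffected.
* Posterior predictive p-values for extreme statistics are approximately
  uniform under correct specification (see Diagnostics); treat only
  persistent values near 0 or 1 across statistics as misfit.
* With a single harvest the interaction and plot effects are structurally
  confounded with genotype and residual; `reml_fit()` drops them and says
  so, and the Bayesian within-harvest probabilities require at least two
  harvests for any variance-based stability measure.
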