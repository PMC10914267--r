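# harvestprob

Probabilistic genotype recommendation for perennial multi-harvest variety
trials.

Perennial fruit breeding evaluates candidate genotypes (for citrus, each
rootstock-scion combination is a candidate) through repeated harvests of the
same plants.  Performance fluctuates from harvest to harvest — the
genotype-by-harvest interaction (GHI) — and residual noise typically grows
by orders of magnitude as trees mature.  Picking winners from such data
means weighing *performance* (high yield) against *stability* (small
fluctuation across harvests), and quantifying the risk of each
recommendation.  `harvestprob` implements a fully Bayesian answer to that
question alongside the classical REML/BLUP baseline, for breeders and
biometricians analysing randomized complete-block trials with repeated
harvests.

## The model

For yield `y_ijk` of genotype *i* in block *j* at harvest *k*:

    y_ijk ~ N(mu + g_i + r_j + h_k + gh_ik + p_ij, sigma)      (B-ID)
    y_ijk ~ N(mu + g_i + r_j + h_k + gh_ik + p_ij, sigma_k)    (B-DG)

with genotype (`g`), block (`r`), harvest (`h`), interaction (`gh`) and
permanent-environment plot (`p`) effects, each with an independent zero-mean
normal prior and its own scale, and half-Cauchy(0, phi) hyperpriors on every
scale, `phi = 10 * max(y)`.  B-ID has one residual scale; B-DG one per
harvest.  Models are fitted by a blocked Gibbs sampler (conjugate effect
updates; exact inverse-gamma scale-mixture updates for the half-Cauchy
scales) and compared by WAIC2.  From the retained draws the package counts,
per posterior sample:

* **probability of superior performance** — how often genotype *i* ranks in
  the top `n` by `g_i` (marginally, pairwise against each peer, and within
  each harvest using `g_i + gh_ik`);
* **probability of superior stability** — how often genotype *i* is among
  the `n` with the smallest per-draw GHI variance `var_k(gh_ik)`.

The frequentist baseline (F-DG) fits the same structure by REML with fixed
block and harvest effects and per-harvest residual variances, tests random
effects by LRT, predicts genotype values by BLUP, and summarises ecological
stability by a persistence index `P_i` — the normalized reciprocal of each
genotype's squared distance to the per-harvest ideotype (best genotypic
value).  Bayesian and frequentist stability rankings are compared by
Spearman correlation.

## Worked example

```r
library(harvestprob)

sim <- simulate_trial(trial_design(), truth_preset_heterogeneous(), seed = 2015)
fit <- fit_bayes(sim$table,
                 bayes_config("diagonal", n_chains = 4, n_iterations = 2000,
                              seed = 2015))
diagnostics_report(fit, sim$table, n_replicates = 500)
#> WAIC2 6613.34 (lppd -3180.36, p_waic2 126.31); mean R-hat 1.059 (scales 1.012)
#> PPC p-values: max 0.504, min 0.056, median 0.396, mean 0.504, sd 0.574

hpd_interval(fit$sigma_g^2, 0.95)
#> 95.0% HPD: [0.767959, 3.19202]

probability_report(fit, selection_config(4))
#> Probability report (top 4 of 24 genotypes per draw, S = 4000)
#>   highest performance probabilities: G8 0.892, G10 0.814, G16 0.768, G14 0.635
#>   highest stability probabilities:   G19 0.345, G7 0.317, G1 0.260, G16 0.249

freq <- reml_fit(sim$table, "diagonal")
freq
#> REML fit (diagonal residuals)
#>   var_g 1.599  var_gh 0.6287  var_p 0.1572
#>   var_e: 1.181 1.045 0.9069 6.265 3.394 5.179 10.32 22.13 338.4 138.4 358.6 501.3
persistence_index(genotype_harvest_values(freq))
#> Persistence (sums to 1); most persistent: G8 0.604, G10 0.102, G16 0.099, G14 0.053
```

Reading the numbers: the simulated truth had genotypic variance 2.44, and
its 95% HPD above covers it; the per-harvest residual variances recovered
by REML span three orders of magnitude, matching the simulated regime.
G8 appears among the top four genotypes in 89% of posterior samples — a
low-risk recommendation; the highest stability probability is only about
0.35, i.e. no genotype is clearly the most stable.  `run_pipeline()` wires
all of the above (both Bayesian fits, WAIC2 selection, probabilities,
REML, persistence and the ranking comparison) into one seeded, manifested
run directory.

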