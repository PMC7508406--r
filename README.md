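# relaxsel

Phylogenetic multilevel meta-analysis of antipredator-trait trajectories
under relaxed selection.

When animals live alongside humans — in cities, in captivity, or under
domestication — predation pressure relaxes and the traits that once kept
them alive (flight-initiation distance, vigilance, alarm calling, stress
physiology) begin to change. `relaxsel` is for meta-analysts who have
assembled per-study trait measurements (means, SDs, sample sizes) across
generations of human contact and want to answer three questions:

1. **How fast does the mean antipredator response decline?** The mean
   trajectory is modelled as an inverse-decay curve
   *f(x) = y<sub>ini</sub> + k·aˣ* (asymptote *y<sub>ini</sub>*, total
   change *k*, per-generation decay factor *a*), fitted by CMA-ES on
   weighted mean absolute error.
2. **Does between-individual variability inflate and then contract?** The
   absolute coefficient of variation follows a Weibull baseline-plus-bump
   curve *f(x) = y<sub>ini</sub> + a·(k/λ)·u^(k−1)·e^(−u^k)* with
   *u = (x − t<sub>min</sub>)/λ* — variance released by relaxed selection,
   later removed by novel human-driven selection.
3. **Is the trajectory significant once non-independence is accounted
   for?** The fitted shape enters a Bayesian multilevel meta-regression
   (Gibbs-sampled, inverse-Wishart variance priors) as a single basis
   covariate, with study, species, phylogeny (Brownian correlation from an
   ultrametric tree) and trait-type random effects, observation weights,
   DIC ranking of life-history interaction models, multilevel I²
   heterogeneity partitioning and phylogenetic heritability
   H² = σ²<sub>phylo</sub>/(σ²<sub>phylo</sub> + σ²<sub>species</sub>).

A synthetic-data generator (`simulate_dataset()`) produces complete
datasets — records, life-history table, phylogeny, ground truth — with the
statistical structure the model assumes, so the whole pipeline is testable
end to end without any external data.

## Worked example

```r
library(relaxsel)
library(dplyr)

ds <- simulate_dataset(sim_config(seed = 42))
#> <sim_dataset> 440 records, 30 species, 20 studies

prep <- prepare_records(ds$records)   # filter, orient, shift, z-score, |CV|

fit <- fit_trajectory(
  transmute(prep, x = generation, y = standardized_mean, weight = weight),
  "inverse", seed = 1
)
fit
#> <traj_fit> inverse curve, weighted MAE = 0.094367 (5 restarts, seed 1)
#> <inverse_params> y_ini = -0.3576, k = 3.286, a = 0.8475

generations_to_asymptote(fit$params, fraction = 0.05)
#> [1] 18.10434
```

The decay factor of the generating truth (0.85) is recovered (0.8475);
on the standardized scale this population is within 5% of its asymptote
after about 18 generations. Is the trajectory significant once study,
species, phylogenetic and trait-type non-independence are modelled?

```r
post <- significance_of_fit(
  prep, fit, tree = ds$tree,
  config = mcmc_config(n_iter = 20000, burn_in = 2000, thin = 10,
                       n_chains = 2, seed = 2)
)
post
#>   term             type     estimate conf.low conf.high    pmcmc    ess significant
#> 1 (Intercept)      fixed    -0.350   -0.854     0.346    2.06e-1   15.9 FALSE
#> 2 basis            fixed     3.29     3.25      3.34     2.78e-4 3524.  TRUE
#> 3 sigma2_study     variance  0.00324  0.00129   0.00759 NA       3069.  NA
#> 4 sigma2_species   variance  0.00546  0.00176   0.0149  NA       2139.  NA
#> 5 sigma2_phylogeny variance  0.00736  0.00205   0.0213  NA       1703.  NA
#> 6 sigma2_trait_ty… variance  0.632    0.00427   3.02    NA       1767.  NA
#> 7 sigma2_residual  variance  0.447    0.391     0.513   NA       3600   NA
```

The basis slope (3.29, CI well away from zero, pMCMC ≈ 3e-4) confirms the
inverse-decay trajectory; the intercept is the asymptote on the
standardized scale. Heterogeneity partition and phylogenetic heritability
from the same posterior:

```r
posterior_partition(attr(post, "mcmc"))
#>   level     estimate conf.low conf.high
#> 1 study        0.701    0.280     1.66
#> 2 species      1.18     0.381     3.13
#> 3 phylogeny    1.58     0.438     4.45
#> 4 residual    96.5     92.7      98.4
#> 5 H2           0.560    0.239     0.845
```

Residual variation dominates (as expected after within-study
standardization — see the vignette), and H² summarizes how much of the
species-linked variance tracks the phylogeny.

`run_pipeline()` chains all of the above per context (urbanization,
captivity, domestication) and per response (mean, CV), adds loess
exploration, DIC ranking of foraging-guild/sociality/longevity interaction
models, and writes the report bundle as plain-text tables with a
reproducibility manifest.

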