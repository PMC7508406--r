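---
title: "Modelling antipredator-trait trajectories under relaxed selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling antipredator-trait trajectories under relaxed selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

relaxsel implements a phylogenetic multilevel meta-analysis of how
antipredator traits change while animals live alongside humans — in cities,
in captivity, or under domestication. Contact with humans relaxes predation
pressure; the questions are how fast the *mean* of fear-related traits
declines across generations, how the *between-individual variability* (the
coefficient of variation, CV) first inflates and then contracts, and how
life history (foraging guild, sociality, longevity) modulates those
dynamics. This vignette explains the models, the choices behind the
implementation, and what the package's synthetic-data tests do and do not
demonstrate.

## Data model and preparation

The unit of analysis is one published measurement: a mean, an SD and a
sample size for one antipredator trait of one species in one study at a
known number of generations of human contact (for urban populations,
years since colonization divided by age at maturity — see
`compute_generations()`). Preparation follows a fixed order
(`prepare_records()`):

1. **Filters** (`apply_filters()`): records from lines selected *for*
   high fear are removed, dogs are removed (breed-level selection swamps
   the domestication signal), and every `(study, trait)` group must retain
   at least 2 values — a trajectory needs two points. Every dropped record
   is logged with a reason.
2. **Direction harmonization** (`harmonize_direction()`): traits measured
   on inverted scales (long escape latency = weak response) are multiplied
   by −1 so larger always means a stronger antipredator response.
3. **Shift to a non-negative baseline** (`shift_to_nonnegative()`): each
   trait group whose minimum is negative is shifted by |min| so its
   baseline is exactly 0. Groups already non-negative are not moved —
   an unconditional shift would displace already-positive traits for no
   reason, and leaves all pairwise differences unchanged either way.
4. **Standardization** (`standardize_within()`): within each
   `(context, study, trait)` group, values are centred and divided by the
   group *sample* SD (n − 1; small groups dominate these data). Groups
   with zero spread get z = 0 with a warning rather than being dropped,
   so their SDs stay available to the CV analysis.
5. **CV** (`compute_abs_cv()`): SD divided by the *raw* (oriented,
   pre-standardization) mean, in absolute value — the standardized group
   mean is 0 by construction, which would make a CV on the standardized
   scale undefined.

A consequence of step 4 worth stating explicitly: z-scoring removes all
between-group location and scale information. Study, species and
phylogenetic effects that act as pure intercept or amplitude shifts are
largely eliminated before the mixed model ever sees the data; what survives
is within-group *shape* and signal-to-noise. The variance components of the
fitted model should be read accordingly (they are typically residual-
dominated), and tests that probe variance-component recovery do so on the
oriented raw means, where that variance still exists.

## Trajectory models

The mean follows an inverse-decay curve
$$f(x) = y_{ini} + k\,a^x, \qquad 0 < a < 1,$$
with asymptote $y_{ini}$, total change $k$, and per-generation decay factor
$a$. Its derivative $k \ln(a) a^x$ is the per-generation rate of trait
loss; `generations_to_asymptote()` reports when the curve comes within a
fraction (default 5%) of its total change — the default is a choice of
convention, since "approximately reached" has no canonical definition.

The CV follows a baseline-plus-bump curve built from the Weibull density,
$$f(x) = y_{ini} + a\,\frac{k}{\lambda}u^{k-1}e^{-u^k}, \qquad
u = \frac{x - t_{min}}{\lambda},$$
rising after onset $t_{min}$ and then declining — the signature of variance
released by relaxed selection and later removed by novel (human) selection.
For $x < t_{min}$ the curve equals $y_{ini}$: the bump is defined as zero
before onset, which avoids fractional powers of negative numbers and is the
$u \to 0^+$ limit for $k > 1$. With $a = 1$ the bump integrates to exactly 1
(it is a scaled density), a property the tests exploit as an oracle.

## Curve fitting

Both curves are fitted by minimizing the weighted mean absolute error with
CMA-ES (covariance matrix adaptation evolution strategy), a derivative-free
optimizer that is unbothered by the non-smooth MAE objective. The
implementation is the standard (mu/mu_w, lambda) formulation with rank-one
and rank-mu covariance updates; population size $4 + \lfloor 3\ln d\rfloor$,
initial step 0.3 in transformed coordinates, at most 5,000 evaluations per
restart, stagnation tolerance $10^{-10}$, and 5 restarts with jittered,
data-driven initializations, keeping the best result. Box constraints are
imposed by smooth transforms — logistic for $a$, log for $k$, $\lambda$ and
$t_{min}$ — rather than rejection, so the covariance adaptation remains
well-behaved. Fits are exactly reproducible from the seed.

Loess exploration (`fit_loess()`, `select_smoothing()`) precedes the
parametric fit; it is local tricube-weighted polynomial regression (exact,
not interpolated), with the span chosen by in-sample MAE and ties going to
the smallest span.

## The Bayesian stage

The fitted curve's *shape* is frozen (the decay factor $a$; or $k, \lambda,
t_{min}$) and enters the multilevel model as a single basis covariate
($a^x$, or the Weibull bump). The model then estimates an intercept
(asymptote/baseline) and a slope on this basis:

$$y = X\beta + u_{study} + u_{species} + u_{phylo} + u_{trait\ type} + e,$$

with $u_{phylo} \sim N(0, \sigma^2_{phylo} A)$ for the Brownian-motion
species correlation matrix $A$ (shared root-to-MRCA path length over tree
height, from the ultrametric phylogeny), the other levels spherical, and
$\mathrm{Var}(e_i) = \sigma^2_e / w_i$. The slope's 95% credible interval
excluding zero is the significance test of the trajectory.

Inference is a plain Gibbs sampler — every full conditional is conjugate:
Gaussian for $\beta$ (flat prior) and each $u$ block, inverse-gamma for
each variance. The scalar inverse-Wishart prior (V = 1, degree of belief
0.02) is implemented as its univariate reduction, inverse-gamma(0.01, 0.01).
Reference settings are 1,000,000 iterations, burn-in 30,000, thinning 100,
and 5 chains; the pipeline default and all tests use scaled-down settings
(typically 3,000–20,000 iterations, burn-in 10–20%, thinning 3–10, 1–2
chains) chosen so that posterior summaries are stable at the effect sizes
the tests probe while the whole suite stays fast. Determinism is exact
given the seed; `pMCMC` is twice the smaller tail fraction, floored at one
over the number of retained draws so finite chains never report zero.

Two readings of "weighted by the inverse of the sample size" exist; taken
literally it *down*-weights precise estimates. The default here is
precision proportional to n (`weighting = "n"`), with `"inverse_n"`
available to reproduce the literal reading, and `"none"` for unit weights.

**DIC.** Model ranking uses DIC computed on the *marginal* likelihood —
random effects integrated out at the sampled variances — evaluated
efficiently through the Woodbury identity (a Q×Q solve per draw, Q = total
random-effect levels, rather than an n×n factorization). DIC weights are
$\exp(-\Delta_i/2)$ normalized. Two quirks are worth knowing: marginal-DIC
$p_D$ can be slightly negative when a skewed variance posterior makes the
plug-in point atypical, and a weakly identified variance component (see
below) contributes erratically to $p_D$. Neither affects the ranking
behavior the tests check.

**Weak identification of the trait-type variance.** The trait-type level
has only two categories (behavioral, physiological). With two levels, an
inverse-gamma(0.01, 0.01) prior and a global intercept in the model, the
posterior of $\sigma^2_{trait\ type}$ has a heavy right tail even when the
generating variance is zero: its posterior *mean* share of total variance
is typically 10–20% under the null, while the posterior *median* is close
to zero. `trait_class_effect_report()` therefore reports the full CI, and
the tests assert the median-based and null-versus-signal contrasts rather
than a small posterior mean.

## Heterogeneity

`partition_heterogeneity()` implements the multilevel I²: each level's
share of $\sum_l \sigma^2_l + \bar v$, with the typical sampling variance
$\bar v$ folded into the residual share so the four shares total exactly
100%. How $\bar v$ was computed in the original analysis is not stated;
the default here is $\bar v = 0$ (all residual spread treated as
heterogeneity), and the argument accepts any value, e.g.
$\hat\sigma^2_e \cdot \overline{1/w}$. Phylogenetic heritability is
restricted to the species-linked components,
$H^2 = \sigma^2_{phylo} / (\sigma^2_{phylo} + \sigma^2_{species})$, the
analogue of Pagel's λ. `posterior_partition()` computes both per retained
draw and summarizes with equal-tailed CIs.

Separating $\sigma^2_{phylo}$ from $\sigma^2_{species}$ requires replicate
studies per species *and* contrast in the tree correlations; with one study
per species the two are exchangeable and only their sum is identified (a
property one test verifies directly by setting $A = I$).

## The synthetic-data generator

`simulate_dataset()` draws records from exactly the structure the model
assumes: a pure-birth (Yule) tree rescaled to height 1; species, phylogeny
(jointly Brownian), study and trait-type intercepts; an inverse-decay mean
trajectory; residual noise with variance $\sigma^2_e / n$; and a reported
SD set so each record's |CV| follows the Weibull trajectory times lognormal
noise (multiplicative, keeping SDs positive — the original analysis has no
generative model for the CV, so this is the package's stand-in). Defaults
emulate the domestication context's scale: 30 species, 20 studies × 2
traits × 11 generations (0–100) = 440 records (the printed count is 437),
trajectory truth $(y_{ini}, k, a) = (0.3, 1.5, 0.85)$ and
$(y_{ini}, a, k, \lambda, t_{min}) = (0.8, 2, 2, 15, 0)$, random-effect
SDs 0.2–0.3, residual SD 0.3, sample sizes 5–50.

Two things the generator deliberately exposes about the method:

* **Amplitude interactions are invisible after standardization.** If a
  guild differs only in the amplitude $k$ and all studies share a
  generation grid, z-scoring removes the difference entirely; and because
  any smooth monotone decay correlates ≈ 0.98 with the common basis, pure
  *rate* differences barely move the per-group slopes either. What makes a
  group × generation interaction detectable in z-scored data is
  within-group signal-to-noise: a guild with a larger amplitude relative to
  residual noise has a visibly steeper standardized slope. The
  selection-consistency test therefore plants a strong two-guild amplitude
  contrast with realistic residual noise (SD 1.5, samples of 3–10).
* **The two-stage significance test is mildly anticonservative.** The
  basis shape is chosen by CMA-ES on the same data on which the slope is
  then tested — a selection over a one-parameter family of candidate
  regressors. Under a flat truth the slope's 95% CI excludes zero in about
  12% of replicates (measured over 110 simulations), not 5%; the Bayesian
  stage alone, with a fixed basis, is calibrated (it matches the analytic
  conjugate posterior to Monte-Carlo error). Users should read borderline
  significance of the trajectory accordingly. Power at a strong planted
  signal is essentially 100%.

What passing tests on this generator do **not** show about real data: the
generator cannot capture unmodelled heterogeneity (nonstationary decay,
publication bias, correlated trait batteries within studies, unequal
generation coverage across studies), so parameter-recovery results are
statements about the method's internal consistency, not about field
accuracy.

## Numerical choices and degenerate inputs

* Ultrametricity is validated to a relative tolerance of 1e−6;
  non-ultrametric trees are rejected unless terminal branches are
  stretched (`height_normalize = TRUE`).
* The phylogenetic correlation matrix gets a 1e−10 diagonal jitter before
  inversion; its construction guarantees positive semi-definiteness.
* A constant basis (all records at one generation) makes the design
  singular; `build_design()` rejects it naming the collinear columns.
  In the life-history model enumeration, a rank-deficient two-factor
  design (sociality confounded with guild in small datasets) drops the
  aliased columns with a warning instead, as `lm()` would.
* Zero-spread standardization groups yield z = 0 with a warning; zero
  means exclude a record from the CV analysis with a logged reason.
* Tie-breaks: equal-MAE spans resolve to the smallest span; DIC ties give
  equal weights.

## Scope and limitations

The package analyzes data it is given (or generates); it does not perform
literature retrieval, fetch trees from remote services, resolve polytomies,
or render the original figures beyond emitting the tables needed to draw
them. Life-history ranking runs by default only for contexts whose simple
mean-trajectory slope is significant (the original design), with
`force_lifehistory = TRUE` as an override. Exported functions, this
vignette and `scripts/acceptance.R` are the interface; there is no shell
command-line tool.
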