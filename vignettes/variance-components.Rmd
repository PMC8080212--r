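---
title: "Variance-component models for developmental cohorts: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Variance-component models for developmental cohorts: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(devgen)
```

# The models

## Univariate polygenic model

For a quantitative trait `y` measured on `N` related and/or unrelated
individuals with covariates `X` and relatedness matrix `K`,

$$y \sim \mathcal N\!\left(X\beta,\; \sigma^2_g K + \sigma^2_e I\right),$$

where `K` is either the expected relationship matrix from a pedigree
(twice the kinship coefficient) or an empirical genetic relatedness
matrix estimated from SNP dosages.  Narrow-sense heritability is
$h^2 = \sigma^2_g / (\sigma^2_g + \sigma^2_e)$.  The environmental
component absorbs everything that is not additive-genetic, including
measurement error; no attempt is made to separate the two.

`fit_polygenic()` maximizes the full likelihood (ML, not REML) because
likelihood-ratio tests across models with the same fixed effects define
all the inference in this package; REML likelihoods are not comparable
across different variance structures in the way these tests require.
Internally the trait and design are rotated into the eigenbasis of `K`,
component by component: the likelihood factorizes over the connected
components of `K`'s off-diagonal support (families, in a family
cohort), so the rotation costs a handful of tiny eigendecompositions
rather than one `N x N` one, and the profile likelihood in `h^2` is a
one-dimensional optimization in which the boundary `h^2 = 0` is exactly
attainable.  Significance of `h^2` uses the likelihood-ratio statistic
against the `h^2 = 0` null with the `1/2 chi^2_0 + 1/2 chi^2_1` mixture
distribution, the standard reference for a variance component tested on
the boundary of its space (the mixture is our choice; the source
workflow does not state its null).

## Bivariate model and genetic correlation

For two traits the stacked covariance has genetic blocks
$\sigma^2_{g1} K$, $\sigma^2_{g2} K$ and
$\rho_g \sigma_{g1} \sigma_{g2} K$, and environmental blocks that are
diagonal per individual with within-person cross-trait covariance
$\rho_e \sigma_{e1} \sigma_{e2}$.  The implied phenotypic correlation is

$$\rho_p = \rho_g \sqrt{h^2_1 h^2_2} + \rho_e \sqrt{(1 - h^2_1)(1 - h^2_2)},$$

an identity the fitted object satisfies by construction and the test
suite asserts to 1e-8.  Genetic correlations are only meaningful between
heritable traits, so the pipeline schedules bivariate fits only for
trait pairs passing the FDR-corrected heritability screen.  Subjects
missing one trait contribute through their observed entries (row
deletion per trait, not per pair).

## Gene x Age interaction

Two mechanisms let genetic influence vary over age in a cross-sectional
cohort.  First, the *magnitude* of genetic effects may change: the log
of the genetic variance is modelled as linear in age,
$\log \sigma^2_g(a) = \alpha_g + \gamma_g (a - \bar a)$, and likewise
$\log \sigma^2_e(a) = \alpha_e + \gamma_e (a - \bar a)$.  Second, the
genetic factors *themselves* may change, so that the trait is
imperfectly pleiotropic with itself across ages: the cross-age genetic
correlation decays as $\exp(-\lambda\,|a_i - a_j|)$ with
$\lambda \ge 0$.  The covariance between individuals i and j is

$$\Omega_{ij} = K_{ij}\,\sigma_g(a_i)\,\sigma_g(a_j)\,
  e^{-\lambda |a_i - a_j|} + \mathbb 1[i = j]\,\sigma^2_e(a_i).$$

Related pairs observed at different ages act as a pseudo-longitudinal
design: only they carry information about `lambda`, which is why the
synthetic cohorts used for recovery tests are family-rich.  `Omega` is
positive semi-definite by construction: the exponential age kernel is a
valid correlation matrix and the Schur product of PSD matrices is PSD.

Age is centred at the sample mean, so `exp(alpha_g)` is interpretable as
the genetic variance at the cohort's average age; the centring choice is
ours.  The decay enters as `exp(-lambda |da|)` with `lambda >= 0`, with
`lambda = 0` tested by the boundary mixture LRT; `gamma_g` and `gamma_e`
are interior parameters tested against `chi^2_1`.

Units: `gamma_g` and `gamma_e` are per year of age on the log-variance
scale; `lambda` is a per-year decay rate; ages are in years.

## Parameterization, optimization, and standard errors

Variances are optimized as logs, correlations through the Fisher z
transform, and `lambda` directly on `[0, 5]` with an L-BFGS-B bound (a
pin at the upper bound raises a warning).  Multi-start (3 seeded starts
for the variance-component fits, 5 for the factor models) guards
against local optima; starts derive from the univariate fits.  The
bivariate and Gene x Age likelihoods are evaluated in compiled code
that exploits the block structure of `K`: per-block Cholesky
factorizations with fixed effects profiled out by generalized least
squares in the same pass.  Standard errors come from central
finite-difference observed information on the transformed scale with a
delta-method back-transform; a parameter at its boundary gets an `NA`
standard error rather than a fabricated one.

A deliberate design point: the univariate model uses a pure-R
eigendecomposition path while the Gene x Age model uses the compiled
Cholesky path.  Constraining `gamma_g = gamma_e = lambda = 0` must then
reproduce the univariate log-likelihood through a completely different
numerical route, which the tests assert to 1e-6.

# The measurement model

## Tetrachoric correlations and the bifactor fit

Binary symptom items are modelled through a latent bivariate-normal
threshold model; `tetrachoric_matrix()` estimates each pairwise latent
correlation by inverting the orthant probability with probit thresholds
fixed at the pairwise-complete margins.  Items nobody (or everybody)
endorses carry no pairwise information and are excluded.

`fit_bifactor()` fits the confirmatory bifactor structure - one general
factor plus one specific factor per symptom domain, all orthogonal - by
unweighted least squares on the tetrachoric matrix.  ULS replaces the
weighted (WLSMV-style) estimator of the original workflow: both are
consistent for the same loadings, and ULS needs no fourth-order weight
matrix; fitted loadings are therefore comparable in pattern but not
digit-for-digit with a WLSMV fit.  Identification: factor variances are
fixed at 1 and each factor's largest-magnitude loading is made
positive.

Two numerical choices deserve note.  First, the fit is two-stage: a
ridge (0.25) on the specific loadings resolves a genuinely flat
direction - a lone within-domain specific loading has vanishing
pairwise products when its siblings are near zero, so the off-diagonal
objective cannot pin it and it otherwise soaks up correlated sampling
noise in the tetrachorics - and a second, unpenalized stage refits with
collapsed specifics pinned at zero, leaving surviving loadings
unbiased.  Second, the ULS solution lives on the standardized latent
scale (unit propensity variance); the returned model is rescaled to the
probit-regression metric (unit residual variance) so loadings,
thresholds, and the scoring likelihood share one parameterization; the
standardized solution is kept in `L_std`.

The hierarchical (second-order) variant lets the specific factors
correlate through their loadings on a second-order general factor; the
implied inter-factor correlation matrix is the outer product of those
loadings.  It exists to quantify how conclusions change when general
and specific variance is *not* parsed apart.

## Factor scores

`score_map()` scores subjects under the probit item likelihood.  The
default estimator is the posterior mean (EAP), computed exactly to
quadrature accuracy with the bifactor dimension-reduction identity:
conditional on the general factor the domains are independent, so the
five-dimensional integral collapses into nested one-dimensional
quadratures (41 nodes per dimension by default; the integrand is
smooth and the grid is generous — scores agree with a 200,000-draw
Monte Carlo integration to about 3e-3).  The posterior mode (`method = "map"`, damped Newton to
gradient norm below 1e-6 on a concave log posterior) is also available.

EAP is the default for a substantive reason.  Over the population,
posterior-mean scores satisfy
`Cov(scores) = Cov(prior) - E[posterior covariance]`, so their
cross-correlations reflect only the mean posterior coupling between
factors; posterior modes are additionally pulled jointly negative for
the many low-symptom subjects, inflating general-specific score
correlations.  Even for EAP, however, orthogonality of score columns is
a property of the *measurement design*, not of the estimator: when
every item loads on both the general factor and a specific factor with
all-positive loadings, the information cross-term makes the posterior
"explain away" the general factor against the specifics, and the
induced general-specific score correlation sits near 0.2-0.3 at
realistic endorsement rates regardless of item count.  Score columns
decorrelate (|r| well below 0.2) when the coupling is weak - for
instance when a substantial share of items mark the general factor
alone, the typical situation in a broad symptom bank.  The test suite
demonstrates both regimes; users should judge score orthogonality for
their own loading pattern rather than assume it.

# Trait preparation

Cognitive batteries are prepared the way the field's cohort pipelines
do: subjects missing at least half the battery are excluded; remaining
gaps are filled by chained-equation imputation with predictive mean
matching (per-column linear regressions on age, sex, and the other
tests; each missing cell takes the observed value of one of the `k = 5`
donors closest in predicted value; 10 iterations; a single completed
table, matching a workflow that analyses one imputed dataset).  PMM
trades point accuracy for distribution preservation - an imputed value
carries its donor's residual, so its RMSE is about `sqrt(2)` times the
multi-predictor residual SD, while the marginal distribution of the
column survives intact, which is what a downstream variance-component
model cares about.

Composites `g` (accuracy) and `gs` (speed) are first principal
components of the standardized accuracy and reaction-time columns,
sign-anchored so the named anchor column loads positively (for raw
reaction times the composite then increases with slowness - the
orientation is explicit rather than implied).  All traits pass through
the rank-based inverse normal transform (Blom offsets,
`qnorm((rank - 3/8)/(n + 1/4))`, average ranks for ties) before model
fitting.  Covariates are intercept, centred age, centred age squared,
sex, and the age x sex and age-squared x sex interactions - "their
interactions" is expanded to exactly those two, the only non-degenerate
products of the named terms.

# Relatedness

`kinship_from_pedigree()` implements the recursive (tabular) numerator
relationship algorithm; no installed package provides it.
`empirical_grm()` is the standardized-dosage estimator
$K_{ij} = M^{-1} \sum_m (x_{im} - 2p_m)(x_{jm} - 2p_m) / (2 p_m (1 -
p_m))$ with sample allele frequencies, pairwise-complete averaging over
missing dosages (unbiased under MCAR), and monomorphic SNPs skipped.
This deliberately replaces the hidden-Markov IBD estimator the source
workflow used: both estimate realized relatedness, and the HMM's LD
modelling buys little on a pruned panel at desk scale.  Before
estimation the panel is LD-pruned (`ld_prune()`, greedy left-to-right
within a sliding window, r-squared threshold 0.1) to approximate
linkage equilibrium.  `validate_grm()` reports symmetry, minimum
eigenvalue (PSD tolerance 1e-8), trace/N, and diagonal and off-diagonal
ranges; the range bounds are conventions and configurable, since no
numeric bounds are standard.

For model fitting on an empirical GRM, `threshold_grm()` zeroes
off-diagonal entries below a cutoff.  Unrelated-pair entries are
sampling noise of order `1/sqrt(M)`; the cutoff should be several times
that (the pipeline default, 0.125, is about 4.5 sigma at its 1,300-SNP
pruned panel).  This restores the family block structure over which the
likelihood factorizes; too low a cutoff chains unrelated individuals
into one giant block and the fits slow to dense-matrix cost.

# The synthetic cohort generator

The generators exist so every downstream stage can be tested end to end
without restricted data; their defaults are the study-like conditions.
A cohort is nuclear families (two founder parents plus children, ages
drawn uniformly on 8-21 for all members, one cross-sectional age per
person) plus unrelated singletons; the default composition (300
two-child families plus 800 singletons) is a choice, since the real
cohort's family composition is not public, and it is configurable.
Genotypes are gene-dropped: founder haplotypes drawn under
Hardy-Weinberg with one minor-allele frequency per LD block
(Uniform(0.05, 0.5)), within-block adjacent-allele copying with
probability 0.7 (sharing the block frequency keeps marginals intact;
there is no recombination map - blockwise copying is the simplest
mechanism that exercises LD pruning), and one independently segregated
allele per parent per SNP.  The default panel of 50,000 SNPs mirrors a
common-variant panel; tests use 2,000-5,000.

The default trait block sets the genetic variance share at 0.46 at the
reference age with per-year trends `gamma_g = -0.146` and
`gamma_e = 0.059` and decay `lambda = 0.027` - magnitudes reported for
externalizing psychopathology in the developmental-cohort literature -
so that a default simulated trait looks like the phenomenon the models
target.  The item bank is 112 items in four domains (34 anxious-misery,
30 externalizing, 26 fear, 22 psychosis-spectrum; the split is a
representative choice, as the real item-to-domain map is not in the
public text) with marginal endorsement targets 15%, 21%, 16%, and 11%;
thresholds are calibrated through the marginal probit integral,
`tau_j = -qnorm(target) * sqrt(1 + ||L_j||^2)`, because the targets are
marginal rates.  Cognitive batteries are generated with a configurable
genetic correlation (default -0.4) between latent ability and the
externalizing factor; in the pipeline's joint draw the decay `lambda`
is set to zero so the shared-genetic-factor construction stays exactly
PSD, while the variance trends `gamma_g` and `gamma_e` - the dominant
reported effects - are preserved.  Missing cognitive entries are MCAR
at rate 0.1.

What the generator does *not* emulate: realistic human LD maps,
ascertainment and screening effects, assortative mating, the X
chromosome, longitudinal repeat measurement, rater effects, or
population stratification.  Passing recovery tests on these cohorts
shows the estimators are correct under their own assumptions; it does
not show robustness to those unmodelled features of real data.

# Problem sizes and what the tests show

Recovery checks run at the scale a single CPU handles in minutes:
heritability recovery on 2,000 individuals over 20 replicates,
likelihood-ratio calibration with 400 null simulations at N = 500,
Gene x Age recovery on a relatives-rich N = 1,500 cohort, bivariate
recovery at N = 2,000, and measurement-model recovery with 24 items on
4,000 subjects.  Exact oracles back the numerics: every model
log-likelihood is checked against a dense multivariate-normal density
on hand-assembled toys to 1e-8, tetrachorics against a fixed-grid
Simpson orthant integration to 1e-3, LD pruning against an exhaustive
pairwise-r-squared scan, and pedigree kinship against a 10,000-locus
gene-dropping simulation.

Known limitations worth restating: ML variance components are biased
downward in small samples relative to REML (visible at N in the
hundreds); `lambda` estimates are boundary-inflated on average when the
truth is at or near zero; factor-score-based heritability is attenuated
by measurement error (scores correlating 0.8-0.9 with the latent factor
attenuate `h^2` by roughly the squared correlation), exactly as in the
real workflow; and bifactor score orthogonality depends on the loading
pattern, as discussed above.
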