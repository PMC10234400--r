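---
title: "Methods: trial adjustment, stability indices and genomic prediction in stabgen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trial adjustment, stability indices and genomic prediction in stabgen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stabgen)
```

# Scope

`stabgen` implements the analysis chain a breeding program uses to select
genotypes that combine high performance with environmental stability from
multi-environment trials (METs): adjustment of plot-level data to genotype
means, two complementary stability analyses (AMMI and Finlay–Wilkinson),
Bayesian whole-genome regression of both traits and stability indices,
cross-validation, and co-selection of top performers and top-stable
genotypes. A synthetic MET generator with a fully known generating process
makes every stage testable end to end without any external data.

# The models

## Plot-level adjustment (eBLUEs)

Plot data from a randomized complete block design (RCBD) repeated over
environments (location × harvest-year cells) are modelled with fixed
effects,

$$Y_{ijk} = \mu + G_i + E_j + B_{k|j} + GE_{ij} + e_{ijk},$$

fitted by ordinary least squares under sum-to-zero constraints
(`fit_single_year()`, `fit_multi_year()`). The reported adjusted mean
(empirical BLUE, the lsMEANS of trial reports) is $\hat\mu + \hat G_i$,
marginal over environments and blocks. On balanced complete data this
equals the genotype's raw mean and is computed directly; with missing
plots the observed-cell least-squares solution is used, falling back to
the minimum-norm (pseudoinverse) solution only for rank-deficient
designs. Connectivity of the genotype × environment layout is checked
explicitly because genotype contrasts are inestimable in disconnected
designs.

`estimate_h2()` treats genotype, environment, block-within-environment
and G×E as random. Balanced designs use the closed-form ANOVA estimators
(identical to REML there); unbalanced designs use EM-REML on Henderson's
mixed-model equations, stopping at a relative parameter change of 1e-8 or
5000 iterations, with the restricted log-likelihood tracked (it is
non-decreasing under EM, which the tests assert; the estimates agree with
`lme4` on unbalanced data to three decimals). Heritability is reported on
an entry-mean basis,

$$H^2 = \frac{\sigma^2_G}{\sigma^2_G + \sigma^2_{GE}/J + \sigma^2_e/(Jr)},$$

with $J$ environments and $r$ blocks. Trial reports rarely print an
explicit heritability formula, and several entry-mean variants exist, so
the choice is isolated behind `estimate_h2()` and can be swapped.

## AMMI stability

`ammi_decompose()` fits the additive-main-effects-and-multiplicative-
interaction model

$$Y_{ij} = \mu + g_i + e_j + \sum_{n=1}^{N} \lambda_n \gamma_{in}
\delta_{jn} + \rho_{ij}$$

by SVD of the double-centered interaction residual. All
$\min(g,e) - 1$ axes are retained internally so the reconstruction is
exact; the sum of squared singular values equals the interaction sum of
squares by construction, and both identities are enforced as tests.
Determinism across linear-algebra backends is obtained by making the
largest-magnitude element of each genotype-score column positive; axes
with numerically zero singular values get zero scores by convention, so
constant or purely additive tables decompose without error.

Genotype interaction scores are $s_{in} = \sqrt{\lambda_n}\,\gamma_{in}$.
Two per-genotype indices are computed (`ammi_stability()`):

* **SPC**, the sum of absolute scores over the retained axes
  $\sum_{n \le N} |s_{in}|$. Absolute values are used because a signed sum
  lets opposite-signed axis contributions cancel, which would let an
  unstable genotype masquerade as stable; with absolute values
  "lower = more stable" stays interpretable.
* **ASV**, the weighted length of the first two axis scores,
  $\sqrt{(SS_1/SS_2 \cdot s_{i1})^2 + s_{i2}^2}$ with $SS_n=\lambda_n^2$
  (the Purchase weighting). When $\lambda_2 = 0$ the weight is undefined
  and $|s_{i1}|$ is returned with a warning flag.

Under this score convention both indices are homogeneous of degree 1/2 in
the table (multiplying all means by $c$ multiplies the indices by
$\sqrt{c}$); rankings are unaffected by any positive rescaling.

The number of supported axes (`select_n_components()`) is tested against
the plot-level error variance carried forward from the adjustment stage.
Two rules are available. The default is a sequential residual F test in
the style of Cornelius: $N$ is the smallest $n$ for which the interaction
remaining after $n$ axes is no longer significant. Its type-I error is
nominal — on a pure-noise interaction it keeps zero axes with probability
$1-\alpha$ — which the test suite verifies by simulation. The classical
per-axis table (Gollob degrees of freedom $g + e - 1 - 2n$) is available
via `method = "gollob"`; it is reported for reference but is well known
to be liberal under the null, which is why it is not the default
selection rule. Either way the result is capped at 2 axes by default,
the usual working choice for stability indices over a handful of
environments.

## Finlay–Wilkinson regression

`fw_fit()` uses the classical two-step estimator stated in the field's
method descriptions: environment effects $\hat h_j$ are environment means
minus the grand mean, then each genotype's cell means are regressed on
$\hat h_j$ by OLS. The slope is reported as a deviation $b_i$ from 1, so
$b_i = 0$ is average responsiveness and $|b_i|$ is the stability index.
On any complete balanced table the genotype-mean of $\hat b_i$ is exactly
zero (the per-trait FW means of trial summaries). A genotype with a flat
response has fitted slope 0, i.e. $b_i = -1$, and is flagged
non-responsive. A Bayesian/shrinkage variant is deliberately not the
default: the two-step OLS is the estimator the method description
specifies; a ridge penalty on the slopes is exposed via `shrink` but off
by default.

## Bayesian whole-genome regression

Both samplers fit $y = \mu + X\beta + e$ by single-site Gibbs sampling
(compiled in C++, single-threaded, driven by R's RNG so `set.seed()`
makes chains bit-reproducible):

* **BRR** (`gibbs_brr()`): $\beta_j \sim N(0, \sigma^2_\beta)$ with a
  common variance — the infinitesimal-model prior.
* **BayesB** (`gibbs_bayesb()`): $\beta_j = d_j u_j$ with
  $P(d_j = 0) = \pi$; included effects carry per-locus variances with
  scaled-inverse-chi-square priors (marginally a scaled-t slab), and
  $\pi$ has a Beta prior updated from the inclusion counts. Posterior
  inclusion probabilities are reported per locus.

Hyperpriors follow the conventions of standard whole-genome-regression
software: prior scales are solved from an a-priori variance partition
`prior_r2` (default 0.5, split equally across effect groups), all
variance priors use 5 degrees of freedom, and the default chain is
30,000 iterations with 5,000 burn-in and thinning 5. Markers are
column-centered before sampling; the centering constant is folded back
into the reported intercept so that GEBV $= \hat\mu + X\hat\beta$ holds
exactly on the raw dosage scale (an all-zero genotype row returns
$\hat\mu$).

With the variances held fixed, the BRR posterior mean equals the ridge
solution $(X'X + \sigma^2_e/\sigma^2_\beta I)^{-1}X'(y-\mu)$ — the
test suite checks the sampler against that closed form to within
Monte-Carlo error. With the spike switched off ($\pi \to 0$) BayesB
collapses to a per-locus-variance ridge; on dense polygenic signals its
estimates correlate above 0.99 with BRR, while on very sparse signals
the heavier-tailed slab legitimately shrinks differently — the collapse
check is therefore formulated on dense-effect data.

## Single-, across- and multi-population models

For two breeding populations sharing a marker panel
(`build_pop_design()`, `fit_genomic()`):

* **SP** fits each population separately;
* **AP** stacks the populations with population intercepts and one
  shared effect vector $\beta_0$;
* **MP** adds block-diagonal population-specific effect blocks so that
  $\beta_{1j} = b_{0j} + b_{1j}$ and $\beta_{2j} = b_{0j} + b_{2j}$, each
  block with its own variance parameter.

MP nests AP: when no population-specific signal exists the two produce
GEBVs equal up to Monte-Carlo error, and when half the loci carry
specific effects MP's out-of-fold predictive ability at least matches
AP's in a majority of replicates — both behaviours are asserted on
matched simulations. The prior variance share is split equally across
the three MP blocks; this follows the equal-split convention used for
multiple model terms in standard software.

## Cross-validation and co-selection

`run_cv()` performs repeated k-fold cross-validation (default 10 folds,
5 repetitions, i.e. exactly 50 model fits), with folds stratified by
population and seeded per repetition; assignment is invariant to genotype
ordering because genotypes are sorted by id before the draw. Predictive
ability is the Pearson correlation between pooled out-of-fold GEBVs and
the observed values, reported as mean ± SD over repetitions.
`run_year_increment()` implements the year-ladder design: training
eBLUEs from the first $k$ harvest years predict the eBLUEs of held-out
later years, for $k = 1, 2, \dots$

`select_overlap()` intersects the top performance fraction (default 10%)
with the most-stable fractions by ASV and by $|b_i|$ (default 20% each).
Set sizes use `floor(n * frac)` with a minimum of 1 and ties broken by
genotype id, so selections are deterministic. Trait direction must be
declared per trait (yield-type traits: higher is better; disease
severity and maturation scores: lower is better); there is no silent
default because "best" is trait-dependent.

# The synthetic trial generator

`sim_config()` + `simulate_markers()` + `simulate_phenotypes()` generate
the study conditions the analyses assume: two clonal populations of 103
and 118 genotypes, biallelic SNP dosages sampled under Hardy–Weinberg
from per-locus frequencies in `maf_range`, 2 locations × 4 harvest years
(8 environments), RCBD with 3 blocks. The default marker panel is 56k
loci, matching a GBS panel after QC; the examples and tests use a few
hundred to a few thousand loci, which preserves every statistical
property being tested at a fraction of the cost.

Plot values are built as
$Y_{ijk} = \mu + g_i + h_j + B_{k|j} + GE_{ij} + b_i h_j + e_{ijk}$:

* genetic values $g_i = X\beta$ with dense-normal or spike-and-slab
  effects, population-specific deviations on a `prop_specific_effects`
  fraction of loci, standardized to unit variance so all other scales are
  in genetic-SD units;
* environment effects $h_j$ (SD `env_sd`, default 1 — environmental
  variance comparable to genetic variance, as MET variance-component
  tables typically show);
* a rank-`gxe_rank` bilinear interaction with orthonormal, sum-to-zero
  score columns (double-centered by construction) scaled to `gxe_sd`,
  default rank 2 — the two analysis lenses (AMMI and FW) get matched
  generating mechanisms and can each be validated against truth;
* FW slope deviations $b_i$ with SD `fw_slope_sd` (default 0.3, in the
  range of FW slope SDs that MET trait summaries report);
* residual variance solved analytically from `h2_target` (default 0.75,
  typical of yield and post-harvest traits in perennial trials) as
  $\sigma^2_e = \sigma^2_g (1 - h^2)/h^2$, so the realized plot-level
  signal-to-noise hits the target by construction. `h2_target = 0` is
  rejected as contradictory (it implies infinite residual variance).

Stability in real populations is partly heritable — otherwise genomic
prediction of stability indices would be meaningless — so the FW slopes
and the bilinear genotype scores are mixed marker-determined/environmental
with fraction `stab_h2` (default 0.5) of their variance explained by
fresh marker regressions.

What the generator deliberately does **not** emulate: linkage
disequilibrium and haplotype structure, pedigree relationships,
selection history, spatial field trend, and weather-driven environmental
covariance. Passing tests therefore demonstrate that the estimators
recover the generating quantities under the assumed model, not that real
coffee data satisfy those assumptions.

# Numerical choices

* Sum-to-zero contrasts everywhere in fixed-effects fits; pseudoinverse
  fallback only at rank deficiency.
* EM-REML: tolerance 1e-8 on relative parameter change, 5000-iteration
  cap, components floored at zero and flagged.
* SVD sign convention as above; singular values below
  $10^{-12}\lambda_1$ treated as zero.
* Two-way tables with missing cells: either drop incomplete genotypes
  (default) or EM-impute under the additive model (optionally with a
  low-rank interaction refinement); at interaction rank 0 the imputed
  value converges to the additive prediction $\mu + g_i + e_j$.
* QC: missingness > 50% removed first, then non-biallelic loci, then
  MAF < 1% (strict inequalities, so MAF = 0.010 survives); remaining
  missing dosages imputed by locus means, which preserves observed
  allele frequencies but yields fractional dosages.
* Samplers floor the residual variance at 1e-12 and guard zero-variance
  inputs, so constant responses collapse gracefully to the intercept.

# Problem sizes used in the shipped checks

The test suite and `scripts/acceptance.R` run entirely on synthetic
data at desk scale, chosen so each check is statistically decisive:
decomposition identities on 100 random 10×6 tables; the ridge oracle on
a 50×20 problem with a 30k-iteration chain; BayesB recovery on 20
replicates of n = 300, p = 500 with 5 large-effect loci at $h^2 = 0.8$;
MP/AP comparisons on 2 × 150 genotypes with 150 loci; cross-validation
contracts on 300–500 genotypes; and the year-ladder on 200 genotypes ×
8 years. The year-ladder check compares the multi-year end of the ladder
against the single-year start (and not adjacent steps) because increments
at the plateau are smaller than the sampling noise of a correlation at
these population sizes — the same plateau behaviour that real
year-increment analyses show.

# Known limitations

* The fixed-effects multi-environment fit materializes a dense design;
  it is meant for trial-sized data (hundreds of genotypes), not for
  thousands of environments.
* EM-REML is dense and intended for the moderate unbalanced designs
  that arise when plots are lost; heavily structured large data would
  want a sparse or average-information REML.
* BayesB treats $\pi$ as shared across loci; no annotation-informed or
  per-chromosome mixture is implemented.
* Stability indices are regressed on markers untransformed; if ASV is
  strongly right-skewed in an application a log transform may be worth
  exploring (not applied here because the method description regresses
  the indices as computed).
* The AP/MP machinery is written for two populations, the design the
  package targets; extending to more populations would generalize the
  block structure but is not implemented.
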