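# stabgen

Stability analysis and genomic prediction for multi-environment trials
(METs), aimed at perennial-crop breeding programs that want to select
genotypes combining **high phenotypic performance** with **environmental
stability** across locations and harvest years.

The package covers the full analysis chain:

1. **Adjustment** — fixed-effects models for RCBD trials repeated over
   environments, `Y = mu + G + E + B|E + GE + e`, fitted by OLS with
   sum-to-zero constraints; adjusted genotype means (eBLUEs / lsMEANS),
   variance components and entry-mean heritability
   `H2 = s2_G / (s2_G + s2_GE/J + s2_e/(J r))`.
2. **Stability** — AMMI (`Y_ij = mu + g_i + e_j + sum_n lambda_n
   gamma_in delta_jn + rho_ij`, SVD of the double-centered interaction)
   with the SPC and ASV indices and an F test for the number of axes; and
   Finlay–Wilkinson regression (two-step OLS of genotype responses on the
   environmental index, slope deviation `b_i` as the stability measure).
3. **Genomic prediction** — Bayesian ridge regression (BRR) and BayesB
   spike-and-slab Gibbs samplers (compiled, bit-reproducible under a
   seed) for `y = mu + X beta + e`, with single-population (SP),
   across-population (AP) and multi-population (MP: `beta_p = b0 + b_p`)
   parameterizations for two related breeding populations.
4. **Evaluation** — year-increment forecasting (train on the first k
   harvest years, predict held-out later years), repeated stratified
   k-fold cross-validation of traits and stability indices, performance ×
   stability correlations, and top-fraction co-selection overlap.
5. **Synthetic METs** — a generator with fully known truth (additive
   genetics from SNP dosages, bilinear and regression-type G×E, RCBD plot
   error, two related populations) so that every estimator is testable
   against its generating process.

## Worked example

```r
library(stabgen)

# a two-population trial: 25 + 30 clones, 300 SNPs, 2 locations x 2 years,
# 3 blocks, plot-level heritability 0.6
cfg <- sim_config(n_genotypes_per_pop = c(25, 30), n_markers = 300,
                  n_locations = 2, n_years = 2, n_blocks = 3,
                  h2_target = 0.6, seed = 7)
raw <- simulate_markers(cfg)
sim <- simulate_phenotypes(raw, cfg)
mk  <- qc_filter(raw)

# adjusted means and heritability
am <- fit_multi_year(sim$phenotypes, "SIM", unique(sim$phenotypes$year))
am
#> AdjustedMeans (scenario custom, trait SIM): 55 genotypes, 4 env, 3 blocks
#>   residual variance 0.7269 on 432 df; mean eBLUE 20.12
estimate_h2(sim$phenotypes, "SIM")
#> VarianceComponents (anova):
#>  sigma2_e sigma2_GE  sigma2_B  sigma2_G  sigma2_E
#>   0.72687   1.42965   0.12131   0.63695   1.80274
#>   entry-mean H2 = 0.604 (4 env x 3 blocks)

# stability per genotype from the environment-wise means
ph <- sim$phenotypes
ph$env <- paste(ph$location, ph$year, sep = ":")
cellm <- tapply(ph$value, list(ph$genotype, ph$env), mean)
st <- stability_summary(cellm, trait = "SIM", sigma2 = 0.73, nrep = 3)
head(st, 3)
#>   genotype trait       spc       asv fw_slope_dev fw_abs_slope asv_rank fw_rank
#> 1  P1_G001   SIM 0.6857838 0.6468885   -0.3191653    0.3191653       18      26
#> 2  P1_G002   SIM 1.3699014 2.0192143   -0.8747813    0.8747813       52      54
#> 3  P1_G003   SIM 0.7810375 1.0452268    0.6594864    0.6594864       29      52

# genomic prediction of the adjusted means (10-fold CV, 5 repetitions)
y  <- setNames(am$means$eblue, am$means$genotype)
cv <- run_cv(y, mk, genomic_config("BRR", n_iter = 2000, burn_in = 400),
             k = 10, reps = 5, seed = 1)
cv
#> PredictionReport (cv)
#>   predictive ability 0.164 (SD 0.062) over 10 x 5 fits

# who is both top-10% performer and top-20% stable?
select_overlap(y, st, direction = "higher")
#> SelectionOverlap: 55 genotypes; top 10% performance (higher better), top 20% stability
#>   set sizes: performance 5, ammi 11, fw 11
#>   intersections: perf_ammi 0, perf_fw 1, ammi_fw 3, all3 0
```

The numbers above are what the code prints under these seeds. The
heritability estimate recovers the simulated signal-to-noise (target
0.6); the cross-validated predictive ability is modest, as expected for
55 training genotypes whose adjusted means still carry strong G×E; the
overlap report gives the Venn-style counts used to pick
performant-and-stable genotypes. Larger panels raise the predictive
ability — the shipped checks demonstrate 0.99+ on noiseless signals at
n = 300 (see below).

The same chain runs as one call via `run_pipeline(default_run_config(...))`,
which writes TSV/JSON stage outputs plus a manifest (config, seeds, stage
timings, output checksums), and works from files
(`read_phenotypes()`, `read_markers()` for VCF or dosage TSV) as well as
from simulated inputs.

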