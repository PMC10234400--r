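# shared fixture builders; everything is generated in code at test time

# small two-population trial with known truth
small_trial <- function(seed = 1, ..., n_markers = 150) {
  cfg <- sim_config(n_genotypes_per_pop = c(25, 30), n_markers = n_markers,
                    n_locations = 2, n_years = 2, n_blocks = 3,
                    h2_target = 0.6, seed = seed, ...)
  mk <- simulate_markers(cfg)
  sim <- simulate_phenotypes(mk, cfg)
  list(cfg = cfg, markers = mk, phen = sim$phenotypes, truth = sim$truth)
}

# complete genotype x environment table with controlled structure
toy_table <- function(g = 10, e = 6, seed = 1, noise_sd = 1) {
  set.seed(seed)
  tab <- matrix(rnorm(g * e, sd = noise_sd), g, e,
                dimnames = list(sprintf("G%02d", seq_len(g)),
                                sprintf("E%d", seq_len(e))))
  tab
}

# long-format plot records for hand-built designs
plot_records <- function(genotype, location, year, block, value,
                         trait = "Y") {
  data.frame(genotype = genotype, location = location, year = year,
             block = block, trait = trait, value = value,
             stringsAsFactors = FALSE)
}

# additive two-way table mu + g_i + e_j
additive_table <- function(g_eff, e_eff, mu = 0) {
  outer(g_eff, e_eff, "+") + mu
}
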