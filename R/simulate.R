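#' Configuration for the synthetic multi-environment trial generator
#'
#' Bundles every knob of the synthetic trial: population sizes, marker panel,
#' trial design (locations x years x blocks), plot-level heritability, and
#' the two genotype-by-environment mechanisms (a low-rank bilinear term and a
#' Finlay-Wilkinson regression term). Defaults emulate a two-population
#' perennial-crop trial: clonal populations of 103 and 118 genotypes, ~56k
#' biallelic SNPs, 2 locations x 4 harvest years (8 environments), and an
#' RCBD with 3 blocks per environment.
#'
#' Genetic values are standardized to unit variance, so `env_sd`, `gxe_sd`
#' and `block_sd` are expressed in genetic-standard-deviation units. The
#' plot-level residual variance is solved from `h2_target` as
#' `varE = varG * (1 - h2) / h2`, so the realized plot-level
#' signal-to-noise matches the requested heritability by construction.
#'
#' @param n_genotypes_per_pop integer vector of population sizes (recycled to
#'   `n_pops`).
#' @param n_pops number of populations (1 or 2).
#' @param n_markers number of biallelic SNPs.
#' @param maf_range allele-frequency range `(lo, hi]` within (0, 0.5] that
#'   per-locus frequencies are drawn from.
#' @param n_locations,n_years,n_blocks trial design; environments are the
#'   full `location x year` cross.
#' @param h2_target plot-level narrow-sense heritability in (0, 1].
#' @param gxe_rank rank of the bilinear (AMMI-type) interaction term; 0
#'   disables it.
#' @param fw_slope_sd standard deviation of the simulated Finlay-Wilkinson
#'   slope deviations `b_i`; 0 disables the regression-type interaction.
#' @param prop_specific_effects fraction of loci whose effects carry a
#'   population-specific component on top of the shared effect.
#' @param effect_prior distribution of marker effects: `"normal"` (dense,
#'   infinitesimal-like) or `"spike_slab"` (most loci have zero effect).
#' @param pi_zero probability a marker effect is exactly zero
#'   (`spike_slab` only).
#' @param mu overall trait mean (trait units).
#' @param env_sd standard deviation of environment main effects.
#' @param gxe_sd standard deviation of the bilinear interaction values.
#' @param block_sd standard deviation of block-within-environment effects.
#' @param missing_rate fraction of marker dosages set missing, completely at
#'   random.
#' @param stab_h2 heritability of the stability mechanisms: the fraction of
#'   variance in the FW slope deviations and in the bilinear genotype scores
#'   that is explained by markers. With 0, stability is purely
#'   environmental; with values above 0, stability indices become partly
#'   predictable from genotypes, which is what makes genomic prediction of
#'   stability a meaningful target.
#' @param seed RNG seed or `NULL`.
#' @return An object of class `SimulationConfig` (a validated list).
#' @export
sim_config <- function(n_genotypes_per_pop = c(103L, 118L),
                       n_pops = 2L,
                       n_markers = 56000L,
                       maf_range = c(0.01, 0.5),
                       n_locations = 2L,
                       n_years = 4L,
                       n_blocks = 3L,
                       h2_target = 0.75,
                       gxe_rank = 2L,
                       fw_slope_sd = 0.3,
                       prop_specific_effects = 0.5,
                       effect_prior = c("normal", "spike_slab"),
                       pi_zero = 0.5,
                       mu = 20,
                       env_sd = 1,
                       gxe_sd = 1,
                       block_sd = 0.3,
                       missing_rate = 0,
                       stab_h2 = 0.5,
                       seed = NULL) {
  effect_prior <- match.arg(effect_prior)
  n_pops <- as.integer(n_pops)
  n_genotypes_per_pop <- as.integer(rep_len(n_genotypes_per_pop, n_pops))
  cfg <- list(
    n_genotypes_per_pop = n_genotypes_per_pop, n_pops = n_pops,
    n_markers = as.integer(n_markers), maf_range = as.numeric(maf_range),
    n_locations = as.integer(n_locations), n_years = as.integer(n_years),
    n_blocks = as.integer(n_blocks), h2_target = h2_target,
    gxe_rank = as.integer(gxe_rank), fw_slope_sd = fw_slope_sd,
    prop_specific_effects = prop_specific_effects,
    effect_prior = effect_prior, pi_zero = pi_zero, mu = mu,
    env_sd = env_sd, gxe_sd = gxe_sd, block_sd = block_sd,
    missing_rate = missing_rate, stab_h2 = stab_h2, seed = seed)
  counts <- c(cfg$n_genotypes_per_pop, cfg$n_pops, cfg$n_markers,
              cfg$n_locations, cfg$n_years, cfg$n_blocks)
  if (any(counts < 1L)) stop("all counts must be >= 1")
  if (length(cfg$maf_range) != 2L || cfg$maf_range[1] >= cfg$maf_range[2])
    stop("degenerate maf_range: lower bound must be below upper bound")
  if (cfg$maf_range[1] <= 0 || cfg$maf_range[2] > 0.5)
    stop("maf_range must lie within (0, 0.5]")
  if (cfg$h2_target < 0 || cfg$h2_target > 1)
    stop("h2_target must be in [0, 1]")
  if (cfg$pi_zero < 0 || cfg$pi_zero > 1) stop("pi_zero must be in [0, 1]")
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1)
    stop("missing_rate must be in [0, 1)")
  if (cfg$stab_h2 < 0 || cfg$stab_h2 > 1) stop("stab_h2 must be in [0, 1]")
  class(cfg) <- "SimulationConfig"
  cfg
}

#' Simulate a SNP dosage panel
#'
#' Draws per-locus allele frequencies uniformly from `config$maf_range` and
#' samples dosages as Binomial(2, p) per genotype (Hardy-Weinberg sampling).
#' With `missing_rate > 0`, dosages are masked missing completely at random.
#' Both populations share the same locus frequencies, which makes them
#' related without simulating linkage or pedigree structure.
#'
#' @param config a [sim_config()] object.
#' @return A [marker_matrix()] with population labels and locus metadata.
#' @export
simulate_markers <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- sum(config$n_genotypes_per_pop)
  p <- config$n_markers
  freq <- runif(p, config$maf_range[1], config$maf_range[2])
  geno <- matrix(rbinom(n * p, 2L, rep(freq, each = n)), nrow = n, ncol = p)
  if (config$missing_rate > 0) {
    miss <- runif(n * p) < config$missing_rate
    geno[miss] <- NA_integer_
  }
  pop <- rep(paste0("P", seq_len(config$n_pops)),
             times = config$n_genotypes_per_pop)
  ids <- unlist(lapply(seq_len(config$n_pops), function(k) {
    sprintf("P%d_G%03d", k, seq_len(config$n_genotypes_per_pop[k]))
  }))
  rownames(geno) <- ids
  colnames(geno) <- sprintf("SNP%05d", seq_len(p))
  map <- data.frame(locus = colnames(geno),
                    chrom = "1",
                    pos = seq_len(p),
                    ref = "A", alt = "T",
                    biallelic = TRUE,
                    stringsAsFactors = FALSE)
  marker_matrix(geno, map = map, pop = pop)
}

# rank-r interaction matrix with orthonormal, sum-to-zero score columns;
# genotype scores may be supplied (e.g. marker-determined latent traits)
.sim_bilinear <- function(g, e, rank, target_sd, gamma_raw = NULL) {
  rank <- min(rank, g - 1L, e - 1L)
  if (rank < 1L) {
    return(list(lambda = numeric(0),
                gamma = matrix(0, g, 0), delta = matrix(0, e, 0),
                interaction = matrix(0, g, e)))
  }
  orth_centered <- function(x) {
    x <- sweep(x, 2, colMeans(x))       # sum-to-zero columns
    qr.Q(qr(x))[, seq_len(ncol(x)), drop = FALSE]
  }
  if (is.null(gamma_raw)) gamma_raw <- matrix(rnorm(g * rank), g, rank)
  gamma <- orth_centered(gamma_raw[, seq_len(rank), drop = FALSE])
  delta <- orth_centered(matrix(rnorm(e * rank), e, rank))
  # descending weights so the first axis dominates, as in real trials
  w <- rev(seq_len(rank)) / sum(seq_len(rank))
  inter <- gamma %*% diag(sqrt(w), rank) %*% t(delta)
  sc <- target_sd / sd(as.vector(inter))
  lambda <- sqrt(w) * sc
  list(lambda = lambda, gamma = gamma, delta = delta,
       interaction = inter * sc)
}

#' Simulate plot-level phenotypes for a multi-environment trial
#'
#' Builds plot values as
#' `Y_ijk = mu + g_i + h_j + block_k(j) + GE_ij + b_i * h_j + e_ijk`,
#' where `g_i = X beta` are additive genetic values (standardized to unit
#' variance), `h_j` are environment main effects, `GE_ij` is a rank-`gxe_rank`
#' bilinear interaction with double-centered scores, `b_i` are
#' Finlay-Wilkinson slope deviations, and the residual variance is solved
#' from `h2_target`. Every genotype appears in every environment and block
#' (complete RCBD).
#'
#' @param markers a [marker_matrix()] from [simulate_markers()].
#' @param config the same [sim_config()] used for the markers.
#' @return A list with `phenotypes` (long-format plot data.frame with columns
#'   genotype, population, location, year, block, trait, value) and `truth`
#'   (a `TruthRecord` list holding the generating effects: `mu`, per-
#'   population marker effects `beta` decomposed as `b0`/`b_specific`,
#'   genetic values `g`, environment effects `h`, FW slopes `fw_slopes`,
#'   bilinear scores, block effects, and `sigma_e`).
#' @export
simulate_phenotypes <- function(markers, config) {
  stopifnot(inherits(config, "SimulationConfig"),
            inherits(markers, "MarkerMatrix"))
  geno <- markers$dosage
  n <- nrow(geno)
  p <- ncol(geno)
  if (p != config$n_markers || n != sum(config$n_genotypes_per_pop))
    stop("marker matrix dimensions do not match the configuration")
  if (config$h2_target <= 0)
    stop("h2_target = 0 is contradictory: the residual variance solved ",
         "from the genetic variance would be infinite")
  if (!is.null(config$seed)) set.seed(config$seed + 1L)

  pop <- markers$pop
  pops <- unique(pop)

  # marker effects: shared b0 plus population-specific deviations
  b0 <- switch(config$effect_prior,
    normal = rnorm(p),
    spike_slab = rnorm(p) * (runif(p) >= config$pi_zero))
  n_spec <- round(config$prop_specific_effects * p)
  spec_idx <- if (n_spec > 0) sample.int(p, n_spec) else integer(0)
  b_spec <- lapply(pops, function(q) {
    v <- numeric(p)
    if (n_spec > 0) v[spec_idx] <- rnorm(n_spec) *
        (if (config$effect_prior == "spike_slab")
           (runif(n_spec) >= config$pi_zero) else 1)
    v
  })
  names(b_spec) <- pops

  Xc <- scale(apply(geno, 2, function(x) {
    x[is.na(x)] <- mean(x, na.rm = TRUE)
    x
  }), center = TRUE, scale = FALSE)
  g_raw <- numeric(n)
  for (q in pops) {
    rows <- pop == q
    g_raw[rows] <- Xc[rows, , drop = FALSE] %*% (b0 + b_spec[[q]])
  }
  scl <- if (sd(g_raw) > 0) 1 / sd(g_raw) else 1   # unit genetic variance
  b0 <- b0 * scl
  b_spec <- lapply(b_spec, function(v) v * scl)
  g <- as.numeric(g_raw * scl)
  names(g) <- rownames(geno)
  var_g <- var(g)

  # environments: full location x year cross
  locs <- paste0("L", seq_len(config$n_locations))
  years <- 2006L + seq_len(config$n_years)
  envs <- expand.grid(location = locs, year = years,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  J <- nrow(envs)
  env_id <- paste(envs$location, envs$year, sep = ":")
  h <- rnorm(J, 0, config$env_sd)
  h <- h - mean(h)
  names(h) <- env_id

  # stability mechanisms are partly marker-determined (heritability
  # stab_h2): latent genetic scores are fresh marker regressions, mixed
  # with independent noise
  genetic_score <- function() {
    u <- as.numeric(Xc %*% rnorm(p))
    u <- (u - mean(u)) / max(sd(u), 1e-12)
    z <- rnorm(n)
    sqrt(config$stab_h2) * u + sqrt(1 - config$stab_h2) * z
  }
  gamma_raw <- if (config$gxe_rank > 0)
    vapply(seq_len(config$gxe_rank), function(k) genetic_score(),
           numeric(n))
  else NULL
  bil <- .sim_bilinear(n, J, config$gxe_rank,
                       if (config$gxe_rank > 0) config$gxe_sd else 0,
                       gamma_raw = gamma_raw)
  rownames(bil$interaction) <- names(g)
  colnames(bil$interaction) <- env_id

  fw <- if (config$fw_slope_sd > 0) {
    s <- genetic_score()
    config$fw_slope_sd * (s - mean(s)) / max(sd(s), 1e-12)
  } else numeric(n)
  names(fw) <- names(g)

  blocks <- expand.grid(env = env_id, block = seq_len(config$n_blocks),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  beff <- rnorm(nrow(blocks), 0, config$block_sd)
  names(beff) <- paste(blocks$env, blocks$block, sep = "|")

  sigma_e <- sqrt(var_g * (1 - config$h2_target) / config$h2_target)

  grid <- expand.grid(genotype = names(g), env_idx = seq_len(J),
                      block = seq_len(config$n_blocks),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  gi <- match(grid$genotype, names(g))
  value <- config$mu + g[gi] + h[grid$env_idx] +
    beff[paste(env_id[grid$env_idx], grid$block, sep = "|")] +
    bil$interaction[cbind(gi, grid$env_idx)] +
    fw[gi] * h[grid$env_idx] +
    rnorm(nrow(grid), 0, sigma_e)

  phen <- data.frame(
    genotype = grid$genotype,
    population = pop[gi],
    location = envs$location[grid$env_idx],
    year = envs$year[grid$env_idx],
    block = grid$block,
    trait = "SIM",
    value = as.numeric(value),
    stringsAsFactors = FALSE)

  truth <- list(mu = config$mu,
                b0 = b0, b_specific = b_spec,
                beta = lapply(b_spec, function(v) b0 + v),
                g = g, h = h, fw_slopes = fw,
                bilinear = bil[c("lambda", "gamma", "delta")],
                interaction = bil$interaction,
                block_effects = beff, sigma_e = sigma_e,
                var_g = var_g)
  class(truth) <- "TruthRecord"
  list(phenotypes = phen, truth = truth)
}
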