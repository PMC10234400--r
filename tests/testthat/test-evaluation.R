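test_that("scenario specifications enforce disjoint, non-empty year sets", {
  expect_error(scenario_spec("I", integer(0), 2014), "empty")
  expect_error(scenario_spec("I", 2007:2014, 2014:2015), "disjoint")
  scs <- make_increment_scenarios(2007:2012, 2014:2015)
  expect_length(scs, 6)
  expect_identical(vapply(scs, `[[`, "", "label"),
                   c("I", "II", "III", "IV", "V", "VI"))
  expect_identical(scs[[3]]$train_years, 2007:2009)
  expect_identical(scs[[6]]$valid_years, 2014:2015)
})

test_that("cross-validation honours its fold contract", {
  trial <- small_trial(seed = 81, n_markers = 100)
  y <- setNames(as.numeric(trial$truth$g), names(trial$truth$g))
  cv <- run_cv(y, trial$markers,
               genomic_config("BRR", n_iter = 400, burn_in = 100),
               k = 5, reps = 3, seed = 2)
  expect_identical(cv$n_fits, 15L)
  for (f in cv$folds) {
    expect_identical(sort(names(f)), sort(names(y)))
    expect_true(all(f %in% 1:5))
    # stratification: each population spread over all folds
    for (q in unique(trial$markers$pop)) {
      tab <- table(f[trial$markers$pop == q])
      expect_true(max(tab) - min(tab) <= 1)
    }
  }
  expect_error(run_cv(y, trial$markers, k = 60,
                      config = genomic_config("BRR", n_iter = 100,
                                              burn_in = 10)),
               "exceeds")
})

test_that("fold assignment is invariant to genotype reordering", {
  trial <- small_trial(seed = 82, n_markers = 60)
  y <- setNames(as.numeric(trial$truth$g), names(trial$truth$g))
  cfg <- genomic_config("BRR", n_iter = 200, burn_in = 50)
  cv1 <- run_cv(y, trial$markers, cfg, k = 4, reps = 1, seed = 5)
  perm <- sample(length(y))
  mk2 <- trial$markers[perm, ]
  cv2 <- run_cv(y[perm], mk2, cfg, k = 4, reps = 1, seed = 5)
  f1 <- cv1$folds[[1]]
  f2 <- cv2$folds[[1]]
  expect_identical(f1[sort(names(f1))], f2[sort(names(f2))])
})

test_that("cross-validation separates perfect signal from pure noise", {
  cfg <- sim_config(n_pops = 1, n_genotypes_per_pop = 300, n_markers = 80,
                    seed = 83)
  mk <- simulate_markers(cfg)
  set.seed(84)
  y <- as.numeric(mk$dosage %*% rnorm(80))
  names(y) <- rownames(mk$dosage)
  cvp <- run_cv(y, mk, genomic_config("BRR", n_iter = 1500,
                                      burn_in = 300), k = 5, reps = 2,
                seed = 6)
  expect_gte(cvp$summary$mean_r, 0.99)
  y0 <- rnorm(300); names(y0) <- rownames(mk$dosage)
  cv0 <- run_cv(y0, mk, genomic_config("BRR", n_iter = 1000,
                                       burn_in = 200), k = 5, reps = 2,
                seed = 6)
  expect_lt(abs(cv0$summary$mean_r), 0.25)
})

test_that("performance-stability correlations behave at the identity and degenerate limits", {
  stab <- data.frame(genotype = sprintf("G%02d", 1:20), trait = "Y",
                     spc = runif(20), asv = seq(0.1, 2, length.out = 20),
                     fw_slope_dev = rnorm(20),
                     fw_abs_slope = abs(rnorm(20)))
  perf <- setNames(stab$asv, stab$genotype)  # identical to the ASV column
  ct <- correlate_performance_stability(perf, stab)
  expect_equal(ct$r[ct$metric == "ammi"], 1, tolerance = 1e-12)
  expect_identical(ct$stars[ct$metric == "ammi"], "***")
  const <- setNames(rep(1, 20), stab$genotype)
  cc <- correlate_performance_stability(const, stab)
  expect_true(all(is.na(cc$r)))
  expect_identical(unique(cc$stars), "undefined")
  expect_error(correlate_performance_stability(perf[1:2], stab[1:2, ]),
               "at least 3")
})

test_that("independent performance and stability rarely correlate", {
  set.seed(85)
  hits <- replicate(100, {
    abs(cor(rnorm(100), rnorm(100)))
  })
  # null distribution of |r| at n = 100: 3 sigma is about 0.3
  expect_gte(mean(hits < 0.3), 0.95)
})

test_that("co-selection overlap handles coincident, antagonistic and rounding cases", {
  n <- 103
  ids <- sprintf("G%03d", 1:n)
  perf <- setNames(seq_len(n), ids)  # higher is better: G103 best
  stab_coin <- data.frame(genotype = ids, trait = "Y", spc = 0,
                          asv = rev(seq_len(n)),      # best performers most stable
                          fw_slope_dev = rev(seq_len(n)) / n,
                          fw_abs_slope = rev(seq_len(n)) / n)
  ov <- select_overlap(perf, stab_coin, direction = "higher")
  expect_identical(unname(ov$sizes["performance"]), 10L)  # floor(103 * 0.10)
  expect_identical(unname(ov$sizes["ammi"]), 20L)
  expect_identical(unname(ov$intersections[["all3"]]), 10L)
  stab_anti <- stab_coin
  stab_anti$asv <- seq_len(n)       # best performers least stable
  ov2 <- select_overlap(perf, stab_anti, direction = "higher")
  expect_identical(unname(ov2$intersections[["perf_ammi"]]), 0L)
  # lower-is-better traits flip the performance ranking
  ov3 <- select_overlap(perf, stab_coin, direction = "lower")
  expect_identical(ov3$sets$performance, ids[1:10])
  expect_error(select_overlap(perf, stab_coin), "direction")
})

test_that("selection counts follow the floor rule with a minimum of one", {
  ids <- sprintf("G%d", 1:7)
  perf <- setNames(rnorm(7), ids)
  stab <- data.frame(genotype = ids, trait = "Y", spc = 0,
                     asv = runif(7), fw_slope_dev = rnorm(7),
                     fw_abs_slope = runif(7))
  ov <- select_overlap(perf, stab, perf_frac = 0.10, stab_frac = 0.20,
                       direction = "higher")
  expect_identical(unname(ov$sizes["performance"]), 1L)  # floor(0.7) -> min 1
  expect_identical(unname(ov$sizes["ammi"]), 1L)
})

test_that("year-increment scenarios validate their inputs", {
  trial <- small_trial(seed = 86, n_markers = 60)
  scs <- list(scenario_spec("I", 2007, 2099))
  expect_error(run_year_increment(trial$phen, trial$markers, scs,
                                  genomic_config("BRR", n_iter = 100,
                                                 burn_in = 10)),
               "validation years")
})

test_that("stability type matches the generating interaction in genomic prediction", {
  # FW-type interaction only: FW slope indices should be the more
  # predictable target; bilinear-only data favour the AMMI index
  wins_fw <- 0; wins_ammi <- 0
  for (r in 1:5) {
    base <- list(n_pops = 1, n_genotypes_per_pop = 150, n_markers = 200,
                 n_locations = 2, n_years = 3, h2_target = 0.8,
                 seed = 900 + r)
    cfg_fw <- do.call(sim_config, c(base, list(gxe_rank = 0,
                                               fw_slope_sd = 0.5)))
    mk <- simulate_markers(cfg_fw)
    sim <- simulate_phenotypes(mk, cfg_fw)
    ph <- sim$phenotypes
    ph$env <- paste(ph$location, ph$year, sep = ":")
    cellm <- tapply(ph$value, list(ph$genotype, ph$env), mean)
    st <- stability_summary(cellm[names(sim$truth$g), ])
    gc <- genomic_config("BRR", n_iter = 800, burn_in = 200)
    set.seed(950 + r)
    r_fw <- run_cv(setNames(st$fw_slope_dev, st$genotype), mk, gc,
                   k = 5, reps = 1, seed = r)$summary$mean_r
    r_asv <- run_cv(setNames(st$asv, st$genotype), mk, gc,
                    k = 5, reps = 1, seed = r)$summary$mean_r
    wins_fw <- wins_fw + (r_fw > r_asv)
  }
  expect_gte(wins_fw, 3)
})
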