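# small deterministic dosage matrix with prescribed allele counts
.qc_fixture <- function() {
  n <- 1000
  mk_col <- function(n_alt1, n_miss = 0) {
    x <- rep(0, n)
    if (n_alt1 > 0) x[seq_len(n_alt1)] <- 1
    if (n_miss > 0) x[n - seq_len(n_miss) + 1] <- NA
    x
  }
  dos <- cbind(
    keep_common = mk_col(500),          # MAF 0.25
    drop_maf = mk_col(18),              # MAF 0.009
    keep_maf = mk_col(22),              # MAF 0.011
    drop_missing = mk_col(100, n_miss = 600),  # 60% missing
    keep_missing = mk_col(100, n_miss = 400),  # 50% missing: kept
    drop_multi = mk_col(400),           # flagged non-biallelic
    keep_rare_edge = mk_col(20))        # MAF 0.010 exactly: kept
  rownames(dos) <- sprintf("g%04d", seq_len(n))
  map <- data.frame(locus = colnames(dos),
                    biallelic = colnames(dos) != "drop_multi")
  marker_matrix(dos, map = map)
}

test_that("QC filters match the hand enumeration and boundary rules", {
  mk <- .qc_fixture()
  f <- qc_filter(mk)
  expect_setequal(colnames(f$dosage),
                  c("keep_common", "keep_maf", "keep_missing",
                    "keep_rare_edge"))
  expect_identical(f$report$removed_missing, 1L)
  expect_identical(f$report$removed_nonbiallelic, 1L)
  expect_identical(f$report$removed_maf, 1L)
  expect_false(anyNA(f$dosage))
  # mean imputation preserves the observed allele frequency
  obs_af <- mean(mk$dosage[1:600, "keep_missing"]) / 2
  expect_equal(mean(f$dosage[, "keep_missing"]) / 2, obs_af,
               tolerance = 1e-12)
  expect_error(qc_filter(mk, max_missing = 0.5, min_maf = 0.6),
               "all loci removed")
})

test_that("fixed-variance BRR matches the closed-form ridge solution", {
  set.seed(42)
  n <- 50; p <- 20
  X <- matrix(rbinom(n * p, 2, 0.3), n, p)
  y <- as.numeric(X %*% rnorm(p, 0, 0.3) + rnorm(n))
  fit <- gibbs_brr(y, X, genomic_config("BRR", n_iter = 12000,
                                        burn_in = 2000, seed = 11),
                   varB = 0.09, varE = 1)
  Xc <- scale(X, scale = FALSE)
  ridge <- solve(crossprod(Xc) + diag(1 / 0.09, p),
                 crossprod(Xc, y - mean(y)))
  expect_lt(max(abs(fit$beta - ridge)), 0.02)
})

test_that("constant responses collapse to the intercept", {
  set.seed(1)
  X <- matrix(rbinom(200, 2, 0.4), 20, 10)
  y <- rep(7, 20)
  fit <- gibbs_brr(y, X, genomic_config("BRR", n_iter = 2000,
                                        burn_in = 500, seed = 2))
  expect_lt(max(abs(fit$beta)), 0.01)
  expect_equal(unname(fit$mu[1]), 7, tolerance = 0.01)
  expect_error(gibbs_brr(c(1, NA, 3), X[1:3, ],
                         genomic_config("BRR", n_iter = 100,
                                        burn_in = 10)),
               "non-finite")
})

test_that("BRR shrinkage grows monotonically with the variance ratio", {
  set.seed(3)
  n <- 60; p <- 30
  X <- matrix(rbinom(n * p, 2, 0.4), n, p)
  y <- as.numeric(X %*% rnorm(p, 0, 0.5) + rnorm(n, 0, 0.5))
  norms <- vapply(c(0.5, 5, 50, 500), function(ratio) {
    f <- gibbs_brr(y, X, genomic_config("BRR", n_iter = 4000,
                                        burn_in = 1000, seed = 4),
                   varB = 1 / ratio, varE = 1)
    mean(abs(f$beta))
  }, 0)
  expect_true(all(diff(norms) < 0))
})

test_that("samplers are bit-reproducible under a fixed seed", {
  set.seed(5)
  X <- matrix(rbinom(600, 2, 0.3), 30, 20)
  y <- rnorm(30)
  cfg <- genomic_config("BayesB", n_iter = 800, burn_in = 200, seed = 9)
  f1 <- gibbs_bayesb(y, X, cfg)
  f2 <- gibbs_bayesb(y, X, cfg)
  expect_identical(f1$beta, f2$beta)
  expect_identical(f1$pip, f2$pip)
  expect_identical(f1$chains$varE, f2$chains$varE)
})

test_that("BayesB finds sparse causal loci and reports calibrated null inclusion", {
  set.seed(6)
  n <- 300; p <- 500
  X <- matrix(rbinom(n * p, 2, 0.3), n, p)
  idx <- sample.int(p, 5)
  b <- numeric(p); b[idx] <- rnorm(5, 0, 1)
  g <- as.numeric(scale(X, scale = FALSE) %*% b)
  y <- g + rnorm(n, 0, sd(g) * 0.5)
  fit <- gibbs_bayesb(y, X, genomic_config("BayesB", n_iter = 5000,
                                           burn_in = 1000, seed = 7))
  expect_true(all(idx %in% order(-fit$pip)[1:10]))
  # pure-noise response: mean inclusion matches the fixed prior 1 - pi
  set.seed(8)
  y0 <- rnorm(150)
  X0 <- matrix(rbinom(150 * 200, 2, 0.3), 150, 200)
  f0 <- gibbs_bayesb(y0, X0, genomic_config("BayesB", n_iter = 4000,
                                            burn_in = 1000, seed = 9,
                                            pi_zero = 0.5,
                                            update_pi = FALSE))
  expect_lt(abs(mean(f0$pip) - 0.5), 0.05)
})

test_that("BayesB collapses to BRR when the spike is switched off (dense signal)", {
  set.seed(10)
  n <- 250; p <- 100
  X <- matrix(rbinom(n * p, 2, 0.3), n, p)
  b <- rnorm(p, 0, 0.2)
  y <- as.numeric(X %*% b + rnorm(n, 0, 1))
  fb <- gibbs_bayesb(y, X, genomic_config("BayesB", n_iter = 8000,
                                          burn_in = 2000, seed = 11,
                                          pi_zero = 1e-8,
                                          update_pi = FALSE))
  fr <- gibbs_brr(y, X, genomic_config("BRR", n_iter = 8000,
                                       burn_in = 2000, seed = 11))
  expect_gt(cor(fb$beta, fr$beta), 0.99)
  expect_error(gibbs_bayesb(y, X, genomic_config("BayesB", pi_zero = 1)),
               "pi")
})

test_that("population designs stack with zero blocks exactly where foreign effects sit", {
  X1 <- matrix(1:12, 3, 4, dimnames = list(paste0("a", 1:3),
                                           paste0("s", 1:4)))
  X2 <- matrix(13:20, 2, 4, dimnames = list(paste0("b", 1:2),
                                            paste0("s", 1:4)))
  des <- build_pop_design(X1, X2, "MP")
  expect_equal(dim(des$X), c(5L, 12L))
  expect_equal(des$group, rep(1:3, each = 4))
  expect_true(all(des$X[4:5, 5:8] == 0))   # pop2 rows x pop1-specific
  expect_true(all(des$X[1:3, 9:12] == 0))  # pop1 rows x pop2-specific
  expect_equal(des$X[1:3, 1:4], X1, ignore_attr = TRUE)
  expect_error(build_pop_design(X1, X2[, c(2, 1, 3, 4)], "AP"),
               "locus mismatch")
})

test_that("GEBVs reproduce fitted values and hand-computed MP predictions", {
  trial <- small_trial(seed = 51, n_markers = 120)
  y <- setNames(as.numeric(trial$truth$g + rnorm(55, 0, 0.5)),
                names(trial$truth$g))
  for (mode in c("SP", "AP", "MP")) {
    fit <- fit_genomic(y, trial$markers,
                       genomic_config("BRR", pop_mode = mode,
                                      n_iter = 1200, burn_in = 300,
                                      seed = 13))
    pr <- predict_gebv(fit, trial$markers)
    expect_equal(pr[names(fit$gebv)], fit$gebv, tolerance = 1e-10)
  }
  # MP prediction for one population uses b0 + b_pop only: 2-locus check
  mp <- fit_genomic(y, trial$markers,
                    genomic_config("BRR", pop_mode = "MP", n_iter = 1200,
                                   burn_in = 300, seed = 13))
  xnew <- matrix(c(2, 0, rep(0, 118)), 1,
                 dimnames = list("new", colnames(trial$markers$dosage)))
  manual <- mp$mu[[1]] + 2 * (mp$beta_mp["SNP00001", "b0"] +
                                mp$beta_mp["SNP00001", "b1"])
  expect_equal(unname(predict_gebv(mp, xnew, population = "P1")),
               unname(manual), tolerance = 1e-12)
  expect_error(predict_gebv(mp, xnew, population = "P9"),
               "unknown population")
  # an all-zero genotype returns the intercept
  f1 <- mp$config; f1$pop_mode <- "SP"
  base <- gibbs_brr(y[1:25], trial$markers$dosage[1:25, ], f1)
  expect_equal(unname(predict_gebv(base, xnew * 0)), unname(base$mu[[1]]))
})

test_that("swapping population labels permutes the fit symmetrically", {
  trial <- small_trial(seed = 61, n_markers = 100)
  y <- setNames(as.numeric(trial$truth$g + rnorm(55, 0, 0.5)),
                names(trial$truth$g))
  mk2 <- trial$markers
  mk2$pop <- ifelse(trial$markers$pop == "P1", "P2", "P1")
  cfg <- genomic_config("BRR", pop_mode = "AP", n_iter = 1000,
                        burn_in = 200, seed = 17)
  ap1 <- fit_genomic(y, trial$markers, cfg)
  ap2 <- fit_genomic(y, mk2, cfg)
  expect_identical(unname(ap1$gebv), unname(ap2$gebv))
  cfg$pop_mode <- "MP"
  mp1 <- fit_genomic(y, trial$markers, cfg)
  mp2 <- fit_genomic(y, mk2, cfg)
  expect_identical(unname(mp1$beta_mp), unname(mp2$beta_mp))
  expect_identical(mp2$pops, c("P2", "P1"))
})

test_that("BRR reaches useful out-of-sample accuracy on a moderately heritable trait", {
  cfg <- sim_config(n_pops = 1, n_genotypes_per_pop = 300,
                    n_markers = 500, h2_target = 0.5, gxe_rank = 0,
                    fw_slope_sd = 0, seed = 71)
  mk <- simulate_markers(cfg)
  sim <- simulate_phenotypes(mk, cfg)
  set.seed(72)
  y <- sim$truth$g + rnorm(300, 0, sd(sim$truth$g))  # h2 = 0.5 entry basis
  names(y) <- names(sim$truth$g)
  test <- sample(300, 60)
  fit <- gibbs_brr(y[-test], mk$dosage[-test, ],
                   genomic_config("BRR", n_iter = 2500, burn_in = 500,
                                  seed = 73))
  r <- cor(predict_gebv(fit, mk$dosage[test, ]), y[test])
  expect_gt(r, 0.3)
})
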