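test_that("two-way assembly passes complete data through and applies the drop policy", {
  tab <- toy_table(5, 4, seed = 1)
  long <- data.frame(genotype = rep(rownames(tab), 4),
                     env = rep(colnames(tab), each = 5),
                     value = as.vector(tab))
  tw <- prepare_two_way(long)
  expect_equal(unclass(tw)[rownames(tab), colnames(tab)], tab)
  # a genotype observed in a single environment is dropped with a report
  long2 <- rbind(long, data.frame(genotype = "G99", env = "E1", value = 0))
  tw2 <- prepare_two_way(long2, missing = "drop")
  expect_false("G99" %in% rownames(tw2))
  expect_identical(attr(tw2, "report")$dropped, "G99")
})

test_that("EM imputation fills a missing cell with the additive prediction", {
  g_eff <- c(G1 = -2, G2 = 0, G3 = 1, G4 = 3, G5 = -1)
  e_eff <- c(E1 = -1, E2 = 0, E3 = 2, E4 = -0.5)
  tab <- additive_table(g_eff, e_eff, mu = 10)
  long <- data.frame(genotype = rep(names(g_eff), 4),
                     env = rep(names(e_eff), each = 5),
                     value = as.vector(tab))
  long <- long[!(long$genotype == "G2" & long$env == "E3"), ]
  tw <- prepare_two_way(long, missing = "em", em_rank = 0)
  expect_equal(tw["G2", "E3"], 10 + 0 + 2, tolerance = 1e-6)
  expect_identical(attr(tw, "report")$imputed$genotype, "G2")
})

test_that("AMMI recovers a constructed rank-1 interaction", {
  set.seed(2)
  u <- as.numeric(scale(rnorm(10), scale = FALSE))
  v <- as.numeric(scale(rnorm(6), scale = FALSE))
  g_eff <- rnorm(10); e_eff <- rnorm(6)
  tab <- additive_table(g_eff, e_eff, mu = 5) + u %*% t(v)
  am <- ammi_decompose(tab)
  expect_equal(am$lambda[1], sqrt(sum(u^2)) * sqrt(sum(v^2)),
               tolerance = 1e-8)
  expect_lt(am$lambda[2], 1e-8)
  gamma1 <- am$gamma[, 1]
  expect_equal(abs(cor(gamma1, u)), 1, tolerance = 1e-8)
})

test_that("AMMI satisfies its decomposition identities on random tables", {
  for (s in 1:20) {
    tab <- toy_table(10, 6, seed = s)
    am <- ammi_decompose(tab)
    # sum of squared singular values equals the interaction sum of squares
    expect_equal(sum(am$lambda^2), sum(am$interaction^2),
                 tolerance = 1e-8)
    # full reconstruction reproduces the table
    rec <- am$mu + outer(am$g, am$e, "+") +
      am$gamma %*% diag(am$lambda) %*% t(am$delta)
    expect_lt(max(abs(rec - tab)), 1e-8)
    # score columns orthonormal
    expect_equal(crossprod(am$gamma), diag(ncol(am$gamma)),
                 tolerance = 1e-8, ignore_attr = TRUE)
    expect_equal(crossprod(am$delta), diag(ncol(am$delta)),
                 tolerance = 1e-8, ignore_attr = TRUE)
  }
})

test_that("additive and constant tables give null AMMI components without error", {
  tab <- additive_table(rnorm(5), rnorm(5), mu = 3)
  am <- ammi_decompose(tab)
  expect_true(all(am$lambda < 1e-10))
  amc <- ammi_decompose(matrix(7, 4, 4))
  expect_true(all(amc$lambda == 0))
  expect_true(all(amc$gamma == 0))
})

test_that("the sequential F test is calibrated on noise and detects rank-1 signal", {
  set.seed(90)
  n0 <- replicate(200, {
    tab <- matrix(rnorm(60), 10, 6)
    as.integer(select_n_components(ammi_decompose(tab, sigma2 = 1,
                                                  nrep = 1)))
  })
  expect_gte(mean(n0 == 0), 0.9)
  set.seed(91)
  n1 <- replicate(50, {
    u <- scale(rnorm(10), scale = FALSE)
    v <- scale(rnorm(6), scale = FALSE)
    tab <- 5 * u %*% t(v) + matrix(rnorm(60, 0, 0.3), 10, 6)
    as.integer(select_n_components(ammi_decompose(tab, sigma2 = 0.09,
                                                  nrep = 1), max_n = 10))
  })
  expect_true(all(n1 >= 1))
  expect_gte(mean(n1 == 1), 0.8)
})

test_that("the retained component count is capped at two by default", {
  set.seed(92)
  tab <- toy_table(12, 8, seed = 92, noise_sd = 5)  # strong high-rank GxE
  am <- ammi_decompose(tab, sigma2 = 0.01, nrep = 1)
  expect_identical(as.integer(select_n_components(am)), 2L)
  expect_gt(as.integer(select_n_components(am, max_n = 10)), 2L)
})

test_that("ASV follows the Pythagorean toy case and null-interaction genotypes score zero", {
  # equal component sums of squares (weight 1) and scores (3, 4) -> ASV 5
  fake <- structure(list(
    mu = 0, g = rep(0, 3), e = rep(0, 3), lambda = c(1, 1),
    gamma = matrix(c(3, 0, 0, 4, 0, 0), 3, 2,
                   dimnames = list(c("a", "b", "c"), NULL)),
    delta = matrix(0, 3, 2), var_fraction = c(0.5, 0.5),
    interaction = matrix(0, 3, 3), ss_interaction = 2,
    sigma2 = NULL, nrep = NULL, n_genotypes = 3, n_environments = 3),
    class = "AMMIResult")
  st <- ammi_stability(fake, N = 2)
  expect_equal(st$asv[st$genotype == "a"], 5)
  # genotype with no interaction: zero scores on both axes
  set.seed(3)
  u <- c(0, as.numeric(scale(rnorm(7), scale = FALSE)))
  u2 <- c(0, as.numeric(scale(rnorm(7), scale = FALSE)))
  v <- as.numeric(scale(rnorm(5), scale = FALSE))
  v2 <- as.numeric(scale(rnorm(5), scale = FALSE))
  tab <- additive_table(rnorm(8), rnorm(5)) + u %*% t(v) + u2 %*% t(v2)
  am <- ammi_decompose(tab)
  st2 <- ammi_stability(am, N = 2)
  expect_lt(st2$asv[1], 1e-8)
  expect_lt(st2$spc[1], 1e-8)
})

test_that("ASV ranking matches an independent recomputation from the SVD", {
  tab <- toy_table(10, 4, seed = 44)
  am <- ammi_decompose(tab)
  st <- ammi_stability(am, N = 2)
  # brute-force recomputation from scratch
  inter <- sweep(sweep(tab, 1, rowMeans(tab)), 2, colMeans(tab)) +
    mean(tab)
  sv <- svd(inter)
  s1 <- sqrt(sv$d[1]) * sv$u[, 1]
  s2 <- sqrt(sv$d[2]) * sv$u[, 2]
  asv_ref <- sqrt((sv$d[1]^2 / sv$d[2]^2 * s1)^2 + s2^2)
  expect_equal(order(st$asv), order(asv_ref))
  expect_equal(st$asv, asv_ref, tolerance = 1e-10)
})

test_that("stability indices scale as sqrt(c) and ignore environment order", {
  tab <- toy_table(8, 5, seed = 55)
  st <- ammi_stability(ammi_decompose(tab), N = 2)
  stc <- ammi_stability(ammi_decompose(tab * 4), N = 2)
  expect_equal(stc$asv, 2 * st$asv, tolerance = 1e-10)
  expect_equal(stc$spc, 2 * st$spc, tolerance = 1e-10)
  perm <- c(3, 1, 5, 2, 4)
  stp <- ammi_stability(ammi_decompose(tab[, perm]), N = 2)
  expect_equal(stp$asv, st$asv, tolerance = 1e-10)
  fw <- fw_fit(tab); fwp <- fw_fit(tab[, perm])
  expect_equal(fw$coef$slope_dev, fwp$coef$slope_dev, tolerance = 1e-12)
})

test_that("FW regression recovers generating slopes and balances to zero", {
  set.seed(66)
  g_eff <- rnorm(12)
  h <- as.numeric(scale(rnorm(6), scale = FALSE))
  b <- rnorm(12, 0, 0.5)
  tab <- outer(g_eff, h * 0) + g_eff + outer(1 + b, h)
  rownames(tab) <- sprintf("G%02d", 1:12); colnames(tab) <- sprintf("E%d", 1:6)
  fw <- fw_fit(tab)
  # noiseless generative recovery (environment effects shift by mean(b)h
  # under re-centering, so slopes are recovered relative to the mean slope)
  expect_equal(fw$coef$slope_dev, (1 + b) / (1 + mean(b)) - 1,
               tolerance = 1e-8)
  expect_equal(mean(fw$h), 0, tolerance = 1e-12)
  # any complete balanced table balances slope deviations to zero
  tab2 <- toy_table(15, 8, seed = 67)
  expect_lt(abs(mean(fw_fit(tab2)$coef$slope_dev)), 1e-10)
})

test_that("flat responders get slope deviation -1 and degenerate tables error", {
  tab <- toy_table(6, 5, seed = 77)
  tab[2, ] <- 3  # constant response
  fw <- fw_fit(tab)
  expect_equal(fw$coef$slope_dev[2], -1, tolerance = 1e-10)
  expect_true(fw$coef$non_responsive[2])
  expect_false(any(fw$coef$non_responsive[-2]))
  flat <- matrix(rep(rnorm(4), 3), 4, 3)  # equal environment means
  expect_error(fw_fit(flat), "inestimable|variance")
})

test_that("FW slopes track first-axis genotype scores when the environment scores align", {
  set.seed(88)
  h <- as.numeric(scale(rnorm(6), scale = FALSE))
  delta1 <- h / sqrt(sum(h^2))       # delta_1 proportional to h
  u <- as.numeric(scale(rnorm(20), scale = FALSE))
  tab <- additive_table(rnorm(20), h) + 3 * u %*% t(delta1)
  fw <- fw_fit(tab)
  am <- ammi_decompose(tab)
  expect_gt(abs(cor(fw$coef$slope_dev, am$gamma[, 1])), 0.95)
})
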