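#' Configuration for Bayesian whole-genome regression
#'
#' Chain and prior settings for [gibbs_brr()], [gibbs_bayesb()] and
#' [fit_genomic()]. Defaults follow the conventions of standard
#' whole-genome-regression software: 30,000 MCMC iterations with 5,000
#' burn-in, thinning 5, prior scales solved from an a-priori partition of
#' the phenotypic variance (`prior_r2`, default 0.5, split equally across
#' effect groups), and 5 degrees of freedom for every scaled-inverse-
#' chi-square prior. For BayesB, the mixture proportion `pi` (probability a
#' marker effect is exactly zero) carries a Beta prior with mean `pi_zero`
#' and weight `pi_counts`, updated from the inclusion counts unless
#' `update_pi = FALSE`.
#'
#' @param model `"BRR"` or `"BayesB"`.
#' @param pop_mode population parameterization used by [fit_genomic()]:
#'   `"SP"` (each population separately), `"AP"` (pooled, shared marker
#'   effects), `"MP"` (pooled, shared + population-specific effects).
#' @param n_iter,burn_in,thin chain length, burn-in, thinning interval.
#' @param prior_r2 prior proportion of variance attributed to markers,
#'   in (0, 1).
#' @param df_prior degrees of freedom of the variance priors.
#' @param pi_zero prior mean of the BayesB zero-effect probability.
#' @param pi_counts prior weight (counts) of the Beta prior on `pi`.
#' @param update_pi logical; sample `pi` (default) or keep it fixed.
#' @param seed RNG seed or `NULL`.
#' @return A `GenomicModelConfig` list.
#' @export
genomic_config <- function(model = c("BRR", "BayesB"),
                           pop_mode = c("SP", "AP", "MP"),
                           n_iter = 30000L, burn_in = 5000L, thin = 5L,
                           prior_r2 = 0.5, df_prior = 5,
                           pi_zero = 0.5, pi_counts = 10,
                           update_pi = TRUE, seed = NULL) {
  model <- match.arg(model)
  pop_mode <- match.arg(pop_mode)
  if (burn_in >= n_iter) stop("burn_in must be smaller than n_iter")
  if (prior_r2 <= 0 || prior_r2 >= 1) stop("prior_r2 must be in (0, 1)")
  if (pi_zero >= 1 && model == "BayesB")
    stop("pi prior mass entirely at 1 leaves no markers in the model")
  cfg <- list(model = model, pop_mode = pop_mode,
              n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
              thin = as.integer(thin), prior_r2 = prior_r2,
              df_prior = df_prior, pi_zero = pi_zero,
              pi_counts = pi_counts, update_pi = isTRUE(update_pi),
              seed = seed)
  class(cfg) <- "GenomicModelConfig"
  cfg
}

# core sampler wrapper: centers X, solves prior scales, runs the chain
.wgr_fit <- function(y, X, W, group, config,
                     varB = NULL, varE = NULL) {
  stopifnot(is.numeric(y))
  if (any(!is.finite(y))) stop("non-finite phenotype values in y")
  X <- as.matrix(X)
  if (nrow(X) != length(y)) stop("rows of X must align with y")
  if (is.null(W)) W <- matrix(1, length(y), 1,
                              dimnames = list(NULL, "mu"))
  if (is.null(group)) group <- rep(1L, ncol(X))
  n_groups <- max(group)
  centers <- colMeans(X)
  Xc <- sweep(X, 2, centers)

  vy <- max(var(y), 1e-8)
  df_b <- config$df_prior
  df_e <- config$df_prior
  r2g <- config$prior_r2 / n_groups
  msx <- vapply(seq_len(n_groups), function(g) {
    s <- sum(apply(Xc[, group == g, drop = FALSE], 2, var))
    max(s, 1e-8)
  }, 0)
  S_b <- vy * r2g / msx * (df_b + 2) / df_b
  if (config$model == "BayesB")
    S_b <- S_b / max(1 - config$pi_zero, 1e-3)
  S_e <- vy * (1 - config$prior_r2) * (df_e + 2) / df_e
  update_varB <- is.null(varB)
  update_varE <- is.null(varE)
  varB0 <- if (update_varB) S_b * df_b / (df_b + 2) else rep(varB, n_groups)
  varE0 <- if (update_varE) vy * (1 - config$prior_r2) else varE
  pi_a <- config$pi_counts * config$pi_zero
  pi_b <- config$pi_counts * (1 - config$pi_zero)

  if (!is.null(config$seed)) set.seed(config$seed)
  res <- .gibbs_wgr_cpp(y, W, Xc, as.integer(group), n_groups,
                        config$model, config$n_iter, config$burn_in,
                        config$thin, df_b, S_b, df_e, S_e,
                        varB0, varE0, config$pi_zero, pi_a, pi_b,
                        update_varB, update_varE,
                        config$model == "BayesB" && config$update_pi)
  names(res$b) <- colnames(X)
  names(res$b_sd) <- colnames(X)
  names(res$pip) <- colnames(X)
  names(res$a) <- colnames(W)
  res$centers <- centers
  res$group <- group
  res$fitted <- as.numeric(W %*% res$a + Xc %*% res$b)
  res
}

.new_fit <- function(res, y, config, loci, pop_mode, pops,
                     pop_of_row = NULL, beta_mp = NULL) {
  # intercepts on the raw dosage scale: training used column-centered
  # markers, so the centering constant c'b folds into the intercept and
  # GEBV = mu + X beta holds exactly for uncentered dosages
  mu_raw <- res$a - sum(res$centers * res$b)
  fit <- list(
    model = config$model, pop_mode = pop_mode,
    mu = mu_raw, beta = res$b, beta_sd = res$b_sd,
    beta_mp = beta_mp, pip = res$pip,
    gebv = setNames(res$fitted, names(y)),
    centers = res$centers, loci = loci, pops = pops,
    pop_of_row = pop_of_row,
    varE = mean(res$varE_chain),
    chains = list(varE = res$varE_chain, varB = res$varB_chain,
                  pi = res$pi_chain, mu = res$a_chain),
    diagnostics = .trace_summary(res),
    config = config)
  class(fit) <- "GenomicModelFit"
  fit
}

# cheap convergence diagnostics: split-half means and lag-1 autocorrelation
# of the residual-variance chain
.trace_summary <- function(res) {
  v <- res$varE_chain
  n <- length(v)
  h <- floor(n / 2)
  ac <- if (n > 2 && sd(v) > 0)
    cor(v[-1], v[-n]) else NA_real_
  list(varE_mean_first_half = mean(v[seq_len(h)]),
       varE_mean_second_half = mean(v[(h + 1):n]),
       varE_lag1_autocor = ac, n_samples = n)
}

#' @export
print.GenomicModelFit <- function(x, ...) {
  cat(sprintf("GenomicModelFit: %s (%s), %d loci\n",
              x$model, x$pop_mode, length(x$loci)))
  cat(sprintf("  intercept(s): %s; residual variance %.4g\n",
              paste(sprintf("%.3f", x$mu), collapse = ", "), x$varE))
  cat(sprintf("  GEBV range [%.3f, %.3f] over %d genotypes\n",
              min(x$gebv), max(x$gebv), length(x$gebv)))
  invisible(x)
}

#' Bayesian ridge regression of phenotypes on markers
#'
#' Gibbs sampler for `y = mu + X beta + e` with a common normal prior on
#' all marker effects, `beta_j ~ N(0, varB)`, and scaled-inverse-chi-square
#' priors on `varB` and the residual variance. Markers are column-centered
#' before regression (the intercept absorbs the mean; GEBVs are unaffected).
#' Posterior means are computed from the thinned post-burn-in samples. With
#' `varB`/`varE` supplied the variances are held fixed, in which case the
#' posterior mean of `beta` equals the ridge solution
#' `(X'X + varE/varB I)^-1 X'(y - mu)` up to Monte-Carlo error.
#'
#' @param y numeric response (adjusted means or a stability index), named
#'   by genotype.
#' @param X marker data: a [marker_matrix()] or plain dosage matrix.
#' @param config a [genomic_config()] (model forced to `"BRR"`).
#' @param varB,varE optional fixed variance components (both `NULL` by
#'   default, i.e. sampled).
#' @return A `GenomicModelFit` with posterior-mean intercept, marker
#'   effects, GEBVs, variance chains and trace diagnostics.
#' @export
gibbs_brr <- function(y, X, config = genomic_config("BRR"),
                      varB = NULL, varE = NULL) {
  config$model <- "BRR"
  Xm <- .dosage_ready(X)
  res <- .wgr_fit(y, Xm, NULL, NULL, config, varB = varB, varE = varE)
  .new_fit(res, y, config, colnames(Xm), "SP",
           if (inherits(X, "MarkerMatrix")) unique(X$pop) else "P1")
}

#' BayesB spike-and-slab regression of phenotypes on markers
#'
#' Gibbs sampler for `y = mu + X beta + e` where each marker effect is zero
#' with probability `pi` and otherwise drawn from a per-locus
#' scaled-t slab (normal with its own scaled-inverse-chi-square variance).
#' `pi` carries a Beta prior updated from the inclusion counts (see
#' [genomic_config()]). Reports per-locus posterior inclusion
#' probabilities.
#'
#' @inheritParams gibbs_brr
#' @param config a [genomic_config()] (model forced to `"BayesB"`).
#' @return A `GenomicModelFit`; `$pip` holds inclusion probabilities.
#' @export
gibbs_bayesb <- function(y, X, config = genomic_config("BayesB")) {
  config$model <- "BayesB"
  if (config$pi_zero >= 1)
    stop("pi prior mass entirely at 1 leaves no markers in the model")
  Xm <- .dosage_ready(X)
  res <- .wgr_fit(y, Xm, NULL, NULL, config)
  .new_fit(res, y, config, colnames(Xm), "SP",
           if (inherits(X, "MarkerMatrix")) unique(X$pop) else "P1")
}

#' Stacked design for across- and multi-population models
#'
#' Builds the row-stacked regression design for two populations sharing a
#' locus panel. `"AP"` stacks the dosage matrices with a single shared
#' effect block and one intercept per population. `"MP"` adds block-
#' diagonal population-specific effect blocks, so the design is
#' `(n1 + n2) x 3p` with zeros where the foreign population's specific
#' effects sit, and marker effects decompose as
#' `beta_1 = b0 + b1`, `beta_2 = b0 + b2`. `"SP"` returns the two designs
#' separately.
#'
#' @param X1,X2 [marker_matrix()] objects or plain dosage matrices with
#'   identical locus sets in identical order.
#' @param mode `"SP"`, `"AP"` or `"MP"`.
#' @return For `"SP"`, a list of two per-population designs; otherwise a
#'   `PopDesign` list with `X` (stacked design), `W` (population
#'   intercepts), `group` (effect-group index per column: 1 = common,
#'   2/3 = specific), `pop` (population label per row) and `loci`.
#' @export
build_pop_design <- function(X1, X2, mode = c("SP", "AP", "MP")) {
  mode <- match.arg(mode)
  M1 <- .dosage_ready(X1); M2 <- .dosage_ready(X2)
  if (!identical(colnames(M1), colnames(M2))) {
    off <- union(setdiff(colnames(M1), colnames(M2)),
                 setdiff(colnames(M2), colnames(M1)))
    stop("locus mismatch between populations: ",
         paste(head(off, 5), collapse = ", "),
         if (length(off) > 5) sprintf(" (+%d more)", length(off) - 5))
  }
  p <- ncol(M1)
  n1 <- nrow(M1); n2 <- nrow(M2)
  pop <- c(rep("P1", n1), rep("P2", n2))
  if (mode == "SP") {
    return(list(P1 = list(X = M1, W = NULL, group = rep(1L, p),
                          pop = rep("P1", n1), loci = colnames(M1)),
                P2 = list(X = M2, W = NULL, group = rep(1L, p),
                          pop = rep("P2", n2), loci = colnames(M2))))
  }
  W <- cbind(mu1 = as.numeric(pop == "P1"), mu2 = as.numeric(pop == "P2"))
  X0 <- rbind(M1, M2)
  if (mode == "AP") {
    out <- list(X = X0, W = W, group = rep(1L, p), pop = pop,
                loci = colnames(M1), mode = "AP")
  } else {
    Xs <- cbind(X0,
                rbind(M1, matrix(0, n2, p)),
                rbind(matrix(0, n1, p), M2))
    colnames(Xs) <- c(paste0(colnames(M1), "_b0"),
                      paste0(colnames(M1), "_b1"),
                      paste0(colnames(M1), "_b2"))
    out <- list(X = Xs, W = W, group = rep(1:3, each = p), pop = pop,
                loci = colnames(M1), mode = "MP")
  }
  class(out) <- "PopDesign"
  out
}

#' Fit a genomic model under the SP, AP or MP parameterization
#'
#' High-level fitting entry point. Splits a two-population marker set by
#' its population labels, builds the requested design with
#' [build_pop_design()], and runs the BRR or BayesB sampler. For `"SP"`,
#' one independent fit per population is returned inside a single
#' `GenomicModelFit` (`$fits`); `"AP"` and `"MP"` return one pooled fit
#' with per-population intercepts, and `"MP"` additionally stores the
#' common/specific effect decomposition in `$beta_mp`.
#'
#' @param y named numeric vector of responses, names matching the genotype
#'   ids of `markers`.
#' @param markers a [marker_matrix()] with population labels.
#' @param config a [genomic_config()].
#' @return A `GenomicModelFit`.
#' @export
fit_genomic <- function(y, markers, config = genomic_config()) {
  stopifnot(inherits(markers, "MarkerMatrix"))
  ids <- rownames(markers$dosage)
  if (is.null(names(y))) {
    if (length(y) != length(ids)) stop("y must be named by genotype")
    names(y) <- ids
  }
  keep <- intersect(ids, names(y))
  mm <- markers[match(keep, ids), ]
  y <- y[keep]
  pops <- unique(mm$pop)
  mode <- config$pop_mode
  if (length(pops) < 2L && mode != "SP") {
    stop("pop_mode '", mode, "' needs two populations; found ",
         length(pops))
  }
  sampler <- function(yy, X, W, group) {
    .wgr_fit(yy, X, W, group, config)
  }
  if (mode == "SP") {
    fits <- lapply(pops, function(q) {
      rows <- mm$pop == q
      Xq <- .dosage_ready(mm)[rows, , drop = FALSE]
      res <- sampler(y[rows], Xq, NULL, NULL)
      .new_fit(res, y[rows], config, colnames(Xq), "SP", q)
    })
    names(fits) <- pops
    out <- list(model = config$model, pop_mode = "SP", fits = fits,
                gebv = do.call(c, unname(lapply(fits, `[[`, "gebv"))),
                loci = colnames(mm$dosage), pops = pops, config = config)
    class(out) <- "GenomicModelFit"
    return(out)
  }
  rows1 <- mm$pop == pops[1]; rows2 <- mm$pop == pops[2]
  M <- .dosage_ready(mm)
  des <- build_pop_design(M[rows1, , drop = FALSE],
                          M[rows2, , drop = FALSE], mode)
  yy <- c(y[rows1], y[rows2])
  res <- .wgr_fit(yy, des$X, des$W, des$group, config)
  beta_mp <- NULL
  if (mode == "MP") {
    p <- length(des$loci)
    beta_mp <- cbind(b0 = res$b[seq_len(p)],
                     b1 = res$b[p + seq_len(p)],
                     b2 = res$b[2 * p + seq_len(p)])
    rownames(beta_mp) <- des$loci
  }
  fit <- .new_fit(res, yy, config, des$loci, mode,
                  pops, pop_of_row = des$pop, beta_mp = beta_mp)
  fit$pop_labels <- setNames(pops, c("P1", "P2"))
  fit
}

#' Genomic estimated breeding values for new genotypes
#'
#' Deterministic prediction `mu_hat + X_new beta_hat` from a fitted model,
#' using the training column centers. Under `"MP"`, the population-resolved
#' effects `b0 + b_p` are used, so the population of each new genotype must
#' be known; under `"SP"` the fit of the matching population is applied.
#'
#' @param fit a `GenomicModelFit`.
#' @param X_new a [marker_matrix()] or dosage matrix over the fit's loci.
#' @param population population label(s) for the new genotypes (taken from
#'   `X_new$pop` when it is a `MarkerMatrix`).
#' @return Named numeric vector of GEBVs.
#' @export
predict_gebv <- function(fit, X_new, population = NULL) {
  stopifnot(inherits(fit, "GenomicModelFit"))
  if (inherits(X_new, "MarkerMatrix") && is.null(population))
    population <- X_new$pop
  M <- .dosage_ready(X_new)
  if (fit$pop_mode == "SP" && !is.null(fit$fits)) {
    if (is.null(population)) {
      if (length(fit$fits) == 1L)
        population <- rep(fit$pops[1], nrow(M))
      else stop("population labels required for SP prediction")
    }
    unknown <- setdiff(unique(population), names(fit$fits))
    if (length(unknown) > 0)
      stop("unknown population label(s): ",
           paste(unknown, collapse = ", "))
    out <- rep(NA_real_, nrow(M))
    names(out) <- rownames(M)
    for (q in unique(population)) {
      rows <- population == q
      out[rows] <- predict_gebv(fit$fits[[q]], M[rows, , drop = FALSE])
    }
    return(out)
  }
  if (!identical(colnames(M), fit$loci)) {
    if (!all(fit$loci %in% colnames(M)))
      stop("X_new is missing loci used in the fit")
    M <- M[, fit$loci, drop = FALSE]
  }
  if (fit$pop_mode == "MP") {
    if (is.null(population)) stop("population labels required under MP")
    unknown <- setdiff(unique(population), fit$pops)
    if (length(unknown) > 0)
      stop("unknown population label(s): ",
           paste(unknown, collapse = ", "))
    out <- rep(NA_real_, nrow(M))
    names(out) <- rownames(M)
    for (q in unique(population)) {
      rows <- population == q
      wq <- match(q, fit$pops)
      beta <- fit$beta_mp[, 1] + fit$beta_mp[, 1 + wq]
      out[rows] <- fit$mu[wq] +
        as.numeric(M[rows, , drop = FALSE] %*% beta)
    }
    return(out)
  }
  # AP or single-population base fit
  if (fit$pop_mode == "AP") {
    if (is.null(population))
      stop("population labels required under AP (per-population intercept)")
    unknown <- setdiff(unique(population), fit$pops)
    if (length(unknown) > 0)
      stop("unknown population label(s): ",
           paste(unknown, collapse = ", "))
    mu <- fit$mu[match(population, fit$pops)]
  } else {
    mu <- fit$mu[[1]]
  }
  setNames(as.numeric(mu + M %*% fit$beta), rownames(M))
}
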