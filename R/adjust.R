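#' Validate a long-format phenotype table
#'
#' Checks the plot-level table contract: required columns present, values
#' finite and numeric, and no duplicated
#' `(genotype, location, year, block, trait)` keys. The environment id used
#' throughout the package is `location:year`.
#'
#' @param data data.frame with columns `genotype`, `location`, `year`,
#'   `block`, `trait`, `value` (and optionally `population`).
#' @return The validated data.frame, invisibly, with a `population` column
#'   filled in if absent.
#' @export
validate_phenotypes <- function(data) {
  req <- c("genotype", "location", "year", "block", "trait", "value")
  miss <- setdiff(req, names(data))
  if (length(miss) > 0)
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  if (!is.numeric(data$value)) stop("column 'value' must be numeric")
  if (any(!is.finite(data$value)))
    stop("non-finite phenotype values at row(s): ",
         paste(head(which(!is.finite(data$value)), 5), collapse = ", "))
  key <- paste(data$genotype, data$location, data$year, data$block,
               data$trait, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicated (genotype, environment, block, trait) record(s), ",
         "first at row ", which(duplicated(key))[1])
  if (is.null(data$population)) data$population <- "P1"
  invisible(data)
}

.env_of <- function(data) paste(data$location, data$year, sep = ":")

# connectivity of the genotype x environment incidence (two-way designs must
# be connected for genotype contrasts to be estimable)
.check_connected <- function(gen, env) {
  gl <- unique(gen); el <- unique(env)
  comp <- rep(NA_integer_, length(gl)); names(comp) <- gl
  adj_g <- split(env, gen)
  adj_e <- split(gen, env)
  cur <- 0L
  for (g0 in gl) {
    if (!is.na(comp[g0])) next
    cur <- cur + 1L
    queue <- g0
    while (length(queue) > 0) {
      g <- queue[[1]]; queue <- queue[-1]
      if (!is.na(comp[g])) next
      comp[g] <- cur
      nb <- unique(unlist(adj_e[unique(adj_g[[g]])], use.names = FALSE))
      queue <- c(queue, nb[is.na(comp[nb])])
    }
  }
  if (max(comp) > 1L) {
    small <- names(comp)[comp != as.integer(names(which.max(table(comp))))]
    stop("disconnected design: genotype(s) ",
         paste(head(small, 5), collapse = ", "),
         " share no environment with the rest of the trial")
  }
  invisible(TRUE)
}

# sum-to-zero OLS solve; falls back to the Moore-Penrose pseudoinverse on
# rank-deficient designs
.ols_sum2zero <- function(formula, df) {
  old <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(old))
  X <- model.matrix(formula, df)
  y <- df$value
  qrX <- qr(X)
  if (qrX$rank == ncol(X)) {
    beta <- qr.coef(qrX, y)
    fitted <- qr.fitted(qrX, y)
  } else {
    sv <- svd(X)
    pos <- sv$d > max(sv$d) * 1e-10
    beta <- sv$v[, pos, drop = FALSE] %*%
      ((t(sv$u[, pos, drop = FALSE]) %*% y) / sv$d[pos])
    beta <- setNames(as.numeric(beta), colnames(X))
    fitted <- as.numeric(X %*% beta)
  }
  rss <- sum((y - fitted)^2)
  df_res <- length(y) - qrX$rank
  list(beta = beta, X = X, fitted = fitted, rss = rss, df_res = df_res,
       rank = qrX$rank)
}

# expand sum-to-zero genotype coefficients to all levels and add intercept
.eblue_from_fit <- function(fit, glevels) {
  beta <- fit$beta
  gcoef <- beta[grep("^genotype[0-9]+$", names(beta))]
  gfull <- c(gcoef, -sum(gcoef))
  names(gfull) <- glevels
  mu <- beta[["(Intercept)"]]
  mu + gfull
}

.new_adjusted_means <- function(eblues, scenario, trait, fit, dropped,
                                data) {
  out <- list(
    means = data.frame(genotype = names(eblues),
                       eblue = as.numeric(eblues),
                       stringsAsFactors = FALSE),
    scenario = scenario, trait = trait,
    sigma2 = if (fit$df_res > 0) fit$rss / fit$df_res else NA_real_,
    df_residual = fit$df_res,
    n_env = length(unique(.env_of(data))),
    n_blocks = length(unique(data$block)),
    dropped = dropped)
  class(out) <- "AdjustedMeans"
  out
}

#' @export
print.AdjustedMeans <- function(x, ...) {
  cat(sprintf(
    "AdjustedMeans (scenario %s, trait %s): %d genotypes, %d env, %d blocks\n",
    x$scenario, x$trait, nrow(x$means), x$n_env, x$n_blocks))
  cat(sprintf("  residual variance %.4g on %d df; mean eBLUE %.4g\n",
              x$sigma2, x$df_residual, mean(x$means$eblue)))
  if (length(x$dropped) > 0)
    cat("  dropped genotypes:", paste(x$dropped, collapse = ", "), "\n")
  invisible(x)
}

#' Adjusted genotype means from a single-environment trial
#'
#' Fits the RCBD fixed-effects model `Y = mu + G_i + B_k + e` by ordinary
#' least squares with sum-to-zero constraints and returns empirical BLUEs
#' `mu + G_i` per genotype. Genotypes absent from the selected year are
#' reported in `dropped`, not silently lost.
#'
#' @param data a plot-level phenotype table (see [validate_phenotypes()]).
#' @param trait trait id to fit.
#' @param year the single harvest year.
#' @param location optional location filter (required when the year spans
#'   several locations).
#' @param scenario scenario label attached to the result (default "I").
#' @return An `AdjustedMeans` object.
#' @export
fit_single_year <- function(data, trait, year, location = NULL,
                            scenario = "I") {
  data <- validate_phenotypes(data)
  all_gen <- unique(data$genotype)
  sub <- data[data$trait == trait & data$year == year, , drop = FALSE]
  if (!is.null(location)) sub <- sub[sub$location %in% location, , drop = FALSE]
  if (length(unique(.env_of(sub))) != 1L)
    stop("fit_single_year needs exactly one environment; got ",
         length(unique(.env_of(sub))))
  dropped <- setdiff(all_gen, unique(sub$genotype))
  if (length(unique(sub$genotype)) < 2L) stop("need at least 2 genotypes")
  sub$genotype <- factor(sub$genotype)
  sub$block <- factor(sub$block)
  fit <- if (nlevels(sub$block) > 1L)
    .ols_sum2zero(value ~ genotype + block, sub)
  else
    .ols_sum2zero(value ~ genotype, sub)
  eblues <- .eblue_from_fit(fit, levels(sub$genotype))
  .new_adjusted_means(eblues, scenario, trait, fit, dropped, sub)
}

#' Adjusted genotype means across environments
#'
#' Fits the multi-environment fixed-effects model
#' `Y = mu + G_i + E_j + B_k|E_j + GE_ij + e` by ordinary least squares with
#' sum-to-zero constraints, where environments are `location:year` cells.
#' The reported eBLUE is the genotype main effect `mu + G_i`, marginal over
#' environments; on balanced complete data this equals the genotype's raw
#' mean (computed directly in that case). Designs with missing plots are
#' solved on the observed cells; rank-deficient designs fall back to the
#' minimum-norm least-squares solution.
#'
#' @param data plot-level phenotype table.
#' @param trait trait id.
#' @param years vector of harvest years to include.
#' @param location optional location filter.
#' @param scenario scenario label (default "custom"); the year-increment
#'   scenarios of the trial design are conventionally labelled I-VII.
#' @return An `AdjustedMeans` object.
#' @export
fit_multi_year <- function(data, trait, years, location = NULL,
                           scenario = "custom") {
  data <- validate_phenotypes(data)
  all_gen <- unique(data$genotype)
  sub <- data[data$trait == trait & data$year %in% years, , drop = FALSE]
  if (!is.null(location)) sub <- sub[sub$location %in% location, , drop = FALSE]
  sub$env <- .env_of(sub)
  if (length(unique(sub$env)) < 2L)
    stop("fit_multi_year needs at least 2 environments")
  dropped <- setdiff(all_gen, unique(sub$genotype))
  .check_connected(sub$genotype, sub$env)
  sub$genotype <- factor(sub$genotype)
  sub$envf <- factor(sub$env)
  sub$block <- factor(sub$block)

  # balanced complete data: genotype main effect equals the raw mean
  tab <- table(sub$genotype, sub$envf, sub$block)
  balanced <- all(tab == 1L)
  if (balanced) {
    gm <- tapply(sub$value, sub$genotype, mean)
    # fitted value of the full fixed model in closed form:
    # cell mean + block deviation within environment
    m_ge <- tapply(sub$value, list(sub$genotype, sub$envf), mean)
    m_eb <- tapply(sub$value, list(sub$envf, sub$block), mean)
    m_e <- tapply(sub$value, sub$envf, mean)
    gi <- as.integer(sub$genotype); ei <- as.integer(sub$envf)
    bi <- as.integer(sub$block)
    fitted <- m_ge[cbind(gi, ei)] + m_eb[cbind(ei, bi)] - m_e[ei]
    rss <- sum((sub$value - fitted)^2)
    g <- nlevels(sub$genotype); J <- nlevels(sub$envf)
    r <- nlevels(sub$block)
    df_res <- J * (g - 1L) * (r - 1L)
    fit <- list(rss = rss, df_res = df_res, rank = length(sub$value) - df_res)
    eblues <- setNames(as.numeric(gm), names(gm))
    return(.new_adjusted_means(eblues, scenario, trait, fit, dropped, sub))
  }
  fit <- .ols_sum2zero(value ~ genotype + envf + envf:block + genotype:envf,
                       sub)
  eblues <- .eblue_from_fit(fit, levels(sub$genotype))
  .new_adjusted_means(eblues, scenario, trait, fit, dropped, sub)
}

# closed-form ANOVA variance components for a balanced complete
# genotype x environment RCBD (equals REML for balanced data)
.vc_anova_balanced <- function(y, gen, env, blk) {
  g <- nlevels(gen); J <- nlevels(env); r <- nlevels(blk)
  n <- length(y)
  gm <- mean(y)
  m_g <- tapply(y, gen, mean)
  m_e <- tapply(y, env, mean)
  m_ge <- tapply(y, list(gen, env), mean)
  m_eb <- tapply(y, list(env, blk), mean)
  ss_g <- J * r * sum((m_g - gm)^2)
  ss_e <- g * r * sum((m_e - gm)^2)
  ss_b <- g * sum((sweep(m_eb, 1, m_e))^2)
  ss_ge <- r * sum((sweep(sweep(m_ge, 1, m_g), 2, m_e) + gm)^2)
  ss_tot <- sum((y - gm)^2)
  ss_err <- ss_tot - ss_g - ss_e - ss_b - ss_ge
  ms <- c(G = ss_g / (g - 1), E = ss_e / (J - 1), B = ss_b / (J * (r - 1)),
          GE = ss_ge / ((g - 1) * (J - 1)),
          err = ss_err / (J * (g - 1) * (r - 1)))
  vc <- c(
    sigma2_e = ms[["err"]],
    sigma2_GE = (ms[["GE"]] - ms[["err"]]) / r,
    sigma2_B = (ms[["B"]] - ms[["err"]]) / g,
    sigma2_G = (ms[["G"]] - ms[["GE"]]) / (J * r),
    sigma2_E = (ms[["E"]] - ms[["GE"]] - ms[["B"]] + ms[["err"]]) / (g * r))
  floored <- names(vc)[vc < 0]
  vc[vc < 0] <- 0
  list(vc = vc, floored = floored, loglik = NULL, iterations = 0L)
}

# EM-REML via Henderson's mixed-model equations for unbalanced data;
# random genotype, environment, block-within-environment and GxE
.vc_em_reml <- function(y, gen, env, blk, tol = 1e-8, max_iter = 5000L) {
  n <- length(y)
  X <- matrix(1, n, 1)
  Zs <- list(
    G = model.matrix(~ 0 + gen),
    E = model.matrix(~ 0 + env),
    B = model.matrix(~ 0 + env:blk),
    GE = model.matrix(~ 0 + gen:env))
  # keep only observed GxE / block cells
  Zs <- lapply(Zs, function(Z) Z[, colSums(Z) > 0, drop = FALSE])
  q <- vapply(Zs, ncol, 0L)
  Z <- do.call(cbind, Zs)
  idx <- split(seq_len(sum(q)), rep(seq_along(q), q))
  W <- cbind(X, Z)
  WtW <- crossprod(W)
  Wty <- crossprod(W, y)
  p <- ncol(X)
  vc <- rep(var(y) / 5, 4)
  varE <- var(y) / 5
  ll_trace <- numeric(0)
  small <- n <= 1500
  for (it in seq_len(max_iter)) {
    A <- WtW
    for (k in seq_along(idx)) {
      ii <- p + idx[[k]]
      diag(A)[ii] <- diag(A)[ii] + varE / max(vc[k], 1e-12)
    }
    Ainv <- solve(A)
    theta <- Ainv %*% Wty
    vc_new <- numeric(4)
    for (k in seq_along(idx)) {
      ii <- p + idx[[k]]
      uk <- theta[ii]
      vc_new[k] <- (sum(uk^2) + varE * sum(diag(Ainv)[ii])) / q[k]
    }
    varE_new <- (sum(y^2) - sum(theta * Wty)) / (n - p)
    if (small) {
      V <- diag(varE_new, n)
      for (k in seq_along(idx))
        V <- V + vc_new[k] * tcrossprod(Zs[[k]])
      cV <- chol(V)
      Vi_y <- backsolve(cV, forwardsolve(t(cV), y))
      Vi_X <- backsolve(cV, forwardsolve(t(cV), X))
      XtViX <- crossprod(X, Vi_X)
      beta <- solve(XtViX, crossprod(X, Vi_y))
      Py <- Vi_y - Vi_X %*% beta
      ll <- -0.5 * (2 * sum(log(diag(cV))) +
                      determinant(XtViX, logarithm = TRUE)$modulus +
                      sum(y * Py))
      ll_trace <- c(ll_trace, as.numeric(ll))
    }
    rel <- max(abs(c(vc_new - vc, varE_new - varE)) /
                 pmax(abs(c(vc, varE)), 1e-10))
    vc <- vc_new
    varE <- varE_new
    if (rel < tol) break
  }
  out <- c(sigma2_e = varE, sigma2_GE = vc[4], sigma2_B = vc[3],
           sigma2_G = vc[1], sigma2_E = vc[2])
  floored <- names(out)[out < 0]
  out[out < 0] <- 0
  list(vc = out, floored = floored, loglik = ll_trace, iterations = it)
}

#' Variance components and entry-mean heritability
#'
#' Treats genotype, environment, block-within-environment and genotype-by-
#' environment effects as random and estimates their variances. Balanced
#' complete designs use the closed-form ANOVA estimators (identical to REML
#' there); unbalanced designs use EM-REML on Henderson's mixed-model
#' equations (relative-change tolerance 1e-8, at most 5000 iterations, with
#' the restricted log-likelihood tracked for monitoring). Negative
#' components are floored at zero and flagged.
#'
#' Heritability is reported on an entry-mean basis:
#' `H2 = sigma2_G / (sigma2_G + sigma2_GE / J + sigma2_e / (J * r))`,
#' with `J` environments and `r` blocks.
#'
#' @param data plot-level phenotype table.
#' @param trait trait id.
#' @param location optional location filter.
#' @return A `VarianceComponents` list: `components` (named vector),
#'   `H2`, `method`, `floored`, `loglik` (EM trace when computed).
#' @export
estimate_h2 <- function(data, trait, location = NULL) {
  data <- validate_phenotypes(data)
  sub <- data[data$trait == trait, , drop = FALSE]
  if (!is.null(location)) sub <- sub[sub$location %in% location, , drop = FALSE]
  sub$env <- factor(.env_of(sub))
  sub$genotype <- factor(sub$genotype)
  sub$block <- factor(sub$block)
  if (nlevels(sub$env) < 2L || nlevels(sub$block) < 2L)
    stop("estimate_h2 needs at least 2 environments and 2 blocks")
  tab <- table(sub$genotype, sub$env, sub$block)
  balanced <- all(tab == 1L)
  res <- if (balanced)
    .vc_anova_balanced(sub$value, sub$genotype, sub$env, sub$block)
  else
    .vc_em_reml(sub$value, sub$genotype, sub$env, sub$block)
  J <- nlevels(sub$env)
  r <- nlevels(sub$block)
  vc <- res$vc
  denom <- vc[["sigma2_G"]] + vc[["sigma2_GE"]] / J +
    vc[["sigma2_e"]] / (J * r)
  H2 <- if (denom > 0) vc[["sigma2_G"]] / denom else 0
  out <- list(components = vc, H2 = H2,
              method = if (balanced) "anova" else "em-reml",
              floored = res$floored, loglik = res$loglik,
              n_env = J, n_blocks = r)
  class(out) <- "VarianceComponents"
  out
}

#' @export
print.VarianceComponents <- function(x, ...) {
  cat("VarianceComponents (", x$method, "):\n", sep = "")
  print(round(x$components, 5))
  cat(sprintf("  entry-mean H2 = %.3f (%d env x %d blocks)\n",
              x$H2, x$n_env, x$n_blocks))
  if (length(x$floored) > 0)
    cat("  floored at zero:", paste(x$floored, collapse = ", "), "\n")
  invisible(x)
}
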