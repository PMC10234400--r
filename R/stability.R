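#' Assemble a complete genotype x environment table of adjusted means
#'
#' Takes per-environment adjusted means (long data.frame with columns
#' `genotype`, `env`, `value`, or a named list of `AdjustedMeans` keyed by
#' environment id) and returns the complete two-way table that the AMMI and
#' Finlay-Wilkinson estimators require. Genotypes with missing cells are
#' either dropped or EM-imputed under the additive model
#' (`mu + g_i + e_j` fill, iterated to convergence, optionally with a
#' low-rank interaction refinement), with a report of affected cells.
#'
#' @param means long data.frame (`genotype`, `env`, `value`) or named list
#'   of `AdjustedMeans`.
#' @param missing one of `"drop"` (remove genotypes not observed in all
#'   environments) or `"em"` (EM-impute missing cells).
#' @param em_rank rank of the interaction term used during EM imputation
#'   (0 = additive fill).
#' @param tol EM convergence tolerance on imputed values.
#' @return A `TwoWayTable`: the matrix plus `report` describing dropped
#'   genotypes or imputed cells.
#' @export
prepare_two_way <- function(means, missing = c("drop", "em"),
                            em_rank = 0L, tol = 1e-8) {
  missing <- match.arg(missing)
  if (is.list(means) && !is.data.frame(means)) {
    stopifnot(!is.null(names(means)))
    means <- do.call(rbind, lapply(names(means), function(e) {
      m <- means[[e]]
      stopifnot(inherits(m, "AdjustedMeans"))
      data.frame(genotype = m$means$genotype, env = e,
                 value = m$means$eblue, stringsAsFactors = FALSE)
    }))
  }
  stopifnot(all(c("genotype", "env", "value") %in% names(means)))
  gl <- sort(unique(means$genotype))
  el <- unique(means$env)
  if (length(el) < 2L) stop("need at least 2 environments")
  tab <- matrix(NA_real_, length(gl), length(el),
                dimnames = list(gl, el))
  tab[cbind(match(means$genotype, gl), match(means$env, el))] <- means$value
  report <- list(dropped = character(0), imputed = NULL)
  if (anyNA(tab)) {
    if (missing == "drop") {
      bad <- rownames(tab)[rowSums(is.na(tab)) > 0]
      report$dropped <- bad
      tab <- tab[!(rownames(tab) %in% bad), , drop = FALSE]
    } else {
      na_idx <- which(is.na(tab), arr.ind = TRUE)
      report$imputed <- data.frame(genotype = rownames(tab)[na_idx[, 1]],
                                   env = colnames(tab)[na_idx[, 2]],
                                   stringsAsFactors = FALSE)
      # start from the additive fill, iterate additive + rank-r refit
      fill <- mean(tab, na.rm = TRUE)
      tab[na_idx] <- fill
      for (it in 1:500) {
        mu <- mean(tab)
        gi <- rowMeans(tab) - mu
        ej <- colMeans(tab) - mu
        pred <- outer(gi, ej, "+") + mu
        if (em_rank > 0) {
          resid <- tab - pred
          sv <- svd(resid, nu = em_rank, nv = em_rank)
          pred <- pred + sv$u %*% diag(sv$d[seq_len(em_rank)],
                                       em_rank) %*% t(sv$v)
        }
        new_vals <- pred[na_idx]
        delta <- max(abs(new_vals - tab[na_idx]))
        tab[na_idx] <- new_vals
        if (delta < tol) break
      }
    }
  }
  if (nrow(tab) < 3L || ncol(tab) < 3L)
    warning("fewer than 3 genotypes or environments remain; ",
            "AMMI decomposition will not be possible")
  structure(tab, class = c("TwoWayTable", "matrix"), report = report)
}

#' AMMI decomposition of a genotype x environment table
#'
#' Fits the additive main effects and multiplicative interaction model
#' `Y_ij = mu + g_i + e_j + sum_n lambda_n gamma_in delta_jn + rho_ij`:
#' grand mean and marginal deviations for the main effects, then a singular
#' value decomposition of the double-centered interaction residual. Retains
#' all `min(g, e) - 1` components, so the full reconstruction reproduces the
#' table exactly (up to numerical precision). Score signs are fixed by
#' making the largest-magnitude element of each genotype-score column
#' positive, so output is deterministic across linear-algebra backends.
#'
#' @param table a complete genotype x environment matrix (a `TwoWayTable`
#'   or plain matrix), at least 3 x 3.
#' @param sigma2 optional plot-level residual variance from the adjustment
#'   stage (used by [select_n_components()]).
#' @param nrep optional number of replicates behind each cell mean.
#' @return An `AMMIResult`: `mu`, `g`, `e`, `lambda` (descending),
#'   `gamma` (genotype scores), `delta` (environment scores),
#'   `var_fraction`, `interaction` (the double-centered matrix), `sigma2`,
#'   `nrep`.
#' @export
ammi_decompose <- function(table, sigma2 = NULL, nrep = NULL) {
  tab <- unclass(table)
  stopifnot(is.matrix(tab), !anyNA(tab))
  g <- nrow(tab); e <- ncol(tab)
  if (g < 3L || e < 3L) stop("AMMI needs at least a 3 x 3 table")
  if (is.null(rownames(tab))) rownames(tab) <- sprintf("G%02d", seq_len(g))
  if (is.null(colnames(tab))) colnames(tab) <- sprintf("E%d", seq_len(e))
  mu <- mean(tab)
  gi <- rowMeans(tab) - mu
  ej <- colMeans(tab) - mu
  inter <- tab - outer(gi, ej, "+") - mu
  K <- min(g, e) - 1L
  sv <- svd(inter)
  lambda <- sv$d[seq_len(K)]
  gamma <- sv$u[, seq_len(K), drop = FALSE]
  delta <- sv$v[, seq_len(K), drop = FALSE]
  # deterministic sign convention; null components (constant or purely
  # additive tables) get zero scores by convention
  null_tol <- max(lambda[1], 0) * 1e-12
  for (k in seq_len(K)) {
    if (lambda[k] <= null_tol) {
      lambda[k] <- 0
      gamma[, k] <- 0
      delta[, k] <- 0
      next
    }
    j <- which.max(abs(gamma[, k]))
    if (gamma[j, k] < 0) {
      gamma[, k] <- -gamma[, k]
      delta[, k] <- -delta[, k]
    }
  }
  rownames(gamma) <- rownames(tab)
  rownames(delta) <- colnames(tab)
  ss <- sum(lambda^2)
  out <- list(mu = mu, g = gi, e = ej, lambda = lambda,
              gamma = gamma, delta = delta,
              var_fraction = if (ss > 0) lambda^2 / ss else rep(0, K),
              interaction = inter, ss_interaction = sum(inter^2),
              sigma2 = sigma2, nrep = nrep,
              n_genotypes = g, n_environments = e)
  class(out) <- "AMMIResult"
  out
}

#' @export
print.AMMIResult <- function(x, ...) {
  cat(sprintf("AMMI decomposition: %d genotypes x %d environments\n",
              x$n_genotypes, x$n_environments))
  k <- min(5L, length(x$lambda))
  cat("  singular values:",
      paste(sprintf("%.3f", x$lambda[seq_len(k)]), collapse = ", "),
      if (length(x$lambda) > k) "..." else "", "\n")
  cat("  variance fraction (PC1, PC2):",
      paste(sprintf("%.1f%%", 100 * x$var_fraction[seq_len(min(2, k))]),
            collapse = ", "), "\n")
  invisible(x)
}

#' Number of significant AMMI components (F test)
#'
#' Decides how many multiplicative components the interaction supports,
#' against the plot-level error variance `sigma2 / nrep` from the
#' adjustment stage (degrees of freedom `df_error`, `Inf` when the error
#' variance is treated as known). Components are assigned Gollob degrees
#' of freedom `df_n = g + e - 1 - 2n`. Two selection rules are available:
#'
#' * `"sequential"` (default): residual F test in the style of Cornelius —
#'   `N` is the smallest `n` such that the interaction left after removing
#'   the first `n` components is no longer significant at `alpha`. Under a
#'   pure-noise interaction this rule keeps 0 components with probability
#'   `1 - alpha`, i.e. it holds its nominal type-I error.
#' * `"gollob"`: per-component F test `(lambda_n^2 / df_n) / (sigma2 /
#'   nrep)`; `N` is the largest run of consecutively significant leading
#'   components. This is the classical per-axis table but is liberal under
#'   the null.
#'
#' Without `sigma2`/`nrep`, the remaining components are pooled as the
#' error term. The result is capped at `max_n` (default 2, the usual
#' working choice for stability indices over a handful of environments).
#' Components whose degrees of freedom are non-positive are untestable and
#' excluded.
#'
#' @param result an [ammi_decompose()] result.
#' @param alpha significance level (default 0.05).
#' @param sigma2,nrep,df_error error variance, replicate count and error df;
#'   default to the values stored in `result`.
#' @param max_n cap on the returned component count (default 2).
#' @param method `"sequential"` or `"gollob"` (see above).
#' @return Integer `N`, with the per-component test table attached as
#'   attribute `"tests"`.
#' @export
select_n_components <- function(result, alpha = 0.05, sigma2 = NULL,
                                nrep = NULL, df_error = Inf, max_n = 2L,
                                method = c("sequential", "gollob")) {
  stopifnot(inherits(result, "AMMIResult"))
  method <- match.arg(method)
  g <- result$n_genotypes; e <- result$n_environments
  lambda <- result$lambda
  K <- length(lambda)
  df_n <- g + e - 1 - 2 * seq_len(K)
  testable <- df_n > 0
  if (is.null(sigma2)) sigma2 <- result$sigma2
  if (is.null(nrep)) nrep <- result$nrep
  have_error <- !is.null(sigma2) && !is.null(nrep)
  df_int <- (g - 1) * (e - 1)
  Fv <- pv <- rep(NA_real_, K)
  if (method == "sequential") {
    # test H0: no interaction beyond component n, for n = 0, 1, ...
    N <- max(which(testable), 0L)
    for (n in 0:sum(testable)) {
      ss_rest <- sum(lambda^2) - sum(lambda[seq_len(n)]^2)
      df_rest <- df_int - sum(df_n[seq_len(n)])
      if (df_rest <= 0) break
      if (have_error) {
        Fstat <- (ss_rest / df_rest) / (sigma2 / nrep)
        pval <- pf(Fstat, df_rest, df_error, lower.tail = FALSE)
      } else break
      if (n + 1 <= K) { Fv[n + 1] <- Fstat; pv[n + 1] <- pval }
      if (pval >= alpha) { N <- n; break }
    }
    if (!have_error) {
      # no external error: fall back to pooled per-component testing
      return(select_n_components(result, alpha, NULL, NULL, df_error,
                                 max_n, method = "gollob"))
    }
  } else {
    for (n in which(testable)) {
      ms_n <- lambda[n]^2 / df_n[n]
      if (have_error) {
        denom <- sigma2 / nrep
        dfe <- df_error
      } else {
        rest <- seq_len(K) > n & testable
        if (!any(rest)) next
        denom <- sum(lambda[rest]^2) / sum(df_n[rest])
        dfe <- sum(df_n[rest])
      }
      if (denom <= 0) next
      Fv[n] <- ms_n / denom
      pv[n] <- pf(Fv[n], df_n[n], dfe, lower.tail = FALSE)
    }
    sig <- !is.na(pv) & pv < alpha
    N <- 0L
    for (n in seq_len(K)) {
      if (isTRUE(sig[n])) N <- n else break
    }
  }
  N <- min(N, max_n)
  structure(as.integer(N),
            tests = data.frame(component = seq_len(K), df = df_n,
                               F = Fv, p = pv, method = method))
}

#' AMMI stability indices (SPC and ASV)
#'
#' Genotype interaction PC scores are `s_in = sqrt(lambda_n) * gamma_in`.
#' The score-sum index is `SPC_i = sum_{n<=N} |s_in|` (absolute values, so
#' opposite-signed components cannot cancel; lower = more stable). The AMMI
#' stability value is the Purchase-style weighted length of the first two
#' PC scores, `ASV_i = sqrt((SS1/SS2 * s_i1)^2 + s_i2^2)` with
#' `SSn = lambda_n^2`; lower ASV = more stable. A genotype with zero
#' interaction scores has ASV 0 (maximally stable). If `lambda_2 = 0` the
#' ASV weight is undefined and `|s_i1|` is returned with a warning flag.
#'
#' @param result an [ammi_decompose()] result.
#' @param N number of components for SPC (default 2).
#' @return data.frame with columns `genotype`, `spc`, `asv` plus attribute
#'   `"asv_degenerate"` when the PC2 weight was undefined.
#' @export
ammi_stability <- function(result, N = 2L) {
  stopifnot(inherits(result, "AMMIResult"), N >= 1L)
  N <- min(N, length(result$lambda))
  s <- sweep(result$gamma, 2, sqrt(result$lambda), "*")
  spc <- rowSums(abs(s[, seq_len(N), drop = FALSE]))
  degenerate <- FALSE
  if (length(result$lambda) >= 2L && result$lambda[2] > 0) {
    w <- result$lambda[1]^2 / result$lambda[2]^2
    asv <- sqrt((w * s[, 1])^2 + s[, 2]^2)
  } else {
    degenerate <- TRUE
    if (length(result$lambda) >= 1L && result$lambda[1] > 0) {
      warning("lambda_2 = 0: ASV weight undefined, returning |s_1|")
      asv <- abs(s[, 1])
    } else {
      asv <- rep(0, nrow(s))
    }
  }
  structure(data.frame(genotype = rownames(result$gamma),
                       spc = as.numeric(spc), asv = as.numeric(asv),
                       stringsAsFactors = FALSE),
            asv_degenerate = degenerate)
}

#' Finlay-Wilkinson regression stability
#'
#' Two-step estimator: (1) environment effects as environment means minus
#' the grand mean; (2) per-genotype ordinary least squares of the cell means
#' on the environment effects. The fitted slope is reported as a deviation
#' `b_i` from 1, so `b_i = 0` means average responsiveness; the stability
#' index is `|b_i|`. A genotype with a constant response has fitted slope 0
#' (`b_i = -1`) and is flagged non-responsive.
#'
#' @param table complete genotype x environment matrix.
#' @param shrink optional ridge penalty on the slope deviations (defaults to
#'   0, the plain two-step OLS estimator).
#' @return An `FWResult`: data.frame `coef` (genotype, intercept,
#'   slope_dev, abs_slope_dev, resid_var, non_responsive), environment
#'   effects `h`, and `mu`.
#' @export
fw_fit <- function(table, shrink = 0) {
  tab <- unclass(table)
  stopifnot(is.matrix(tab), !anyNA(tab))
  if (ncol(tab) < 2L) stop("need at least 2 environments")
  if (is.null(rownames(tab)))
    rownames(tab) <- sprintf("G%02d", seq_len(nrow(tab)))
  mu <- mean(tab)
  h <- colMeans(tab) - mu
  ssh <- sum(h^2)
  if (ssh <= 0 || length(unique(round(h, 12))) < 2L)
    stop("environment effects have no variance; FW slopes are inestimable")
  gi <- rowMeans(tab) - mu
  centered <- sweep(tab, 1, rowMeans(tab))
  slope <- as.numeric(centered %*% h) / (ssh + shrink)
  slope_dev <- slope - 1
  resid <- centered - outer(slope, h)
  dfres <- max(ncol(tab) - 2L, 1L)
  out <- list(
    coef = data.frame(genotype = rownames(tab),
                      intercept = as.numeric(gi),
                      slope_dev = slope_dev,
                      abs_slope_dev = abs(slope_dev),
                      resid_var = rowSums(resid^2) / dfres,
                      non_responsive = abs(slope) < 1e-8,
                      stringsAsFactors = FALSE),
    h = h, mu = mu)
  class(out) <- "FWResult"
  out
}

#' @export
print.FWResult <- function(x, ...) {
  cat(sprintf("Finlay-Wilkinson fit: %d genotypes x %d environments\n",
              nrow(x$coef), length(x$h)))
  cat(sprintf("  mean slope deviation %.4g (SD %.3f); %d non-responsive\n",
              mean(x$coef$slope_dev), sd(x$coef$slope_dev),
              sum(x$coef$non_responsive)))
  invisible(x)
}

#' Combined stability table for one trait
#'
#' Convenience wrapper running [ammi_decompose()], [select_n_components()],
#' [ammi_stability()] and [fw_fit()] on one two-way table and joining the
#' results per genotype, with ranks (1 = most stable).
#'
#' @param table complete genotype x environment matrix.
#' @param trait trait label carried into the output.
#' @param sigma2,nrep optional plot-level error variance and replicate count
#'   for the component F test.
#' @param alpha significance level for [select_n_components()].
#' @return data.frame: genotype, trait, spc, asv, fw_slope_dev,
#'   fw_abs_slope, asv_rank, fw_rank, plus attributes `n_components` and
#'   `ammi`/`fw` with the underlying fits.
#' @export
stability_summary <- function(table, trait = "trait", sigma2 = NULL,
                              nrep = NULL, alpha = 0.05) {
  am <- ammi_decompose(table, sigma2 = sigma2, nrep = nrep)
  N <- select_n_components(am, alpha = alpha)
  N_use <- max(as.integer(N), 1L)
  st <- ammi_stability(am, N = max(N_use, 2L))
  fw <- fw_fit(table)
  stopifnot(identical(st$genotype, fw$coef$genotype))
  out <- data.frame(genotype = st$genotype, trait = trait,
                    spc = st$spc, asv = st$asv,
                    fw_slope_dev = fw$coef$slope_dev,
                    fw_abs_slope = fw$coef$abs_slope_dev,
                    stringsAsFactors = FALSE)
  out$asv_rank <- rank(out$asv, ties.method = "first")
  out$fw_rank <- rank(out$fw_abs_slope, ties.method = "first")
  attr(out, "n_components") <- as.integer(N)
  attr(out, "ammi") <- am
  attr(out, "fw") <- fw
  out
}
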