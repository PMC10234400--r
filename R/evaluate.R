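#' Training/validation scenario for year-increment forecasting
#'
#' @param label scenario label (conventionally I-VII).
#' @param train_years years used to compute training eBLUEs.
#' @param valid_years years whose eBLUEs are predicted.
#' @param location optional location filter applied to both sets.
#' @return A `ScenarioSpec` list.
#' @export
scenario_spec <- function(label, train_years, valid_years,
                          location = NULL) {
  if (length(train_years) == 0) stop("scenario with empty training years")
  if (length(intersect(train_years, valid_years)) > 0)
    stop("training and validation years must be disjoint")
  structure(list(label = label, train_years = train_years,
                 valid_years = valid_years, location = location),
            class = "ScenarioSpec")
}

#' Cumulative year-increment scenarios
#'
#' Builds the standard ladder of scenarios in which training data grow one
#' harvest year at a time while the validation years stay fixed: scenario I
#' trains on the first year only, scenario II on the first two, and so on.
#'
#' @param train_pool ordered vector of candidate training years.
#' @param valid_years fixed validation years.
#' @param location optional location filter.
#' @return List of [scenario_spec()] objects labelled with Roman numerals.
#' @export
make_increment_scenarios <- function(train_pool, valid_years,
                                     location = NULL) {
  lapply(seq_along(train_pool), function(k) {
    scenario_spec(as.character(utils::as.roman(k)), train_pool[seq_len(k)],
                  valid_years, location = location)
  })
}

.eblue_for_years <- function(data, trait, years, location, scenario) {
  if (length(years) == 1L)
    fit_single_year(data, trait, years, location = location,
                    scenario = scenario)
  else
    fit_multi_year(data, trait, years, location = location,
                   scenario = scenario)
}

#' Year-increment forecasting of genotype performance
#'
#' For each scenario, computes training eBLUEs from the training years,
#' fits a whole-genome regression per population, predicts GEBVs, and
#' reports predictive ability as the Pearson correlation between predicted
#' GEBVs and the validation-year eBLUEs.
#'
#' @param data plot-level phenotype table.
#' @param markers a [marker_matrix()] covering the genotypes.
#' @param scenarios list of [scenario_spec()] objects.
#' @param config a [genomic_config()]; fits are run per population
#'   (SP-style) within each scenario.
#' @param trait trait id (default the first trait in `data`).
#' @return A `PredictionReport` whose `$results` has one row per
#'   scenario x population with columns `scenario`, `n_train_years`,
#'   `population`, `trait`, `r`.
#' @export
run_year_increment <- function(data, markers, scenarios, config,
                               trait = NULL) {
  data <- validate_phenotypes(data)
  if (is.null(trait)) trait <- data$trait[1]
  stopifnot(inherits(markers, "MarkerMatrix"))
  ids <- rownames(markers$dosage)
  rows <- list()
  for (sc in scenarios) {
    stopifnot(inherits(sc, "ScenarioSpec"))
    if (!all(sc$valid_years %in% unique(data$year)))
      stop("validation years absent from the data in scenario ", sc$label)
    valid <- .eblue_for_years(data, trait, sc$valid_years, sc$location,
                              sc$label)
    train <- .eblue_for_years(data, trait, sc$train_years, sc$location,
                              sc$label)
    for (q in unique(markers$pop)) {
      gen_q <- ids[markers$pop == q]
      tr <- train$means[train$means$genotype %in% gen_q, ]
      va <- valid$means[valid$means$genotype %in% gen_q, ]
      common <- intersect(tr$genotype, va$genotype)
      mm_q <- markers[match(common, ids), ]
      yy <- setNames(tr$eblue[match(common, tr$genotype)], common)
      fit <- if (config$model == "BayesB")
        gibbs_bayesb(yy, mm_q, config) else gibbs_brr(yy, mm_q, config)
      gebv <- predict_gebv(fit, mm_q)
      obs <- va$eblue[match(common, va$genotype)]
      rows[[length(rows) + 1L]] <- data.frame(
        scenario = sc$label, n_train_years = length(sc$train_years),
        population = q, trait = trait,
        r = cor(gebv, obs), stringsAsFactors = FALSE)
    }
  }
  out <- list(results = do.call(rbind, rows), kind = "year_increment",
              config = config)
  class(out) <- "PredictionReport"
  out
}

#' Cross-validated genomic prediction
#'
#' Repeated k-fold cross-validation of a genomic model. Folds are random,
#' stratified by population (each population is split into k folds
#' separately, so pooled fits never extrapolate entirely across
#' populations), and seeded per repetition, so the assignment is invariant
#' to genotype reordering. Predictive ability per repetition is the Pearson
#' correlation between the pooled out-of-fold GEBVs and the observed
#' values.
#'
#' @param y named numeric vector (adjusted means or stability index per
#'   genotype).
#' @param markers a [marker_matrix()].
#' @param config a [genomic_config()].
#' @param k number of folds (default 10).
#' @param reps number of repetitions (default 5).
#' @param seed base seed; repetition `r` uses `seed + r`.
#' @return A `PredictionReport` with `$results` (one row per repetition),
#'   `$summary` (mean and SD of predictive ability), `$folds` and
#'   `$n_fits` (exactly `k * reps`).
#' @export
run_cv <- function(y, markers, config = genomic_config(), k = 10L,
                   reps = 5L, seed = 1L) {
  stopifnot(inherits(markers, "MarkerMatrix"))
  ids <- rownames(markers$dosage)
  if (is.null(names(y))) {
    stopifnot(length(y) == length(ids))
    names(y) <- ids
  }
  keep <- intersect(ids, names(y))
  mm <- markers[match(keep, ids), ]
  y <- y[keep]
  n <- length(y)
  if (k < 2L) stop("k must be at least 2")
  if (k > n) stop("k = ", k, " exceeds the number of genotypes (", n, ")")
  folds_all <- list()
  fit_log <- list()
  res <- data.frame()
  for (r in seq_len(reps)) {
    set.seed(seed + r)
    fold <- integer(n)
    names(fold) <- keep
    for (q in sort(unique(mm$pop))) {
      idx <- which(mm$pop == q)
      # deterministic given the seed and stratification, invariant to the
      # order genotypes arrive in
      idx <- idx[order(names(y)[idx])]
      fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
    folds_all[[r]] <- fold
    pred <- rep(NA_real_, n)
    names(pred) <- keep
    for (f in seq_len(k)) {
      test <- fold == f
      cfg <- config
      cfg$seed <- NULL
      fit <- fit_genomic(y[!test], mm[!test, ], cfg)
      pred[test] <- predict_gebv(fit, mm[test, ])
      fit_log[[length(fit_log) + 1L]] <- list(rep = r, fold = f,
                                              n_train = sum(!test))
    }
    res <- rbind(res, data.frame(rep = r, r = cor(pred, y)))
  }
  out <- list(results = res,
              summary = data.frame(mean_r = mean(res$r), sd_r = sd(res$r),
                                   k = k, reps = reps),
              folds = folds_all, n_fits = length(fit_log),
              fit_log = fit_log, kind = "cv", config = config, seed = seed)
  class(out) <- "PredictionReport"
  out
}

#' @export
print.PredictionReport <- function(x, ...) {
  cat("PredictionReport (", x$kind, ")\n", sep = "")
  if (!is.null(x$summary))
    cat(sprintf("  predictive ability %.3f (SD %.3f) over %d x %d fits\n",
                x$summary$mean_r, x$summary$sd_r, x$summary$k,
                x$summary$reps))
  else print(x$results)
  invisible(x)
}

#' Correlation between performance and stability
#'
#' Pearson correlation (with two-sided test) between adjusted genotype
#' means and each stability index, per trait. Significance is annotated
#' with the usual stars (0.05, 0.01, 0.001). Zero-variance inputs yield
#' `NA` with a note rather than an error.
#'
#' @param means `AdjustedMeans` object or named numeric vector of
#'   performance values.
#' @param stab stability table from [stability_summary()].
#' @param metrics which stability columns to correlate against
#'   (default ASV and the signed FW slope deviation).
#' @return data.frame: trait, metric, r, p, stars, n.
#' @export
correlate_performance_stability <- function(means, stab,
    metrics = c(ammi = "asv", fw = "fw_slope_dev")) {
  perf <- if (inherits(means, "AdjustedMeans"))
    setNames(means$means$eblue, means$means$genotype) else means
  common <- intersect(names(perf), stab$genotype)
  if (length(common) < 3L) stop("need at least 3 common genotypes")
  rows <- lapply(seq_along(metrics), function(i) {
    v <- stab[[metrics[i]]][match(common, stab$genotype)]
    x <- perf[common]
    if (sd(x) == 0 || sd(v) == 0) {
      return(data.frame(trait = stab$trait[1], metric = names(metrics)[i],
                        r = NA_real_, p = NA_real_, stars = "undefined",
                        n = length(common), stringsAsFactors = FALSE))
    }
    ct <- cor.test(x, v)
    stars <- if (ct$p.value < 0.001) "***" else if (ct$p.value < 0.01)
      "**" else if (ct$p.value < 0.05) "*" else "ns"
    data.frame(trait = stab$trait[1], metric = names(metrics)[i],
               r = unname(ct$estimate), p = ct$p.value, stars = stars,
               n = length(common), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Co-selection of top performance and top stability genotypes
#'
#' Ranks genotypes by performance (direction declared per trait), by AMMI
#' stability (lowest ASV) and by Finlay-Wilkinson stability (absolute slope
#' deviation nearest zero), selects the top `perf_frac` / `stab_frac`
#' fractions (floor rule, minimum 1, ties broken by genotype id) and
#' reports Venn-style intersection counts.
#'
#' @param means `AdjustedMeans` or named numeric performance vector.
#' @param stab stability table from [stability_summary()].
#' @param perf_frac fraction selected on performance (default 0.10).
#' @param stab_frac fraction selected on each stability index
#'   (default 0.20).
#' @param direction `"higher"` if large trait values are favourable (yield,
#'   vigor, bean weight) or `"lower"` (disease severity, maturation
#'   scores). No silent default: must be declared.
#' @return A `SelectionOverlap`: selected sets, pairwise and triple
#'   intersection counts and sizes.
#' @export
select_overlap <- function(means, stab, perf_frac = 0.10,
                           stab_frac = 0.20,
                           direction = c("higher", "lower")) {
  if (missing(direction))
    stop("trait direction must be declared ('higher' or 'lower'); ",
         "there is no silent default")
  direction <- match.arg(direction)
  perf <- if (inherits(means, "AdjustedMeans"))
    setNames(means$means$eblue, means$means$genotype) else means
  common <- sort(intersect(names(perf), stab$genotype))
  perf <- perf[common]
  st <- stab[match(common, stab$genotype), ]
  n <- length(common)
  take <- function(score, frac, decreasing) {
    sz <- max(1L, floor(n * frac))
    ord <- order(if (decreasing) -score else score, common)
    common[ord[seq_len(sz)]]
  }
  top_perf <- take(perf, perf_frac, direction == "higher")
  top_asv <- take(st$asv, stab_frac, FALSE)
  top_fw <- take(st$fw_abs_slope, stab_frac, FALSE)
  out <- list(
    sets = list(performance = top_perf, ammi = top_asv, fw = top_fw),
    sizes = c(performance = length(top_perf), ammi = length(top_asv),
              fw = length(top_fw)),
    intersections = c(
      perf_ammi = length(intersect(top_perf, top_asv)),
      perf_fw = length(intersect(top_perf, top_fw)),
      ammi_fw = length(intersect(top_asv, top_fw)),
      all3 = length(Reduce(intersect, list(top_perf, top_asv, top_fw)))),
    n = n, perf_frac = perf_frac, stab_frac = stab_frac,
    direction = direction)
  class(out) <- "SelectionOverlap"
  out
}

#' @export
print.SelectionOverlap <- function(x, ...) {
  cat(sprintf(
    "SelectionOverlap: %d genotypes; top %.0f%% performance (%s better), top %.0f%% stability\n",
    x$n, 100 * x$perf_frac, x$direction, 100 * x$stab_frac))
  cat("  set sizes:", paste(names(x$sizes), x$sizes, collapse = ", "),
      "\n")
  cat("  intersections:",
      paste(names(x$intersections), x$intersections, collapse = ", "),
      "\n")
  invisible(x)
}
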