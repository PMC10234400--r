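#' Read a long-format phenotype table
#'
#' Reads tab- or comma-separated plot-level phenotype data. Required
#' columns are `genotype`, `location`, `year`, `block`, `trait`, `value`
#' (`population` is optional); `col_map` renames non-standard headers.
#' Extra columns are preserved as passthrough metadata. Duplicate
#' `(genotype, environment, block, trait)` records and non-numeric values
#' are rejected with the offending row reported.
#'
#' @param path file path.
#' @param sep field separator; `NULL` (default) auto-detects tab vs comma
#'   from the header line.
#' @param col_map optional named character vector mapping standard names to
#'   the file's column names, e.g. `c(genotype = "clone_id")`.
#' @return A validated phenotype data.frame.
#' @export
read_phenotypes <- function(path, sep = NULL, col_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep)) {
    hdr <- readLines(path, n = 1L)
    sep <- if (grepl("\t", hdr)) "\t" else ","
  }
  df <- read.table(path, header = TRUE, sep = sep,
                   stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(col_map)) {
    for (std in names(col_map)) {
      j <- match(col_map[[std]], names(df))
      if (is.na(j)) stop("col_map column not found: ", col_map[[std]])
      names(df)[j] <- std
    }
  }
  req <- c("genotype", "location", "year", "block", "trait", "value")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0)
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  if (!is.numeric(df$value)) {
    bad <- suppressWarnings(which(is.na(as.numeric(df$value))))
    stop("non-numeric value at line ", bad[1] + 1L, " of ", path)
  }
  validate_phenotypes(df)
  df
}

#' Write a phenotype table as tab-separated text
#' @param data phenotype data.frame.
#' @param path output path.
#' @export
write_phenotypes <- function(data, path) {
  write.table(data, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read marker genotypes from VCF or a dosage matrix
#'
#' VCF input (VCFv4.2, GT field only, phasing ignored) is parsed with
#' `vcfR`; dosages count alternate alleles and `./.` calls become missing.
#' Records with more than one ALT allele are kept but flagged
#' non-biallelic so [qc_filter()] removes them. Dosage input is a
#' tab-separated matrix with a locus-id header row and genotype ids in the
#' first column.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"vcf"` or `"dosage"`.
#' @param pop optional population labels, one per genotype.
#' @return A [marker_matrix()].
#' @export
read_markers <- function(path, format = c("auto", "vcf", "dosage"),
                         pop = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "dosage"
  if (format == "vcf") {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    gt <- vcfR::extract.gt(v, element = "GT")
    alt <- vcfR::getALT(v)
    ids <- vcfR::getID(v)
    fixed <- vcfR::getFIX(v)
    if (is.null(ids) || anyNA(ids))
      ids <- paste(fixed[, "CHROM"], fixed[, "POS"], sep = "_")
    count_alt <- function(g) {
      if (is.na(g) || g %in% c("./.", ".|.", ".")) return(NA_integer_)
      sum(strsplit(g, "[/|]")[[1]] != "0")
    }
    dos <- t(apply(gt, c(1, 2), count_alt))
    storage.mode(dos) <- "double"
    colnames(dos) <- ids
    map <- data.frame(locus = ids,
                      chrom = fixed[, "CHROM"], pos = as.integer(fixed[, "POS"]),
                      ref = fixed[, "REF"], alt = alt,
                      biallelic = !grepl(",", alt),
                      stringsAsFactors = FALSE)
    return(marker_matrix(dos, map = map, pop = pop))
  }
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  ids <- df[[1]]
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("dosage matrix must be numeric: ", path)
  storage.mode(m) <- "double"
  rownames(m) <- ids
  marker_matrix(m, pop = pop, imputed = any(abs(m - round(m)) > 1e-8,
                                            na.rm = TRUE))
}

#' Write a dosage matrix as tab-separated text
#' @param markers a [marker_matrix()].
#' @param path output path.
#' @export
write_dosage <- function(markers, path) {
  stopifnot(inherits(markers, "MarkerMatrix"))
  df <- data.frame(genotype = rownames(markers$dosage),
                   markers$dosage, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write markers as a minimal biallelic-SNP VCF
#'
#' Emits a VCFv4.2 file with GT-only genotype columns. Integer dosages map
#' to `0/0`, `0/1`, `1/1`; missing dosages to `./.`. Fractional (imputed)
#' dosages cannot be represented and are rejected.
#'
#' @param markers a [marker_matrix()].
#' @param path output path.
#' @export
write_vcf <- function(markers, path) {
  stopifnot(inherits(markers, "MarkerMatrix"))
  dos <- markers$dosage
  if (any(abs(dos - round(dos)) > 1e-8, na.rm = TRUE))
    stop("fractional dosages cannot be written as GT calls")
  map <- markers$map
  chrom <- if (!is.null(map$chrom)) map$chrom else rep("1", ncol(dos))
  pos <- if (!is.null(map$pos)) map$pos else seq_len(ncol(dos))
  ref <- if (!is.null(map$ref)) map$ref else rep("A", ncol(dos))
  alt <- if (!is.null(map$alt)) map$alt else rep("T", ncol(dos))
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  lines <- c("##fileformat=VCFv4.2",
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", rownames(dos)), collapse = "\t"))
  body <- vapply(seq_len(ncol(dos)), function(j) {
    calls <- gt_code[as.character(round(dos[, j]))]
    calls[is.na(calls)] <- "./."
    paste(c(chrom[j], pos[j], colnames(dos)[j], ref[j], alt[j], ".",
            "PASS", ".", "GT", calls), collapse = "\t")
  }, "")
  writeLines(c(lines, body), path)
  invisible(path)
}

#' Default end-to-end pipeline configuration
#'
#' Assembles a `RunConfig` for [run_pipeline()]: simulation settings, model
#' settings, selection fractions and trait direction, plus stage toggles.
#' Any element can be overridden via `...` using the same names.
#'
#' @param out_dir output directory.
#' @param seed global seed; stage seeds are derived from it.
#' @param ... overrides, e.g. `sim = sim_config(...)`,
#'   `model = genomic_config(...)`, `cv_k`, `cv_reps`, `perf_frac`,
#'   `stab_frac`, `trait_direction`, `stages`, `phenotypes_path`,
#'   `markers_path`.
#' @return A `RunConfig` list.
#' @export
default_run_config <- function(out_dir = "stabgen_run", seed = 1L, ...) {
  cfg <- list(
    out_dir = out_dir, seed = as.integer(seed),
    phenotypes_path = NULL, markers_path = NULL,
    sim = sim_config(seed = seed),
    model = genomic_config(seed = seed),
    cv_k = 10L, cv_reps = 5L,
    perf_frac = 0.10, stab_frac = 0.20,
    trait_direction = "higher",
    stages = c("simulate", "adjust", "stability", "predict", "evaluate"))
  over <- list(...)
  cfg[names(over)] <- over
  class(cfg) <- "RunConfig"
  cfg
}

#' Read a pipeline configuration from a YAML file
#'
#' Scalar fields map directly onto [default_run_config()]; nested `sim:`
#' and `model:` blocks are passed to [sim_config()] and
#' [genomic_config()].
#'
#' @param path YAML file.
#' @return A `RunConfig`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  args <- raw[setdiff(names(raw), c("sim", "model"))]
  if (!is.null(raw$sim)) args$sim <- do.call(sim_config, raw$sim)
  if (!is.null(raw$model)) args$model <- do.call(genomic_config, raw$model)
  do.call(default_run_config, args)
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in order: `simulate` (or read the configured
#' input files), `adjust` (eBLUEs per environment plus variance
#' components), `stability` (AMMI + FW indices), `predict`
#' (cross-validated genomic prediction of the adjusted means and of both
#' stability indices) and `evaluate` (performance-stability correlation and
#' co-selection overlap). All stage outputs are written as tab-separated
#' text or JSON under `config$out_dir`, together with a manifest recording
#' the configuration, seeds, stage timings and md5 checksums of every
#' output file. A failing stage aborts with the stage name and leaves a
#' `FAILED_<stage>` marker in the output directory.
#'
#' @param config a `RunConfig` from [default_run_config()] or
#'   [read_run_config()].
#' @return Invisibly, a list with the stage results and the manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = config$seed, stages = list(),
                   config = .config_as_list(config))
  outputs <- character(0)
  state <- new.env(parent = emptyenv())
  run_stage <- function(name, fun) {
    if (!(name %in% config$stages)) return(invisible(NULL))
    t0 <- proc.time()[["elapsed"]]
    ok <- tryCatch({ fun(); TRUE }, error = function(e) {
      file.create(file.path(config$out_dir, paste0("FAILED_", name)))
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    manifest$stages[[name]] <<- list(
      elapsed_s = round(proc.time()[["elapsed"]] - t0, 3))
    invisible(ok)
  }

  run_stage("simulate", function() {
    if (!is.null(config$phenotypes_path)) {
      state$phen <- read_phenotypes(config$phenotypes_path)
      state$markers <- if (!is.null(config$markers_path))
        read_markers(config$markers_path) else NULL
    } else {
      cfg <- config$sim
      cfg$seed <- config$seed
      state$markers <- simulate_markers(cfg)
      sim <- simulate_phenotypes(state$markers, cfg)
      state$phen <- sim$phenotypes
      state$truth <- sim$truth
      jsonlite::write_json(
        list(mu = sim$truth$mu, sigma_e = sim$truth$sigma_e,
             h = as.list(sim$truth$h),
             fw_slopes = as.list(sim$truth$fw_slopes)),
        file.path(config$out_dir, "truth.json"), auto_unbox = TRUE,
        digits = NA)
      outputs <<- c(outputs, "truth.json")
    }
    if (!is.null(state$markers)) {
      state$markers <- qc_filter(state$markers)
      write_dosage(state$markers, file.path(config$out_dir, "markers.tsv"))
      outputs <<- c(outputs, "markers.tsv")
    }
    write_phenotypes(state$phen, file.path(config$out_dir,
                                           "phenotypes.tsv"))
    outputs <<- c(outputs, "phenotypes.tsv")
  })

  run_stage("adjust", function() {
    phen <- state$phen
    trait <- phen$trait[1]
    envs <- unique(.env_of(phen))
    per_env <- lapply(envs, function(e) {
      parts <- strsplit(e, ":", fixed = TRUE)[[1]]
      fit_single_year(phen, trait, year = parts[2], location = parts[1],
                      scenario = "per-env")
    })
    names(per_env) <- envs
    state$per_env <- per_env
    state$overall <- fit_multi_year(phen, trait, unique(phen$year))
    state$vc <- estimate_h2(phen, trait)
    eb <- do.call(rbind, lapply(envs, function(e) {
      data.frame(genotype = per_env[[e]]$means$genotype, env = e,
                 trait = trait, eblue = per_env[[e]]$means$eblue)
    }))
    write.table(eb, file.path(config$out_dir, "eblues.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(components = as.list(state$vc$components), H2 = state$vc$H2,
           method = state$vc$method),
      file.path(config$out_dir, "varcomp.json"), auto_unbox = TRUE,
      digits = NA)
    outputs <<- c(outputs, "eblues.tsv", "varcomp.json")
  })

  run_stage("stability", function() {
    long <- do.call(rbind, lapply(names(state$per_env), function(e) {
      m <- state$per_env[[e]]
      data.frame(genotype = m$means$genotype, env = e,
                 value = m$means$eblue, stringsAsFactors = FALSE)
    }))
    tw <- prepare_two_way(long, missing = "drop")
    sig2 <- mean(vapply(state$per_env, `[[`, 0, "sigma2"))
    state$two_way <- tw
    state$stab <- stability_summary(tw, trait = state$phen$trait[1],
                                    sigma2 = sig2,
                                    nrep = length(unique(state$phen$block)))
    write.table(state$stab, file.path(config$out_dir, "stability.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    outputs <<- c(outputs, "stability.tsv")
  })

  run_stage("predict", function() {
    if (is.null(state$markers))
      stop("predict stage needs marker data")
    perf <- setNames(state$overall$means$eblue,
                     state$overall$means$genotype)
    targets <- list(
      performance = perf,
      asv = setNames(state$stab$asv, state$stab$genotype),
      fw = setNames(state$stab$fw_slope_dev, state$stab$genotype))
    cvres <- lapply(names(targets), function(nm) {
      cv <- run_cv(targets[[nm]], state$markers, config$model,
                   k = config$cv_k, reps = config$cv_reps,
                   seed = config$seed)
      data.frame(target = nm, mean_r = cv$summary$mean_r,
                 sd_r = cv$summary$sd_r, n_fits = cv$n_fits)
    })
    state$cv <- do.call(rbind, cvres)
    write.table(state$cv, file.path(config$out_dir, "cv_report.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    outputs <<- c(outputs, "cv_report.tsv")
  })

  run_stage("evaluate", function() {
    perf <- setNames(state$overall$means$eblue,
                     state$overall$means$genotype)
    state$correlations <- correlate_performance_stability(perf, state$stab)
    state$overlap <- select_overlap(perf, state$stab,
                                    perf_frac = config$perf_frac,
                                    stab_frac = config$stab_frac,
                                    direction = config$trait_direction)
    write.table(state$correlations,
                file.path(config$out_dir, "correlations.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(sets = state$overlap$sets,
           intersections = as.list(state$overlap$intersections)),
      file.path(config$out_dir, "overlap.json"), auto_unbox = TRUE,
      digits = NA)
    outputs <<- c(outputs, "correlations.tsv", "overlap.json")
  })

  manifest$outputs <- as.list(
    tools::md5sum(file.path(config$out_dir, outputs)))
  names(manifest$outputs) <- outputs
  jsonlite::write_json(manifest,
                       file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(list(state = as.list(state), manifest = manifest))
}

.config_as_list <- function(cfg) {
  strip <- function(x) {
    if (is.list(x)) lapply(unclass(x), strip) else x
  }
  strip(cfg)
}
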