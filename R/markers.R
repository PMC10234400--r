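#' Genotype-by-SNP dosage matrix
#'
#' Container for marker data: a genotypes x loci matrix of alternate-allele
#' dosages (0/1/2, `NA` for missing calls), per-locus metadata, and optional
#' population labels. Allele frequency and missingness are computed from the
#' observed dosages.
#'
#' @param dosage numeric matrix, genotypes in rows (rownames = genotype ids),
#'   loci in columns (colnames = locus ids). Values must be in `[0, 2]` or
#'   `NA`; integer dosages are expected before imputation.
#' @param map optional data.frame of locus metadata with a `locus` column
#'   matching `colnames(dosage)`; a logical `biallelic` column marks loci to
#'   be removed by [qc_filter()]. Missing columns are filled with defaults.
#' @param pop optional character vector of population labels, one per row.
#' @param imputed logical; `TRUE` once missing dosages have been imputed
#'   (fractional values allowed).
#' @return An object of class `MarkerMatrix`.
#' @export
marker_matrix <- function(dosage, map = NULL, pop = NULL, imputed = FALSE) {
  dosage <- as.matrix(dosage)
  if (is.null(rownames(dosage)))
    rownames(dosage) <- sprintf("G%03d", seq_len(nrow(dosage)))
  if (is.null(colnames(dosage)))
    colnames(dosage) <- sprintf("SNP%05d", seq_len(ncol(dosage)))
  rng <- range(dosage, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 2)
    stop("dosages must lie in [0, 2] (alternate-allele counts)")
  if (!imputed && any(abs(dosage - round(dosage)) > 1e-8, na.rm = TRUE))
    stop("raw dosages must be integers 0/1/2 (set imputed = TRUE for ",
         "fractional imputed values)")
  if (is.null(map)) {
    map <- data.frame(locus = colnames(dosage), stringsAsFactors = FALSE)
  }
  if (is.null(map$biallelic)) map$biallelic <- TRUE
  if (!identical(map$locus, colnames(dosage)))
    stop("map$locus must match colnames(dosage) in order")
  if (!is.null(pop)) {
    pop <- as.character(pop)
    if (length(pop) != nrow(dosage))
      stop("pop must have one label per genotype")
  } else {
    pop <- rep("P1", nrow(dosage))
  }
  af <- colMeans(dosage, na.rm = TRUE) / 2
  missf <- colMeans(is.na(dosage))
  map$af <- as.numeric(af)
  map$maf <- pmin(map$af, 1 - map$af)
  map$missingness <- as.numeric(missf)
  obj <- list(dosage = dosage, map = map, pop = pop, imputed = imputed)
  class(obj) <- "MarkerMatrix"
  obj
}

#' @export
print.MarkerMatrix <- function(x, ...) {
  cat("MarkerMatrix:", nrow(x$dosage), "genotypes x", ncol(x$dosage),
      "loci\n")
  cat("  populations:",
      paste(sprintf("%s (n=%d)", names(table(x$pop)), table(x$pop)),
            collapse = ", "), "\n")
  cat(sprintf("  mean MAF %.3f, mean missingness %.3f, imputed: %s\n",
              mean(x$map$maf), mean(x$map$missingness), x$imputed))
  invisible(x)
}

#' Dimensions of a MarkerMatrix
#' @param x a `MarkerMatrix`.
#' @export
dim.MarkerMatrix <- function(x) dim(x$dosage)

#' Subset a MarkerMatrix by genotypes and/or loci
#' @param x a `MarkerMatrix`.
#' @param i genotype (row) index.
#' @param j locus (column) index.
#' @param ... unused.
#' @export
`[.MarkerMatrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$dosage))
  if (missing(j)) j <- seq_len(ncol(x$dosage))
  marker_matrix(x$dosage[i, j, drop = FALSE],
                map = x$map[j, , drop = FALSE][,
                  setdiff(names(x$map), c("af", "maf", "missingness")),
                  drop = FALSE],
                pop = x$pop[i], imputed = x$imputed)
}

#' Quality-control filter for marker data
#'
#' Applies the standard GBS-panel filters in order: loci with missingness
#' above `max_missing` are removed, then non-biallelic loci, then loci with
#' minor allele frequency below `min_maf` (computed on observed calls).
#' Remaining missing dosages are imputed by the locus mean, which preserves
#' the observed allele frequency. A per-filter removal report is attached.
#'
#' @param raw a [marker_matrix()].
#' @param max_missing loci with missingness strictly above this fraction are
#'   removed (default 0.50).
#' @param min_maf loci with MAF strictly below this are removed
#'   (default 0.01).
#' @return A `MarkerMatrix` of surviving loci with no missing dosages and a
#'   `report` element counting removals per filter.
#' @export
qc_filter <- function(raw, max_missing = 0.5, min_maf = 0.01) {
  stopifnot(inherits(raw, "MarkerMatrix"))
  map <- raw$map
  drop_miss <- map$missingness > max_missing
  drop_bi <- !drop_miss & !map$biallelic
  drop_maf <- !drop_miss & !drop_bi & (map$maf < min_maf)
  keep <- !(drop_miss | drop_bi | drop_maf)
  if (!any(keep))
    stop("all loci removed by QC filters (missingness > ", max_missing,
         ", non-biallelic, MAF < ", min_maf, ")")
  dos <- raw$dosage[, keep, drop = FALSE]
  # per-locus mean imputation
  if (anyNA(dos)) {
    cm <- colMeans(dos, na.rm = TRUE)
    idx <- which(is.na(dos), arr.ind = TRUE)
    dos[idx] <- cm[idx[, 2]]
  }
  out <- marker_matrix(dos, map = map[keep, setdiff(names(map),
                         c("af", "maf", "missingness")), drop = FALSE],
                       pop = raw$pop, imputed = TRUE)
  out$report <- list(
    n_input = nrow(map),
    removed_missing = sum(drop_miss),
    removed_nonbiallelic = sum(drop_bi),
    removed_maf = sum(drop_maf),
    n_retained = sum(keep))
  out
}

# imputed, numeric dosage matrix ready for regression
.dosage_ready <- function(markers) {
  if (inherits(markers, "MarkerMatrix")) {
    dos <- markers$dosage
    if (anyNA(dos)) {
      cm <- colMeans(dos, na.rm = TRUE)
      idx <- which(is.na(dos), arr.ind = TRUE)
      dos[idx] <- cm[idx[, 2]]
    }
    dos
  } else {
    as.matrix(markers)
  }
}
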