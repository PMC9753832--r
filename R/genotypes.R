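#' Construct a genotype matrix object
#'
#' The central container of the package: an individuals-by-SNPs dosage matrix
#' together with per-SNP metadata. Dosages count copies of the A1 allele
#' (0, 1, 2) with `NA` for missing genotypes.
#'
#' @param dosages Numeric matrix, individuals in rows and SNPs in columns.
#'   Values must be in `{0, 1, 2, NA}`.
#' @param map Data frame with one row per SNP and columns `id`, `chrom`
#'   (integer chromosome), `pos` (1-based bp), `a1`, `a2` (allele characters).
#' @param samples Character vector of individual identifiers, one per row.
#' @return An object of class `geno_matrix` with elements `dosages`, `map`
#'   (with a recomputed `maf` column) and `samples`. SNPs are sorted by
#'   (chrom, pos).
#' @export
geno_matrix <- function(dosages, map, samples) {
  dosages <- as.matrix(dosages)
  if (!is.data.frame(map)) stop("`map` must be a data.frame")
  needed <- c("id", "chrom", "pos", "a1", "a2")
  missing_cols <- setdiff(needed, names(map))
  if (length(missing_cols)) {
    stop("map is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (ncol(dosages) != nrow(map)) {
    stop("ncol(dosages) [", ncol(dosages), "] != nrow(map) [", nrow(map), "]")
  }
  if (nrow(dosages) != length(samples)) {
    stop("nrow(dosages) != length(samples)")
  }
  bad <- !(dosages %in% c(0, 1, 2) | is.na(dosages))
  if (any(bad)) stop("dosages must be 0, 1, 2 or NA")
  storage.mode(dosages) <- "double"
  if (any(map$pos <= 0)) stop("positions must be positive 1-based bp")
  ord <- order(map$chrom, map$pos)
  map <- map[ord, , drop = FALSE]
  dosages <- dosages[, ord, drop = FALSE]
  rownames(map) <- NULL
  rownames(dosages) <- samples
  colnames(dosages) <- map$id
  obj <- structure(
    list(dosages = dosages, map = map, samples = as.character(samples)),
    class = "geno_matrix"
  )
  obj$map$maf <- snp_maf(obj)
  obj
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf(
    "<geno_matrix> %d individuals x %d SNPs on %d chromosome(s)\n",
    nrow(x$dosages), ncol(x$dosages), length(unique(x$map$chrom))
  ))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$dosages)

#' Number of individuals / SNPs in a genotype matrix
#' @param G A `geno_matrix`.
#' @return Integer count.
#' @export
n_individuals <- function(G) nrow(G$dosages)

#' @rdname n_individuals
#' @export
n_snps <- function(G) ncol(G$dosages)

#' Per-SNP allele frequency and minor allele frequency
#'
#' Frequencies are computed from non-missing dosages. `snp_freq` returns the
#' frequency of the counted (A1) allele; `snp_maf` folds it to `[0, 0.5]`.
#'
#' @param G A `geno_matrix`.
#' @return Numeric vector, one value per SNP (`NaN` for all-missing SNPs).
#' @export
snp_freq <- function(G) {
  colMeans(G$dosages, na.rm = TRUE) / 2
}

#' @rdname snp_freq
#' @export
snp_maf <- function(G) {
  p <- snp_freq(G)
  pmin(p, 1 - p)
}

#' Subset a genotype matrix
#'
#' @param G A `geno_matrix`.
#' @param samples Character vector of sample ids, or logical/integer row index.
#' @param snps Character vector of SNP ids, or logical/integer column index.
#' @return A `geno_matrix` restricted to the requested rows/columns. MAF
#'   metadata is recomputed on the retained individuals.
#' @export
subset_geno <- function(G, samples = NULL, snps = NULL) {
  ri <- seq_len(nrow(G$dosages))
  ci <- seq_len(ncol(G$dosages))
  if (!is.null(samples)) {
    ri <- if (is.character(samples)) match(samples, G$samples) else ri[samples]
    if (anyNA(ri)) stop("unknown sample id(s)")
  }
  if (!is.null(snps)) {
    ci <- if (is.character(snps)) match(snps, G$map$id) else ci[snps]
    if (anyNA(ci)) stop("unknown SNP id(s)")
  }
  geno_matrix(G$dosages[ri, ci, drop = FALSE],
              G$map[ci, setdiff(names(G$map), "maf"), drop = FALSE],
              G$samples[ri])
}

#' Center dosage columns for marker-effect models
#'
#' Missing dosages are imputed to the SNP mean (2p) before centering, so the
#' returned matrix is complete. Column means used for centering are attached
#' as attribute `"centers"` so that out-of-sample panels can be centered
#' identically.
#'
#' @param G A `geno_matrix`.
#' @param centers Optional numeric vector of per-SNP centers (2p from a
#'   reference set); defaults to observed column means.
#' @return Numeric matrix of centered dosages.
#' @export
center_dosages <- function(G, centers = NULL) {
  Z <- G$dosages
  cm <- colMeans(Z, na.rm = TRUE)
  cm[is.nan(cm)] <- 0
  if (anyNA(Z)) {
    idx <- which(is.na(Z), arr.ind = TRUE)
    Z[idx] <- cm[idx[, 2]]
  }
  if (is.null(centers)) centers <- cm
  Z <- sweep(Z, 2, centers, "-")
  attr(Z, "centers") <- centers
  Z
}
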