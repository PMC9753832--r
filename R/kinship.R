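#' Genomic relationship matrix (VanRaden method 1)
#'
#' `G = ZZ' / (2 * sum(p * (1 - p)))` where `Z` is the dosage matrix with each
#' column centered by twice the observed allele frequency; missing dosages are
#' mean-imputed (to `2p`) before centering. Optionally all SNPs on one
#' chromosome are excluded, giving the leave-one-chromosome-out (LOCO) GRM
#' used by the association scan.
#'
#' @param G A [geno_matrix()].
#' @param exclude_chrom Optional chromosome whose SNPs are left out.
#' @return A `kinship` object: list with `values` (n x n symmetric matrix with
#'   sample-id dimnames), `kind = "genomic"` and `excluded_chrom`.
#' @export
compute_grm <- function(G, exclude_chrom = NULL) {
  keep <- rep(TRUE, n_snps(G))
  if (!is.null(exclude_chrom)) keep <- G$map$chrom != exclude_chrom
  if (!any(keep)) stop("no SNPs available for the GRM after exclusion")
  Gs <- subset_geno(G, snps = keep)
  Z <- center_dosages(Gs)
  p <- attr(Z, "centers") / 2
  denom <- 2 * sum(p * (1 - p))
  if (denom <= 0) stop("allele frequencies not computable (all SNPs monomorphic)")
  K <- tcrossprod(Z) / denom
  dimnames(K) <- list(G$samples, G$samples)
  structure(list(values = K, kind = "genomic",
                 excluded_chrom = exclude_chrom),
            class = "kinship")
}

#' Pedigree-based additive relationship matrix (tabular method)
#'
#' Builds the numerator relationship matrix A recursively:
#' `a_ii = 1 + a_sd / 2` and `a_ij = (a_js + a_jd) / 2`, with founders taken
#' as unrelated and non-inbred. Unknown parents are coded 0 or NA.
#'
#' @param ped Data frame with columns `id`, `sire`, `dam`.
#' @return A `kinship` object of kind `"pedigree"` over all pedigree members.
#' @export
compute_a_matrix <- function(ped) {
  ped <- as.data.frame(ped)
  names(ped)[1:3] <- c("id", "sire", "dam")
  ids <- as.character(ped$id)
  if (anyDuplicated(ids)) stop("duplicate ids in pedigree")
  code <- function(x) {
    x <- as.character(x)
    x[is.na(x) | x == "0"] <- NA
    match(x, ids)
  }
  s <- code(ped$sire)
  d <- code(ped$dam)
  if (any(s == seq_along(ids), na.rm = TRUE) ||
      any(d == seq_along(ids), na.rm = TRUE)) {
    stop("individual is its own parent")
  }
  n <- length(ids)
  ord <- topo_order(s, d, n)
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  done <- integer(0)
  for (i in ord) {
    si <- s[i]; di <- d[i]
    A[i, i] <- 1 + if (!is.na(si) && !is.na(di)) A[si, di] / 2 else 0
    if (length(done)) {
      aij <- (if (!is.na(si)) A[done, si] else 0) / 2 +
             (if (!is.na(di)) A[done, di] else 0) / 2
      A[i, done] <- aij
      A[done, i] <- aij
    }
    done <- c(done, i)
  }
  structure(list(values = A, kind = "pedigree", excluded_chrom = NULL),
            class = "kinship")
}

# Kahn-style topological sort; errors on cycles (an animal its own ancestor).
topo_order <- function(s, d, n) {
  placed <- logical(n)
  ord <- integer(0)
  repeat {
    ready <- which(!placed &
                   (is.na(s) | placed[ifelse(is.na(s), 1L, s)]) &
                   (is.na(d) | placed[ifelse(is.na(d), 1L, d)]))
    if (!length(ready)) {
      if (all(placed)) return(ord)
      stop("pedigree contains a cycle (individual is its own ancestor)")
    }
    placed[ready] <- TRUE
    ord <- c(ord, ready)
  }
}

#' @export
print.kinship <- function(x, ...) {
  cat(sprintf("<kinship> %s, %d individuals%s\n", x$kind, nrow(x$values),
              if (!is.null(x$excluded_chrom))
                sprintf(" (chromosome %s excluded)", x$excluded_chrom) else ""))
  invisible(x)
}

#' Subset a kinship matrix to a set of individuals
#' @param K A `kinship` object.
#' @param ids Character vector of individual ids (order is respected).
#' @return A `kinship` object restricted to `ids`.
#' @export
subset_kinship <- function(K, ids) {
  idx <- match(ids, rownames(K$values))
  if (anyNA(idx)) stop("ids absent from kinship matrix: ",
                       paste(ids[is.na(idx)], collapse = ", "))
  structure(list(values = K$values[idx, idx, drop = FALSE], kind = K$kind,
                 excluded_chrom = K$excluded_chrom),
            class = "kinship")
}
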