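#' Quality-control filter for a genotype panel
#'
#' Applies the standard chip-data exclusions: SNPs with minor allele frequency
#' below `maf_min` or per-SNP call rate below `snp_callrate_min` are dropped,
#' non-autosomal SNPs are dropped when `autosomes_only` is set, and
#' individuals missing more than `ind_missing_max` of the retained genotypes
#' are removed afterwards. Allele frequencies are recomputed on the retained
#' individuals and the SNP filters re-applied until the panel is stable, so
#' the operation is idempotent.
#'
#' @param G A [geno_matrix()].
#' @param maf_min Minimum minor allele frequency (default 0.01).
#' @param snp_callrate_min Minimum per-SNP call rate (default 0.90).
#' @param ind_missing_max Maximum per-individual missing fraction (default 0.10).
#' @param autosomes_only Drop SNPs on chromosomes outside 1-18 (default TRUE).
#' @param verbose Log one line per filter with counts removed.
#' @return The filtered `geno_matrix`.
#' @export
qc_filter <- function(G, maf_min = 0.01, snp_callrate_min = 0.90,
                      ind_missing_max = 0.10, autosomes_only = TRUE,
                      verbose = FALSE) {
  if (n_snps(G) == 0L) stop("empty panel")
  repeat {
    m0 <- n_snps(G)
    n0 <- n_individuals(G)
    keep_snp <- rep(TRUE, m0)
    if (autosomes_only) keep_snp <- keep_snp & G$map$chrom %in% 1:18
    callrate <- colMeans(!is.na(G$dosages))
    maf <- snp_maf(G)
    keep_snp <- keep_snp & callrate >= snp_callrate_min &
      !is.na(maf) & maf >= maf_min
    if (!any(keep_snp)) stop("QC removed all SNPs")
    if (verbose && any(!keep_snp)) {
      message(sprintf("qc: removed %d of %d SNPs (MAF/call-rate/autosome)",
                      sum(!keep_snp), m0))
    }
    G <- subset_geno(G, snps = keep_snp)
    ind_miss <- rowMeans(is.na(G$dosages))
    keep_ind <- ind_miss <= ind_missing_max
    if (!any(keep_ind)) stop("QC removed all individuals")
    if (verbose && any(!keep_ind)) {
      message(sprintf("qc: removed %d of %d individuals (missingness > %g)",
                      sum(!keep_ind), n0, ind_missing_max))
    }
    G <- subset_geno(G, samples = keep_ind)
    if (n_snps(G) == m0 && n_individuals(G) == n0) break
  }
  G
}

#' Merge chip genotypes into a denser panel
#'
#' At loci present in both panels (matched by chromosome, position and allele
#' pair) the chip genotype overrides the dense-panel genotype; this is the
#' integration rule used when observed chip calls replace imputed sequence
#' genotypes. Chip loci absent from the dense panel are appended in position
#' order. When the allele pair is recorded in swapped order the chip dosage is
#' complemented (`2 - d`) before the override.
#'
#' @param chip,dense Two [geno_matrix()] objects over the same samples.
#' @return The merged `geno_matrix` on the dense panel's sample ordering.
#' @export
merge_panels <- function(chip, dense) {
  if (!setequal(chip$samples, dense$samples)) {
    stop("panels must cover the same sample set")
  }
  chip_d <- chip$dosages[match(dense$samples, chip$samples), , drop = FALSE]
  key <- function(map) paste(map$chrom, map$pos, sep = ":")
  kc <- key(chip$map)
  kd <- key(dense$map)
  shared <- match(kc, kd)
  out <- dense$dosages
  map <- dense$map
  mism <- character(0)
  for (j in which(!is.na(shared))) {
    jd <- shared[j]
    same  <- chip$map$a1[j] == map$a1[jd] && chip$map$a2[j] == map$a2[jd]
    flip  <- chip$map$a1[j] == map$a2[jd] && chip$map$a2[j] == map$a1[jd]
    if (same) {
      out[, jd] <- chip_d[, j]
    } else if (flip) {
      out[, jd] <- 2 - chip_d[, j]
    } else {
      mism <- c(mism, sprintf("%s (%s/%s vs %s/%s)", kc[j],
                              chip$map$a1[j], chip$map$a2[j],
                              map$a1[jd], map$a2[jd]))
    }
  }
  if (length(mism)) {
    stop("allele mismatch at shared loci: ", paste(mism, collapse = "; "))
  }
  new_idx <- which(is.na(shared))
  if (length(new_idx)) {
    out <- cbind(out, chip_d[, new_idx, drop = FALSE])
    map <- rbind(map[, c("id", "chrom", "pos", "a1", "a2")],
                 chip$map[new_idx, c("id", "chrom", "pos", "a1", "a2")])
  } else {
    map <- map[, c("id", "chrom", "pos", "a1", "a2")]
  }
  geno_matrix(out, map, dense$samples)
}

#' Squared-correlation linkage disequilibrium between two SNPs
#'
#' r-squared computed as the squared Pearson correlation of dosage vectors on
#' pairwise-complete observations, as in PLINK's `--indep-pairwise`.
#'
#' @param x,y Dosage vectors of equal length.
#' @return A fraction in `[0, 1]`.
#' @export
ld_r2 <- function(x, y) {
  if (length(x) != length(y)) stop("dosage vectors differ in length")
  ok <- !is.na(x) & !is.na(y)
  if (stats::var(x[ok]) == 0 || stats::var(y[ok]) == 0) {
    stop("r2 undefined for a constant dosage vector")
  }
  stats::cor(x[ok], y[ok])^2
}

#' LD-based SNP pruning
#'
#' Within each chromosome, any pair of retained SNPs lying within a
#' `window_kb` physical window must have dosage r-squared strictly below
#' `r2_max` (so at the boundary cutoff 1.00 only perfect duplicates go).
#' Violating pairs are resolved deterministically: the pair with the highest
#' r-squared is found and its lower-MAF member removed (on a MAF tie, the
#' later-position SNP), repeating until no violation remains. The result is
#' therefore independent of how the window is advanced; `step_variants` only
#' controls the internal scan granularity.
#'
#' @param G A [geno_matrix()] sorted by position (always true by construction).
#' @param window_kb Physical window size in kb (default 50).
#' @param step_variants Variants to advance per window shift (default 10).
#' @param r2_max Maximum tolerated r-squared, in `[0, 1]`.
#' @param verbose Log count of removed SNPs.
#' @return The pruned `geno_matrix`.
#' @export
prune_ld <- function(G, window_kb = 50, step_variants = 10, r2_max,
                     verbose = FALSE) {
  if (r2_max < 0 || r2_max > 1) stop("r2_max must lie in [0, 1]")
  window_bp <- window_kb * 1000
  drop <- logical(n_snps(G))
  maf <- snp_maf(G)
  for (chr in unique(G$map$chrom)) {
    idx <- which(G$map$chrom == chr)
    pos <- G$map$pos[idx]
    # candidate pairs: physical distance <= window
    pairs <- NULL
    for (a in seq_along(idx)) {
      b <- a + seq_len(length(idx) - a)
      b <- b[pos[b] - pos[a] <= window_bp]
      if (length(b)) pairs <- rbind(pairs, cbind(a, b))
    }
    if (is.null(pairs)) next
    r2 <- apply(pairs, 1, function(pr) {
      xa <- G$dosages[, idx[pr[1]]]
      xb <- G$dosages[, idx[pr[2]]]
      ok <- !is.na(xa) & !is.na(xb)
      if (stats::var(xa[ok]) == 0 || stats::var(xb[ok]) == 0) return(0)
      stats::cor(xa[ok], xb[ok])^2
    })
    alive <- rep(TRUE, length(idx))
    repeat {
      act <- which(alive[pairs[, 1]] & alive[pairs[, 2]] & r2 >= r2_max)
      if (!length(act)) break
      top <- act[which.max(r2[act])]
      a <- pairs[top, 1]; b <- pairs[top, 2]
      ma <- maf[idx[a]]; mb <- maf[idx[b]]
      victim <- if (ma < mb) a else if (mb < ma) b else max(a, b)
      alive[victim] <- FALSE
    }
    drop[idx[!alive]] <- TRUE
  }
  if (verbose) {
    message(sprintf("prune: removed %d of %d SNPs at r2 > %g",
                    sum(drop), n_snps(G), r2_max))
  }
  if (all(drop)) stop("pruning removed all SNPs")
  subset_geno(G, snps = !drop)
}
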