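#' Bonferroni significance thresholds
#'
#' Genome-wide (`0.05 / N`) and suggestive (`1 / N`) significance levels for a
#' scan of `N` SNPs; with the 50,482-SNP chip panel these are 9.90E-7 and
#' 1.98E-5.
#'
#' @param n_tests Number of SNPs tested.
#' @return List with `n_tests`, `genomewide` and `suggestive`.
#' @export
bonferroni_thresholds <- function(n_tests) {
  if (length(n_tests) != 1L || is.na(n_tests) || n_tests < 1) {
    stop("n_tests must be a positive count")
  }
  list(n_tests = n_tests, genomewide = 0.05 / n_tests, suggestive = 1 / n_tests)
}

#' Proportion of phenotypic variance explained by one SNP
#'
#' `PVE = 2 q (1 - q) b^2 / sigma_p2` for a SNP with minor allele frequency
#' `q` and allele substitution effect `b` on a trait with phenotypic variance
#' `sigma_p2`.
#'
#' @param q Minor allele frequency in `[0, 0.5]`.
#' @param b Allele substitution effect.
#' @param sigma_p2 Phenotypic variance (> 0).
#' @return A fraction.
#' @export
snp_pve <- function(q, b, sigma_p2) {
  if (any(sigma_p2 <= 0)) stop("sigma_p2 must be positive")
  if (any(q < 0 | q > 0.5)) stop("q must lie in [0, 0.5]")
  2 * q * (1 - q) * b^2 / sigma_p2
}

# Profile REML for y = X b + g + e with g ~ N(0, K sg2), via the
# eigendecomposition of K: maximizes the restricted likelihood over the
# variance ratio r = sg2 / se2 on log scale.
reml_eigen <- function(y, X, eig) {
  n <- length(y)
  p <- ncol(X)
  yt <- crossprod(eig$vectors, y)
  Xt <- crossprod(eig$vectors, X)
  d <- pmax(eig$values, 0)
  crit <- function(logr) {
    w <- exp(logr) * d + 1
    XtWX <- crossprod(Xt, Xt / w)
    bh <- solve(XtWX, crossprod(Xt, yt / w))
    rss <- sum((yt - Xt %*% bh)^2 / w)
    0.5 * ((n - p) * log(rss / (n - p)) + sum(log(w)) +
           determinant(XtWX, logarithm = TRUE)$modulus[1] + (n - p))
  }
  # the profiled criterion can be multimodal at small n: bracket the global
  # minimum on a coarse grid of log-ratios before local refinement
  grid <- seq(-25, 25, length.out = 101)
  vals <- vapply(grid, crit, 1.0)
  i <- which.min(vals)
  lo <- grid[max(1, i - 1)]
  hi <- grid[min(length(grid), i + 1)]
  opt <- stats::optimize(crit, interval = c(lo, hi), tol = 1e-8)
  r <- exp(opt$minimum)
  w <- r * d + 1
  XtWX <- crossprod(Xt, Xt / w)
  bh <- solve(XtWX, crossprod(Xt, yt / w))
  se2 <- sum((yt - Xt %*% bh)^2 / w) / (n - p)
  list(sigma_g = r * se2, sigma_e = se2, loglik = -opt$objective,
       yt = yt, Xt = Xt, w = w * se2, U = eig$vectors)
}

#' Mixed-linear-model association scan with leave-one-chromosome-out GRM
#'
#' For each chromosome, the polygenic model
#' `yc = 1 mu + g + e`, `g ~ N(0, G_loco sigma_g2)`, is fitted once by REML
#' with the genomic relationship matrix built from all other chromosomes;
#' every SNP on the chromosome is then tested by generalized least squares
#' under the fitted covariance (Wald test against the standard normal). The
#' response is the pre-corrected phenotype, so only an intercept enters the
#' fixed part. Missing SNP dosages are mean-imputed per SNP. Monomorphic SNPs
#' are emitted with `beta = 0`, `p = 1` and `monomorphic = TRUE`.
#'
#' @param yc Named numeric vector of corrected phenotypes (names are animal
#'   ids; all must be present in `panel`).
#' @param panel [geno_matrix()] of SNPs to test.
#' @param grm_source [geno_matrix()] used to build the LOCO GRMs (must span at
#'   least two chromosomes); defaults to `panel`.
#' @return Data frame with one row per SNP: `id`, `chrom`, `pos`, `maf`,
#'   `beta`, `se`, `p`, `pve`, `monomorphic`.
#' @export
mlm_scan <- function(yc, panel, grm_source = panel) {
  ids <- names(yc)
  if (is.null(ids)) stop("yc must be a named vector of animal ids")
  panel <- subset_geno(panel, samples = ids)
  grm_source <- subset_geno(grm_source, samples = ids)
  if (length(unique(grm_source$map$chrom)) < 2L) {
    stop("grm_source must span at least 2 chromosomes for LOCO scanning")
  }
  y <- as.numeric(yc)
  n <- length(y)
  sigma_p2 <- stats::var(y)
  X1 <- matrix(1, n, 1)
  out <- vector("list", length(unique(panel$map$chrom)))
  chroms <- sort(unique(panel$map$chrom))
  for (ci in seq_along(chroms)) {
    chr <- chroms[ci]
    K <- compute_grm(grm_source, exclude_chrom = chr)$values
    eig <- eigen(K, symmetric = TRUE)
    fit <- reml_eigen(y, X1, eig)
    idx <- which(panel$map$chrom == chr)
    Gc <- subset_geno(panel, snps = idx)
    Z <- center_dosages(Gc)
    Xs <- sweep(Z, 2, attr(Z, "centers"), "+")  # imputed, uncentered dosages
    Xt <- crossprod(fit$U, Xs)
    u1 <- crossprod(fit$U, X1)
    wy <- fit$yt / fit$w
    a11 <- sum(u1^2 / fit$w)
    b1 <- sum(u1 * wy)
    a12 <- colSums(u1[, 1] * Xt / fit$w)
    a22 <- colSums(Xt^2 / fit$w)
    b2 <- colSums(Xt * as.vector(wy))
    det2 <- a11 * a22 - a12^2
    beta <- (a11 * b2 - a12 * b1) / det2
    vbeta <- a11 / det2
    mono <- apply(Gc$dosages, 2, function(x) {
      v <- stats::var(x, na.rm = TRUE)
      is.na(v) || v == 0
    })
    beta[mono] <- 0
    z <- ifelse(mono, 0, beta / sqrt(vbeta))
    p <- ifelse(mono, 1, 2 * stats::pnorm(-abs(z)))
    q <- panel$map$maf[idx]
    q[is.na(q) | is.nan(q)] <- 0
    out[[ci]] <- data.frame(
      id = panel$map$id[idx], chrom = chr, pos = panel$map$pos[idx],
      maf = q, beta = beta, se = ifelse(mono, NA_real_, sqrt(vbeta)),
      p = p, pve = snp_pve(q, beta, sigma_p2), monomorphic = mono,
      stringsAsFactors = FALSE, row.names = NULL)
  }
  do.call(rbind, out)
}

#' Merge significant SNPs into QTL regions
#'
#' Significant SNPs on one chromosome are merged into regions whose bounds
#' are the minimum and maximum member positions; a gap larger than
#' `merge_gap_mb` between consecutive significant SNPs starts a new region.
#'
#' @param records Scan results from [mlm_scan()], sorted by (chrom, pos).
#' @param threshold Significance threshold on `p`.
#' @param merge_gap_mb Gap (Mb) separating regions (default 10).
#' @return Data frame: `chrom`, `start_bp`, `end_bp`, `top_snp`, `top_p`,
#'   `n_significant`.
#' @export
call_regions <- function(records, threshold, merge_gap_mb = 10) {
  sig <- records[records$p < threshold, , drop = FALSE]
  if (nrow(sig) == 0L) {
    return(data.frame(chrom = integer(0), start_bp = numeric(0),
                      end_bp = numeric(0), top_snp = character(0),
                      top_p = numeric(0), n_significant = integer(0)))
  }
  sig <- sig[order(sig$chrom, sig$pos), , drop = FALSE]
  gap_bp <- merge_gap_mb * 1e6
  res <- list()
  for (chr in unique(sig$chrom)) {
    s <- sig[sig$chrom == chr, , drop = FALSE]
    grp <- cumsum(c(1, diff(s$pos) > gap_bp))
    for (g in unique(grp)) {
      sg <- s[grp == g, , drop = FALSE]
      top <- which.min(sg$p)
      res[[length(res) + 1]] <- data.frame(
        chrom = chr, start_bp = min(sg$pos), end_bp = max(sg$pos),
        top_snp = sg$id[top], top_p = sg$p[top], n_significant = nrow(sg),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, res)
}

#' Fold-internal pre-selection of significant sequence SNPs
#'
#' Runs the LOCO association scan restricted to the reference animals of one
#' cross-validation fold and returns the SNPs passing the suggestive (or
#' genome-wide) Bonferroni threshold for the scanned panel. Validation
#' animals' phenotypes never enter the scan.
#'
#' @param reference_ids Animal ids of the fold's reference population.
#' @param yc Named vector of corrected phenotypes (superset of the reference).
#' @param dense_panel [geno_matrix()] of sequence-density SNPs.
#' @param threshold_kind `"suggestive"` (default) or `"genomewide"`.
#' @param fold_id Optional label stored in the result.
#' @return A `selection_set` list: `fold_id`, `snp_ids`, `threshold_used`,
#'   `n_tests`, `records` (the scan restricted to selected SNPs).
#' @export
preselect_snps <- function(reference_ids, yc, dense_panel,
                           threshold_kind = c("suggestive", "genomewide"),
                           fold_id = NA) {
  threshold_kind <- match.arg(threshold_kind)
  if (!all(reference_ids %in% names(yc))) {
    stop("corrected phenotypes missing for some reference animals")
  }
  scan <- mlm_scan(yc[reference_ids], dense_panel, dense_panel)
  thr <- bonferroni_thresholds(nrow(scan))[[threshold_kind]]
  sel <- scan$p < thr
  if (!any(sel)) {
    warning("no SNPs passed the pre-selection threshold; returning empty set")
  }
  structure(list(fold_id = fold_id, snp_ids = scan$id[sel],
                 threshold_used = thr, n_tests = nrow(scan),
                 records = scan[sel, , drop = FALSE]),
            class = "selection_set")
}
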