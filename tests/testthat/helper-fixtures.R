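# Shared fixtures, built in code.

# hand-built panel: rows = individuals, cols = SNPs
toy_geno <- function(dosages, chrom = NULL, pos = NULL, a1 = "A", a2 = "B",
                     samples = NULL) {
  dosages <- as.matrix(dosages)
  m <- ncol(dosages)
  if (is.null(chrom)) chrom <- rep(1L, m)
  if (is.null(pos)) pos <- seq_len(m) * 1000L
  if (is.null(samples)) samples <- paste0("ind", seq_len(nrow(dosages)))
  geno_matrix(dosages,
              data.frame(id = paste0("s", seq_len(m)), chrom = chrom,
                         pos = pos, a1 = a1, a2 = a2,
                         stringsAsFactors = FALSE),
              samples)
}

# small simulated dataset reused across tests
tiny_sim <- function(seed = 7, n = 120, ...) {
  args <- list(n_animals = n, n_sires = 20, n_dams = 40, n_chrom = 3,
               dense_snps_per_chrom = 80, chip_fraction = 0.5, seed = seed)
  extra <- list(...)
  args[names(extra)] <- extra
  simulate_population(do.call(sim_config, args))
}

# independent brute-force LD pruning oracle: repeatedly drop the lower-MAF
# member of the highest-r2 violating pair (ties: later position) until no
# pair within the window violates the cutoff. O(m^2) recompute each pass.
prune_oracle <- function(G, window_kb, r2_max) {
  keep <- seq_len(n_snps(G))
  repeat {
    worst <- NULL
    worst_r2 <- -Inf
    for (ai in seq_along(keep)) {
      for (bi in seq_along(keep)) {
        if (bi <= ai) next
        a <- keep[ai]; b <- keep[bi]
        if (G$map$chrom[a] != G$map$chrom[b]) next
        if (abs(G$map$pos[b] - G$map$pos[a]) > window_kb * 1000) next
        xa <- G$dosages[, a]; xb <- G$dosages[, b]
        ok <- !is.na(xa) & !is.na(xb)
        if (var(xa[ok]) == 0 || var(xb[ok]) == 0) next
        r2 <- cor(xa[ok], xb[ok])^2
        if (r2 >= r2_max && r2 > worst_r2) {
          worst_r2 <- r2
          worst <- c(a, b)
        }
      }
    }
    if (is.null(worst)) break
    ma <- G$map$maf[worst[1]]; mb <- G$map$maf[worst[2]]
    victim <- if (ma < mb) worst[1] else if (mb < ma) worst[2] else max(worst)
    keep <- setdiff(keep, victim)
  }
  sort(keep)
}

# restricted log-likelihood of a one-component animal model, coded
# independently of the package's REML routines (direct matrix formula).
restricted_ll <- function(y, X, K, sg, se) {
  V <- sg * K + diag(se, length(y))
  Vi <- solve(V)
  XtVX <- t(X) %*% Vi %*% X
  P <- Vi - Vi %*% X %*% solve(XtVX) %*% t(X) %*% Vi
  -0.5 * (determinant(V)$modulus[1] + determinant(XtVX)$modulus[1] +
          drop(t(y) %*% P %*% y))
}
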