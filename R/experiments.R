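# Replication harnesses: simulation studies exercising the estimators under
# the generator's study conditions. Used by the test suite and by
# scripts/acceptance.R; sizes are arguments so callers can scale them.

#' Heritability recovery study
#'
#' Simulates replicate populations at a known heritability and re-estimates
#' it by REML on the chip-panel GRM with the full fixed-effect model.
#'
#' @param n_reps Number of replicates (default 30).
#' @param config Generator configuration; the default matches the trait
#'   conditions (h2 = 0.26, n = 482) with a 5,000-SNP chip panel.
#' @param seed Base seed; replicate r uses `seed + r`.
#' @return List with `h2_hat` (per-replicate estimates), `mean`, `se`
#'   (empirical standard error of the mean) and `true_h2`.
#' @export
h2_recovery_study <- function(n_reps = 30,
                              config = sim_config(n_chrom = 5,
                                                  dense_snps_per_chrom = 1000,
                                                  chip_fraction = 1),
                              seed = 1L) {
  h2_hat <- vapply(seq_len(n_reps), function(r) {
    cfg <- config
    cfg$seed <- seed + r
    sim <- simulate_population(cfg)
    spec <- model_spec(list(chip = compute_grm(sim$chip)))
    heritability(reml_fit(sim$pheno, spec))
  }, 1.0)
  list(h2_hat = h2_hat, mean = mean(h2_hat),
       se = stats::sd(h2_hat) / sqrt(n_reps), true_h2 = config$h2)
}

#' Type-I error of the LOCO association scan under the null
#'
#' Fixes one simulated genotype panel, then repeatedly draws a pure-noise
#' phenotype and scans one chromosome with the leave-one-chromosome-out GRM,
#' recording the p-value of one pre-chosen test SNP per replicate.
#'
#' @param n_reps Null replicates (default 1000).
#' @param n_animals,n_chrom,dense_snps_per_chrom Panel size controls.
#' @param alpha Nominal level whose rejection rate is reported (default 0.05).
#' @param seed Integer seed.
#' @return List with `p` (replicate p-values of the test SNP),
#'   `rejection_rate`, `alpha` and the binomial 95% CI half-width.
#' @export
gwas_null_calibration <- function(n_reps = 1000, n_animals = 150,
                                  n_chrom = 3, dense_snps_per_chrom = 50,
                                  alpha = 0.05, seed = 1L) {
  cfg <- sim_config(n_animals = n_animals, n_sires = 25, n_dams = 60,
                    n_chrom = n_chrom,
                    dense_snps_per_chrom = dense_snps_per_chrom,
                    chip_fraction = 1, n_qtl = 0, qtl_pve = numeric(0),
                    h2 = 0.2, seed = seed)
  sim <- simulate_population(cfg)
  panel <- sim$dense
  chr1 <- subset_geno(panel, snps = panel$map$chrom == 1)
  # median-MAF SNP on the scanned chromosome as the tracked test SNP
  test_snp <- chr1$map$id[order(chr1$map$maf)][ceiling(n_snps(chr1) / 2)]
  set.seed(seed + 1L)
  p <- vapply(seq_len(n_reps), function(r) {
    y <- stats::setNames(stats::rnorm(n_individuals(panel)), panel$samples)
    scan <- mlm_scan(y, chr1, panel)
    scan$p[scan$id == test_snp]
  }, 1.0)
  list(p = p, rejection_rate = mean(p < alpha), alpha = alpha,
       ci_halfwidth = 1.96 * sqrt(alpha * (1 - alpha) / n_reps),
       test_snp = test_snp)
}

#' Power of the scan at a planted large-effect SNP
#'
#' Plants a single SNP explaining `pve` of the phenotypic variance in each
#' replicate and reports how often its LOCO-scan p-value beats `threshold`.
#'
#' @param n_reps Replicates (default 50).
#' @param n_animals Cohort size (default 482).
#' @param pve Variance fraction explained by the planted SNP (default 0.20).
#' @param threshold Significance threshold to beat (default 9.90e-7, the
#'   genome-wide level of a 50,482-SNP scan).
#' @param seed Integer seed.
#' @return List with `p` (per-replicate p-values of the planted SNP) and
#'   `power`.
#' @export
gwas_power_study <- function(n_reps = 50, n_animals = 482, pve = 0.20,
                             threshold = 0.05 / 50482, seed = 1L) {
  power_p <- vapply(seq_len(n_reps), function(r) {
    cfg <- sim_config(n_animals = n_animals, n_sires = 80, n_dams = 226,
                      n_chrom = 2, dense_snps_per_chrom = 60,
                      chip_fraction = 1, n_qtl = 1, qtl_pve = pve,
                      h2 = pve + 0.05, seed = seed + r)
    sim <- simulate_population(cfg)
    y <- stats::setNames(sim$pheno$trait, sim$pheno$animal_id)
    qtl_id <- sim$truth$qtl_ids[1]
    chr <- sim$dense$map$chrom[sim$dense$map$id == qtl_id]
    scan <- mlm_scan(y, subset_geno(sim$dense, snps = sim$dense$map$chrom == chr),
                     sim$dense)
    scan$p[scan$id == qtl_id]
  }, 1.0)
  list(p = power_p, power = mean(power_p < threshold), threshold = threshold)
}

#' Reliability ordering study across prediction approaches
#'
#' Replicates the cross-validated comparison of pedigree BLUP, chip GBLUP and
#' the one- and two-component models with fold-internal pre-selection, on
#' populations carrying a handful of major QTLs plus polygenic background.
#'
#' @param n_reps Replicates (default 20).
#' @param config Generator configuration (default: the generator's standard
#'   conditions — 482 animals, four off-chip QTLs of 2.5% PVE each).
#' @param approaches Approaches to compare (default the GBLUP family plus
#'   PBLUP).
#' @param seed Base seed.
#' @param verbose Progress logging.
#' @return List with `means` (replicates x approaches matrix of mean
#'   reliabilities) and `overall` (column means).
#' @export
reliability_ordering_study <- function(
    n_reps = 20,
    config = sim_config(),
    approaches = c("PBLUP", "GBLUP-80K", "GBLUP-80K-GWASiWGS-one",
                   "GBLUP-80K-GWASiWGS-two"),
    seed = 1L, verbose = FALSE) {
  means <- matrix(NA_real_, n_reps, length(approaches),
                  dimnames = list(NULL, approaches))
  for (r in seq_len(n_reps)) {
    cfg <- config
    cfg$seed <- seed + 1000L + r
    sim <- simulate_population(cfg)
    data <- prepare_pipeline_data(sim, r2_prune = NA)
    folds <- make_folds(as.character(data$pheno$animal_id), k = 5,
                        seed = seed + r)
    cache <- new.env(parent = emptyenv())
    for (ap in approaches) {
      res <- run_cv(data, ap, folds, preselect_cache = cache)
      means[r, ap] <- res$mean
    }
    if (verbose) {
      message(sprintf("rep %d: %s", r,
                      paste(sprintf("%s=%.3f", approaches, means[r, ]),
                            collapse = " ")))
    }
  }
  list(means = means, overall = colMeans(means))
}
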