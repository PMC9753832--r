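#' Configuration for the synthetic pig-like dataset
#'
#' Defaults emulate, at desk scale, a growing-finishing pig cohort: 482
#' animals from 80 sires and 226 dams, a trait with mean 1.91 (% units),
#' coefficient of variation 0.3173 and heritability 0.26, four major QTLs
#' each explaining 2-3% of phenotypic variance, sex and four slaughter
#' batches as class effects, and age and carcass weight as covariates. The
#' genome itself is scaled down (6 chromosomes of 400 SNPs at 10 kb spacing
#' by default) so that a full analysis runs in minutes; `n_chrom`,
#' `dense_snps_per_chrom` and `snp_spacing_bp` scale it up.
#'
#' @param n_animals Genotyped, phenotyped offspring (default 482).
#' @param n_sires,n_dams Founder counts (defaults 80 / 226).
#' @param n_chrom Autosome count (default 6).
#' @param dense_snps_per_chrom SNPs per chromosome in the sequence-density
#'   panel (default 400).
#' @param snp_spacing_bp Physical spacing between adjacent SNPs (default 1e4).
#' @param chip_fraction Fraction of dense SNPs on the chip panel, taken as an
#'   evenly spaced subset (default 1/3).
#' @param ld_block_mean_kb Mean length of founder haplotype blocks; controls
#'   how fast LD decays with distance (default 100).
#' @param n_pool Size of the ancestral haplotype pool per chromosome
#'   (default 6; smaller pools give stronger linkage disequilibrium).
#' @param maf_min Minimum minor allele frequency retained after simulation
#'   (default 0.01).
#' @param n_qtl,qtl_pve Number of planted QTLs and the fraction of phenotypic
#'   variance each explains (defaults: 4 QTLs at 0.025 each).
#' @param h2 Narrow-sense heritability of the trait (default 0.26).
#' @param trait_mean,trait_cv Trait mean (% units, default 1.91) and
#'   coefficient of variation (default 0.3173).
#' @param batch_levels Number of slaughter batches (default 4).
#' @param beta_age,beta_cw Covariate slopes (trait units per day / per kg).
#' @param seed Integer seed; one seed fans out to independent substreams for
#'   haplotypes, pedigree, effects and noise.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_animals = 482, n_sires = 80, n_dams = 226,
                       n_chrom = 6, dense_snps_per_chrom = 400,
                       snp_spacing_bp = 1e4, chip_fraction = 1 / 3,
                       ld_block_mean_kb = 100, n_pool = 6, maf_min = 0.01,
                       n_qtl = 4, qtl_pve = rep(0.025, n_qtl), h2 = 0.26,
                       trait_mean = 1.91, trait_cv = 0.3173,
                       batch_levels = 4, beta_age = 0.005, beta_cw = 0.02,
                       seed = 1L) {
  cfg <- as.list(environment())
  cfg$sex_levels <- 2L
  if (length(cfg$qtl_pve) != cfg$n_qtl) stop("qtl_pve must have n_qtl entries")
  if (cfg$h2 < 0 || cfg$h2 >= 1) stop("h2 must lie in [0, 1)")
  if (sum(cfg$qtl_pve) >= cfg$h2 && cfg$n_qtl > 0) {
    stop("infeasible PVE allocation: sum(qtl_pve) must be < h2")
  }
  if (cfg$chip_fraction <= 0 || cfg$chip_fraction > 1) {
    stop("chip_fraction must lie in (0, 1]")
  }
  structure(cfg, class = "sim_config")
}

#' Read a simulation configuration from a YAML key-value file
#' @param path Path to a YAML file whose keys match [sim_config()] arguments.
#' @return A `sim_config`.
#' @export
read_sim_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(sim_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) stop("unknown config key(s): ",
                            paste(unknown, collapse = ", "))
  do.call(sim_config, vals)
}

#' Plant QTLs with exact per-SNP variance contributions
#'
#' Chooses `length(pve_list)` SNPs from the dense panel (minor allele
#' frequency at least 0.1, spread across chromosomes where possible) and
#' assigns each the allele substitution effect that makes its contribution to
#' phenotypic variance exactly the requested fraction:
#' `b = sqrt(pve * sigma_p2 / (2 q (1 - q)))` at the realized frequency `q`,
#' with a random sign. Recomputing `2 q (1 - q) b^2 / sigma_p2` from the
#' returned effects reproduces `pve_list` to machine precision.
#'
#' @param dense A [geno_matrix()].
#' @param pve_list Target per-QTL fractions of phenotypic variance.
#' @param sigma_p2 Phenotypic variance of the trait.
#' @param positions Optional SNP column indices to use instead of sampling.
#' @param exclude Optional column indices never used as QTLs (the simulator
#'   passes the chip subset here, so causal variants are sequence-only).
#' @return List with `positions` (column indices), `snp_ids` and `effects`.
#' @export
plant_qtl <- function(dense, pve_list, sigma_p2, positions = NULL,
                      exclude = integer(0)) {
  if (length(pve_list) == 0L) {
    return(list(positions = integer(0), snp_ids = character(0),
                effects = numeric(0)))
  }
  maf <- snp_maf(dense)
  if (is.null(positions)) {
    eligible <- setdiff(which(!is.na(maf) & maf >= 0.1), exclude)
    if (length(eligible) < length(pve_list)) {
      # not enough off-chip candidates (e.g. chip == dense): allow any SNP
      eligible <- which(!is.na(maf) & maf >= 0.1)
    }
    if (length(eligible) < length(pve_list)) {
      stop("not enough SNPs with MAF >= 0.1 to plant the requested QTLs")
    }
    # spread across chromosomes round-robin where possible
    by_chr <- split(eligible, dense$map$chrom[eligible])
    by_chr <- by_chr[sample.int(length(by_chr))]
    positions <- integer(0)
    i <- 0
    while (length(positions) < length(pve_list)) {
      bucket <- by_chr[[i %% length(by_chr) + 1]]
      bucket <- setdiff(bucket, positions)
      if (length(bucket)) positions <- c(positions, sample(bucket, 1))
      i <- i + 1
    }
  }
  q <- maf[positions]
  if (any(is.na(q) | q == 0)) {
    stop("cannot plant a QTL on a monomorphic SNP (q = 0)")
  }
  b <- unname(sqrt(pve_list * sigma_p2 / (2 * q * (1 - q))))
  b <- b * sample(c(-1, 1), length(b), replace = TRUE)
  list(positions = positions, snp_ids = dense$map$id[positions], effects = b)
}

# Founder haplotypes as mosaics over a small ancestral pool: along each
# chromosome the active pool haplotype switches with probability
# 1 - exp(-spacing / block_mean), giving adjacent-SNP LD that decays with
# physical distance.
sim_founder_haplotypes <- function(n_hap, m, spacing_bp, block_mean_kb,
                                   n_pool) {
  f <- stats::runif(m, 0.1, 0.9)
  pool <- matrix(stats::rbinom(n_pool * m, 1, rep(f, each = n_pool)),
                 nrow = n_pool)
  p_switch <- 1 - exp(-(spacing_bp / 1000) / block_mean_kb)
  haps <- matrix(0L, n_hap, m)
  for (h in seq_len(n_hap)) {
    switches <- c(TRUE, stats::runif(m - 1) < p_switch)
    state <- sample.int(n_pool, sum(switches), replace = TRUE)
    idx <- cumsum(switches)
    src <- state[idx]
    haps[h, ] <- pool[cbind(src, seq_len(m))]
  }
  haps
}

# Gene drop one gamete from a parent's two haplotypes with crossover
# probability per interval of distance_bp * 1e-8 (1 cM/Mb).
meiosis <- function(hap1, hap2, spacing_bp) {
  m <- length(hap1)
  cross <- c(stats::runif(1) < 0.5, stats::runif(m - 1) < spacing_bp * 1e-8)
  from_first <- cumsum(cross) %% 2 == 0
  ifelse(from_first, hap1, hap2)
}

#' Simulate a pig-like population for genomic-prediction studies
#'
#' Generates founder haplotypes with block LD structure, drops genes through
#' a two-generation pedigree (sires and dams drawn with replacement),
#' genotypes the offspring on a dense panel and an evenly thinned chip subset,
#' plants QTLs with exact variance contributions, and builds phenotypes as
#' mean + sex + batch + age and carcass-weight regressions + QTL effects +
#' polygenic background + residual. The polygenic term is rescaled so the
#' realized ratio of breeding-value variance to phenotypic variance matches
#' the target heritability, and the residual variance is set from the
#' realized breeding values.
#'
#' @param config A [sim_config()].
#' @return List with elements `dense` and `chip` ([geno_matrix()] panels over
#'   the offspring), `pedigree` (founders then offspring; `0` = unknown
#'   parent), `pheno` (animal_id, trait, sex, batch, age, carcass_weight) and
#'   `truth` (true breeding values, QTL positions/effects, realized
#'   heritability, fixed-effect values, variance bookkeeping).
#' @export
simulate_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  substream <- sample.int(.Machine$integer.max - 1, 4)
  names(substream) <- c("haplotypes", "pedigree", "effects", "noise")

  n_f <- config$n_sires + config$n_dams
  m_per <- config$dense_snps_per_chrom
  m <- m_per * config$n_chrom

  # --- founder haplotypes ---
  set.seed(substream[["haplotypes"]])
  founder_h1 <- matrix(0L, n_f, m)
  founder_h2 <- matrix(0L, n_f, m)
  for (ch in seq_len(config$n_chrom)) {
    cols <- (ch - 1) * m_per + seq_len(m_per)
    H <- sim_founder_haplotypes(2 * n_f, m_per, config$snp_spacing_bp,
                                config$ld_block_mean_kb, config$n_pool)
    founder_h1[, cols] <- H[seq_len(n_f), ]
    founder_h2[, cols] <- H[n_f + seq_len(n_f), ]
  }

  # --- pedigree and gene dropping ---
  set.seed(substream[["pedigree"]])
  sire_ids <- sprintf("S%03d", seq_len(config$n_sires))
  dam_ids <- sprintf("D%03d", seq_len(config$n_dams))
  off_ids <- sprintf("A%04d", seq_len(config$n_animals))
  sire_of <- sample(config$n_sires, config$n_animals, replace = TRUE)
  dam_of <- sample(config$n_dams, config$n_animals, replace = TRUE)
  dose <- matrix(0L, config$n_animals, m)
  for (i in seq_len(config$n_animals)) {
    si <- sire_of[i]
    di <- config$n_sires + dam_of[i]
    gam <- integer(m)
    for (ch in seq_len(config$n_chrom)) {
      cols <- (ch - 1) * m_per + seq_len(m_per)
      g1 <- meiosis(founder_h1[si, cols], founder_h2[si, cols],
                    config$snp_spacing_bp)
      g2 <- meiosis(founder_h1[di, cols], founder_h2[di, cols],
                    config$snp_spacing_bp)
      dose[i, cols] <- g1 + g2
    }
  }
  pedigree <- data.frame(
    id = c(sire_ids, dam_ids, off_ids),
    sire = c(rep("0", n_f), sire_ids[sire_of]),
    dam = c(rep("0", n_f), dam_ids[dam_of]),
    stringsAsFactors = FALSE)

  map <- data.frame(
    id = sprintf("snp_%d_%d", rep(seq_len(config$n_chrom), each = m_per),
                 rep(seq_len(m_per), config$n_chrom)),
    chrom = rep(seq_len(config$n_chrom), each = m_per),
    pos = rep(seq_len(m_per) * config$snp_spacing_bp, config$n_chrom),
    a1 = "A", a2 = "B", stringsAsFactors = FALSE)
  dense <- geno_matrix(dose, map, off_ids)
  keep <- !is.na(dense$map$maf) & dense$map$maf >= config$maf_min
  if (!any(keep)) stop("all simulated SNPs fell below maf_min")
  dense <- subset_geno(dense, snps = keep)

  # chip = evenly spaced subset within each chromosome
  chip_idx <- unlist(lapply(split(seq_len(n_snps(dense)), dense$map$chrom),
    function(ix) {
      k <- max(1L, round(length(ix) * config$chip_fraction))
      ix[unique(round(seq(1, length(ix), length.out = k)))]
    }), use.names = FALSE)
  chip <- subset_geno(dense, snps = sort(chip_idx))

  # --- genetic architecture ---
  set.seed(substream[["effects"]])
  sigma_p <- config$trait_mean * config$trait_cv
  sigma_p2 <- sigma_p^2
  qtl <- plant_qtl(dense, config$qtl_pve, sigma_p2,
                   exclude = sort(chip_idx))
  Zq <- center_dosages(subset_geno(dense, snps = qtl$positions))
  g_qtl <- if (length(qtl$positions)) drop(Zq %*% qtl$effects) else
    numeric(config$n_animals)
  poly_target <- max(0, config$h2 - sum(config$qtl_pve)) * sigma_p2
  if (poly_target > 0) {
    bg <- setdiff(seq_len(n_snps(dense)), qtl$positions)
    Zb <- center_dosages(subset_geno(dense, snps = bg))
    u <- drop(Zb %*% stats::rnorm(length(bg)))
    u <- u - mean(u)
    u <- u * sqrt(poly_target / stats::var(u))
  } else {
    u <- numeric(config$n_animals)
  }
  tbv <- g_qtl + u
  var_tbv <- stats::var(tbv)
  sigma_e2 <- if (config$h2 > 0 && var_tbv > 0) {
    var_tbv * (1 - config$h2) / config$h2
  } else {
    sigma_p2
  }

  # --- fixed effects, covariates, phenotype ---
  set.seed(substream[["noise"]])
  sex <- factor(sample(c("M", "F"), config$n_animals, replace = TRUE),
                levels = c("M", "F"))
  batch <- factor(sample(sprintf("B%d", seq_len(config$batch_levels)),
                         config$n_animals, replace = TRUE),
                  levels = sprintf("B%d", seq_len(config$batch_levels)))
  sex_eff <- c(M = 0, F = 0.3 * sigma_p)
  L <- config$batch_levels
  batch_eff <- stats::setNames(
    0.3 * sigma_p * (seq_len(L) - (L + 1) / 2) / max(1, (L - 1) / 2),
    levels(batch))
  age <- round(stats::rnorm(config$n_animals, 220, 8))
  cw <- stats::rnorm(config$n_animals, 85, 4)
  e <- stats::rnorm(config$n_animals, 0, sqrt(sigma_e2))
  trait <- config$trait_mean + sex_eff[sex] + batch_eff[batch] +
    config$beta_age * (age - mean(age)) + config$beta_cw * (cw - mean(cw)) +
    tbv + e
  pheno <- data.frame(animal_id = off_ids, trait = as.numeric(trait),
                      sex = sex, batch = batch, age = age,
                      carcass_weight = cw, stringsAsFactors = FALSE)
  true_h2 <- if (var_tbv + sigma_e2 > 0) var_tbv / (var_tbv + sigma_e2) else 0
  truth <- list(
    true_breeding_values = stats::setNames(tbv, off_ids),
    qtl_positions = qtl$positions, qtl_ids = qtl$snp_ids,
    qtl_effects = qtl$effects, qtl_pve = config$qtl_pve,
    true_h2 = true_h2, sigma_e2 = sigma_e2, sigma_p2 = sigma_p2,
    fixed_effect_values = list(sex = sex_eff, batch = batch_eff,
                               beta_age = config$beta_age,
                               beta_cw = config$beta_cw),
    substream_seeds = substream)
  list(dense = dense, chip = chip, pedigree = pedigree, pheno = pheno,
       truth = truth, config = config)
}

#' Write a simulated dataset to disk
#'
#' Writes both genotype panels as PLINK triples (`chip.*`, `dense.*`),
#' tab-separated phenotype, pedigree and truth tables.
#'
#' @param sim Result of [simulate_population()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_plink(sim$chip, file.path(dir, "chip"))
  write_plink(sim$dense, file.path(dir, "dense"))
  utils::write.table(sim$pheno, file.path(dir, "phenotypes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$pedigree, file.path(dir, "pedigree.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  truth_tab <- data.frame(animal_id = names(sim$truth$true_breeding_values),
                          tbv = sim$truth$true_breeding_values)
  utils::write.table(truth_tab, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  qtl_tab <- data.frame(snp_id = sim$truth$qtl_ids,
                        effect = sim$truth$qtl_effects,
                        pve = sim$truth$qtl_pve)
  utils::write.table(qtl_tab, file.path(dir, "qtl.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
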