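test_that("zero-heritability limit yields null breeding values", {
  sim <- tiny_sim(seed = 41, h2 = 0, n_qtl = 0, qtl_pve = numeric(0))
  expect_true(all(sim$truth$true_breeding_values == 0))
  expect_equal(sim$truth$true_h2, 0)
  expect_length(sim$truth$qtl_positions, 0)
})

test_that("chip_fraction = 1 makes the chip panel identical to the dense one", {
  sim <- tiny_sim(seed = 42, chip_fraction = 1)
  expect_identical(sim$chip$dosages, sim$dense$dosages)
  expect_identical(sim$chip$map, sim$dense$map)
})

test_that("the chip panel is an evenly thinned subset of the dense panel", {
  sim <- tiny_sim(seed = 43)
  expect_true(all(sim$chip$map$id %in% sim$dense$map$id))
  expect_lt(n_snps(sim$chip), n_snps(sim$dense))
  shared <- match(sim$chip$map$id, sim$dense$map$id)
  expect_identical(sim$chip$dosages,
                   sim$dense$dosages[, shared, drop = FALSE])
})

test_that("planted QTL effects invert the PVE formula exactly", {
  # b = sqrt(pve * sigma_p2 / (2 q (1-q))): at pve 0.0274, q 0.25,
  # sigma_p2 0.28 the magnitude is ~0.1430
  G <- toy_geno(matrix(rep(c(0, 0, 1, 1), 25), ncol = 1))  # maf 0.25
  qtl <- plant_qtl(G, 0.0274, 0.28, positions = 1L)
  expect_equal(abs(qtl$effects), sqrt(0.0274 * 0.28 / (2 * 0.25 * 0.75)),
               tolerance = 1e-12)
  expect_equal(abs(qtl$effects), 0.1430, tolerance = 1e-3)
  # round trip through the PVE formula is exact
  expect_equal(snp_pve(0.25, qtl$effects, 0.28), 0.0274, tolerance = 1e-12)

  # several QTLs on a simulated panel round-trip too
  sim <- tiny_sim(seed = 44)
  q <- snp_maf(sim$dense)[sim$truth$qtl_positions]
  expect_equal(unname(snp_pve(q, sim$truth$qtl_effects,
                              sim$truth$sigma_p2)),
               sim$truth$qtl_pve, tolerance = 1e-12)

  # zero target gives a zero effect; monomorphic SNPs are refused
  expect_equal(plant_qtl(G, 0, 0.28, positions = 1L)$effects, 0)
  G0 <- toy_geno(matrix(0, 10, 1))
  expect_error(plant_qtl(G0, 0.01, 0.28, positions = 1L), "monomorphic")
})

test_that("infeasible variance allocations are rejected", {
  expect_error(sim_config(h2 = 0.1, n_qtl = 4, qtl_pve = rep(0.03, 4)),
               "infeasible")
  expect_error(sim_config(h2 = 0, n_qtl = 1, qtl_pve = 0.02), "infeasible")
  expect_error(sim_config(chip_fraction = 0), "chip_fraction")
})

test_that("simulation is byte-identical under a fixed seed", {
  a <- tiny_sim(seed = 45)
  b <- tiny_sim(seed = 45)
  expect_identical(a$dense$dosages, b$dense$dosages)
  expect_identical(a$pheno, b$pheno)
  expect_identical(a$truth$qtl_effects, b$truth$qtl_effects)
  c <- tiny_sim(seed = 46)
  expect_false(identical(a$dense$dosages, c$dense$dosages))
})

test_that("generator bookkeeping matches its stated variance structure", {
  sim <- tiny_sim(seed = 47, n = 300)
  tbv <- sim$truth$true_breeding_values
  # realized var(TBV) / (var(TBV) + sigma_e2) equals the recorded true h2
  expect_equal(var(tbv) / (var(tbv) + sim$truth$sigma_e2),
               sim$truth$true_h2, tolerance = 1e-12)
  # which sits near the configured target
  expect_equal(sim$truth$true_h2, 0.26, tolerance = 0.02)
  # all retained SNPs clear the MAF floor, on autosomes, sorted
  expect_true(all(sim$dense$map$maf >= sim$config$maf_min))
  expect_true(!is.unsorted(order(sim$dense$map$chrom, sim$dense$map$pos)))
  # QTLs live off the chip
  expect_false(any(sim$truth$qtl_ids %in% sim$chip$map$id))
})

test_that("pedigree is two-generation with parents preceding offspring", {
  sim <- tiny_sim(seed = 48)
  ped <- sim$pedigree
  known <- ped$sire != "0"
  expect_true(all(match(ped$sire[known], ped$id) < which(known)))
  expect_true(all(match(ped$dam[known], ped$id) < which(known)))
  # A matrix from it is positive definite
  A <- compute_a_matrix(ped)
  expect_gt(min(eigen(A$values, symmetric = TRUE,
                      only.values = TRUE)$values), 0)
})

test_that("thinning lowers the count of high-LD adjacent pairs per Mb", {
  sim <- simulate_population(sim_config(
    n_animals = 300, n_sires = 50, n_dams = 120, n_chrom = 3,
    dense_snps_per_chrom = 200, chip_fraction = 0.3, seed = 49))
  high_ld_per_mb <- function(G) {
    n_pairs <- 0
    for (ch in unique(G$map$chrom)) {
      idx <- which(G$map$chrom == ch)
      for (j in idx[-length(idx)]) {
        r2 <- tryCatch(ld_r2(G$dosages[, j], G$dosages[, j + 1]),
                       error = function(e) 0)
        if (r2 > 0.55) n_pairs <- n_pairs + 1
      }
    }
    span_mb <- sum(tapply(G$map$pos, G$map$chrom, function(p) diff(range(p)))) / 1e6
    n_pairs / span_mb
  }
  expect_gt(high_ld_per_mb(sim$dense), high_ld_per_mb(sim$chip))
})

test_that("datasets round-trip through the on-disk layout", {
  sim <- tiny_sim(seed = 50)
  dir <- tempfile()
  write_dataset(sim, dir)
  chip <- read_plink(file.path(dir, "chip"))
  expect_identical(unname(chip$dosages), unname(sim$chip$dosages))
  ph <- read.delim(file.path(dir, "phenotypes.tsv"))
  expect_equal(ph$trait, sim$pheno$trait, tolerance = 1e-12)
  # YAML config round trip
  cfg_path <- tempfile(fileext = ".yaml")
  writeLines(c("n_animals: 50", "n_sires: 10", "n_dams: 20", "seed: 3",
               "n_chrom: 2", "dense_snps_per_chrom: 40"), cfg_path)
  cfg <- read_sim_config(cfg_path)
  expect_equal(cfg$n_animals, 50)
  expect_equal(cfg$n_chrom, 2)
  writeLines("bogus_key: 1", cfg_path)
  expect_error(read_sim_config(cfg_path), "unknown config key")
})
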