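test_that("PLINK write/read round-trips dosages, ids and positions", {
  set.seed(1)
  dos <- matrix(sample(c(0, 1, 2, NA), 60, replace = TRUE,
                       prob = c(.3, .3, .3, .1)), nrow = 5)
  G <- toy_geno(dos, chrom = rep(1:2, each = 6),
                pos = rep(c(5000L, 10000L, 1000000L, 2000000L, 150000000L,
                            150000100L), 2))
  prefix <- tempfile()
  write_plink(G, prefix)
  G2 <- read_plink(prefix)
  expect_identical(unname(G2$dosages), unname(G$dosages))
  expect_identical(G2$map$id, G$map$id)
  expect_identical(G2$map$pos, as.integer(G$map$pos))
  expect_identical(G2$samples, G$samples)
})

test_that("bed genotype bytes decode under the PLINK 2-bit coding", {
  # Codes are read from the low-order bit pair upwards:
  # 00 -> hom A1 (2), 01 -> missing, 10 -> het (1), 11 -> hom A2 (0).
  # Byte 0b11011000 therefore decodes, sample-wise, to 2, 1, NA, 0.
  prefix <- tempfile()
  writeBin(c(as.raw(c(0x6c, 0x1b, 0x01)), as.raw(0xD8)), paste0(prefix, ".bed"))
  writeLines("1\tsnp1\t0\t100\tA\tB", paste0(prefix, ".bim"))
  writeLines(paste0("F", 1:4, " I", 1:4, " 0 0 0 -9"), paste0(prefix, ".fam"))
  G <- read_plink(prefix)
  expect_equal(unname(G$dosages[, 1]), c(2, 1, NA, 0))
})

test_that("malformed PLINK triples raise explicit errors", {
  sim <- tiny_sim()
  prefix <- tempfile()
  write_plink(sim$chip, prefix)
  # corrupt the magic bytes
  bad <- readBin(paste0(prefix, ".bed"), "raw", file.size(paste0(prefix, ".bed")))
  bad[1] <- as.raw(0x00)
  writeBin(bad, paste0(prefix, ".bed"))
  expect_error(read_plink(prefix), "magic")
  # restore magic but drop a fam row -> size mismatch
  write_plink(sim$chip, prefix)
  fam <- readLines(paste0(prefix, ".fam"))
  writeLines(c(fam, fam[1]), paste0(prefix, ".fam"))
  expect_error(read_plink(prefix), "mismatch")
  expect_error(read_plink(tempfile()), "missing")
})

test_that("qc_filter applies MAF, call-rate and missingness rules in order", {
  # SNP1: maf 0.25, call rate 1; SNP2: maf ~0.005 (too rare); SNP3: call rate 0.5
  dos <- cbind(c(1, 0, 0, 0), c(0, 0, 0, 0), c(NA, NA, 1, 0))
  dos[1, 2] <- 0  # keep SNP2 monomorphic-ish: maf 0 < 0.01
  G <- toy_geno(dos)
  out <- qc_filter(G)
  expect_equal(n_snps(out), 1L)
  expect_equal(out$map$id, "s1")

  # a SNP at maf 0.005 is removed at the 0.01 rule
  set.seed(2)
  dos2 <- cbind(rep(c(0, 1), 50), c(1, rep(0, 99)))  # maf .25ish and .005
  G2 <- toy_geno(dos2)
  expect_false("s2" %in% qc_filter(G2)$map$id)

  # individuals missing more than 10% are removed after the SNP pass
  set.seed(4)
  dos3 <- matrix(sample(0:2, 200, replace = TRUE), nrow = 20)
  dos3[1, 1:3] <- NA  # 30% missing for individual 1; SNP call rates stay 0.95
  G3 <- toy_geno(dos3)
  out3 <- qc_filter(G3)
  expect_equal(n_individuals(out3), 19L)
  expect_false("ind1" %in% out3$samples)

  # idempotence on an already-clean panel
  sim <- tiny_sim()
  clean <- qc_filter(sim$chip)
  again <- qc_filter(clean)
  expect_identical(again$dosages, clean$dosages)
})

test_that("merge_panels overrides shared loci with chip calls", {
  chip <- toy_geno(cbind(c(2, 2), c(0, 1)), pos = c(100L, 300L),
                   samples = c("a", "b"))
  dense <- toy_geno(cbind(c(1, 1), c(1, 1), c(2, 0)),
                    pos = c(100L, 200L, 300L), samples = c("a", "b"))
  out <- merge_panels(chip, dense)
  expect_equal(n_snps(out), 3L)
  expect_equal(unname(out$dosages[, out$map$pos == 100]), c(2, 2))
  expect_equal(unname(out$dosages[, out$map$pos == 200]), c(1, 1))
  expect_equal(unname(out$dosages[, out$map$pos == 300]), c(0, 1))
})

test_that("merge_panels appends chip-only loci and handles allele flips", {
  # disjoint positions: union of SNP sets
  chip <- toy_geno(cbind(c(0, 2)), pos = 500L, samples = c("a", "b"))
  dense <- toy_geno(cbind(c(1, 1), c(2, 0)), pos = c(100L, 300L),
                    samples = c("a", "b"))
  out <- merge_panels(chip, dense)
  expect_equal(n_snps(out), 3L)
  expect_equal(sort(out$map$pos), c(100L, 300L, 500L))

  # swapped allele order: chip dosage complemented before override
  chipf <- toy_geno(cbind(c(0, 1)), pos = 100L, a1 = "B", a2 = "A",
                    samples = c("a", "b"))
  outf <- merge_panels(chipf, dense)
  expect_equal(unname(outf$dosages[, outf$map$pos == 100]), c(2, 1))

  # genuinely different alleles: error naming the locus
  chipm <- toy_geno(cbind(c(0, 1)), pos = 100L, a1 = "C", a2 = "G",
                    samples = c("a", "b"))
  expect_error(merge_panels(chipm, dense), "allele mismatch")
})

test_that("ld_r2 is the squared dosage correlation, invariant to relabeling", {
  x <- c(0, 1, 2, 0, 1, 2)
  expect_equal(ld_r2(x, x), 1)
  expect_equal(ld_r2(x, 2 - x), 1)
  # hand computation: cov = 1.5/3, var_x = 2.75/3, var_y = 1/3 -> r2 = 9/11
  expect_equal(ld_r2(c(0, 1, 2, 0), c(0, 1, 1, 0)), 2.25 / 2.75)
  expect_error(ld_r2(c(1, 1, 1), c(0, 1, 2)), "constant")
  expect_error(ld_r2(c(0, 1), c(0, 1, 2)), "length")
})

test_that("prune_ld removes redundant SNPs deterministically", {
  # 3 identical SNPs within 50 kb: exactly one survives
  x <- rep(c(0, 1, 2, 1), 5)
  G <- toy_geno(cbind(x, x, x), pos = c(1000L, 2000L, 3000L))
  expect_equal(n_snps(prune_ld(G, r2_max = 0.55)), 1L)

  # at the 1.00 boundary only perfect duplicates go; independent SNPs stay
  set.seed(3)
  dos <- matrix(sample(0:2, 200, replace = TRUE), nrow = 20)
  dos <- cbind(dos, dos[, 1])  # a perfect duplicate of SNP 1
  G2 <- toy_geno(dos, pos = seq_len(ncol(dos)) * 1000L)
  out2 <- prune_ld(G2, r2_max = 1.00)
  expect_equal(n_snps(out2), ncol(dos) - 1L)

  # idempotence and monotonicity in the cutoff
  sim <- tiny_sim()
  p55 <- prune_ld(sim$dense, r2_max = 0.55)
  expect_identical(prune_ld(p55, r2_max = 0.55)$map$id, p55$map$id)
  p30 <- prune_ld(sim$dense, r2_max = 0.30)
  expect_lte(n_snps(p30), n_snps(p55))
  expect_error(prune_ld(sim$dense, r2_max = 1.5), "r2_max")
})

test_that("prune_ld matches the brute-force removal oracle", {
  set.seed(11)
  sim <- simulate_population(sim_config(
    n_animals = 60, n_sires = 10, n_dams = 25, n_chrom = 2,
    dense_snps_per_chrom = 50, chip_fraction = 1, seed = 13))
  G <- sim$dense
  for (cutoff in c(0.9, 0.55, 0.3)) {
    got <- prune_ld(G, r2_max = cutoff)$map$id
    want <- G$map$id[prune_oracle(G, window_kb = 50, r2_max = cutoff)]
    expect_identical(got, want)
  }
})
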