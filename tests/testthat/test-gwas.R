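test_that("Bonferroni thresholds follow 0.05/N and 1/N", {
  thr <- bonferroni_thresholds(50482)
  expect_identical(thr$genomewide, 0.05 / 50482)
  expect_identical(thr$suggestive, 1 / 50482)
  expect_equal(signif(thr$genomewide, 3), 9.90e-7)
  expect_equal(signif(thr$suggestive, 3), 1.98e-5)
  expect_equal(bonferroni_thresholds(1)$genomewide, 0.05)
  expect_equal(bonferroni_thresholds(1)$suggestive, 1.0)
  # genome-wide level is suggestive x 0.05, at any N
  for (n in c(7, 8103716)) {
    t2 <- bonferroni_thresholds(n)
    expect_equal(t2$genomewide, t2$suggestive * 0.05, tolerance = 1e-14)
  }
  expect_equal(bonferroni_thresholds(8103716)$genomewide, 6.17e-9,
               tolerance = 1e-3)
  expect_error(bonferroni_thresholds(0), "positive")
})

test_that("snp_pve evaluates and bounds the variance-explained formula", {
  expect_equal(snp_pve(0, 1, 1), 0)
  expect_equal(snp_pve(0.3, 0, 1), 0)
  expect_equal(snp_pve(0.25, 0.1430, 0.28), 0.0274, tolerance = 1e-3)
  b <- seq(0, 1, by = 0.1)
  expect_true(all(diff(snp_pve(0.25, b, 1)) > 0))
  expect_error(snp_pve(0.25, 0.1, 0), "sigma_p2")
  expect_error(snp_pve(0.7, 0.1, 1), "q must")
})

test_that("the LOCO scan is invariant to allele relabeling", {
  sim <- tiny_sim(seed = 61)
  dat <- prepare_pipeline_data(sim, r2_prune = NA)
  scan1 <- mlm_scan(dat$yc, dat$chip, dat$chip)
  flipped <- dat$chip
  flipped$dosages[, 5] <- 2 - flipped$dosages[, 5]
  scan2 <- mlm_scan(dat$yc, flipped, flipped)
  expect_equal(scan2$beta[5], -scan1$beta[5], tolerance = 1e-8)
  expect_equal(scan2$p[5], scan1$p[5], tolerance = 1e-8)
  expect_equal(scan2$p[-5], scan1$p[-5], tolerance = 1e-8)
})

test_that("monomorphic SNPs are flagged and a permuted trait is null", {
  sim <- tiny_sim(seed = 62)
  dat <- prepare_pipeline_data(sim, r2_prune = NA)
  panel <- dat$chip
  panel$dosages[, 3] <- 1  # constant
  scan <- mlm_scan(dat$yc, panel, dat$chip)
  expect_true(scan$monomorphic[3])
  expect_equal(scan$p[3], 1)
  expect_equal(scan$beta[3], 0)
  # permuted phenotype: p-values approximately uniform
  set.seed(1)
  ycp <- setNames(sample(as.numeric(dat$yc)), names(dat$yc))
  scan_null <- mlm_scan(ycp, dat$chip, dat$chip)
  qq_slope <- coef(lm(sort(scan_null$p) ~ 0 + stats::ppoints(nrow(scan_null))))
  expect_equal(unname(qq_slope), 1, tolerance = 0.2)
})

test_that("QTL regions merge by chromosome and gap", {
  rec <- data.frame(
    id = paste0("s", 1:6),
    chrom = c(3, 3, 3, 3, 7, 7),
    pos = c(94.40e6, 95.27e6, 100.1e6, 104.56e6, 10e6, 60e6),
    p = c(1e-8, 1.41e-10, 1e-7, 5e-8, 1e-9, 1e-9))
  reg <- call_regions(rec, threshold = 1e-5, merge_gap_mb = 10)
  r3 <- reg[reg$chrom == 3, ]
  expect_equal(nrow(r3), 1L)
  expect_equal(c(r3$start_bp, r3$end_bp), c(94.40e6, 104.56e6))
  expect_equal(r3$top_snp, "s2")
  expect_equal(r3$n_significant, 4L)
  # two significant SNPs 50 Mb apart become two regions
  expect_equal(nrow(reg[reg$chrom == 7, ]), 2L)
  # one significant SNP: zero-width region
  reg1 <- call_regions(rec[2, ], threshold = 1e-5)
  expect_equal(reg1$start_bp, reg1$end_bp)
  # nothing significant: empty result
  expect_equal(nrow(call_regions(rec, threshold = 1e-20)), 0L)
})

test_that("pre-selection never touches validation phenotypes", {
  sim <- tiny_sim(seed = 63)
  dat <- prepare_pipeline_data(sim, r2_prune = NA)
  ids <- names(dat$yc)
  ref <- ids[1:90]
  sel <- suppressWarnings(preselect_snps(ref, dat$yc, dat$dense))
  yc2 <- dat$yc
  yc2[setdiff(ids, ref)] <- rnorm(length(ids) - 90) * 100
  sel2 <- suppressWarnings(preselect_snps(ref, yc2, dat$dense))
  expect_identical(sel$snp_ids, sel2$snp_ids)
  expect_identical(sel$threshold_used, sel2$threshold_used)
  expect_error(preselect_snps(c(ref, "nobody"), dat$yc, dat$dense), "missing")
})

test_that("a null trait selects about N * threshold SNPs", {
  sim <- simulate_population(sim_config(
    n_animals = 200, n_sires = 30, n_dams = 80, n_chrom = 3,
    dense_snps_per_chrom = 100, chip_fraction = 1, n_qtl = 0,
    qtl_pve = numeric(0), h2 = 0, seed = 64))
  set.seed(2)
  sizes <- vapply(1:8, function(r) {
    yc <- setNames(rnorm(200), sim$pheno$animal_id)
    sel <- suppressWarnings(preselect_snps(sim$pheno$animal_id, yc, sim$dense))
    length(sel$snp_ids)
  }, 1L)
  # expected count is ~1 per scan (threshold 1/N over N tests)
  expect_lte(mean(sizes), 6)
})

test_that("a planted QTL is recovered near the top of the selection", {
  hits <- vapply(1:5, function(r) {
    sim <- simulate_population(sim_config(
      n_animals = 300, n_sires = 50, n_dams = 120, n_chrom = 3,
      dense_snps_per_chrom = 120, chip_fraction = 0.4, n_qtl = 1,
      qtl_pve = 0.08, h2 = 0.3, seed = 640 + r))
    dat <- prepare_pipeline_data(sim, r2_prune = NA)
    sel <- suppressWarnings(
      preselect_snps(names(dat$yc), dat$yc, dat$dense))
    if (!length(sel$snp_ids)) return(FALSE)
    top <- sel$records$id[which.min(sel$records$p)]
    qtl_pos <- dat$dense$map$pos[dat$dense$map$id == sim$truth$qtl_ids]
    qtl_chr <- dat$dense$map$chrom[dat$dense$map$id == sim$truth$qtl_ids]
    near <- abs(dat$dense$map$pos[dat$dense$map$id == top] - qtl_pos) <= 2e5 &
      dat$dense$map$chrom[dat$dense$map$id == top] == qtl_chr
    isTRUE(near)
  }, TRUE)
  expect_gte(mean(hits), 0.8)
})
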