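test_that("REML shrinks the genetic variance to the floor under a null trait", {
  sim <- tiny_sim(seed = 31, h2 = 0, n_qtl = 0, qtl_pve = numeric(0))
  spec <- model_spec(list(g = compute_grm(sim$chip)))
  vc <- reml_fit(sim$pheno, spec)
  expect_lt(heritability(vc), 0.1)
  vc_ai <- reml_fit(sim$pheno, spec, method = "ai")
  expect_lt(heritability(vc_ai), 0.1)
})

test_that("REML optimum matches an independent restricted-likelihood surface", {
  sim <- simulate_population(sim_config(
    n_animals = 12, n_sires = 4, n_dams = 6, n_chrom = 2,
    dense_snps_per_chrom = 30, chip_fraction = 1, n_qtl = 0,
    qtl_pve = numeric(0), h2 = 0.3, seed = 9))
  spec <- model_spec(list(g = compute_grm(sim$chip)),
                     class_effects = "sex", covariates = character(0))
  vc <- reml_fit(sim$pheno, spec)
  K <- subset_kinship(compute_grm(sim$chip),
                      as.character(sim$pheno$animal_id))$values
  y <- sim$pheno$trait
  X <- gpsel:::build_design(sim$pheno, spec)
  # the package's optimum evaluated with the independent formula
  expect_equal(restricted_ll(y, X, K, vc$sigma_g, vc$sigma_e), vc$loglik,
               tolerance = 1e-6)
  # a fine local grid around the optimum never improves on it materially
  grid <- expand.grid(fg = seq(0.7, 1.3, length.out = 41),
                      fe <- seq(0.7, 1.3, length.out = 41))
  lls <- mapply(function(fg, fe)
    restricted_ll(y, X, K, vc$sigma_g * fg, vc$sigma_e * fe),
    grid[[1]], grid[[2]])
  expect_lte(max(lls), vc$loglik + 1e-8)
})

test_that("one-component GBLUP equals ridge SNP-BLUP", {
  sim <- simulate_population(sim_config(
    n_animals = 150, n_sires = 25, n_dams = 60, n_chrom = 3,
    dense_snps_per_chrom = 100, chip_fraction = 1, seed = 5))
  G <- sim$chip
  spec <- model_spec(list(g = compute_grm(G)))
  vc <- reml_fit(sim$pheno, spec)
  bl <- blup_solve(sim$pheno, spec, vc)
  Z <- center_dosages(G)
  p <- attr(Z, "centers") / 2
  cc <- 2 * sum(p * (1 - p))
  X <- gpsel:::build_design(sim$pheno, spec)
  y <- sim$pheno$trait
  V <- vc$sigma_g * tcrossprod(Z) / cc + diag(vc$sigma_e, nrow(Z))
  b <- solve(crossprod(X, solve(V, X)), crossprod(X, solve(V, y)))
  r <- drop(y - X %*% b)
  lambda <- vc$sigma_e / (vc$sigma_g / cc)
  a <- solve(crossprod(Z) + diag(lambda, ncol(Z)), crossprod(Z, r))
  expect_gte(stats::cor(bl$gebv$total, drop(Z %*% a)), 0.999999)
})

test_that("two identical components at (v, v) collapse to one at 2v", {
  sim <- tiny_sim(seed = 12)
  K <- compute_grm(sim$chip)
  v <- 0.1
  b2 <- blup_solve(sim$pheno, model_spec(list(a = K, b = K)),
                   list(sigma_g = c(v, v), sigma_e = 0.2))
  b1 <- blup_solve(sim$pheno, model_spec(list(a = K)),
                   list(sigma_g = 2 * v, sigma_e = 0.2))
  expect_equal(b2$gebv$total, b1$gebv$total, tolerance = 1e-8)
})

test_that("GEBVs vanish in the zero-variance shrinkage limit", {
  sim <- tiny_sim(seed = 13)
  spec <- model_spec(list(g = compute_grm(sim$chip)))
  bl <- blup_solve(sim$pheno, spec, list(sigma_g = 1e-12, sigma_e = 0.3))
  expect_lt(max(abs(bl$gebv$total)), 1e-8)
})

test_that("heritability is the genetic fraction of total variance", {
  expect_equal(heritability(list(sigma_g = 0.07, sigma_e = 0.21)), 0.25)
  expect_equal(heritability(list(sigma_g = 0, sigma_e = 0.2)), 0)
  expect_equal(heritability(list(sigma_g = c(0.1, 0.1), sigma_e = 0)), 1)
  expect_error(heritability(list(sigma_g = 0, sigma_e = 0)), "zero")
})

test_that("corrected phenotypes satisfy the MME identities", {
  sim <- tiny_sim(seed = 14)
  spec <- model_spec(list(g = compute_grm(sim$chip)))
  vc <- reml_fit(sim$pheno, spec)
  bl <- blup_solve(sim$pheno, spec, vc)
  yc <- corrected_phenotypes(bl)
  # yc = y - X bhat equals ghat + ehat
  ghat <- bl$gebv$total[match(bl$train_ids, bl$gebv$animal_id)]
  expect_equal(unname(yc), unname(ghat + bl$residuals), tolerance = 1e-10)
  # y = X bhat + ghat + ehat exactly
  expect_equal(unname(bl$y),
               unname(drop(bl$X %*% bl$fixed_effects) + ghat + bl$residuals),
               tolerance = 1e-10)
  # masked animals are excluded from the output
  ph <- sim$pheno
  ph$trait[1:10] <- NA
  bl2 <- blup_solve(ph, spec, vc)
  yc2 <- corrected_phenotypes(bl2)
  expect_false(any(ph$animal_id[1:10] %in% names(yc2)))
  expect_length(yc2, nrow(ph) - 10)
})

test_that("estimates are invariant to animal order and covariate rescaling", {
  sim <- tiny_sim(seed = 15)
  spec <- model_spec(list(g = compute_grm(sim$chip)))
  vc <- reml_fit(sim$pheno, spec)
  perm <- sample(nrow(sim$pheno))
  vc_perm <- reml_fit(sim$pheno[perm, ], spec)
  expect_equal(vc_perm$sigma_g, vc$sigma_g, tolerance = 1e-6)
  expect_equal(vc_perm$sigma_e, vc$sigma_e, tolerance = 1e-6)
  ph <- sim$pheno
  ph$age <- ph$age * 100 + 7
  ph$carcass_weight <- ph$carcass_weight / 50 - 2
  expect_equal(heritability(reml_fit(ph, spec)), heritability(vc),
               tolerance = 1e-6)
})
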