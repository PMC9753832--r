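#' Settings for the four-distribution mixture SNP-effect model
#'
#' SNP effects within each genetic component follow a mixture of four normal
#' distributions whose variances stand in the fixed ratio
#' `1000 s1 = 100 s2 = 10 s3 = s4`, so only the largest-class variance is
#' estimated per component. Mixing proportions are sampled from
#' `Dirichlet(125, 25, 5, 1)` given the class counts; the chain starts from
#' `pi = (0.889, 0.1, 0.01, 0.001)` (the Dirichlet parameters drive the
#' sampling, the starting vector is only an initial value). The default chain
#' runs 50,000 samples with the first 10,000 discarded as burn-in; analyses
#' in a hurry scale both down.
#'
#' @param dirichlet_alpha Dirichlet concentration (default `c(125,25,5,1)`).
#' @param pi_init Starting mixing proportions (default
#'   `c(0.889, 0.1, 0.01, 0.001)`).
#' @param variance_ratios Class-variance ratios relative to the largest class
#'   (default `c(1/1000, 1/100, 1/10, 1)`, strictly increasing).
#' @param chain_length,burn_in,thin Gibbs chain controls (defaults 50,000 /
#'   10,000 / 10).
#' @param inv_chi2_df Prior degrees of freedom for each component's
#'   largest-class variance (default 4.2); the prior scale is set so the
#'   prior-mean total genetic variance equals half the phenotypic variance,
#'   split across components and classes by `pi_init`.
#' @param resid_df Prior degrees of freedom for the residual variance
#'   (default 2, weakly informative; prior scale `var(y)/2`).
#' @param update_pi,update_sigma4,update_sigma_e Set to `FALSE` to hold the
#'   corresponding parameter fixed at its starting value (used e.g. for the
#'   ridge-regression limit with `pi_init = c(0,0,0,1)`).
#' @return A `mixture_spec` list.
#' @export
mixture_spec <- function(dirichlet_alpha = c(125, 25, 5, 1),
                         pi_init = c(0.889, 0.1, 0.01, 0.001),
                         variance_ratios = c(1 / 1000, 1 / 100, 1 / 10, 1),
                         chain_length = 50000, burn_in = 10000, thin = 10,
                         inv_chi2_df = 4.2, resid_df = 2,
                         update_pi = TRUE, update_sigma4 = TRUE,
                         update_sigma_e = TRUE) {
  if (abs(sum(pi_init) - 1) > 1e-8) stop("pi_init must sum to 1")
  if (any(diff(variance_ratios) <= 0)) {
    stop("variance_ratios must be strictly increasing")
  }
  if (burn_in >= chain_length) stop("burn_in must be < chain_length")
  structure(as.list(environment()), class = "mixture_spec")
}

# center a component panel; geno_matrix objects are centered here, plain
# matrices must already be centered (and carry their centers if prediction
# with new animals is intended).
center_component <- function(panel) {
  if (inherits(panel, "geno_matrix")) {
    Z <- center_dosages(panel)
    list(Z = Z, ids = panel$map$id, centers = attr(Z, "centers"),
         samples = panel$samples)
  } else {
    Z <- as.matrix(panel)
    if (max(abs(colMeans(Z))) > 1e-6) {
      stop("component panel matrix is not column-centered")
    }
    list(Z = Z, ids = colnames(Z),
         centers = attr(Z, "centers") %||% rep(0, ncol(Z)),
         samples = rownames(Z))
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit the Bayesian mixture SNP-effect model by Gibbs sampling
#'
#' Fits `y = 1 mu + X b + Z_s a + e` (one component) or
#' `y = 1 mu + X b + Z_s1 a1 + Z_s2 a2 + e` (two components), where each
#' effect vector follows the four-distribution normal mixture of
#' [mixture_spec()]. A single-site Gibbs sampler cycles over fixed effects
#' (flat-prior normal conditionals), per-SNP class indicators and effects,
#' per-component mixing proportions (Dirichlet), per-component largest-class
#' variance and the residual variance (scaled inverse-chi-squared
#' conditionals). Posterior summaries are averages over post-burn-in samples.
#'
#' @param pheno Phenotype table; rows with `NA` response are excluded (masked
#'   validation animals never influence the fit).
#' @param component_panels One [geno_matrix()] or a list of one/two (dosage
#'   columns are centered internally; already-centered plain matrices are also
#'   accepted).
#' @param spec A [mixture_spec()].
#' @param response,class_effects,covariates Fixed-part columns, as in
#'   [model_spec()].
#' @param seed Optional integer; when given, `set.seed(seed)` is called so
#'   the chain is bit-reproducible.
#' @return A `mixture_posterior`: per-SNP posterior mean effects and class
#'   probabilities, mixing-proportion / variance posterior means, fixed
#'   effects, training GEBVs (`gebv = Z_s %*% effect_mean` summed over
#'   components) and thinned variance traces.
#' @export
gibbs_fit <- function(pheno, component_panels, spec = mixture_spec(),
                      response = "trait", class_effects = c("sex", "batch"),
                      covariates = c("age", "carcass_weight"), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (!is.list(component_panels) || inherits(component_panels, "geno_matrix")) {
    component_panels <- list(component_panels)
  }
  if (length(component_panels) < 1L || length(component_panels) > 2L) {
    stop("1 or 2 component panels are supported")
  }
  use <- !is.na(pheno[[response]])
  ph <- pheno[use, , drop = FALSE]
  ids <- as.character(ph$animal_id)
  y <- ph[[response]]
  fixed_spec <- list(response = response, class_effects = class_effects,
                     covariates = covariates)
  X <- build_design(ph, fixed_spec)
  comps <- lapply(component_panels, function(p) {
    if (inherits(p, "geno_matrix")) p <- subset_geno(p, samples = ids)
    center_component(p)
  })
  Z <- do.call(cbind, lapply(comps, `[[`, "Z"))
  comp_index <- rep(seq_along(comps) - 1L,
                    vapply(comps, function(c) ncol(c$Z), 1L))
  ncomp <- length(comps)
  vy <- stats::var(y)
  mean_zz <- vapply(comps, function(c) mean(colSums(c$Z^2)) / length(y), 1)
  exp_a2 <- sum(spec$pi_init * spec$variance_ratios)
  target <- (vy / 2) / ncomp
  df4 <- spec$inv_chi2_df
  s4_scale <- target * (df4 - 2) / df4 /
    (pmax(mean_zz, 1e-12) * vapply(comps, function(c) ncol(c$Z), 1) * exp_a2)
  s4_init <- s4_scale * df4 / (df4 - 2)
  pi_mat <- matrix(rep(spec$pi_init, each = ncomp), nrow = ncomp)
  fit <- .gibbs_mix_cpp(
    y = y, X = X, Z = Z, comp = comp_index,
    ratios = spec$variance_ratios, alpha = spec$dirichlet_alpha,
    pi_init = pi_mat, s4_init = s4_init, sigma_e_init = vy / 2,
    s4_prior_scale = s4_scale, s4_prior_df = df4,
    se_prior_scale = vy / 2, se_prior_df = spec$resid_df,
    chain_length = as.integer(spec$chain_length),
    burn_in = as.integer(spec$burn_in), thin = as.integer(spec$thin),
    update_pi = spec$update_pi, update_sigma4 = spec$update_sigma4,
    update_sigma_e = spec$update_sigma_e)
  m_per <- vapply(comps, function(c) ncol(c$Z), 1L)
  split_idx <- split(seq_along(comp_index), comp_index)
  effects <- lapply(split_idx, function(ix) {
    stats::setNames(fit$effect_mean[ix], unlist(lapply(comps, `[[`, "ids"))[ix])
  })
  gebv <- drop(Z %*% fit$effect_mean)
  structure(list(
    effect_mean = effects,
    snp_ids = lapply(comps, `[[`, "ids"),
    centers = lapply(comps, `[[`, "centers"),
    pi_mean = fit$pi_mean, sigma4_mean = drop(fit$sigma4_mean),
    sigma_e_mean = fit$sigma_e_mean,
    class_prob = fit$class_prob,
    fixed_effects = stats::setNames(drop(fit$fixed_mean), colnames(X)),
    gebv = stats::setNames(gebv, ids),
    trace = fit$trace, spec = spec, train_ids = ids),
    class = "mixture_posterior")
}

#' Predict GEBVs from a fitted mixture posterior
#'
#' Applies the posterior-mean SNP effects to (possibly new) animals:
#' dosages are centered with the training centers and multiplied by the
#' effect means, summed over genetic components.
#'
#' @param posterior A `mixture_posterior` from [gibbs_fit()].
#' @param panels One [geno_matrix()] or list matching the fitted components;
#'   each must contain every fitted SNP.
#' @param target_ids Animal ids to predict (default: all panel samples).
#' @return Named numeric vector of GEBVs.
#' @export
predict_gebv <- function(posterior, panels, target_ids = NULL) {
  if (!is.list(panels) || inherits(panels, "geno_matrix")) {
    panels <- list(panels)
  }
  if (length(panels) != length(posterior$snp_ids)) {
    stop("number of panels does not match fitted components")
  }
  if (is.null(target_ids)) target_ids <- panels[[1]]$samples
  total <- stats::setNames(numeric(length(target_ids)), target_ids)
  for (c in seq_along(panels)) {
    G <- subset_geno(panels[[c]], samples = target_ids)
    miss <- setdiff(posterior$snp_ids[[c]], G$map$id)
    if (length(miss)) {
      stop("panel for component ", c, " is missing fitted SNPs: ",
           paste(utils::head(miss, 5), collapse = ", "),
           if (length(miss) > 5) sprintf(" (and %d more)", length(miss) - 5))
    }
    G <- subset_geno(G, snps = posterior$snp_ids[[c]])
    ord <- match(posterior$snp_ids[[c]], G$map$id)
    Zc <- center_dosages(G)
    imputed <- sweep(Zc, 2, attr(Zc, "centers"), "+")[, ord, drop = FALSE]
    Z <- sweep(imputed, 2, posterior$centers[[c]], "-")
    total <- total + drop(Z %*% posterior$effect_mean[[c]])
  }
  total
}
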