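#' Specify a mixed model for variance-component estimation and BLUP
#'
#' @param components Named list of one or two [compute_grm()] /
#'   [compute_a_matrix()] kinship objects, one per random genetic component.
#' @param response Phenotype column name (default `"trait"`).
#' @param class_effects Character vector of factor-coded fixed effects.
#' @param covariates Character vector of regression covariates (centered
#'   internally).
#' @return A `model_spec` list.
#' @export
model_spec <- function(components, response = "trait",
                       class_effects = c("sex", "batch"),
                       covariates = c("age", "carcass_weight")) {
  if (!is.list(components)) components <- list(components)
  if (length(components) < 1L || length(components) > 2L) {
    stop("between 1 and 2 genetic components are supported")
  }
  stopifnot(all(vapply(components, inherits, TRUE, what = "kinship")))
  structure(list(response = response, class_effects = class_effects,
                 covariates = covariates, components = components),
            class = "model_spec")
}

# Fixed-effect design matrix: intercept, reference-coded class effects,
# centered covariates. Drops aliased columns and factors with one level.
build_design <- function(pheno, spec) {
  n <- nrow(pheno)
  X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  for (ce in spec$class_effects) {
    if (!ce %in% names(pheno)) next
    f <- factor(pheno[[ce]])
    if (nlevels(f) < 2L) next
    D <- stats::model.matrix(~f)[, -1, drop = FALSE]
    colnames(D) <- paste0(ce, levels(f)[-1])
    X <- cbind(X, D)
  }
  for (cv in spec$covariates) {
    if (!cv %in% names(pheno)) next
    v <- pheno[[cv]]
    X <- cbind(X, matrix(v - mean(v), ncol = 1, dimnames = list(NULL, cv)))
  }
  q <- qr(X)
  if (q$rank < ncol(X)) X <- X[, q$pivot[seq_len(q$rank)], drop = FALSE]
  X
}

# restricted log-likelihood (constant terms dropped) for V = sum th_i K_i + th_e I
reml_loglik <- function(y, X, Ks, theta) {
  n <- length(y)
  V <- diag(theta[length(theta)], n)
  for (i in seq_along(Ks)) V <- V + theta[i] * Ks[[i]]
  cV <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(cV)) return(list(ll = -Inf))
  Vinv <- chol2inv(cV)
  XtVX <- crossprod(X, Vinv %*% X)
  cX <- tryCatch(chol(XtVX), error = function(e) NULL)
  if (is.null(cX)) return(list(ll = -Inf))
  P <- Vinv - Vinv %*% X %*% chol2inv(cX) %*% crossprod(X, Vinv)
  Py <- P %*% y
  ll <- -0.5 * (2 * sum(log(diag(cV))) + 2 * sum(log(diag(cX))) +
                drop(crossprod(y, Py)))
  list(ll = ll, P = P, Py = Py)
}

#' REML variance-component estimation
#'
#' Average-information REML with an expectation-maximization fallback: when
#' the AI step would leave the parameter space or reduce the restricted
#' likelihood, an EM step (which cannot decrease it) is taken instead.
#' Convergence requires both `|delta loglik| < 1e-8` and a relative parameter
#' change below `1e-6`; variances are floored at `1e-8 * var(y)`.
#'
#' @param pheno Phenotype data frame (one row per animal; column `animal_id`
#'   plus the response and fixed-effect columns). Rows with `NA` response are
#'   excluded from fitting.
#' @param spec A [model_spec()]; every phenotyped animal must be present in
#'   all component kinship matrices.
#' @param max_iter Iteration cap (default 200); hitting it returns the partial
#'   fit flagged `converged = FALSE`.
#' @param method `"auto"` (default) solves single-component models exactly by
#'   profiling the restricted likelihood over the variance ratio in the
#'   eigenbasis of the kinship matrix, and uses iterative AI-REML otherwise;
#'   `"ai"` forces the iterative algorithm.
#' @return A `varcomp` list: `sigma_g` (one variance per genetic component),
#'   `sigma_e`, `loglik`, `converged`, `n_iter`.
#' @export
reml_fit <- function(pheno, spec, max_iter = 200,
                     method = c("auto", "ai")) {
  method <- match.arg(method)
  use <- !is.na(pheno[[spec$response]])
  ph <- pheno[use, , drop = FALSE]
  y <- ph[[spec$response]]
  X <- build_design(ph, spec)
  ids <- as.character(ph$animal_id)
  Ks <- lapply(spec$components, function(K) subset_kinship(K, ids)$values)
  n <- length(y)
  k <- length(Ks)
  if (method == "auto" && k == 1L) {
    eig <- eigen(Ks[[1]], symmetric = TRUE)
    fit <- reml_eigen(y, X, eig)
    floor_v <- 1e-8 * stats::var(y)
    return(structure(list(sigma_g = max(fit$sigma_g, floor_v),
                          sigma_e = max(fit$sigma_e, floor_v),
                          loglik = fit$loglik, converged = TRUE, n_iter = 1L),
                     class = "varcomp"))
  }
  vy <- stats::var(y)
  floor_v <- 1e-8 * vy
  theta <- c(rep(vy / (2 * k), k), vy / 2)
  st <- reml_loglik(y, X, Ks, theta)
  ll <- st$ll
  converged <- FALSE
  iter <- 0
  for (iter in seq_len(max_iter)) {
    P <- st$P; Py <- st$Py
    KPy <- lapply(Ks, function(K) K %*% Py)
    KPy[[k + 1]] <- Py
    grad <- numeric(k + 1)
    for (i in seq_len(k + 1)) {
      trPK <- if (i <= k) sum(P * Ks[[i]]) else sum(diag(P))
      grad[i] <- -0.5 * (trPK - drop(crossprod(Py, KPy[[i]])))
    }
    AI <- matrix(0, k + 1, k + 1)
    PKPy <- lapply(KPy, function(v) P %*% v)
    for (i in seq_len(k + 1)) {
      for (j in i:(k + 1)) {
        AI[i, j] <- AI[j, i] <- 0.5 * drop(crossprod(KPy[[i]], PKPy[[j]]))
      }
    }
    step <- tryCatch(solve(AI, grad), error = function(e) NULL)
    cand <- if (is.null(step)) NULL else theta + step
    st_new <- NULL
    if (!is.null(cand) && all(cand > 0)) {
      st_try <- reml_loglik(y, X, Ks, cand)
      if (is.finite(st_try$ll) && st_try$ll >= ll - 1e-10) st_new <- st_try
    }
    if (is.null(st_new)) {
      # EM step: monotone in the restricted likelihood
      cand <- theta
      for (i in seq_len(k + 1)) {
        trPK <- if (i <= k) sum(P * Ks[[i]]) else sum(diag(P))
        cand[i] <- theta[i] +
          theta[i]^2 * (drop(crossprod(Py, KPy[[i]])) - trPK) / n
      }
      cand <- pmax(cand, floor_v)
      st_new <- reml_loglik(y, X, Ks, cand)
    }
    rel <- max(abs(cand - theta) / pmax(abs(theta), 1e-12))
    dll <- st_new$ll - ll
    theta <- pmax(cand, floor_v)
    ll <- st_new$ll
    st <- st_new
    if (abs(dll) < 1e-8 && rel < 1e-6) {
      converged <- TRUE
      break
    }
  }
  structure(list(sigma_g = theta[seq_len(k)], sigma_e = theta[k + 1],
                 loglik = ll, converged = converged, n_iter = iter),
            class = "varcomp")
}

#' Narrow-sense heritability from variance components
#'
#' Ratio of total additive genetic variance to total phenotypic variance,
#' `h2 = sum(sigma_g) / (sum(sigma_g) + sigma_e)`.
#'
#' @param varcomp A `varcomp` from [reml_fit()], or a list with `sigma_g`
#'   and `sigma_e`.
#' @return A fraction in `[0, 1]`.
#' @export
heritability <- function(varcomp) {
  sg <- sum(varcomp$sigma_g)
  se <- varcomp$sigma_e
  if (any(c(varcomp$sigma_g, se) < 0)) stop("variances must be non-negative")
  if (sg + se == 0) stop("all variance components are zero")
  sg / (sg + se)
}

#' Solve the mixed-model equations at given variance components
#'
#' Computes GLS fixed-effect estimates and BLUPs of each genetic component at
#' the variances supplied. Animals present in the kinship matrices but with a
#' missing (masked) phenotype receive predictions through their kinship rows
#' with the training animals.
#'
#' @param pheno Phenotype data frame; rows with `NA` response are treated as
#'   prediction-only animals.
#' @param spec A [model_spec()].
#' @param varcomp A `varcomp` (typically from [reml_fit()]).
#' @return A `blup_solution` list: `fixed_effects`, `gebv` (data frame with
#'   one column per component and a `total`), `residuals` (training animals),
#'   `train_ids`, `yc` inputs (`y`, `X` on the training set).
#' @export
blup_solve <- function(pheno, spec, varcomp) {
  use <- !is.na(pheno[[spec$response]])
  ph <- pheno[use, , drop = FALSE]
  y <- ph[[spec$response]]
  X <- build_design(ph, spec)
  train_ids <- as.character(ph$animal_id)
  all_ids <- as.character(pheno$animal_id)
  k <- length(spec$components)
  th <- c(varcomp$sigma_g, varcomp$sigma_e)
  if (any(th < 0)) stop("invalid variance components")
  n <- length(y)
  Ks_tt <- lapply(spec$components, function(K) subset_kinship(K, train_ids)$values)
  V <- diag(th[k + 1], n)
  for (i in seq_len(k)) V <- V + th[i] * Ks_tt[[i]]
  ev_min <- min(eigen(V, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min < 1e-8) V <- V + diag(1e-6, n)
  cV <- tryCatch(chol(V), error = function(e)
    stop("singular covariance matrix in the mixed-model equations"))
  Vinv <- chol2inv(cV)
  XtVX <- crossprod(X, Vinv %*% X)
  bhat <- solve(XtVX, crossprod(X, Vinv %*% y))
  r <- drop(y - X %*% bhat)
  Vr <- Vinv %*% r
  gebv <- matrix(0, length(all_ids), k,
                 dimnames = list(all_ids, names(spec$components)))
  for (i in seq_len(k)) {
    K_at <- subset_kinship(spec$components[[i]], all_ids)$values[
      , match(train_ids, all_ids), drop = FALSE]
    gebv[, i] <- th[i] * (K_at %*% Vr)
  }
  total <- rowSums(gebv)
  ghat_train <- total[match(train_ids, all_ids)]
  ehat <- r - ghat_train
  structure(list(
    fixed_effects = stats::setNames(drop(bhat), colnames(X)),
    gebv = data.frame(animal_id = all_ids, gebv,
                      total = total, row.names = NULL,
                      check.names = FALSE),
    residuals = stats::setNames(ehat, train_ids),
    train_ids = train_ids,
    y = stats::setNames(y, train_ids),
    X = X), class = "blup_solution")
}

#' Corrected phenotypes from a full-data BLUP fit
#'
#' The phenotype adjusted for estimated fixed effects,
#' `yc = y - X b-hat`, identical at the mixed-model-equation solution to
#' GEBV + estimated residual. Only phenotyped (training) animals appear in the
#' output.
#'
#' @param blup A `blup_solution` from [blup_solve()].
#' @return Named numeric vector of corrected phenotypes.
#' @export
corrected_phenotypes <- function(blup) {
  if (is.null(blup$residuals)) stop("BLUP solution lacks residuals")
  yc <- blup$y - drop(blup$X %*% blup$fixed_effects)
  stats::setNames(yc, blup$train_ids)
}
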