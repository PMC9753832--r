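#' Random k-fold partition of animals
#'
#' @param animal_ids Character vector of ids.
#' @param k Number of folds (default 5).
#' @param seed Integer seed making the plan deterministic.
#' @return A `fold_plan`: list with `k`, `seed` and `assignments` (named
#'   integer vector mapping animal to fold). Fold sizes differ by at most 1.
#' @export
make_folds <- function(animal_ids, k = 5, seed = 1L) {
  n <- length(animal_ids)
  if (n < k) stop("need at least k animals to form k folds")
  set.seed(seed)
  perm <- sample(animal_ids)
  sizes <- rep(n %/% k, k)
  if (n %% k) sizes[seq_len(n %% k)] <- sizes[seq_len(n %% k)] + 1L
  fold <- rep(seq_len(k), times = sizes)
  structure(list(k = k, seed = seed,
                 assignments = stats::setNames(fold, perm)[animal_ids]),
            class = "fold_plan")
}

#' Remove pre-selected loci from the chip panel
#'
#' When pre-selected sequence SNPs enter a model alongside the chip panel,
#' loci present in both (matched by chromosome and position) are deleted from
#' the chip side so no SNP enters twice; the pre-selected panel is returned
#' unchanged.
#'
#' @param chip,preselected Two [geno_matrix()] objects.
#' @return List with elements `chip` (deduplicated, possibly with zero SNPs)
#'   and `preselected`.
#' @export
dedup_panels <- function(chip, preselected) {
  kc <- paste(chip$map$chrom, chip$map$pos, sep = ":")
  kp <- paste(preselected$map$chrom, preselected$map$pos, sep = ":")
  keep <- !(kc %in% kp)
  if (!any(keep)) {
    warning("all chip SNPs duplicate pre-selected loci; chip panel is empty")
    chip$dosages <- chip$dosages[, 0, drop = FALSE]
    chip$map <- chip$map[0, , drop = FALSE]
    return(list(chip = chip, preselected = preselected))
  }
  list(chip = subset_geno(chip, snps = keep), preselected = preselected)
}

#' Cross-validated prediction reliability
#'
#' Squared correlation between predicted breeding values and corrected
#' phenotypes in the validation group, divided by the trait heritability.
#'
#' @param gebv Predicted breeding values of the validation animals.
#' @param yc Their corrected phenotypes.
#' @param h2 Heritability used as denominator (> 0).
#' @return A non-negative reliability.
#' @export
reliability <- function(gebv, yc, h2) {
  if (length(gebv) != length(yc)) stop("gebv and yc differ in length")
  if (length(gebv) < 3) stop("need at least 3 validation animals")
  if (h2 <= 0) stop("h2 must be positive")
  if (stats::var(gebv) == 0) {
    warning("zero-variance GEBV vector; reliability set to 0")
    return(0)
  }
  stats::cor(gebv, yc)^2 / h2
}

.APPROACHES <- c("PBLUP", "GBLUP-80K", "GBLUP-iWGS",
                 "GBLUP-80K-GWASiWGS-one", "GBLUP-80K-GWASiWGS-two",
                 "Bayes-80K", "Bayes-iWGS",
                 "Bayes-80K-GWASiWGS-one", "Bayes-80K-GWASiWGS-two")

#' The nine prediction approaches
#' @return Character vector of approach names accepted by [run_cv()].
#' @export
approach_names <- function() .APPROACHES

needs_preselect <- function(approach) grepl("GWASiWGS", approach)

#' Run one prediction approach under k-fold cross-validation
#'
#' For every fold the validation phenotypes are masked; if the approach uses
#' pre-selection, the association scan runs on the reference animals only;
#' the approach's model is fitted (variance components re-estimated per fold
#' for BLUP models), validation breeding values are predicted, and the
#' reliability against corrected phenotypes is computed. The heritability
#' denominator comes from the full-data chip GBLUP fit supplied in `data`.
#'
#' @param data List as produced by [prepare_pipeline_data()]: elements
#'   `pheno`, `pedigree`, `chip`, `dense`, `iwgs` (the pruned merged panel),
#'   `yc` (named corrected phenotypes), `h2`.
#' @param approach One of [approach_names()].
#' @param fold_plan A [make_folds()] plan.
#' @param bayes_spec [mixture_spec()] used by the Bayesian approaches.
#' @param preselect_cache Optional environment; fold-wise pre-selections are
#'   memoised there so several approaches can share one scan per fold.
#' @param strict_correction If `TRUE`, corrected phenotypes used for
#'   pre-selection are recomputed per fold from the reference animals only
#'   instead of reusing the full-data correction.
#' @param verbose Log one line per fold.
#' @return An `approach_result`: `approach`, `per_fold` reliabilities,
#'   `mean`, `se` (sd of the fold reliabilities over `sqrt(k)`), and the
#'   per-fold number of pre-selected SNPs where applicable.
#' @export
run_cv <- function(data, approach, fold_plan, bayes_spec = mixture_spec(),
                   preselect_cache = NULL, strict_correction = FALSE,
                   verbose = FALSE) {
  approach <- match.arg(approach, .APPROACHES)
  if (approach == "GBLUP-iWGS" || approach == "Bayes-iWGS") {
    if (is.null(data$iwgs)) stop(approach, " requires the pruned merged panel in data$iwgs")
  }
  if (approach == "PBLUP" && is.null(data$pedigree)) {
    stop("PBLUP requires data$pedigree")
  }
  ids <- as.character(data$pheno$animal_id)
  k <- fold_plan$k
  rel <- numeric(k)
  n_sel <- rep(NA_integer_, k)
  A_full <- if (approach == "PBLUP") compute_a_matrix(data$pedigree) else NULL
  for (f in seq_len(k)) {
    val_ids <- ids[fold_plan$assignments[ids] == f]
    ref_ids <- setdiff(ids, val_ids)
    ph <- data$pheno
    ph$trait[ph$animal_id %in% val_ids] <- NA
    sel <- NULL
    if (needs_preselect(approach)) {
      key <- sprintf("fold%d_%s", f, if (strict_correction) "strict" else "full")
      if (!is.null(preselect_cache) && !is.null(preselect_cache[[key]])) {
        sel <- preselect_cache[[key]]
      } else {
        yc_sel <- if (strict_correction) {
          spec_ref <- model_spec(list(chip = compute_grm(
            subset_geno(data$chip, samples = ref_ids))))
          ph_ref <- ph[ph$animal_id %in% ref_ids, , drop = FALSE]
          vc_ref <- reml_fit(ph_ref, spec_ref)
          corrected_phenotypes(blup_solve(ph_ref, spec_ref, vc_ref))
        } else {
          data$yc
        }
        sel <- suppressWarnings(
          preselect_snps(ref_ids, yc_sel, data$dense, fold_id = f))
        if (!is.null(preselect_cache)) preselect_cache[[key]] <- sel
      }
      n_sel[f] <- length(sel$snp_ids)
    }
    pred <- fit_and_predict(approach, ph, data, sel, val_ids, A_full,
                            bayes_spec)
    rel[f] <- reliability(pred[val_ids], data$yc[val_ids], data$h2)
    if (verbose) {
      message(sprintf("%s fold %d: reliability %.3f%s", approach, f, rel[f],
                      if (!is.na(n_sel[f]))
                        sprintf(" (%d pre-selected SNPs)", n_sel[f]) else ""))
    }
  }
  structure(list(approach = approach, per_fold = rel, mean = mean(rel),
                 se = stats::sd(rel) / sqrt(k), n_preselected = n_sel,
                 seed = fold_plan$seed),
            class = "approach_result")
}

# dispatch one approach on one fold; returns named GEBV vector covering all
# animals (training fits, validation predictions).
fit_and_predict <- function(approach, ph, data, sel, val_ids, A_full,
                            bayes_spec) {
  presel_panel <- NULL
  chip_panel <- data$chip
  if (needs_preselect(approach)) {
    if (length(sel$snp_ids)) {
      presel_panel <- subset_geno(data$dense, snps = sel$snp_ids)
      dd <- dedup_panels(chip_panel, presel_panel)
      chip_panel <- dd$chip
      if (n_snps(chip_panel) == 0L) {
        warning("chip panel empty after deduplication; using pre-selected SNPs only")
      }
    } else {
      # empty selection: degrade to the one-component chip counterpart
      approach <- if (grepl("^GBLUP", approach)) "GBLUP-80K" else "Bayes-80K"
    }
  }
  if (grepl("^Bayes", approach)) {
    panels <- switch(approach,
      "Bayes-80K" = list(data$chip),
      "Bayes-iWGS" = list(data$iwgs),
      "Bayes-80K-GWASiWGS-one" = {
        if (n_snps(chip_panel)) list(merge_panels(chip_panel, presel_panel))
        else list(presel_panel)
      },
      "Bayes-80K-GWASiWGS-two" = {
        if (n_snps(chip_panel)) list(chip_panel, presel_panel)
        else list(presel_panel)
      })
    post <- gibbs_fit(ph, panels, bayes_spec)
    return(predict_gebv(post, panels, as.character(data$pheno$animal_id)))
  }
  components <- switch(approach,
    "PBLUP" = list(ped = A_full),
    "GBLUP-80K" = list(g = compute_grm(data$chip)),
    "GBLUP-iWGS" = list(g = compute_grm(data$iwgs)),
    "GBLUP-80K-GWASiWGS-one" = {
      panel <- if (n_snps(chip_panel)) merge_panels(chip_panel, presel_panel)
               else presel_panel
      list(g = compute_grm(panel))
    },
    "GBLUP-80K-GWASiWGS-two" = {
      if (n_snps(chip_panel)) {
        list(g1 = compute_grm(chip_panel), g2 = compute_grm(presel_panel))
      } else {
        list(g = compute_grm(presel_panel))
      }
    })
  spec <- model_spec(components)
  vc <- reml_fit(ph, spec)
  blup <- blup_solve(ph, spec, vc)
  stats::setNames(blup$gebv$total, blup$gebv$animal_id)
}

#' Prepare the shared inputs of the cross-validation study
#'
#' Applies quality control to both panels, integrates chip genotypes into the
#' dense panel, LD-prunes the merged panel, fits the full-data chip GBLUP to
#' obtain corrected phenotypes and the heritability used as reliability
#' denominator.
#'
#' @param sim A dataset from [simulate_population()] (or a list with the same
#'   elements read from disk).
#' @param r2_prune LD cutoff for the pruned sequence panel (default 0.55;
#'   `NA` skips pruning when no sequence-panel approach will be run).
#' @param verbose Log filter counts.
#' @return List consumed by [run_cv()]: `pheno`, `pedigree`, `chip`, `dense`
#'   (merged), `iwgs` (pruned merged), `yc`, `h2`, `varcomp`.
#' @export
prepare_pipeline_data <- function(sim, r2_prune = 0.55, verbose = FALSE) {
  chip <- qc_filter(sim$chip, verbose = verbose)
  dense <- qc_filter(sim$dense, verbose = verbose)
  merged <- merge_panels(chip, dense)
  iwgs <- if (is.na(r2_prune)) NULL else
    prune_ld(merged, r2_max = r2_prune, verbose = verbose)
  spec <- model_spec(list(chip = compute_grm(chip)))
  vc <- reml_fit(sim$pheno, spec)
  blup <- blup_solve(sim$pheno, spec, vc)
  list(pheno = sim$pheno, pedigree = sim$pedigree, chip = chip,
       dense = merged, iwgs = iwgs,
       yc = corrected_phenotypes(blup), h2 = heritability(vc),
       varcomp = vc)
}

#' Run the full study end-to-end
#'
#' simulate -> QC -> merge -> prune -> full-data GBLUP correction -> GWAS ->
#' fold-internal pre-selection -> cross-validated prediction with the
#' requested approaches, plus a JSON run manifest.
#'
#' @param config A [sim_config()].
#' @param approaches Character vector of [approach_names()], or `"all"`.
#' @param seed Seed for the fold plan (simulation uses `config$seed`).
#' @param bayes_spec [mixture_spec()] for the Bayesian approaches.
#' @param r2_prune LD cutoff for the pruned sequence panel (default 0.55).
#' @param out_dir Optional directory; when given, the reliability table
#'   (`cv_results.tsv`), GWAS table (`gwas_chip.tsv`) and `manifest.json`
#'   are written there.
#' @param verbose Progress logging.
#' @return List with `results` (one `approach_result` per approach),
#'   `summary` data frame, `gwas` (full-data chip scan), `regions`,
#'   `thresholds`, `data` (prepared inputs) and `manifest`.
#' @export
run_pipeline <- function(config = sim_config(), approaches = "all",
                         seed = 1L, bayes_spec = mixture_spec(),
                         r2_prune = 0.55, out_dir = NULL, verbose = FALSE) {
  if (identical(approaches, "all")) approaches <- .APPROACHES
  approaches <- vapply(approaches, match.arg, "", choices = .APPROACHES)
  t0 <- Sys.time()
  sim <- simulate_population(config)
  data <- prepare_pipeline_data(sim, r2_prune = r2_prune, verbose = verbose)
  scan <- mlm_scan(data$yc, data$chip, data$chip)
  thr <- bonferroni_thresholds(nrow(scan))
  regions <- call_regions(scan, thr$suggestive)
  folds <- make_folds(as.character(data$pheno$animal_id), k = 5, seed = seed)
  cache <- new.env(parent = emptyenv())
  results <- lapply(approaches, function(ap) {
    if (verbose) message("running ", ap)
    run_cv(data, ap, folds, bayes_spec = bayes_spec,
           preselect_cache = cache, verbose = verbose)
  })
  names(results) <- approaches
  summary <- do.call(rbind, lapply(results, function(r) {
    data.frame(approach = r$approach,
               t(stats::setNames(r$per_fold, paste0("fold", seq_along(r$per_fold)))),
               mean = r$mean, se = r$se, row.names = NULL)
  }))
  manifest <- list(
    created = format(t0, "%Y-%m-%d %H:%M:%S"),
    seed_folds = seed, seed_simulation = config$seed,
    config = unclass(config),
    panels = list(
      chip = list(n = n_individuals(data$chip), m = n_snps(data$chip),
                  checksum = sum(data$chip$dosages, na.rm = TRUE)),
      dense = list(n = n_individuals(data$dense), m = n_snps(data$dense),
                   checksum = sum(data$dense$dosages, na.rm = TRUE)),
      iwgs_pruned = list(m = n_snps(data$iwgs), r2_cutoff = r2_prune)),
    h2 = data$h2,
    thresholds = thr[c("genomewide", "suggestive")],
    approaches = unname(approaches),
    runtime_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(summary, file.path(out_dir, "cv_results.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(scan, file.path(out_dir, "gwas_chip.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(results = results, summary = summary, gwas = scan, regions = regions,
       thresholds = thr, folds = folds, data = data, manifest = manifest)
}

#' @export
print.approach_result <- function(x, ...) {
  cat(sprintf("%s: mean reliability %.3f +/- %.3f (folds: %s)\n",
              x$approach, x$mean, x$se,
              paste(sprintf("%.3f", x$per_fold), collapse = ", ")))
  invisible(x)
}
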