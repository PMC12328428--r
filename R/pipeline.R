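#' Pipeline configuration
#'
#' Validated configuration for [run_pipeline()]: stage toggles and all
#' stage parameters. Unknown keys are rejected.
#'
#' @param simulate,cluster,select,validate Stage toggles. The default runs
#'   the fast composition-level simulation; enabling `cluster` switches to
#'   cell-level simulation followed by SOM clustering.
#' @param cohort List of overrides for [cohort_config()].
#' @param som_grid,som_epochs,K,cofactor SOM / metaclustering parameters.
#' @param covariate_set Propensity covariates, see [propensity_covariates()].
#' @param gamma,nlambda,inner_folds Adaptive-LASSO parameters.
#' @param n_boot,n_perm,n_boot_inner,cost_grid,gamma_grid Validation
#'   parameters.
#' @param seed Master seed.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(simulate = TRUE, cluster = FALSE, select = TRUE,
                            validate = TRUE, cohort = list(),
                            som_grid = c(10, 10), som_epochs = 10, K = 44,
                            cofactor = 5,
                            covariate_set = propensity_covariates(),
                            gamma = 1, nlambda = 100, inner_folds = 5,
                            n_boot = 1000, n_perm = 1000, n_boot_inner = 100,
                            cost_grid = 2^seq(-5, 15, 2),
                            gamma_grid = 2^seq(-15, 3, 2), seed = 1L) {
  cfg <- as.list(environment())
  allowed_cohort <- names(formals(cohort_config))
  bad <- setdiff(names(cohort), allowed_cohort)
  if (length(bad)) stop("unknown cohort key(s): ", paste(bad, collapse = ", "))
  stopifnot(length(som_grid) == 2, K >= 1, n_boot >= 1, n_perm >= 1,
            seed == round(seed))
  structure(cfg, class = "pipeline_config")
}

#' Run the full discovery-and-validation pipeline
#'
#' Executes the workflow end to end: simulate a cohort (composition-level,
#' or cell-level plus SOM clustering when the `cluster` stage is enabled),
#' CLR-transform cluster abundances, run LOOCV adaptive-LASSO stability
#' selection with per-fold IPW, and validate the D-TCL set with bootstrap
#' SVM and a label-permutation test. Every stage writes its outputs under
#' `out` and subsequent stages read only those on-disk artifacts, so the
#' pipeline is restartable. A run manifest (package version, resolved
#' configuration, per-stage seeds, file digests, timestamp) is written
#' alongside.
#'
#' @param config A [pipeline_config()].
#' @param out Output directory.
#' @return Invisibly, the manifest (also saved in `out`).
#' @export
run_pipeline <- function(config = pipeline_config(), out) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  stage_seeds <- stats::setNames(
    as.list(sample.int(.Machine$integer.max - 1L, 4)),
    c("simulate", "cluster", "select", "validate"))
  log_stage <- function(msg) message(sprintf("[%s] %s",
                                             format(Sys.time(), "%H:%M:%S"),
                                             msg))
  skipped <- character()

  if (config$simulate) {
    log_stage("simulate: generating synthetic cohort")
    cc <- do.call(cohort_config,
                  utils::modifyList(list(seed = stage_seeds$simulate),
                                    config$cohort))
    if (config$cluster) {
      sim <- simulate_cells(cc)
      tr <- arcsinh_transform(sim$cells, config$cofactor)
      log_stage("cluster: SOM training + metaclustering")
      pooled <- do.call(rbind, lapply(tr, function(m) m[, , drop = FALSE]))
      som <- som_train(pooled, config$som_grid[1], config$som_grid[2],
                       epochs = config$som_epochs,
                       seed = stage_seeds$cluster)
      mc <- metacluster(som, config$K)
      comp <- assign_and_count(tr, som, mc)
      cohort <- list(covariates = sim$covariates, composition = comp,
                     truth = sim$truth)
    } else {
      cohort <- simulate_composition(cc)
    }
    write_cohort(cohort, out)
  } else skipped <- c(skipped, "simulate")

  sel <- NULL
  if (config$select) {
    log_stage("select: LOOCV adaptive-LASSO stability selection")
    comp <- read_composition(file.path(out, "composition_counts.csv"))
    cov <- utils::read.csv(file.path(out, "covariates.csv"))
    sel <- dtcl_select(comp, cov, covariate_set = config$covariate_set,
                       gamma = config$gamma, nlambda = config$nlambda,
                       inner_folds = config$inner_folds,
                       seed = stage_seeds$select)
    utils::write.csv(data.frame(feature = names(sel$selection_frequency),
                                frequency = sel$selection_frequency,
                                dtcl = names(sel$selection_frequency) %in%
                                  sel$dtcl),
                     file.path(out, "selection_frequency.csv"),
                     row.names = FALSE)
    utils::write.csv(data.frame(subject_id = sel$subject_ids,
                                serostatus = sel$y,
                                heldout_prob = sel$heldout_prob),
                     file.path(out, "heldout_probabilities.csv"),
                     row.names = FALSE)
    co <- coef(sel)
    utils::write.csv(data.frame(term = names(co), coefficient = unname(co)),
                     file.path(out, "final_coefficients.csv"),
                     row.names = FALSE)
    utils::write.csv(data.frame(fold = seq_len(nrow(sel$selection_matrix)),
                                sel$selection_matrix, check.names = FALSE),
                     file.path(out, "selection_matrix.csv"),
                     row.names = FALSE)
  } else skipped <- c(skipped, "select")

  if (config$validate && !is.null(sel)) {
    if (length(sel$dtcl) >= 1) {
      log_stage("validate: bootstrap SVM + permutation test")
      freq <- utils::read.csv(file.path(out, "selection_frequency.csv"))
      dtcl <- freq$feature[freq$dtcl]
      Xv <- sel$features[, dtcl, drop = FALSE]
      bs <- bootstrap_svm(Xv, sel$y, n_boot = config$n_boot,
                          cost_grid = config$cost_grid,
                          gamma_grid = config$gamma_grid,
                          seed = stage_seeds$validate)
      modal <- attr(bs$hyperparameters, "modal")
      pt <- permutation_test_auc(Xv, sel$y, n_perm = config$n_perm,
                                 fixed_cost = modal[1],
                                 fixed_gamma = modal[2],
                                 n_boot_inner = config$n_boot_inner,
                                 seed = stage_seeds$validate + 1L)
      utils::write.csv(bs$metrics, file.path(out, "bootstrap_metrics.csv"),
                       row.names = FALSE)
      utils::write.csv(data.frame(metric = rownames(bs$summary),
                                  bs$summary),
                       file.path(out, "bootstrap_summary.csv"),
                       row.names = FALSE)
      utils::write.csv(bs$mean_roc, file.path(out, "mean_roc.csv"),
                       row.names = FALSE)
      utils::write.csv(data.frame(permuted_mean_auc = pt$permuted),
                       file.path(out, "permutation_null.csv"),
                       row.names = FALSE)
      utils::write.csv(data.frame(observed_mean_auc = pt$observed,
                                  p_value = pt$p),
                       file.path(out, "permutation_summary.csv"),
                       row.names = FALSE)
    } else {
      log_stage("validate: no D-TCLs selected, nothing to validate")
      skipped <- c(skipped, "validate (empty D-TCL set)")
    }
  } else if (!config$validate) skipped <- c(skipped, "validate")

  files <- setdiff(list.files(out, full.names = TRUE),
                   file.path(out, c("manifest.rds", "manifest.txt")))
  manifest <- list(package_version = as.character(
                     utils::packageVersion("seroclust")),
                   config = unclass(config), stage_seeds = stage_seeds,
                   skipped = skipped,
                   digests = tools::md5sum(files),
                   timestamp = format(Sys.time(), tz = "UTC"))
  saveRDS(manifest, file.path(out, "manifest.rds"))
  writeLines(c(paste("package_version:", manifest$package_version),
               paste("timestamp:", manifest$timestamp),
               paste("skipped:", paste(skipped, collapse = ", ")),
               paste0(names(manifest$digests), ": ",
                      unname(manifest$digests))),
             file.path(out, "manifest.txt"))
  invisible(manifest)
}
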