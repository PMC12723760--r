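# End-to-end orchestration: (optional) simulation -> preprocessing + model
# grid selection -> posterior classification -> baseline summary ->
# trajectories -> cross-validation -> power table -> classification tree,
# with every artifact written to a run directory plus a manifest.

#' Serialize a fitted LCMM to JSON
#'
#' Writes the model definition, all parameters, fit statistics and
#' convergence metadata (not the data) so a fit can be archived and audited.
#'
#' @param fit An \code{lcmm_fit}.
#' @param path JSON path.
#' @export
fit_to_json <- function(fit, path) {
  rec <- list(
    spec = unclass(fit$spec),
    zeta = fit$zeta, alpha = fit$alpha, gamma = as.list(fit$gamma),
    sigma_b = fit$sigma_b, sigma_e = fit$sigma_e, D = fit$D,
    transform = unclass(fit$transform), basis = unclass(fit$basis),
    scaling = fit$scaling,
    loglik = fit$loglik, n_params = fit$n_params, BIC = fit$BIC,
    ICL = fit$ICL, entropy = fit$entropy, converged = fit$converged,
    n_iter = fit$n_iter, n_starts_used = fit$n_starts_used,
    seed = fit$seed,
    package_version = as.character(utils::packageVersion("cogmix")))
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}

#' Default pipeline configuration
#'
#' @param out_dir Run directory (created if absent).
#' @param visits,baseline Input CSV paths (ignored when \code{simulate_n}
#'   is set).
#' @param simulate_n If non-NULL, simulate a cohort of this size from
#'   [preset_a4learn_like()] instead of reading files.
#' @param G_grid,df_grid,n_starts,seed Model selection controls.
#' @param cv_folds Cross-validation folds (0 disables CV).
#' @param cp_grid Tree tuning grid.
#' @param verbose Print stage banners.
#' @return A \code{pipeline_config} list.
#' @export
pipeline_config <- function(out_dir, visits = NULL, baseline = NULL,
                            simulate_n = NULL, G_grid = 1:3, df_grid = 1:3,
                            n_starts = 3, seed = 20260121, cv_folds = 10,
                            cp_grid = c(0.0005, 0.001, 0.002, 0.005, 0.01,
                                        0.02, 0.05),
                            verbose = TRUE) {
  structure(list(out_dir = out_dir, visits = visits, baseline = baseline,
                 simulate_n = simulate_n, G_grid = G_grid, df_grid = df_grid,
                 n_starts = n_starts, seed = seed, cv_folds = cv_folds,
                 cp_grid = cp_grid, verbose = verbose),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes every stage in order and writes all artifacts into
#' \code{config$out_dir}: the (simulated or read) cohort, the selection
#' table, the selected fit (JSON) and posteriors (CSV), the baseline summary
#' by class, class trajectories, cross-validated baseline predictions and
#' metrics, a class-specific power table (stable class as the benefit
#' anchor), the tuned classification tree, and a manifest with file hashes
#' and seeds. A stage failure retains partial results; the manifest records
#' the failure point.
#'
#' @param config A \code{pipeline_config}.
#' @return The run directory, invisibly; the manifest is
#'   \code{manifest.json} inside it.
#' @export
run_pipeline <- function(config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)
  say <- function(...) if (isTRUE(config$verbose)) message(sprintf(...))
  manifest <- list(seed = config$seed, stages = list(),
                   package_version = as.character(utils::packageVersion("cogmix")))
  finish <- function() {
    files <- setdiff(list.files(config$out_dir), "manifest.json")
    manifest$files <- as.list(tools::md5sum(
      file.path(config$out_dir, files)))
    names(manifest$files) <- files
    jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                         digits = NA)
  }
  stage <- function(name, expr) {
    say("[%s]", name)
    res <- tryCatch(expr, error = function(e) {
      manifest$stages[[name]] <<- paste("FAILED:", conditionMessage(e))
      say("  stage %s failed: %s", name, conditionMessage(e))
      NULL
    })
    if (is.null(manifest$stages[[name]])) manifest$stages[[name]] <<- "ok"
    res
  }
  on.exit(finish())

  truth <- NULL; true_class <- NULL
  cohort <- stage("data", {
    if (!is.null(config$simulate_n)) {
      truth <- preset_a4learn_like(n_subjects = config$simulate_n)
      sim <- simulate_cohort(truth, seed = derive_seed(config$seed, 1))
      true_class <- sim$true_class
      write_cohort(sim$cohort, out("visits.csv"), out("baseline.csv"))
      truth_to_json(truth, out("truth.json"))
      sim$cohort
    } else read_cohort(config$visits, config$baseline)
  })
  if (is.null(cohort)) return(invisible(config$out_dir))

  sel <- stage("select_model", {
    s <- select_model(cohort, df_grid = config$df_grid,
                      G_grid = config$G_grid, n_starts = config$n_starts,
                      seed = derive_seed(config$seed, 2))
    utils::write.csv(s$table, out("selection.csv"), row.names = FALSE)
    s
  })
  if (is.null(sel)) return(invisible(config$out_dir))
  fit <- sel$best_fit
  fit_to_json(fit, out("fit.json"))

  stage("classification", {
    tau <- fit$posterior
    post <- data.frame(subject_id = names(fit$class_labels),
                       stats::setNames(as.data.frame(tau),
                                       paste0("tau_", seq_len(ncol(tau)))),
                       class = unname(fit$class_labels))
    utils::write.csv(post, out("posterior.csv"), row.names = FALSE)
  })

  stage("summary", {
    labs <- fit$class_labels
    sub <- cohort_subset(cohort, names(labs))
    write_summary(summarize_by_class(sub, labs), out("summary_by_class.csv"),
                  out("summary_by_class.txt"))
  })

  stage("trajectories", {
    tr <- class_trajectories(fit)
    utils::write.csv(tr, out("trajectories.csv"), row.names = FALSE)
  })

  cvres <- NULL
  if (config$cv_folds >= 2 && fit$spec$G > 1) {
    cvres <- stage("cross_validation", {
      labs <- fit$class_labels
      ptau <- stats::setNames(cohort$baseline$ptau217,
                              cohort$baseline$subject_id)
      folds <- make_folds(labs, ptau, K = config$cv_folds,
                          seed = derive_seed(config$seed, 3))
      cv <- cross_validate(cohort_subset(cohort, names(labs)), fit$spec,
                           folds, fit, n_starts = max(1, config$n_starts - 1),
                           seed = derive_seed(config$seed, 4))
      utils::write.csv(cv$predictions, out("cv_predictions.csv"),
                       row.names = FALSE)
      pr <- cv$predictions
      probs <- as.matrix(pr[, grep("^p_class", names(pr)), drop = FALSE])
      m <- classification_metrics(
        stats::setNames(pr$predicted, pr$subject_id),
        labs[pr$subject_id], probs[order(match(pr$subject_id,
                                               names(labs))), , drop = FALSE])
      m$confusion <- as.data.frame(m$confusion)
      jsonlite::write_json(m, out("cv_metrics.json"), auto_unbox = TRUE,
                           digits = NA, force = TRUE)
      cv
    })
  }

  stage("power", {
    gs <- group_summaries_from_fit(fit, horizons = c(2, 4))
    gs$group <- as.character(gs$group)
    gs$group[gs$group == "1"] <- "reference"
    pt <- power_table(gs, reference_group = "reference")
    utils::write.csv(pt, out("power.csv"), row.names = FALSE)
  })

  stage("tree", {
    labs <- fit$class_labels
    feats <- tree_features(cohort, names(labs))
    ok <- stats::complete.cases(feats)
    tt <- tune_tree(feats[ok, , drop = FALSE], labs[rownames(feats)[ok]],
                    cp_grid = config$cp_grid,
                    seed = derive_seed(config$seed, 5))
    tree_to_json(tt$model, out("tree.json"))
    utils::write.csv(tt$cv_table, out("tree_cv.csv"), row.names = FALSE)
    imp <- variable_importance(tt$model)
    utils::write.csv(data.frame(variable = names(imp), importance_pct = imp),
                     out("tree_importance.csv"), row.names = FALSE)
  })

  invisible(config$out_dir)
}

# Restrict a cohort to a subject set.
cohort_subset <- function(cohort, subjects) {
  cohort_data(
    cohort$visits[cohort$visits$subject_id %in% subjects, , drop = FALSE],
    cohort$baseline[cohort$baseline$subject_id %in% subjects, , drop = FALSE])
}

# Baseline feature table for the classification tree: treatment arm,
# biomarkers, demographics, atrophy z-score and baseline PACC.
tree_features <- function(cohort, subjects = NULL) {
  b <- cohort$baseline
  if (!is.null(subjects)) b <- b[b$subject_id %in% subjects, , drop = FALSE]
  if (!"hipp_atrophy_z" %in% names(b)) {
    ok <- stats::complete.cases(b[c("hippocampal_volume", "icv")])
    b$hipp_atrophy_z <- NA_real_
    if (sum(ok) >= 3)
      b$hipp_atrophy_z[ok] <- residualize_and_z(b$hippocampal_volume[ok],
                                                b$icv[ok])
  }
  v <- cohort$visits
  first <- v[!duplicated(v$subject_id), ]
  feats <- data.frame(
    active_treatment = as.integer(b$arm == "solanezumab"),
    ptau217 = b$ptau217, amyloid_centiloid = b$amyloid_centiloid,
    apoe4_carrier = b$apoe4_carrier, sex_female = b$sex_female,
    age = b$age, education = b$education, hipp_atrophy_z = b$hipp_atrophy_z,
    pacc_baseline = first$pacc[match(b$subject_id, first$subject_id)])
  rownames(feats) <- b$subject_id
  feats
}
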