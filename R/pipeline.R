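.run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Executes, in order: metabolite exclusion, metadata group tests, PLS-DA
#' and OPLS fitting with cross-validated Q2, permutation/bootstrap model
#' validation with the overfitting diagnostic (skipped when
#' `n_permutations = 0` or `validate_models = FALSE`), the four-step
#' biomarker selection, the group-stratified component-age screen with the
#' metabolite-level consistency check, and pathway over-representation
#' analysis overall and per component. Every stochastic stage draws a named
#' substream from `config$seed`, so a run is fully determined by the config
#' and data.
#'
#' @param config A [run_config()].
#' @param dataset A `metabolomics_dataset`.
#' @param pathway_sets Optional pathway definitions for the enrichment
#'   stage.
#' @param out_dir Optional output directory; when given, result tables,
#'   a JSON run manifest and a text summary are written there.
#' @return A `pipeline_report` list.
#' @export
run_pipeline <- function(config, dataset, pathway_sets = NULL,
                         out_dir = NULL) {
  stopifnot(inherits(config, "run_config"),
            inherits(dataset, "metabolomics_dataset"))
  seed <- config$seed

  ds <- .run_stage("preprocess",
                   suppressMessages(
                     exclude_metabolites(dataset, config$excluded_metabolites)))
  X <- ds$concentrations
  y <- encode_group(ds)

  metadata_tests <- .run_stage("metadata_tests", metadata_group_tests(ds))

  models <- .run_stage("models", {
    sc <- autoscale(X)
    plsda <- suppressWarnings(fit_plsda(sc$values, y, config$n_pls))
    opls <- suppressWarnings(
      fit_opls(sc$values, y, config$n_opls_predictive, config$n_orthogonal))
    plsda$q2 <- q2_crossval(X, y, model_spec("plsda",
                                             n_components = config$n_pls),
                            config$k_folds, stage_seed(seed, "q2_plsda"),
                            rescale = config$rescale_in_resampling)
    opls$q2 <- q2_crossval(X, y,
                           model_spec("opls",
                                      n_predictive = config$n_opls_predictive,
                                      n_orthogonal = config$n_orthogonal),
                           config$k_folds, stage_seed(seed, "q2_opls"),
                           rescale = config$rescale_in_resampling)
    list(plsda = plsda, opls = opls)
  })

  validation <- list(skipped = TRUE)
  if (config$validate_models && config$n_permutations > 0) {
    validation <- .run_stage("validation", {
      out <- list(skipped = FALSE)
      for (kind in c("plsda", "opls")) {
        spec <- if (kind == "plsda")
          model_spec("plsda", n_components = config$n_pls)
        else
          model_spec("opls", n_predictive = config$n_opls_predictive,
                     n_orthogonal = config$n_orthogonal)
        rep <- permutation_metric_test(
          X, y, spec, config$n_permutations, config$k_folds,
          stage_seed(seed, paste0("perm_", kind)),
          rescale = config$rescale_in_resampling)
        diag <- overfit_diagnostic(rep)
        boot <- NULL
        if (config$n_bootstrap_model >= 100) {
          boot <- bootstrap_model_pvalue(
            X, y, spec, config$n_bootstrap_model,
            stage_seed(seed, paste0("boot_", kind)), config$k_folds,
            perm_q2 = rep$perm_q2, observed_q2 = rep$observed_q2,
            rescale = config$rescale_in_resampling)
        }
        out[[kind]] <- list(report = rep, diagnostic = diag,
                            bootstrap = boot)
      }
      out
    })
  }

  selection <- .run_stage("selection",
                          select_metabolites(X, y, config,
                                             seed = stage_seed(seed, "selection")))

  age_profiles <- NULL
  consistency <- NULL
  if (!is.null(selection$step3)) {
    age_profiles <- .run_stage("age_screen",
                               component_age_screen(selection$step3$scores,
                                                    ds$group, ds$age, config))
    if (nrow(selection$final) > 0) {
      consistency <- .run_stage("age_consistency",
                                verify_metabolite_age_consistency(
                                  selection$final, ds, age_profiles, config))
    }
  }

  enrichment <- NULL
  if (!is.null(pathway_sets) && nrow(selection$final) > 0) {
    enrichment <- .run_stage("enrichment", {
      universe <- metabolite_ids(ds)
      overall <- enrichment_ora(selection$final$metabolite, universe,
                                pathway_sets,
                                n_permutations = max(config$n_permutations,
                                                     1000L),
                                seed = stage_seed(seed, "enrich_overall"))
      per_comp <- if (!is.null(age_profiles))
        per_component_enrichment(selection, age_profiles, pathway_sets,
                                 universe, config,
                                 seed = stage_seed(seed, "enrich_components"))
      list(overall = overall, per_component = per_comp)
    })
  }

  report <- structure(
    list(config = config,
         n_samples = n_samples(ds), n_metabolites = n_metabolites(ds),
         metadata_tests = metadata_tests,
         models = models, validation = validation,
         selection = selection, age_profiles = age_profiles,
         consistency = consistency, enrichment = enrichment),
    class = "pipeline_report")
  if (!is.null(out_dir)) .run_stage("write_report",
                                    write_report(report, out_dir))
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("== metabolomics pipeline report ==\n")
  cat(sprintf("data: %d samples x %d metabolites\n",
              x$n_samples, x$n_metabolites))
  cat(sprintf("PLS-DA (%d comp):  R2Y = %.3f, Q2 = %.3f\n",
              x$config$n_pls, x$models$plsda$r2y, x$models$plsda$q2))
  cat(sprintf("OPLS (%d pred, %d orth): R2Y = %.3f, Q2 = %.3f\n",
              x$config$n_opls_predictive, x$config$n_orthogonal,
              x$models$opls$r2y, x$models$opls$q2))
  if (isTRUE(x$validation$skipped)) {
    cat("model validation: skipped\n")
  } else {
    for (kind in c("plsda", "opls")) {
      v <- x$validation[[kind]]
      cat(sprintf("%s validation: overfit verdict '%s'%s\n", kind,
                  v$diagnostic$verdict,
                  if (is.null(v$bootstrap)) "" else
                    sprintf(", bootstrap model P = %.3g",
                            v$bootstrap$p_model)))
    }
  }
  s1 <- x$selection$step1
  if (!is.null(s1$auc))
    cat(sprintf("step-1 AUC = %.3f (95%% CI %.3f-%.3f)\n",
                s1$auc$auc, s1$auc$ci_lower, s1$auc$ci_upper))
  cat(sprintf("selection: %d -> %d -> %d metabolites\n",
              length(s1$selected), length(x$selection$step2$selected),
              nrow(x$selection$final)))
  if (!is.null(x$age_profiles)) {
    cat("component age classification:\n")
    for (i in seq_len(nrow(x$age_profiles)))
      cat(sprintf("  %s: %s (r_case = %.2f, r_control = %.2f)\n",
                  x$age_profiles$component[i],
                  x$age_profiles$classification[i],
                  x$age_profiles$r_case[i], x$age_profiles$r_control[i]))
  }
  if (!is.null(x$enrichment) && nrow(x$enrichment$per_component$headline)) {
    cat("per-component top pathways:\n")
    h <- x$enrichment$per_component$headline
    for (i in seq_len(nrow(h)))
      cat(sprintf("  %s [%s]: %s (P = %.3g)\n", h$component[i],
                  h$classification[i], h$top_pathway[i],
                  h$p_permutation[i]))
  }
  invisible(x)
}

#' Write pipeline result tables and a run manifest
#'
#' Writes the selection trail, component-age table, consistency table and
#' enrichment tables as comma-separated text, a JSON manifest (config and
#' versions) and a human-readable summary. Identical reports produce
#' byte-identical tables.
#'
#' @param report A `pipeline_report`.
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, the vector of written file paths.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  wr <- function(df, name) {
    path <- file.path(out_dir, name)
    utils::write.csv(df, path, row.names = FALSE)
    written <<- c(written, path)
  }
  wr(report$selection$trail, "selection_trail.csv")
  if (!is.null(report$metadata_tests)) wr(report$metadata_tests,
                                          "metadata_tests.csv")
  if (!is.null(report$age_profiles))
    wr(as.data.frame(report$age_profiles), "component_age.csv")
  if (!is.null(report$consistency)) wr(report$consistency,
                                       "metabolite_age_consistency.csv")
  if (!is.null(report$enrichment)) {
    wr(report$enrichment$overall, "enrichment_overall.csv")
    if (!is.null(report$enrichment$per_component))
      wr(report$enrichment$per_component$headline, "enrichment_headline.csv")
  }
  manifest <- list(package = "oplsage",
                   version = as.character(utils::packageVersion("oplsage")),
                   r_version = R.version.string,
                   config = unclass(report$config))
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  written <- c(written, manifest_path)
  summary_path <- file.path(out_dir, "summary.txt")
  writeLines(utils::capture.output(print(report)), summary_path)
  written <- c(written, summary_path)
  invisible(written)
}
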