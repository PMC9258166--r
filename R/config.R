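#' Pipeline run configuration
#'
#' Bundles every tunable parameter of the analysis with the defaults used for
#' the 39+39 cohort design: a 3-component PLS-DA compared against an OPLS
#' model with 1 predictive and 3 orthogonal components, 1000-permutation
#' validation, 500-replicate bootstrap model validation, a 1000-round
#' VIP-stability filter at the strict "VIP > 1 in more than 95% of rounds"
#' rule, PCA reduction to the components covering 80% of variance with the
#' `|c| > 0.9 max|c|` coefficient rule, and a group-stratified Spearman
#' screen at `|r| > 0.5` with Bonferroni-corrected `P < alpha / N_pca`.
#'
#' @param n_pls Number of PLS-DA components.
#' @param n_opls_predictive,n_orthogonal OPLS predictive / orthogonal
#'   component counts.
#' @param k_folds Cross-validation folds for Q2.
#' @param n_permutations Label permutations for the metric and loading
#'   permutation tests (0 disables the model-validation stage).
#' @param n_bootstrap_model Bootstrap replicates for the model P-value and
#'   the AUC confidence interval.
#' @param n_bootstrap_vip Resampling rounds of the VIP stability filter.
#' @param train_fraction Fraction of subjects in the training split /
#'   resamples.
#' @param vip_threshold VIP cut (strict `>`).
#' @param loading_threshold Minimum absolute predictive loading.
#' @param loading_pvalue_threshold Loading permutation-test alpha.
#' @param vip_stability_fraction Stability cut (strict `>`).
#' @param pca_variance_target Cumulative variance the retained principal
#'   components must reach.
#' @param pca_coeff_fraction Fraction of the within-component maximum
#'   absolute coefficient a metabolite must exceed.
#' @param spearman_r_threshold Minimum |Spearman r| for an age correlation.
#' @param alpha Significance level (Bonferroni-divided by the number of
#'   principal components in the age screen).
#' @param excluded_metabolites Metabolite identifiers removed before any
#'   analysis (defaults to the two therapy-related analytes of an L-DOPA
#'   treated cohort).
#' @param seed Master seed; every stochastic stage derives a named substream
#'   from it via [stage_seed()].
#' @param stability_with_replacement Draw the 80% stability resamples with
#'   replacement (m-out-of-n bootstrap, default) or without (subsampling).
#' @param rescale_in_resampling Refit the autoscaling on each training split
#'   inside cross-validation and resampling (default), avoiding information
#'   leakage into Q2; set to `FALSE` to scale once up front.
#' @param validate_models Run the permutation/bootstrap model-validation
#'   stage in [run_pipeline()] (selection always runs).
#' @return An object of class `run_config`.
#' @export
run_config <- function(n_pls = 3L,
                       n_opls_predictive = 1L,
                       n_orthogonal = 3L,
                       k_folds = 7L,
                       n_permutations = 1000L,
                       n_bootstrap_model = 500L,
                       n_bootstrap_vip = 1000L,
                       train_fraction = 0.8,
                       vip_threshold = 1.0,
                       loading_threshold = 0.04,
                       loading_pvalue_threshold = 0.05,
                       vip_stability_fraction = 0.95,
                       pca_variance_target = 0.80,
                       pca_coeff_fraction = 0.9,
                       spearman_r_threshold = 0.5,
                       alpha = 0.05,
                       excluded_metabolites = c("DOPA", "Tyr"),
                       seed = 1L,
                       stability_with_replacement = TRUE,
                       rescale_in_resampling = TRUE,
                       validate_models = TRUE) {
  cfg <- list(n_pls = as.integer(n_pls),
              n_opls_predictive = as.integer(n_opls_predictive),
              n_orthogonal = as.integer(n_orthogonal),
              k_folds = as.integer(k_folds),
              n_permutations = as.integer(n_permutations),
              n_bootstrap_model = as.integer(n_bootstrap_model),
              n_bootstrap_vip = as.integer(n_bootstrap_vip),
              train_fraction = train_fraction,
              vip_threshold = vip_threshold,
              loading_threshold = loading_threshold,
              loading_pvalue_threshold = loading_pvalue_threshold,
              vip_stability_fraction = vip_stability_fraction,
              pca_variance_target = pca_variance_target,
              pca_coeff_fraction = pca_coeff_fraction,
              spearman_r_threshold = spearman_r_threshold,
              alpha = alpha,
              excluded_metabolites = as.character(excluded_metabolites),
              seed = as.integer(seed),
              stability_with_replacement = isTRUE(stability_with_replacement),
              rescale_in_resampling = isTRUE(rescale_in_resampling),
              validate_models = isTRUE(validate_models))
  stopifnot(cfg$n_pls >= 1L, cfg$n_opls_predictive >= 1L,
            cfg$n_orthogonal >= 0L, cfg$k_folds >= 2L,
            cfg$n_permutations >= 0L, cfg$n_bootstrap_model >= 0L,
            cfg$n_bootstrap_vip >= 1L)
  for (fr in c("train_fraction", "vip_stability_fraction",
               "pca_variance_target", "pca_coeff_fraction"))
    if (!(cfg[[fr]] > 0 && cfg[[fr]] <= 1))
      stop(sprintf("'%s' must lie in (0, 1]", fr))
  if (!(cfg$alpha > 0 && cfg$alpha < 1)) stop("'alpha' must lie in (0, 1)")
  if (cfg$spearman_r_threshold < 0 || cfg$spearman_r_threshold >= 1)
    stop("'spearman_r_threshold' must lie in [0, 1)")
  structure(cfg, class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat("run_config:\n")
  for (nm in names(x))
    cat(sprintf("  %-28s %s\n", nm, paste(x[[nm]], collapse = ", ")))
  invisible(x)
}
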