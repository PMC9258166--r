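#' Step 1: training-split VIP screen with loading filters
#'
#' Draws a single stratified training split (`train_fraction` of each
#' group), fits the configured OPLS model on the autoscaled training data
#' and keeps the metabolites with `VIP > vip_threshold`, a loading
#' permutation-test `P < loading_pvalue_threshold` and
#' `|loading| > loading_threshold`. The model is then refitted on the
#' selected columns and all subjects are scored for a bootstrap ROC/AUC.
#' With `n_permutations = 0` the loading P filter is skipped (all pass).
#'
#' @param X Concentration matrix (samples x metabolites) or a
#'   `metabolomics_dataset`.
#' @param y Class labels (taken from the dataset when `X` is one).
#' @param config A [run_config()].
#' @param seed Seed; defaults to `config$seed`.
#' @return List with the selected set, per-metabolite VIP/loading/P, the
#'   training index and the AUC with its confidence interval.
#' @export
step1_screen <- function(X, y = NULL, config = run_config(),
                         seed = config$seed) {
  if (inherits(X, "metabolomics_dataset")) {
    if (is.null(y)) y <- encode_group(X)
    X <- X$concentrations
  }
  if (is.character(y) || is.factor(y)) y <- encode_group(y)
  spec <- model_spec("opls", n_predictive = config$n_opls_predictive,
                     n_orthogonal = config$n_orthogonal)
  set.seed(stage_seed(seed, "step1_split"))
  train <- sort(unlist(lapply(split(seq_along(y), y), function(ix)
    sample(ix, max(2L, round(config$train_fraction * length(ix))))),
    use.names = FALSE))
  sc <- .scale_fit(X[train, , drop = FALSE])
  Xtr <- sc$values
  m <- suppressWarnings(.fit_spec(Xtr, y[train], spec))
  v <- m$vip
  L <- m$loadings[, 1]
  names(L) <- colnames(X)
  if (config$n_permutations > 0) {
    lp <- loading_permutation_test(Xtr, y[train], spec,
                                   n_permutations = config$n_permutations,
                                   seed = stage_seed(seed, "step1_loadperm"))
    pvals <- lp$p_value
  } else {
    pvals <- rep(0, ncol(X))
    names(pvals) <- colnames(X)
  }
  keep <- v > config$vip_threshold &
    pvals < config$loading_pvalue_threshold &
    abs(L) > config$loading_threshold
  selected <- colnames(X)[keep]
  auc <- NULL
  if (length(selected) == 0) {
    warning("step 1 selected no metabolites")
  } else {
    m2 <- suppressWarnings(
      .fit_spec(Xtr[, selected, drop = FALSE], y[train], spec))
    Xall <- .scale_transform(sc, X)[, selected, drop = FALSE]
    scores <- predict(m2, Xall)
    auc <- roc_auc_bootstrap(scores, y,
                             n_bootstrap = config$n_bootstrap_model,
                             seed = stage_seed(seed, "step1_auc"))
  }
  list(selected = selected, vip = v, loading = L, loading_p = pvals,
       train_idx = train, auc = auc, spec = spec)
}

# the retention rule of the stability filter, strict per the "more than
# 95% of the trials" wording: a fraction of exactly the threshold is dropped
.stability_select <- function(fraction, threshold) {
  names(fraction)[fraction > threshold]
}

#' Step 2: bootstrap VIP stability filter
#'
#' Repeats the model training `n_bootstrap_vip` times on stratified
#' resamples of `train_fraction` of each group (drawn with replacement by
#' default; set `stability_with_replacement = FALSE` in the config for
#' plain subsampling), recording for each metabolite the fraction of rounds
#' with `VIP > vip_threshold`. Metabolites with a fraction strictly above
#' `vip_stability_fraction` are retained.
#'
#' @inheritParams step1_screen
#' @param universe Optional metabolite set to intersect the stable set with
#'   (typically the step-1 selection).
#' @return List with the per-metabolite `stability_fraction` and the
#'   `selected` set.
#' @export
step2_vip_stability <- function(X, y = NULL, config = run_config(),
                                seed = config$seed, universe = NULL) {
  if (inherits(X, "metabolomics_dataset")) {
    if (is.null(y)) y <- encode_group(X)
    X <- X$concentrations
  }
  if (is.character(y) || is.factor(y)) y <- encode_group(y)
  spec <- model_spec("opls", n_predictive = config$n_opls_predictive,
                     n_orthogonal = config$n_orthogonal)
  idx_by_group <- split(seq_along(y), y)
  sizes <- lapply(idx_by_group, function(ix)
    max(2L, round(config$train_fraction * length(ix))))
  B <- config$n_bootstrap_vip
  cnt <- numeric(ncol(X))
  set.seed(stage_seed(seed, "step2_stability"))
  redraws <- 0L
  max_redraws <- ceiling(0.05 * B)
  b <- 1L
  while (b <= B) {
    idx <- unlist(Map(function(ix, m)
      sample(ix, m, replace = config$stability_with_replacement),
      idx_by_group, sizes), use.names = FALSE)
    fit <- tryCatch(
      suppressWarnings(.fit_spec(.scale_fit(X[idx, , drop = FALSE])$values,
                                 y[idx], spec)),
      error = function(e) NULL)
    if (is.null(fit)) {
      redraws <- redraws + 1L
      if (redraws > max_redraws)
        stop("stability filter: too many failed resampling rounds")
      next
    }
    cnt <- cnt + (fit$vip > config$vip_threshold)
    b <- b + 1L
  }
  fraction <- cnt / B
  names(fraction) <- colnames(X)
  selected <- .stability_select(fraction, config$vip_stability_fraction)
  if (!is.null(universe)) selected <- intersect(selected, universe)
  list(stability_fraction = fraction, selected = selected, n_rounds = B)
}

#' Step 3: PCA feature reduction with the 0.9-max coefficient rule
#'
#' PCA (singular value decomposition of the autoscaled submatrix of the
#' stability-validated metabolites, all subjects). `N_pca` is the smallest
#' number of components whose cumulative explained variance reaches
#' `pca_variance_target` (capped at the matrix rank). Per component, the
#' significant metabolites are those with
#' `|c_j| > pca_coeff_fraction * max_j |c_j|`, the coefficients being the
#' unit-norm component loadings, sign-fixed so each component's
#' largest-magnitude coefficient is positive.
#'
#' @param X_sub Concentration matrix restricted to the step-2 metabolites
#'   (>= 2 columns).
#' @param config A [run_config()].
#' @return List with `n_components`, per-component `variance_explained`,
#'   the loading matrix, the per-sample component scores and the
#'   per-component significant sets (components named `f1`, `f2`, ...).
#' @export
step3_pca_reduce <- function(X_sub, config = run_config()) {
  stopifnot(is.matrix(X_sub))
  if (ncol(X_sub) < 2) stop("at least two metabolites are required for PCA")
  sc <- autoscale(X_sub)
  pr <- stats::prcomp(sc$values, center = FALSE, scale. = FALSE)
  var_expl <- pr$sdev^2 / sum(pr$sdev^2)
  rank <- sum(pr$sdev > pr$sdev[1] * 1e-10)
  n_comp <- which(cumsum(var_expl) >= config$pca_variance_target - 1e-12)[1]
  if (is.na(n_comp)) n_comp <- rank
  n_comp <- min(n_comp, rank)
  rot <- pr$rotation[, seq_len(n_comp), drop = FALSE]
  scores <- pr$x[, seq_len(n_comp), drop = FALSE]
  for (i in seq_len(n_comp)) {
    jmax <- which.max(abs(rot[, i]))
    if (rot[jmax, i] < 0) {
      rot[, i] <- -rot[, i]
      scores[, i] <- -scores[, i]
    }
  }
  comp_names <- paste0("f", seq_len(n_comp))
  colnames(rot) <- colnames(scores) <- comp_names
  significant <- lapply(comp_names, function(cn) {
    cj <- rot[, cn]
    names(which(abs(cj) > config$pca_coeff_fraction * max(abs(cj))))
  })
  names(significant) <- comp_names
  list(n_components = n_comp, variance_explained = var_expl,
       loadings = rot, scores = scores, significant = significant)
}

#' Step 4: intersect the stability and PCA selections
#'
#' Final metabolites are those retained by the stability filter that are
#' also significant in at least one principal component; each is assigned
#' to the component where its absolute coefficient is largest among the
#' components in which it is significant.
#'
#' @param step2_selected Character vector from [step2_vip_stability()].
#' @param step3 Result of [step3_pca_reduce()].
#' @return Data frame with `metabolite`, assigned `component` and the
#'   `coefficient` on that component.
#' @export
step4_intersect <- function(step2_selected, step3) {
  final <- intersect(step2_selected,
                     unique(unlist(step3$significant, use.names = FALSE)))
  rows <- lapply(final, function(m) {
    comps <- names(step3$significant)[vapply(step3$significant,
                                             function(s) m %in% s, logical(1))]
    coefs <- step3$loadings[m, comps]
    comp <- comps[which.max(abs(coefs))]
    data.frame(metabolite = m, component = comp,
               coefficient = step3$loadings[m, comp],
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(metabolite = character(0), component = character(0),
               coefficient = numeric(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Run the full four-step biomarker selection
#'
#' Orchestrates [step1_screen()], [step2_vip_stability()] (intersected with
#' the step-1 set), [step3_pca_reduce()] and [step4_intersect()], and
#' assembles a per-metabolite selection trail (VIP, loading, loading P,
#' stability fraction, component assignment, final flag).
#'
#' @inheritParams step1_screen
#' @return A `selection_result` list: the per-step results, the final
#'   selection with component assignments and the `trail` data frame.
#' @export
select_metabolites <- function(X, y = NULL, config = run_config(),
                               seed = config$seed) {
  if (inherits(X, "metabolomics_dataset")) {
    if (is.null(y)) y <- encode_group(X)
    X <- X$concentrations
  }
  if (is.character(y) || is.factor(y)) y <- encode_group(y)
  step1 <- step1_screen(X, y, config, seed = stage_seed(seed, "step1"))
  step2 <- step2_vip_stability(X, y, config,
                               seed = stage_seed(seed, "step2"),
                               universe = step1$selected)
  if (length(step2$selected) >= 2) {
    step3 <- step3_pca_reduce(X[, step2$selected, drop = FALSE], config)
    final <- step4_intersect(step2$selected, step3)
  } else {
    if (length(step2$selected) < 2)
      warning("fewer than two stability-validated metabolites; PCA skipped")
    step3 <- NULL
    final <- data.frame(metabolite = character(0), component = character(0),
                        coefficient = numeric(0), stringsAsFactors = FALSE)
  }
  trail <- data.frame(
    metabolite = colnames(X),
    vip = unname(step1$vip[colnames(X)]),
    loading = unname(step1$loading[colnames(X)]),
    loading_p = unname(step1$loading_p[colnames(X)]),
    stability_fraction = unname(step2$stability_fraction[colnames(X)]),
    step1_selected = colnames(X) %in% step1$selected,
    step2_selected = colnames(X) %in% step2$selected,
    component = final$component[match(colnames(X), final$metabolite)],
    coefficient = final$coefficient[match(colnames(X), final$metabolite)],
    final_selected = colnames(X) %in% final$metabolite,
    stringsAsFactors = FALSE)
  structure(list(step1 = step1, step2 = step2, step3 = step3,
                 final = final, trail = trail, config = config),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat("selection_result:\n")
  cat(sprintf("  step 1 (VIP/loading screen): %d metabolites\n",
              length(x$step1$selected)))
  cat(sprintf("  step 2 (stability filter):   %d metabolites\n",
              length(x$step2$selected)))
  if (!is.null(x$step3))
    cat(sprintf("  step 3 (PCA): %d components\n", x$step3$n_components))
  cat(sprintf("  final selection: %d metabolites\n", nrow(x$final)))
  invisible(x)
}
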