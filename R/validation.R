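#' Permutation test for model regression metrics
#'
#' Refits the model under random label permutations, recording R2Y, the
#' cross-validated Q2 and the Pearson correlation of each permuted label
#' vector with the original ("label similarity", the x-axis of the standard
#' permutation-validation plot). One-sided empirical P-values use the +1
#' correction `P = (1 + #{perm >= observed}) / (1 + n_permutations)` and
#' therefore lie in (0, 1].
#'
#' @param X Concentration-scale matrix (autoscaled internally; fold scalers
#'   are refitted per training fold when `rescale = TRUE`).
#' @param y Class labels.
#' @param spec A [model_spec()].
#' @param n_permutations Number of label permutations (>= 1).
#' @param k_folds Cross-validation folds for Q2.
#' @param seed Seed (named substreams for folds and permutations).
#' @param rescale Refit scaling inside cross-validation (default).
#' In addition to the uniformly random permutations that form the null
#' distributions, a sweep of *partial* permutations (swapping 1 to n/2
#' case/control label pairs) is recorded: their R2Y against label
#' similarity spans the whole similarity axis and is what the overfitting
#' diagnostic regresses on, mirroring the standard permutation-validation
#' plot. Partial permutations are not exchangeable draws, so they never
#' enter the P-values.
#'
#' @return A `validation_report` list: `observed_r2y`, `observed_q2`,
#'   `perm_r2y`, `perm_q2`, `perm_label_similarity`, `p_r2y`, `p_q2`, and
#'   the diagnostic sweep `diag_r2y` / `diag_similarity`.
#' @export
permutation_metric_test <- function(X, y, spec, n_permutations = 1000L,
                                    k_folds = 7L, seed = 1L, rescale = TRUE) {
  if (inherits(X, "scaled_matrix")) X <- X$values
  if (is.character(y) || is.factor(y)) y <- encode_group(y)
  stopifnot(n_permutations >= 1)
  Xs <- .scale_fit(X)$values
  # folds are drawn without looking at the labels: the same splits score the
  # observed and every permuted label vector, so the Q2 null is exchangeable
  cache <- .cv_cache(X, y, k_folds, stage_seed(seed, "metric_folds"), rescale,
                     stratified = FALSE)
  obs_model <- suppressWarnings(.fit_spec(Xs, y, spec))
  observed_r2y <- obs_model$r2y
  observed_q2 <- .q2_from_cache(cache, y, spec)
  perm_r2y <- perm_q2 <- sim <- numeric(n_permutations)
  set.seed(stage_seed(seed, "metric_perms"))
  for (b in seq_len(n_permutations)) {
    yp <- sample(y)
    perm_r2y[b] <- suppressWarnings(.fit_spec(Xs, yp, spec))$r2y
    perm_q2[b] <- .q2_from_cache(cache, yp, spec)
    sim[b] <- stats::cor(yp, y)
  }
  # partial-permutation sweep for the overfitting diagnostic: swap k label
  # pairs across groups so the similarity axis is covered from -1 to ~1
  n_diag <- max(40L, min(100L, n_permutations))
  diag_r2y <- diag_sim <- numeric(n_diag)
  ca <- which(y > 0)
  co <- which(y < 0)
  n_pairs <- min(length(ca), length(co))
  for (b in seq_len(n_diag)) {
    k <- sample.int(n_pairs, 1)
    yp <- y
    swap_ca <- sample(ca, k)
    swap_co <- sample(co, k)
    tmp <- yp[swap_ca]
    yp[swap_ca] <- yp[swap_co]
    yp[swap_co] <- tmp
    diag_r2y[b] <- suppressWarnings(.fit_spec(Xs, yp, spec))$r2y
    diag_sim[b] <- stats::cor(yp, y)
  }
  structure(list(observed_r2y = observed_r2y, observed_q2 = observed_q2,
                 perm_r2y = perm_r2y, perm_q2 = perm_q2,
                 perm_label_similarity = sim,
                 diag_r2y = diag_r2y, diag_similarity = diag_sim,
                 p_r2y = (1 + sum(perm_r2y >= observed_r2y)) /
                   (1 + n_permutations),
                 p_q2 = (1 + sum(perm_q2 >= observed_q2)) /
                   (1 + n_permutations),
                 n_permutations = n_permutations, spec = spec),
            class = "validation_report")
}

#' Overfitting diagnostic from a permutation report
#'
#' A healthy model degrades when labels are permuted: permuted R2Y values
#' should fall below the observed fit, and the further a permuted label
#' vector is from the original the lower its R2Y should be. The model is
#' flagged `"overfit"` when the fraction of permutations reaching the
#' observed R2Y exceeds 0.05, or when permuted R2Y does not increase with
#' label similarity (correlation <= 0) - i.e. random labels are fitted about
#' as well as the real ones. The similarity trend is evaluated on the
#' partial-permutation sweep of the report; because the fit is invariant to
#' a global sign flip of the labels, the trend is computed against
#' `|similarity|`.
#'
#' @param report A `validation_report` from [permutation_metric_test()].
#' @return List with `verdict` ("ok"/"overfit"), the exceedance fraction and
#'   the R2Y-vs-similarity correlation.
#' @export
overfit_diagnostic <- function(report) {
  stopifnot(inherits(report, "validation_report"))
  if (length(report$perm_r2y) == 0) stop("empty permutation distribution")
  frac <- mean(report$perm_r2y >= report$observed_r2y)
  r2y <- if (!is.null(report$diag_r2y)) report$diag_r2y else report$perm_r2y
  sim <- if (!is.null(report$diag_similarity)) report$diag_similarity else
    report$perm_label_similarity
  rho <- suppressWarnings(stats::cor(abs(sim), r2y))
  if (is.na(rho)) rho <- 0
  list(verdict = if (frac > 0.05 || rho <= 0) "overfit" else "ok",
       frac_r2y_ge_observed = frac,
       r2y_similarity_cor = rho)
}

#' Bootstrap model P-value
#'
#' Resamples subjects with replacement (stratified by group), refits the
#' model and records the cross-validated Q2 of each replicate, giving the
#' resampling distribution of the model's predictability. Because
#' duplicated subjects must never sit on both sides of a validation split,
#' fold assignment is done over the unique subjects of a replicate and
#' every duplicate inherits its subject's fold. The model P-value is the
#' share of a permutation-null Q2 distribution at or above the observed Q2
#' (with the +1 correction), which is exactly calibrated under the null by
#' exchangeability; the bootstrap distribution and its percentile interval
#' quantify how stable the observed Q2 is under subject resampling.
#' (Thresholding the null at the bootstrap median instead double-counts
#' resampling pessimism - duplicate-aware resample cross-validation is
#' biased low - and measurably miscalibrates the null, so it is not used.)
#'
#' @inheritParams permutation_metric_test
#' @param n_bootstrap Bootstrap replicates (>= 100).
#' @param perm_q2 Optional permutation-null Q2 vector (reused from
#'   [permutation_metric_test()]); computed internally when `NULL`.
#' @param observed_q2 The observed cross-validated Q2 matching `perm_q2`;
#'   computed internally when either is `NULL`.
#' @param n_permutations Permutations for the internal null when `perm_q2`
#'   is not supplied.
#' @return List with `p_model`, `boot_q2`, its 95% percentile interval
#'   `boot_ci`, the `observed_q2` and the null `perm_q2`.
#' @export
bootstrap_model_pvalue <- function(X, y, spec, n_bootstrap = 500L,
                                   seed = 1L, k_folds = 7L,
                                   perm_q2 = NULL, observed_q2 = NULL,
                                   n_permutations = 200L,
                                   rescale = TRUE) {
  if (inherits(X, "scaled_matrix")) X <- X$values
  if (is.character(y) || is.factor(y)) y <- encode_group(y)
  if (n_bootstrap < 100) stop("'n_bootstrap' must be at least 100")
  if (is.null(perm_q2) || is.null(observed_q2)) {
    rep <- permutation_metric_test(X, y, spec, n_permutations,
                                   k_folds, seed, rescale)
    perm_q2 <- rep$perm_q2
    observed_q2 <- rep$observed_q2
  }
  idx_by_group <- split(seq_along(y), y)
  set.seed(stage_seed(seed, "bootstrap_model"))
  boot_q2 <- numeric(n_bootstrap)
  for (b in seq_len(n_bootstrap)) {
    for (try in 1:20) {
      draw <- unlist(lapply(idx_by_group, function(ix)
        sample(ix, length(ix), replace = TRUE)), use.names = FALSE)
      uniq <- unique(draw)
      if (length(unique(y[uniq])) == 2L && length(uniq) >= 2 * k_folds) break
      if (try == 20) stop("could not draw a two-class bootstrap replicate")
    }
    fold_of <- integer(length(uniq))
    for (cl in unique(y[uniq])) {
      u <- sample(which(y[uniq] == cl))
      fold_of[u] <- rep_len(seq_len(k_folds), length(u))
    }
    fold <- fold_of[match(draw, uniq)]
    yb <- y[draw]
    press <- 0
    for (f in seq_len(k_folds)) {
      tr <- draw[fold != f]
      te <- draw[fold == f]
      if (length(te) == 0 || length(unique(y[tr])) < 2L) next
      if (rescale) {
        sc <- .scale_fit(X[tr, , drop = FALSE])
        Xtr <- sc$values
        Xte <- .scale_transform(sc, X[te, , drop = FALSE])
      } else {
        Xtr <- X[tr, , drop = FALSE]
        Xte <- X[te, , drop = FALSE]
      }
      m <- suppressWarnings(.fit_spec(Xtr, y[tr], spec))
      press <- press + sum((y[te] - predict(m, Xte))^2)
    }
    boot_q2[b] <- 1 - press / sum((yb - mean(yb))^2)
  }
  list(p_model = (1 + sum(perm_q2 >= observed_q2)) / (1 + length(perm_q2)),
       boot_q2 = boot_q2,
       boot_ci = stats::quantile(boot_q2, c(0.025, 0.975), names = FALSE),
       observed_q2 = observed_q2, perm_q2 = perm_q2)
}

#' Per-metabolite loading permutation test
#'
#' Builds the null distribution of each metabolite's predictive loading (the
#' x-loading of the first predictive component) under label permutation and
#' returns two-tailed empirical P-values
#' `(1 + #{|perm| >= |observed|}) / (1 + n_permutations)`.
#'
#' @inheritParams permutation_metric_test
#' @return List with `loading` (observed predictive loadings) and `p_value`
#'   (two-tailed empirical P per metabolite).
#' @export
loading_permutation_test <- function(X, y, spec, n_permutations = 1000L,
                                     seed = 1L) {
  if (inherits(X, "scaled_matrix")) X <- X$values
  if (is.character(y) || is.factor(y)) y <- encode_group(y)
  stopifnot(n_permutations >= 1)
  Xs <- .scale_fit(X)$values
  obs <- suppressWarnings(.fit_spec(Xs, y, spec))$loadings[, 1]
  cnt <- numeric(length(obs))
  set.seed(stage_seed(seed, "perm_loading"))
  for (b in seq_len(n_permutations)) {
    yp <- sample(y)
    lp <- suppressWarnings(.fit_spec(Xs, yp, spec))$loadings[, 1]
    cnt <- cnt + (abs(lp) >= abs(obs))
  }
  p <- (1 + cnt) / (1 + n_permutations)
  names(p) <- names(obs) <- colnames(Xs)
  list(loading = obs, p_value = p, n_permutations = n_permutations)
}

# Mann-Whitney identity: AUC = (R1 - n1(n1+1)/2) / (n1 n0) with mid-ranks,
# so ties count one half
.auc_rank <- function(scores, is_case) {
  n1 <- sum(is_case)
  n0 <- sum(!is_case)
  r <- rank(scores)
  (sum(r[is_case]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC AUC with a percentile bootstrap confidence interval
#'
#' AUC is computed by the rank (Mann-Whitney) identity, so it equals the
#' probability that a random case scores above a random control with ties
#' counted one half. The confidence interval is a stratified percentile
#' bootstrap over subjects.
#'
#' @param scores Per-sample real scores (higher = more case-like).
#' @param labels Class labels (both classes must be present).
#' @param n_bootstrap Bootstrap replicates; 0 skips the interval.
#' @param seed Seed for the bootstrap.
#' @param conf_level Confidence level (default 0.95).
#' @return List with `auc`, `ci_lower`, `ci_upper` and the bootstrap AUC
#'   distribution.
#' @export
roc_auc_bootstrap <- function(scores, labels, n_bootstrap = 2000L,
                              seed = 1L, conf_level = 0.95) {
  if (is.character(labels) || is.factor(labels)) labels <- encode_group(labels)
  is_case <- labels > 0
  if (!any(is_case) || all(is_case)) stop("both classes must be present")
  if (!all(is.finite(scores))) stop("scores must be finite")
  auc <- .auc_rank(scores, is_case)
  if (n_bootstrap < 1)
    return(list(auc = auc, ci_lower = NA_real_, ci_upper = NA_real_,
                boot_auc = numeric(0)))
  ca <- which(is_case)
  co <- which(!is_case)
  set.seed(stage_seed(seed, "roc_boot"))
  boot <- vapply(seq_len(n_bootstrap), function(b) {
    idx <- c(sample(ca, length(ca), replace = TRUE),
             sample(co, length(co), replace = TRUE))
    .auc_rank(scores[idx], is_case[idx])
  }, numeric(1))
  qs <- stats::quantile(boot, c((1 - conf_level) / 2, 1 - (1 - conf_level) / 2),
                        names = FALSE)
  list(auc = auc, ci_lower = qs[1], ci_upper = qs[2], boot_auc = boot)
}
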