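#' Spearman rank correlation with a t-approximation P-value
#'
#' Rank correlation with mid-rank ties; the two-tailed P-value uses the
#' t-distribution approximation `t = r sqrt((n-2)/(1-r^2))` with n-2
#' degrees of freedom, adequate at the cohort sizes the screen targets.
#'
#' @param x,y Numeric vectors of equal length >= 4, finite, non-constant.
#' @return List with `r`, `p` and `n`.
#' @export
spearman_cor <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 4)
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("inputs must be finite")
  if (stats::sd(x) < 1e-15 || stats::sd(y) < 1e-15)
    stop("constant input: Spearman correlation undefined")
  n <- length(x)
  r <- stats::cor(rank(x), rank(y))
  den <- 1 - r^2
  p <- if (den < 1e-15) 0 else {
    tstat <- r * sqrt((n - 2) / den)
    2 * stats::pt(-abs(tstat), n - 2)
  }
  list(r = r, p = p, n = n)
}

#' Group-stratified age screen of principal-component scores
#'
#' For each principal component and each group, the Spearman correlation of
#' the component score with age is computed; a group counts as correlated
#' when `|r| > spearman_r_threshold` and `P < alpha / N_pca` (Bonferroni
#' over the components). Each component is then classified as
#' `"case-only"`, `"control-only"`, `"both"` or `"neither"`; the class
#' records which group correlates, not the correlation sign. Groups with
#' fewer than 4 subjects yield `"neither"` with a warning.
#'
#' @param scores Numeric matrix of component scores (samples x components),
#'   columns named, e.g. from [step3_pca_reduce()].
#' @param group Per-sample group labels.
#' @param age Per-sample age in years.
#' @param config A [run_config()] (uses `alpha` and
#'   `spearman_r_threshold`).
#' @return Data frame of class `component_age_profile`, one row per
#'   component.
#' @export
component_age_screen <- function(scores, group, age, config = run_config()) {
  stopifnot(is.matrix(scores), ncol(scores) >= 1,
            nrow(scores) == length(age))
  group <- normalize_group(group)
  k <- ncol(scores)
  thr_p <- config$alpha / k
  if (is.null(colnames(scores))) colnames(scores) <- paste0("f", seq_len(k))
  rows <- lapply(colnames(scores), function(cn) {
    res <- list()
    for (g in c("case", "control")) {
      idx <- which(group == g)
      if (length(idx) < 4) {
        warning("group '", g, "' has fewer than 4 subjects; component '",
                cn, "' classified as neither")
        res[[g]] <- list(r = NA_real_, p = NA_real_, n = length(idx))
      } else {
        res[[g]] <- spearman_cor(scores[idx, cn], age[idx])
      }
    }
    corr <- vapply(res, function(z)
      !is.na(z$r) && abs(z$r) > config$spearman_r_threshold && z$p < thr_p,
      logical(1))
    cls <- if (corr[["case"]] && corr[["control"]]) "both"
      else if (corr[["case"]]) "case-only"
      else if (corr[["control"]]) "control-only"
      else "neither"
    data.frame(component = cn,
               r_case = res$case$r, p_case = res$case$p,
               r_control = res$control$r, p_control = res$control$p,
               n_case = res$case$n, n_control = res$control$n,
               classification = cls, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("component_age_profile", "data.frame")
  out
}

#' Verify metabolite-level age correlations against component behavior
#'
#' Confirmatory check that each finally selected metabolite repeats, at the
#' concentration level, the age behavior of the principal component it is
#' assigned to: its within-group Spearman correlations with age must be
#' significant (unadjusted `alpha`) exactly in the groups where the
#' component is classified as age-correlated, and the correlation sign must
#' equal `sign(coefficient) * sign(component r)` in those groups.
#'
#' @param final Data frame from [step4_intersect()] (metabolite, component,
#'   coefficient).
#' @param dataset The `metabolomics_dataset` (post-exclusion).
#' @param profiles A `component_age_profile` from [component_age_screen()].
#' @param config A [run_config()].
#' @return Data frame with per-metabolite correlations, significance flags
#'   and the `consistent` verdict.
#' @export
verify_metabolite_age_consistency <- function(final, dataset, profiles,
                                              config = run_config()) {
  stopifnot(nrow(final) >= 1)
  group <- dataset$group
  age <- dataset$age
  rows <- lapply(seq_len(nrow(final)), function(i) {
    m <- final$metabolite[i]
    comp <- final$component[i]
    xs <- as.numeric(scale(dataset$concentrations[, m]))
    res <- list()
    for (g in c("case", "control")) {
      idx <- which(group == g)
      res[[g]] <- tryCatch(spearman_cor(xs[idx], age[idx]),
                           error = function(e)
                             list(r = NA_real_, p = NA_real_, n = length(idx)))
    }
    sig <- vapply(res, function(z) !is.na(z$p) && z$p < config$alpha,
                  logical(1))
    prof <- profiles[profiles$component == comp, ]
    expect_case <- prof$classification %in% c("case-only", "both")
    expect_ctrl <- prof$classification %in% c("control-only", "both")
    pattern_ok <- (sig[["case"]] == expect_case) &&
      (sig[["control"]] == expect_ctrl)
    sign_ok <- TRUE
    if (expect_case && sig[["case"]])
      sign_ok <- sign_ok &&
        sign(res$case$r) == sign(final$coefficient[i]) * sign(prof$r_case)
    if (expect_ctrl && sig[["control"]])
      sign_ok <- sign_ok &&
        sign(res$control$r) == sign(final$coefficient[i]) * sign(prof$r_control)
    data.frame(metabolite = m, component = comp,
               coefficient = final$coefficient[i],
               r_case = res$case$r, p_case = res$case$p,
               r_control = res$control$r, p_control = res$control$p,
               sig_case = sig[["case"]], sig_control = sig[["control"]],
               classification = prof$classification,
               consistent = pattern_ok && sign_ok,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
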