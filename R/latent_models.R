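#' Describe a latent model to be fitted
#'
#' A lightweight specification consumed by the cross-validation, permutation
#' and resampling machinery, which must refit the same model many times.
#'
#' @param kind `"plsda"` or `"opls"`.
#' @param n_components PLS-DA component count (ignored for OPLS).
#' @param n_predictive,n_orthogonal OPLS component counts (ignored for
#'   PLS-DA).
#' @return A `model_spec` object.
#' @export
model_spec <- function(kind = c("opls", "plsda"), n_components = 3L,
                       n_predictive = 1L, n_orthogonal = 3L) {
  kind <- match.arg(kind)
  structure(list(kind = kind, n_components = as.integer(n_components),
                 n_predictive = as.integer(n_predictive),
                 n_orthogonal = as.integer(n_orthogonal)),
            class = "model_spec")
}

.fit_spec <- function(X, y, spec) {
  switch(spec$kind,
         plsda = fit_plsda(X, y, spec$n_components),
         opls = fit_opls(X, y, spec$n_predictive, spec$n_orthogonal),
         stop("unknown model kind: ", spec$kind))
}

# Sequential extraction of PLS1 components (single response). With one
# response the NIPALS inner loop converges in a single pass, so each
# component is computed in closed form: w = X'y normalized, t = Xw,
# p = X't/(t't), q = y't/(t't), then X is deflated by t p'. y is not
# deflated (standard single-response simplification; predictions are
# identical). Each component is sign-fixed so its largest-magnitude
# x-loading is positive.
.pls_core <- function(X, y0, ncomp, tol = 1e-12) {
  n <- nrow(X)
  p <- ncol(X)
  W <- P <- matrix(0, p, 0)
  Tm <- matrix(0, n, 0)
  q <- tt <- numeric(0)
  Xd <- X
  for (a in seq_len(ncomp)) {
    w <- crossprod(Xd, y0)
    nw <- sqrt(sum(w^2))
    if (!is.finite(nw) || nw < tol) break
    w <- w / nw
    t <- Xd %*% w
    tsq <- sum(t^2)
    if (tsq < tol) break
    pv <- crossprod(Xd, t) / tsq
    qa <- sum(y0 * t) / tsq
    jmax <- which.max(abs(pv))
    if (pv[jmax] < 0) {
      w <- -w; t <- -t; pv <- -pv; qa <- -qa
    }
    Xd <- Xd - tcrossprod(t, pv)
    W <- cbind(W, w)
    P <- cbind(P, pv)
    Tm <- cbind(Tm, t)
    q <- c(q, qa)
    tt <- c(tt, tsq)
  }
  list(W = W, P = P, T = Tm, q = q, tt = tt)
}

.finish_model <- function(kind, core, X_for_fit, y, y_mean, n_orthogonal,
                          Wo, Po, To, feature_names) {
  A <- ncol(core$W)
  if (A == 0) stop("no latent component could be extracted")
  b <- core$W %*% solve(crossprod(core$P, core$W), core$q)
  fitted <- drop(X_for_fit %*% b) + y_mean
  ss_tot <- sum((y - y_mean)^2)
  r2y <- 1 - sum((y - fitted)^2) / ss_tot
  rownames(b) <- feature_names
  dimnames(core$W) <- dimnames(core$P) <- list(feature_names, NULL)
  model <- structure(
    list(kind = kind,
         n_predictive = A,
         n_orthogonal = n_orthogonal,
         weights = core$W, loadings = core$P, y_loadings = core$q,
         scores = core$T, score_ss = core$tt,
         orthogonal_weights = Wo, orthogonal_loadings = Po,
         orthogonal_scores = To,
         coefficients = b, y_mean = y_mean,
         fitted = fitted, r2y = r2y, q2 = NA_real_,
         feature_names = feature_names),
    class = "latent_model")
  model$vip <- vip(model)
  model
}

.check_xy <- function(X, y) {
  if (inherits(X, "scaled_matrix")) X <- X$values
  stopifnot(is.matrix(X), is.numeric(X))
  if (is.character(y) || is.factor(y)) y <- encode_group(y)
  y <- as.numeric(y)
  if (length(y) != nrow(X)) stop("'y' must have one value per row of X")
  if (nrow(X) < 4) stop("at least 4 samples are required")
  if (stats::sd(y) < 1e-12) stop("zero-variance response")
  list(X = X, y = y)
}

#' Fit a PLS-DA model by NIPALS
#'
#' Single-response partial least squares discriminant analysis on an
#' autoscaled matrix with a +1/-1 class encoding, extracting components that
#' maximize covariance between predictor scores and the class label.
#' Requesting more components than the predictor rank supports truncates the
#' model with a warning.
#'
#' @param X Autoscaled numeric matrix (or `scaled_matrix`), samples x
#'   metabolites.
#' @param y Class labels: +1/-1 vector, or case/control labels.
#' @param n_components Number of components to extract.
#' @return A `latent_model` with weights, loadings, scores, regression
#'   coefficients, training `r2y` and the VIP vector.
#' @export
fit_plsda <- function(X, y, n_components = 3L) {
  xy <- .check_xy(X, y)
  y_mean <- mean(xy$y)
  core <- .pls_core(xy$X, xy$y - y_mean, n_components)
  if (ncol(core$W) < n_components)
    warning(sprintf("requested %d components, extracted %d (rank limit)",
                    n_components, ncol(core$W)))
  .finish_model("plsda", core, xy$X, xy$y, y_mean, 0L,
                NULL, NULL, NULL, colnames(xy$X))
}

#' Fit an OPLS model by NIPALS with orthogonal signal correction
#'
#' Splits predictor variation into a label-predictive part and orthogonal
#' components uncorrelated with the class label. Each orthogonal round
#' computes the PLS weight `w` and loading `p`, takes the part of `p`
#' orthogonal to `w` as the orthogonal weight, and deflates the predictors by
#' the resulting orthogonal component; the predictive PLS model is then
#' fitted on the filtered matrix. By construction every orthogonal score
#' satisfies `t_o' y = 0` exactly. If no orthogonal variation is left the
#' loop stops early and the realized `n_orthogonal` is recorded.
#'
#' @inheritParams fit_plsda
#' @param n_predictive Predictive components.
#' @param n_orthogonal Orthogonal components (0 reduces to [fit_plsda()]).
#' @param tol Floor on the orthogonal weight norm.
#' @return A `latent_model`; prediction of new samples applies the stored
#'   orthogonal filtering before the predictive regression.
#' @export
fit_opls <- function(X, y, n_predictive = 1L, n_orthogonal = 3L,
                     tol = 1e-10) {
  xy <- .check_xy(X, y)
  stopifnot(n_orthogonal >= 0)
  y_mean <- mean(xy$y)
  y0 <- xy$y - y_mean
  Xf <- xy$X
  p <- ncol(Xf)
  Wo <- Po <- matrix(0, p, 0)
  To <- matrix(0, nrow(Xf), 0)
  for (i in seq_len(n_orthogonal)) {
    w <- crossprod(Xf, y0)
    w <- w / sqrt(sum(w^2))
    t <- Xf %*% w
    pv <- crossprod(Xf, t) / sum(t^2)
    wo <- pv - drop(crossprod(w, pv)) * w
    nwo <- sqrt(sum(wo^2))
    if (!is.finite(nwo) || nwo < tol) {
      warning(sprintf("orthogonal variation exhausted after %d component(s)",
                      i - 1L))
      break
    }
    wo <- wo / nwo
    to <- Xf %*% wo
    po <- crossprod(Xf, to) / sum(to^2)
    jmax <- which.max(abs(po))
    if (po[jmax] < 0) {
      wo <- -wo; to <- -to; po <- -po
    }
    Xf <- Xf - tcrossprod(to, po)
    Wo <- cbind(Wo, wo)
    Po <- cbind(Po, po)
    To <- cbind(To, to)
  }
  core <- .pls_core(Xf, y0, n_predictive)
  if (ncol(core$W) < n_predictive)
    warning(sprintf("requested %d predictive components, extracted %d",
                    n_predictive, ncol(core$W)))
  dimnames(Wo) <- dimnames(Po) <- list(colnames(xy$X), NULL)
  .finish_model("opls", core, Xf, xy$y, y_mean, ncol(Wo),
                Wo, Po, To, colnames(xy$X))
}

#' @export
print.latent_model <- function(x, ...) {
  cat(sprintf("%s model: %d predictive, %d orthogonal component(s)\n",
              toupper(x$kind), x$n_predictive, x$n_orthogonal))
  cat(sprintf("  R2Y = %.3f%s\n", x$r2y,
              if (is.na(x$q2)) "" else sprintf(", Q2 = %.3f", x$q2)))
  invisible(x)
}

#' Predict class scores for new samples
#'
#' Applies the model's stored orthogonal filtering (OPLS only) and the
#' predictive regression coefficients. `newdata` must be scaled with the
#' training centers and scales (see [scale_apply()]).
#'
#' @param object A `latent_model`.
#' @param newdata Scaled numeric matrix with the training columns.
#' @param ... Unused.
#' @return Numeric vector of predicted scores (around +1 for cases, -1 for
#'   controls).
#' @export
predict.latent_model <- function(object, newdata, ...) {
  stopifnot(is.matrix(newdata))
  if (!is.null(colnames(newdata)) && !is.null(object$feature_names) &&
      !identical(colnames(newdata), object$feature_names)) {
    miss <- setdiff(object$feature_names, colnames(newdata))
    if (length(miss)) stop("newdata lacks column(s): ", paste(miss, collapse = ", "))
    newdata <- newdata[, object$feature_names, drop = FALSE]
  }
  if (object$n_orthogonal > 0) {
    for (i in seq_len(ncol(object$orthogonal_weights))) {
      to <- newdata %*% object$orthogonal_weights[, i, drop = FALSE]
      newdata <- newdata -
        tcrossprod(to, object$orthogonal_loadings[, i, drop = FALSE])
    }
  }
  drop(newdata %*% object$coefficients) + object$y_mean
}

#' Variable influence on projection (VIP)
#'
#' `VIP_j = sqrt(p * sum_a SSY_a w_ja^2 / sum_a SSY_a)` over the predictive
#' components, with `SSY_a` the response variance explained by component `a`
#' and `w_a` the unit-norm weight vectors; the mean squared VIP equals 1 by
#' construction. For OPLS only predictive components enter, so VIP measures
#' discrimination importance.
#'
#' @param model A fitted `latent_model`.
#' @return Named nonnegative vector, one entry per metabolite.
#' @export
vip <- function(model) {
  stopifnot(inherits(model, "latent_model"), model$n_predictive >= 1)
  ssy <- model$y_loadings^2 * model$score_ss
  if (sum(ssy) <= 0) stop("zero explained response variance")
  p <- nrow(model$weights)
  v <- sqrt(p * drop(model$weights^2 %*% ssy) / sum(ssy))
  names(v) <- model$feature_names
  v
}

# stratified fold assignment; retries until every training fold contains
# both classes (possible single-class folds arise only when k exceeds the
# minority class size)
.stratified_folds <- function(y, k, seed, max_tries = 25L) {
  n <- length(y)
  stopifnot(k >= 2, k <= n)
  if (k == n) return(seq_len(n))  # leave-one-out
  for (try in seq_len(max_tries)) {
    set.seed(stage_seed(seed + try - 1L, "folds"))
    fold <- integer(n)
    for (cl in unique(y)) {
      idx <- sample(which(y == cl))
      fold[idx] <- rep_len(sample.int(k), length(idx))
    }
    ok <- all(vapply(seq_len(k), function(f)
      length(unique(y[fold != f])) == 2L, logical(1)))
    if (ok) {
      if (try > 1) warning("refolded to avoid a single-class training fold")
      return(fold)
    }
  }
  stop("could not build folds with both classes in every training part")
}

.cv_cache <- function(X, y, k_folds, seed, rescale, stratified = TRUE) {
  fold <- if (stratified) {
    .stratified_folds(y, k_folds, seed)
  } else {
    # label-independent folds: required for exact exchangeability when the
    # same folds score both observed and permuted labels
    set.seed(stage_seed(seed, "plain_folds"))
    sample(rep_len(seq_len(k_folds), length(y)))
  }
  lapply(seq_len(k_folds), function(f) {
    te <- which(fold == f)
    tr <- which(fold != f)
    if (rescale) {
      sc <- .scale_fit(X[tr, , drop = FALSE])
      list(tr = tr, te = te, Xtr = sc$values,
           Xte = .scale_transform(sc, X[te, , drop = FALSE]))
    } else {
      list(tr = tr, te = te, Xtr = X[tr, , drop = FALSE],
           Xte = X[te, , drop = FALSE])
    }
  })
}

.q2_from_cache <- function(cache, y, spec) {
  press <- 0
  for (f in cache) {
    m <- suppressWarnings(.fit_spec(f$Xtr, y[f$tr], spec))
    press <- press + sum((y[f$te] - predict(m, f$Xte))^2)
  }
  1 - press / sum((y - mean(y))^2)
}

#' Cross-validated predictability Q2
#'
#' Stratified K-fold cross-validation: for each fold the model (and, by
#' default, the autoscaling) is refitted on the training part and the
#' held-out samples are predicted; `Q2 = 1 - PRESS / SS` with
#' `PRESS = sum_i (y_i - yhat_(-i))^2` and `SS = sum_i (y_i - ybar)^2`.
#'
#' @param X Numeric matrix on the concentration scale (or already scaled if
#'   `rescale = FALSE`).
#' @param y Class labels.
#' @param spec A [model_spec()].
#' @param k_folds Number of folds (between 2 and n).
#' @param seed Seed for the fold draw.
#' @param rescale Refit autoscaling on each training fold (default), the
#'   leakage-free construction.
#' @return Q2 as a single number (can be negative for models that predict
#'   worse than the mean).
#' @export
q2_crossval <- function(X, y, spec, k_folds = 7L, seed = 1L, rescale = TRUE) {
  if (inherits(X, "scaled_matrix")) X <- X$values
  if (is.character(y) || is.factor(y)) y <- encode_group(y)
  stopifnot(k_folds >= 2, k_folds <= nrow(X))
  cache <- .cv_cache(X, y, k_folds, seed, rescale)
  .q2_from_cache(cache, y, spec)
}
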