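#' Remove named metabolites from a dataset
#'
#' Exact matching on metabolite identifiers; names not present in the panel
#' are reported with a warning and otherwise ignored. Used up front to drop
#' therapy-related analytes before any modeling.
#'
#' @param dataset A `metabolomics_dataset`.
#' @param exclusion_list Character vector of metabolite identifiers.
#' @return The dataset without the named columns.
#' @export
exclude_metabolites <- function(dataset, exclusion_list) {
  exclusion_list <- as.character(exclusion_list)
  if (length(exclusion_list) == 0) return(dataset)
  present <- intersect(exclusion_list, metabolite_ids(dataset))
  absent <- setdiff(exclusion_list, present)
  if (length(absent))
    warning("exclusion name(s) not in panel: ", paste(absent, collapse = ", "))
  if (length(present) == 0) return(dataset)
  message(sprintf("excluding %d metabolite(s)", length(present)))
  subset_dataset(dataset,
                 metabolites = setdiff(metabolite_ids(dataset), present))
}

#' Autoscale a concentration matrix
#'
#' Column-wise standardization to zero mean and unit variance (sample
#' standard deviation, denominator n-1), the pre-analysis transform applied
#' to every matrix entering the latent-variable models. The fitted centers
#' and scales are stored so the identical transform can be applied to
#' held-out samples with [scale_apply()] and inverted with [scale_invert()].
#' Columns with (numerically) zero variance are dropped with a warning.
#'
#' @param x Numeric matrix (samples x metabolites) or a
#'   `metabolomics_dataset`.
#' @return An object of class `scaled_matrix` with fields `values`,
#'   `column_means`, `column_sds` and `dropped`.
#' @export
autoscale <- function(x) {
  if (inherits(x, "metabolomics_dataset")) x <- x$concentrations
  stopifnot(is.matrix(x), is.numeric(x), nrow(x) >= 2)
  ctr <- colMeans(x)
  sds <- apply(x, 2, stats::sd)
  drop <- !is.finite(sds) | sds < 1e-12
  if (any(drop))
    warning(sprintf("dropping %d constant column(s): %s", sum(drop),
                    paste(colnames(x)[drop], collapse = ", ")))
  keep <- !drop
  vals <- sweep(sweep(x[, keep, drop = FALSE], 2, ctr[keep]), 2, sds[keep], "/")
  structure(list(values = vals, column_means = ctr[keep],
                 column_sds = sds[keep],
                 dropped = colnames(x)[drop]),
            class = "scaled_matrix")
}

#' Apply a fitted autoscaling to new samples
#' @param sc A `scaled_matrix` from [autoscale()].
#' @param newdata Numeric matrix with the same columns as the training data.
#' @return Scaled numeric matrix.
#' @export
scale_apply <- function(sc, newdata) {
  stopifnot(inherits(sc, "scaled_matrix"), is.matrix(newdata))
  cols <- names(sc$column_means)
  if (!is.null(colnames(newdata)) && !is.null(cols)) {
    miss <- setdiff(cols, colnames(newdata))
    if (length(miss)) stop("newdata lacks column(s): ", paste(miss, collapse = ", "))
    newdata <- newdata[, cols, drop = FALSE]
  }
  sweep(sweep(newdata, 2, sc$column_means), 2, sc$column_sds, "/")
}

#' Invert an autoscaling
#' @param sc A `scaled_matrix`.
#' @param values Scaled matrix (defaults to `sc$values`).
#' @return Matrix on the original concentration scale.
#' @export
scale_invert <- function(sc, values = sc$values) {
  stopifnot(inherits(sc, "scaled_matrix"))
  sweep(sweep(values, 2, sc$column_sds, "*"), 2, sc$column_means, "+")
}

# fast internal scaler for resampling loops: keeps all columns, flooring
# zero variances to 1 so matrix dimensions stay fixed across folds
.scale_fit <- function(x) {
  n <- nrow(x)
  ctr <- colMeans(x)
  v <- colSums(sweep(x, 2, ctr)^2) / (n - 1)
  s <- sqrt(v)
  s[!is.finite(s) | s < 1e-12] <- 1
  list(values = sweep(sweep(x, 2, ctr), 2, s, "/"), center = ctr, scale = s)
}

.scale_transform <- function(sc, newdata) {
  sweep(sweep(newdata, 2, sc$center), 2, sc$scale, "/")
}

#' Welch t-tests of metadata variables between groups
#'
#' Two-tailed Welch two-sample t-test of each numeric per-sample variable
#' (age plus any extra metadata columns) between cases and controls; the
#' standard cohort-balance check run before modeling.
#'
#' @param dataset A `metabolomics_dataset`.
#' @param variables Character vector of variable names; defaults to `"age"`
#'   plus every numeric column of the dataset's metadata.
#' @return Data frame with one row per variable: group means, Welch `t`,
#'   degrees of freedom and two-tailed `P`.
#' @export
metadata_group_tests <- function(dataset, variables = NULL) {
  values <- data.frame(age = dataset$age)
  if (!is.null(dataset$metadata)) {
    num <- vapply(dataset$metadata, is.numeric, logical(1))
    values <- cbind(values, dataset$metadata[, num, drop = FALSE])
  }
  if (is.null(variables)) variables <- names(values)
  case <- dataset$group == "case"
  rows <- list()
  for (v in variables) {
    if (!v %in% names(values)) {
      warning("unknown metadata variable: ", v)
      next
    }
    x <- values[[v]][case]
    y <- values[[v]][!case]
    x <- x[is.finite(x)]
    y <- y[is.finite(y)]
    if (length(x) < 2 || length(y) < 2) {
      warning("variable '", v, "' skipped: fewer than 2 values in a group")
      next
    }
    tt <- stats::t.test(x, y)
    rows[[v]] <- data.frame(variable = v, n_case = length(x),
                            n_control = length(y),
                            mean_case = mean(x), mean_control = mean(y),
                            t = unname(tt$statistic),
                            df = unname(tt$parameter),
                            p = tt$p.value, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
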