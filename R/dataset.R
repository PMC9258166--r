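#' Construct a metabolomics dataset
#'
#' Container for a samples-by-metabolites concentration matrix together with
#' the per-sample metadata (case/control group, age) and per-metabolite
#' biochemical class annotation used throughout the pipeline.
#'
#' @param concentrations Numeric matrix, samples in rows and metabolites in
#'   columns, with unique row and column names. All values must be finite and
#'   nonnegative (concentration units, e.g. micromolar).
#' @param group Per-sample group labels. `"case"`/`"PD"` and
#'   `"control"`/`"HC"` spellings are accepted (case-insensitive), as are the
#'   numeric encodings `+1`/`-1`.
#' @param age Per-sample age in years; finite and positive.
#' @param metabolite_class Optional per-metabolite class label (e.g.
#'   "Sphingomyelins", "Acylcarnitines"); defaults to `"unclassified"`.
#' @param metadata Optional data frame of additional per-sample covariates
#'   (rows aligned with samples), used by [metadata_group_tests()].
#' @return An object of class `metabolomics_dataset`.
#' @seealso [read_dataset()], [generate_dataset()]
#' @export
metabolomics_dataset <- function(concentrations, group, age,
                                 metabolite_class = NULL, metadata = NULL) {
  if (!is.matrix(concentrations) || !is.numeric(concentrations))
    stop("'concentrations' must be a numeric matrix")
  n <- nrow(concentrations)
  p <- ncol(concentrations)
  if (is.null(rownames(concentrations)) || is.null(colnames(concentrations)))
    stop("'concentrations' must carry sample row names and metabolite column names")
  if (anyDuplicated(rownames(concentrations)))
    stop("duplicated sample identifiers")
  if (anyDuplicated(colnames(concentrations)))
    stop("duplicated metabolite identifiers")
  if (!all(is.finite(concentrations)) || any(concentrations < 0))
    stop("concentrations must be finite and nonnegative")
  group <- normalize_group(group)
  if (length(group) != n) stop("'group' must have one label per sample")
  age <- as.numeric(age)
  if (length(age) != n || !all(is.finite(age)) || any(age <= 0))
    stop("every sample needs a finite positive age")
  if (is.null(metabolite_class)) {
    metabolite_class <- rep("unclassified", p)
  } else if (length(metabolite_class) != p) {
    stop("'metabolite_class' must have one entry per metabolite")
  }
  if (!is.null(metadata)) {
    metadata <- as.data.frame(metadata)
    if (nrow(metadata) != n) stop("'metadata' rows must align with samples")
    rownames(metadata) <- rownames(concentrations)
  }
  structure(
    list(concentrations = concentrations,
         group = group,
         age = age,
         metabolite_class = as.character(metabolite_class),
         metadata = metadata),
    class = "metabolomics_dataset"
  )
}

#' Normalize group labels to "case"/"control"
#'
#' @param group Vector of labels: case/control, PD/HC (any case) or +1/-1.
#' @return Character vector with values `"case"` and `"control"`.
#' @keywords internal
normalize_group <- function(group) {
  if (is.numeric(group)) {
    if (!all(group %in% c(-1, 1))) stop("numeric group labels must be +1/-1")
    return(ifelse(group > 0, "case", "control"))
  }
  g <- tolower(as.character(group))
  out <- ifelse(g %in% c("case", "pd", "patient", "+1", "1"), "case",
                ifelse(g %in% c("control", "hc", "healthy", "-1"), "control", NA))
  if (anyNA(out))
    stop("unrecognized group labels: ",
         paste(unique(group[is.na(out)]), collapse = ", "))
  out
}

#' Encode group labels as a +1/-1 response vector
#'
#' Cases (PD) map to +1 and controls (HC) to -1, the coding used by the
#' discriminant models.
#'
#' @param group Group labels in any form accepted by [metabolomics_dataset()],
#'   or a `metabolomics_dataset`.
#' @return Numeric vector of +1/-1.
#' @export
encode_group <- function(group) {
  if (inherits(group, "metabolomics_dataset")) group <- group$group
  ifelse(normalize_group(group) == "case", 1, -1)
}

#' @export
print.metabolomics_dataset <- function(x, ...) {
  cat(sprintf("metabolomics_dataset: %d samples x %d metabolites\n",
              nrow(x$concentrations), ncol(x$concentrations)))
  cat(sprintf("  cases: %d, controls: %d\n",
              sum(x$group == "case"), sum(x$group == "control")))
  cat(sprintf("  age: %.1f-%.1f years\n", min(x$age), max(x$age)))
  cat(sprintf("  metabolite classes: %d\n", length(unique(x$metabolite_class))))
  invisible(x)
}

#' Number of samples / metabolites in a dataset
#' @param dataset A `metabolomics_dataset`.
#' @return Integer count.
#' @export
n_samples <- function(dataset) nrow(dataset$concentrations)

#' @rdname n_samples
#' @export
n_metabolites <- function(dataset) ncol(dataset$concentrations)

#' @rdname n_samples
#' @export
sample_ids <- function(dataset) rownames(dataset$concentrations)

#' @rdname n_samples
#' @export
metabolite_ids <- function(dataset) colnames(dataset$concentrations)

#' Subset a dataset to a set of samples and/or metabolites
#' @param dataset A `metabolomics_dataset`.
#' @param samples,metabolites Index vectors (names, positions or logical).
#' @return A `metabolomics_dataset`.
#' @keywords internal
subset_dataset <- function(dataset, samples = NULL, metabolites = NULL) {
  if (is.null(samples)) samples <- seq_len(n_samples(dataset))
  if (is.null(metabolites)) metabolites <- seq_len(n_metabolites(dataset))
  conc <- dataset$concentrations[samples, metabolites, drop = FALSE]
  midx <- match(colnames(conc), metabolite_ids(dataset))
  sidx <- match(rownames(conc), sample_ids(dataset))
  metabolomics_dataset(
    conc,
    group = dataset$group[sidx],
    age = dataset$age[sidx],
    metabolite_class = dataset$metabolite_class[midx],
    metadata = if (is.null(dataset$metadata)) NULL else
      dataset$metadata[sidx, , drop = FALSE]
  )
}
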