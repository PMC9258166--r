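#' @keywords internal
detect_delimiter <- function(path) {
  line <- readLines(path, n = 1L, warn = FALSE)
  counts <- vapply(c("," = ",", "\t" = "\t", ";" = ";"), function(d)
    lengths(regmatches(line, gregexpr(d, line, fixed = TRUE))), integer(1))
  if (all(counts == 0)) stop("could not detect a comma/tab/semicolon delimiter in ", path)
  names(counts)[which.max(counts)]
}

NA_STRINGS <- c("", "NA", "NaN", "<LOD", "< LOD", "<lod")

#' Read a concentration table and sample metadata into a dataset
#'
#' Reads a delimited concentration table (samples in rows, metabolites in
#' columns, first column the sample identifier) and a metadata table (sample
#' identifier, `group`, `age`, plus optional numeric covariates), joins them
#' by sample identifier and returns a [metabolomics_dataset()].
#'
#' The delimiter is auto-detected among comma, tab and semicolon. Cells that
#' are empty or read `<LOD` are treated as missing; a missing cell is imputed
#' with half the minimum observed value of its metabolite, and metabolites
#' missing in more than 20% of samples are dropped with a warning. Samples
#' present in only one of the two files are reported and dropped.
#'
#' @param concentration_path Path to the concentration table.
#' @param metadata_path Path to the metadata table.
#' @param class_path Optional path to a two-column table (metabolite, class)
#'   with metabolite class annotations.
#' @return A `metabolomics_dataset`.
#' @export
read_dataset <- function(concentration_path, metadata_path, class_path = NULL) {
  for (f in c(concentration_path, metadata_path))
    if (!file.exists(f)) stop("file not found: ", f)
  conc_raw <- utils::read.table(concentration_path, header = TRUE,
                                sep = detect_delimiter(concentration_path),
                                check.names = FALSE, stringsAsFactors = FALSE,
                                na.strings = NA_STRINGS, dec = ".")
  meta_raw <- utils::read.table(metadata_path, header = TRUE,
                                sep = detect_delimiter(metadata_path),
                                check.names = FALSE, stringsAsFactors = FALSE,
                                na.strings = NA_STRINGS, dec = ".")
  if (ncol(conc_raw) < 2) stop("concentration table needs a sample column plus metabolites")
  conc_ids <- as.character(conc_raw[[1]])
  mat <- as.matrix(conc_raw[, -1, drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- conc_ids

  meta_id_col <- intersect(c("sample_id", "sample", "id"), tolower(names(meta_raw)))
  names(meta_raw) <- tolower(names(meta_raw))
  id_col <- if (length(meta_id_col)) meta_id_col[1] else names(meta_raw)[1]
  for (req in c("group", "age"))
    if (!req %in% names(meta_raw))
      stop(sprintf("metadata file lacks required column '%s'", req))
  meta_ids <- as.character(meta_raw[[id_col]])

  common <- intersect(conc_ids, meta_ids)
  if (length(common) == 0) stop("no overlapping samples between the two files")
  only_conc <- setdiff(conc_ids, meta_ids)
  only_meta <- setdiff(meta_ids, conc_ids)
  if (length(only_conc) || length(only_meta))
    warning(sprintf("dropping %d sample(s) present in only one file: %s",
                    length(only_conc) + length(only_meta),
                    paste(c(only_conc, only_meta), collapse = ", ")))
  mat <- mat[common, , drop = FALSE]
  meta <- meta_raw[match(common, meta_ids), , drop = FALSE]

  # missing-value policy: drop metabolites >20% missing, impute rest at half-minimum
  miss_frac <- colMeans(is.na(mat))
  drop <- miss_frac > 0.2
  if (any(drop)) {
    warning(sprintf("dropping %d metabolite(s) missing in >20%% of samples: %s",
                    sum(drop), paste(colnames(mat)[drop], collapse = ", ")))
    mat <- mat[, !drop, drop = FALSE]
  }
  for (j in which(colSums(is.na(mat)) > 0)) {
    obs <- mat[!is.na(mat[, j]), j]
    if (length(obs) == 0) stop("metabolite with no observed values: ", colnames(mat)[j])
    mat[is.na(mat[, j]), j] <- 0.5 * min(obs)
  }

  mclass <- NULL
  if (!is.null(class_path)) {
    cls <- utils::read.table(class_path, header = TRUE,
                             sep = detect_delimiter(class_path),
                             check.names = FALSE, stringsAsFactors = FALSE)
    mclass <- cls[[2]][match(colnames(mat), as.character(cls[[1]]))]
    mclass[is.na(mclass)] <- "unclassified"
  }
  extra <- meta[, setdiff(names(meta), c(id_col, "group", "age")), drop = FALSE]
  num <- vapply(extra, is.numeric, logical(1))
  metabolomics_dataset(mat, group = meta$group, age = meta$age,
                       metabolite_class = mclass,
                       metadata = if (any(num)) extra[, num, drop = FALSE] else NULL)
}

#' Write a dataset to delimited text files
#'
#' Inverse of [read_dataset()]: writes the concentration matrix (sample
#' identifier in the first column) and the metadata table. Numbers are written
#' with full double precision, so a write/read round trip reproduces the
#' dataset up to floating-point representation.
#'
#' @param dataset A `metabolomics_dataset`.
#' @param concentration_path,metadata_path Output file paths.
#' @param sep Field delimiter (default comma).
#' @return Invisibly, the dataset.
#' @export
write_dataset <- function(dataset, concentration_path, metadata_path, sep = ",") {
  conc <- data.frame(sample_id = sample_ids(dataset),
                     dataset$concentrations, check.names = FALSE)
  utils::write.table(conc, concentration_path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  meta <- data.frame(sample_id = sample_ids(dataset),
                     group = dataset$group, age = dataset$age,
                     check.names = FALSE)
  if (!is.null(dataset$metadata)) meta <- cbind(meta, dataset$metadata)
  utils::write.table(meta, metadata_path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(dataset)
}

#' Read pathway sets from a GMT-like file
#'
#' One set per line: name, description, then member metabolite identifiers,
#' tab-separated. Duplicate members within a set are de-duplicated; lines
#' without at least one member are skipped with a warning; repeated set names
#' are retained (with a warning) since downstream code treats sets as a list.
#'
#' @param path Path to the GMT-like file.
#' @return A list of `pathway_set` objects (fields `name`, `description`,
#'   `members`).
#' @export
read_pathway_sets <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  for (ln in lines) {
    fields <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    fields <- fields[nzchar(fields)]
    if (length(fields) < 3) {
      warning("skipping pathway line with no members: ",
              substr(ln, 1, 40))
      next
    }
    sets[[length(sets) + 1L]] <- pathway_set(fields[1], unique(fields[-(1:2)]),
                                             description = fields[2])
  }
  nm <- vapply(sets, `[[`, "", "name")
  if (anyDuplicated(nm))
    warning("duplicated pathway set name(s): ",
            paste(unique(nm[duplicated(nm)]), collapse = ", "))
  sets
}

#' Construct a pathway set
#'
#' @param name Set name.
#' @param members Character vector of member metabolite identifiers (nonempty).
#' @param description Optional free-text description.
#' @return A `pathway_set` object.
#' @export
pathway_set <- function(name, members, description = "") {
  members <- unique(as.character(members))
  if (length(members) < 1) stop("a pathway set needs at least one member")
  structure(list(name = as.character(name), description = description,
                 members = members),
            class = "pathway_set")
}

#' Write pathway sets in the GMT-like format
#' @param sets List of `pathway_set` objects.
#' @param path Output path.
#' @return Invisibly, `sets`.
#' @export
write_pathway_sets <- function(sets, path) {
  lines <- vapply(sets, function(s)
    paste(c(s$name, if (nzchar(s$description)) s$description else "-", s$members),
          collapse = "\t"), "")
  writeLines(lines, path)
  invisible(sets)
}

#' @keywords internal
as_pathway_sets <- function(sets) {
  if (inherits(sets, "pathway_set")) return(list(sets))
  if (is.list(sets) && all(vapply(sets, inherits, TRUE, "pathway_set")))
    return(sets)
  if (is.list(sets) && !is.null(names(sets)))
    return(Map(pathway_set, names(sets), sets))
  stop("'pathway_sets' must be pathway_set objects or a named list of id vectors")
}
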