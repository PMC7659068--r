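#' Construct a labeled genetic distance matrix
#'
#' Validates and normalises a square matrix of pairwise genetic distances
#' (substitutions/site): labels must be unique, the diagonal zero, entries
#' non-negative, and the matrix symmetric. Small numerical asymmetries
#' (< 1e-9) are averaged away; larger ones are an error. `NA` entries are
#' permitted and flag pairs whose distance is undefined (e.g. saturated or
#' non-overlapping fragment pairs); downstream ordination refuses them.
#'
#' @param values Square numeric matrix with matching row/column names, or
#'   unlabeled if `labels` is given.
#' @param labels Optional label vector overriding the dimnames.
#' @return A `dist_matrix`: a numeric matrix with class attribute.
#' @export
dist_matrix <- function(values, labels = NULL) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values))
    stop_format("distance matrix is not square: %d x %d", nrow(values), ncol(values))
  labels <- labels %||% rownames(values) %||% colnames(values)
  if (is.null(labels)) stop_format("distance matrix labels are required")
  labels <- as.character(labels)
  if (length(labels) != nrow(values))
    stop_format("got %d labels for a %d x %d matrix", length(labels),
                nrow(values), ncol(values))
  if (anyDuplicated(labels))
    stop_format("duplicate distance-matrix label(s): %s",
                paste(unique(labels[duplicated(labels)]), collapse = ", "))
  if (!is.null(rownames(values)) && !is.null(colnames(values))) {
    if (!identical(rownames(values), colnames(values))) {
      if (!setequal(rownames(values), colnames(values)))
        stop_format("row and column labels differ")
      values <- values[, rownames(values), drop = FALSE]
    }
  }
  storage.mode(values) <- "double"
  if (any(values < 0, na.rm = TRUE)) {
    ij <- which(values < 0, arr.ind = TRUE)[1L, ]
    stop_format("negative distance at (%s, %s)", labels[ij[1L]], labels[ij[2L]])
  }
  asym <- abs(values - t(values))
  if (any(asym > 1e-9, na.rm = TRUE)) {
    ij <- which(asym > 1e-9, arr.ind = TRUE)[1L, ]
    stop_format("asymmetric distances for (%s, %s): %g vs %g",
                labels[ij[1L]], labels[ij[2L]],
                values[ij[1L], ij[2L]], values[ij[2L], ij[1L]])
  }
  values <- (values + t(values)) / 2
  diag(values) <- 0
  dimnames(values) <- list(labels, labels)
  structure(values, class = c("dist_matrix", "matrix", "array"))
}

#' Read a labeled square distance matrix from CSV
#'
#' Expects a comma-separated file whose first row and first column carry the
#' same labels (the usual spreadsheet export of a supplementary distance
#' matrix). Row/column label order may differ; columns are realigned to the
#' row order.
#'
#' @param path Path to the CSV file.
#' @return A [dist_matrix].
#' @export
read_distance_csv <- function(path) {
  if (!file.exists(path)) stop_format("file not found: %s", path)
  tab <- utils::read.csv(path, row.names = 1, check.names = FALSE,
                         fileEncoding = "UTF-8")
  m <- as.matrix(tab)
  if (!is.numeric(m)) stop_format("non-numeric entries in '%s'", path)
  dist_matrix(m)
}

#' Write a distance matrix to CSV
#'
#' @param d A [dist_matrix].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_distance_csv <- function(d, path) {
  stopifnot(inherits(d, "dist_matrix"))
  df <- data.frame(label = rownames(d), unclass(d), check.names = FALSE)
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read an infection table with possibly ambiguous haplogroup calls
#'
#' Each row is one parasite observation: an observation id, the host taxon
#' it was found in, and one or more candidate parasite haplogroup ids. A
#' candidate set of size > 1 marks an ambiguous observation (typically a
#' short fragment missing all diagnostic sites of its group); such
#' observations are later expanded into alternative association matrices.
#'
#' @param path Path to a TSV file with header columns `observation`, `host`
#'   and `candidates`; multiple candidates are separated by `|`.
#' @return A data frame of class `infection_table` with columns
#'   `observation`, `host` and a list column `candidates`.
#' @export
read_infection_table <- function(path) {
  if (!file.exists(path)) stop_format("file not found: %s", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  infection_table(tab)
}

#' Construct an infection table from a data frame
#'
#' @param tab Data frame with columns `observation`, `host`, `candidates`
#'   (either a `|`-separated character column or a list column).
#' @return A data frame of class `infection_table`.
#' @rdname read_infection_table
#' @export
infection_table <- function(tab) {
  need <- c("observation", "host", "candidates")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols) > 0L)
    stop_format("infection table lacks column(s): %s",
                paste(missing_cols, collapse = ", "))
  obs <- as.character(tab$observation)
  if (anyDuplicated(obs))
    stop_format("duplicate observation id(s): %s",
                paste(unique(obs[duplicated(obs)]), collapse = ", "))
  cand <- tab$candidates
  if (!is.list(cand))
    cand <- strsplit(as.character(cand), "|", fixed = TRUE)
  cand <- lapply(cand, function(x) unique(trimws(as.character(x))))
  empty <- vapply(cand, function(x) length(x) == 0L || any(!nzchar(x)), logical(1))
  if (any(empty))
    stop_format("observation '%s' has an empty candidate field", obs[empty][1L])
  out <- data.frame(observation = obs, host = as.character(tab$host),
                    stringsAsFactors = FALSE)
  out$candidates <- cand
  class(out) <- c("infection_table", "data.frame")
  out
}

#' Number of ambiguous observations in an infection table
#' @param tab An `infection_table`.
#' @return Integer count of observations with more than one candidate.
#' @export
n_ambiguous <- function(tab) {
  stopifnot(inherits(tab, "infection_table"))
  sum(lengths(tab$candidates) > 1L)
}
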