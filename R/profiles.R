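#' Construct an expression profile matrix
#'
#' A profile matrix holds one numeric feature vector per entity (drug,
#' target, or non-target). For LINCS L1000-like data the feature dimension
#' is the 978 landmark genes, but any positive dimension is accepted.
#'
#' @param features numeric matrix, one row per entity.
#' @param ids character vector of unique entity identifiers; defaults to
#'   `rownames(features)`.
#' @return a `profile_matrix`: the feature matrix with `ids` as row names.
#' @examples
#' pm <- profile_matrix(matrix(rnorm(6), 2, 3), c("d1", "d2"))
#' profile_ids(pm)
#' @export
profile_matrix <- function(features, ids = rownames(features)) {
  features <- as.matrix(features)
  storage.mode(features) <- "double"
  if (is.null(ids)) {
    stop("entity ids are required (supply `ids` or row names)")
  }
  ids <- as.character(ids)
  if (length(ids) != nrow(features)) {
    stop("number of ids (", length(ids), ") does not match number of rows (",
         nrow(features), ")")
  }
  if (anyDuplicated(ids)) {
    stop("entity ids must be unique; duplicated: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  if (!all(is.finite(features))) {
    stop("all feature values must be finite")
  }
  rownames(features) <- ids
  class(features) <- c("profile_matrix", class(features))
  features
}

#' @rdname profile_matrix
#' @param pm a `profile_matrix`.
#' @export
profile_ids <- function(pm) rownames(pm)

#' Read / write profile matrices as delimited text
#'
#' Format: header row of feature names, first column the entity id,
#' remaining columns numeric features. Tab-separated by default; a `.csv`
#' extension switches to comma.
#'
#' @param path file path; the extension selects the delimiter.
#' @return `read_profiles()` returns a [profile_matrix()].
#' @export
read_profiles <- function(path) {
  if (!file.exists(path)) stop("profile file not found: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE)
  profile_matrix(as.matrix(df[, -1, drop = FALSE]), ids = df[[1]])
}

#' @rdname read_profiles
#' @param pm a [profile_matrix()].
#' @export
write_profiles <- function(pm, path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- data.frame(id = rownames(pm), unclass(pm), check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write an interaction edge list
#'
#' Two-column delimited text (drug id, target id), with a header row; any
#' further columns are ignored.
#'
#' @param path file path (TSV by default, CSV by extension).
#' @return `read_edges()` returns a two-column character data frame with
#'   columns `drug` and `target`.
#' @export
read_edges <- function(path) {
  if (!file.exists(path)) stop("edge file not found: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("edge list must have at least two columns")
  data.frame(drug = as.character(df[[1]]), target = as.character(df[[2]]),
             stringsAsFactors = FALSE)
}

#' @rdname read_edges
#' @param edges a two-column data frame (drug, target).
#' @export
write_edges <- function(edges, path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::write.table(data.frame(drug = edges[[1]], target = edges[[2]]),
                     path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}
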