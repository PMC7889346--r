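#' Build a binary drug x target interaction matrix
#'
#' Positions listed in `edges` become 1; everything else is 0. Target
#' columns that receive no positive edge at all are flagged as non-targets:
#' pairs of a drug with a non-target form the candidate negative pool from
#' which negative samples are drawn.
#'
#' @param drug_profiles,target_profiles [profile_matrix()] objects supplying
#'   the row/column id order. The target matrix covers targets and
#'   non-targets alike.
#' @param edges data frame or 2-column matrix of (drug id, target id)
#'   positive pairs. Unknown ids are an error; duplicated edges are dropped
#'   with a warning.
#' @return an `interaction_matrix`: list with `y` (m x n binary matrix with
#'   dimnames), `drug_ids`, `target_ids`, `nontarget` (logical per column),
#'   and optional `cell_line` label.
#' @param cell_line optional metadata label for the cell line the profiles
#'   were measured in.
#' @examples
#' dp <- profile_matrix(matrix(rnorm(4), 2, 2), c("d1", "d2"))
#' tp <- profile_matrix(matrix(rnorm(6), 3, 2), c("t1", "t2", "t3"))
#' im <- build_interaction_matrix(dp, tp, data.frame(drug = "d1", target = "t1"))
#' im$nontarget
#' @export
build_interaction_matrix <- function(drug_profiles, target_profiles, edges,
                                     cell_line = NULL) {
  drug_ids <- profile_ids(drug_profiles)
  target_ids <- profile_ids(target_profiles)
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  y <- matrix(0L, length(drug_ids), length(target_ids),
              dimnames = list(drug_ids, target_ids))
  if (nrow(edges) > 0) {
    di <- match(as.character(edges[[1]]), drug_ids)
    ti <- match(as.character(edges[[2]]), target_ids)
    if (anyNA(di)) {
      stop("unknown drug id(s) in edge list: ",
           paste(unique(edges[[1]][is.na(di)]), collapse = ", "))
    }
    if (anyNA(ti)) {
      stop("unknown target id(s) in edge list: ",
           paste(unique(edges[[2]][is.na(ti)]), collapse = ", "))
    }
    dup <- duplicated(cbind(di, ti))
    if (any(dup)) {
      warning(sum(dup), " duplicate edge(s) removed")
      di <- di[!dup]; ti <- ti[!dup]
    }
    y[cbind(di, ti)] <- 1L
  }
  structure(list(y = y, drug_ids = drug_ids, target_ids = target_ids,
                 nontarget = colSums(y) == 0L, cell_line = cell_line),
            class = "interaction_matrix")
}

#' Construct an interaction matrix from a prebuilt binary matrix
#'
#' Lower-level constructor used by the synthetic generator and the label
#' permutation control. Non-target flags default to the all-zero columns
#' but may be supplied explicitly (flagged columns must then be all zero).
#'
#' @param y binary m x n matrix with drug/target dimnames.
#' @param nontarget optional logical vector per column.
#' @param cell_line optional metadata label.
#' @export
interaction_matrix <- function(y, nontarget = NULL, cell_line = NULL) {
  y <- as.matrix(y)
  storage.mode(y) <- "integer"
  if (!all(y %in% c(0L, 1L))) stop("y entries must be 0 or 1")
  if (is.null(rownames(y)) || is.null(colnames(y))) {
    stop("y must carry drug ids as rownames and target ids as colnames")
  }
  if (is.null(nontarget)) {
    nontarget <- colSums(y) == 0L
  } else {
    nontarget <- as.logical(nontarget)
    if (length(nontarget) != ncol(y)) stop("nontarget flag length mismatch")
    if (any(nontarget & colSums(y) > 0L)) {
      stop("a column flagged as non-target has a positive entry")
    }
  }
  structure(list(y = y, drug_ids = rownames(y), target_ids = colnames(y),
                 nontarget = nontarget, cell_line = cell_line),
            class = "interaction_matrix")
}

#' @export
print.interaction_matrix <- function(x, ...) {
  cat("Interaction matrix:", length(x$drug_ids), "drugs x",
      length(x$target_ids), "targets/non-targets\n")
  cat("  positives:", sum(x$y), " non-targets:", sum(x$nontarget),
      " candidate negative pool:", negative_pool_size(x), "\n")
  if (!is.null(x$cell_line)) cat("  cell line:", x$cell_line, "\n")
  invisible(x)
}

#' Size of the candidate negative pool
#'
#' Number of drug x non-target pairs, i.e. number of drugs times number of
#' non-target columns.
#'
#' @param im an `interaction_matrix`.
#' @return integer-valued numeric count.
#' @export
negative_pool_size <- function(im) {
  length(im$drug_ids) * sum(im$nontarget)
}

#' Positive pairs of an interaction matrix
#'
#' @param im an `interaction_matrix`.
#' @return two-column integer matrix of (drug index, target index).
#' @export
positive_pairs <- function(im) {
  w <- which(im$y == 1L, arr.ind = TRUE)
  colnames(w) <- c("drug", "target")
  w[order(w[, 1], w[, 2]), , drop = FALSE]
}

#' Sample negative drug-target pairs from the non-target pool
#'
#' Draws uniformly, without replacement, from all drug x non-target cells.
#' By convention the number of negatives equals the number of positive
#' pairs, so ranking triples are balanced at the cell-line level.
#'
#' @param im an `interaction_matrix`.
#' @param n_negatives number of pairs to draw; defaults to the positive
#'   count.
#' @param seed integer seed; the draw is reproducible given the seed.
#' @return two-column integer matrix of (drug index, target index) pairs.
#' @export
sample_negatives <- function(im, n_negatives = NULL, seed = 1L) {
  pool_cols <- which(im$nontarget)
  if (length(pool_cols) == 0) stop("non-target pool is empty")
  m <- length(im$drug_ids)
  pool_size <- m * length(pool_cols)
  if (is.null(n_negatives)) n_negatives <- sum(im$y)
  if (pool_size < n_negatives) {
    stop("candidate negative pool (", pool_size,
         ") smaller than requested negative count (", n_negatives, ")")
  }
  cells <- with_seed(seed, sample.int(pool_size, n_negatives))
  ## cells enumerate the m x |pool| grid column-major
  i <- ((cells - 1L) %% m) + 1L
  k <- pool_cols[((cells - 1L) %/% m) + 1L]
  out <- cbind(drug = i, target = k)
  out[order(out[, 1], out[, 2]), , drop = FALSE]
}
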