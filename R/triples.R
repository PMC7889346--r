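#' Generate partial-order ranking triples
#'
#' A triple (d_i, t_j, t_k) asserts that drug i's known target j must
#' outscore the sampled negative k. In `"cross"` mode each drug contributes
#' the Cartesian product of its positive targets and its sampled negatives
#' (the set definition of the per-drug triple group H_i). In `"paired"`
#' mode each positive is paired with exactly one negative of the same drug,
#' matching positives and negatives in per-drug index order (negatives are
#' recycled if a drug has fewer negatives than positives).
#'
#' Drugs with no positives or no sampled negatives contribute no triples.
#'
#' @param positives,negatives two-column integer matrices of
#'   (drug index, target index) pairs on the same index space.
#' @param mode `"cross"` (default) or `"paired"`.
#' @return a `triple_set`: integer matrix with columns `drug`, `pos`, `neg`,
#'   one row per triple, without duplicates.
#' @export
generate_triples <- function(positives, negatives, mode = c("cross", "paired")) {
  mode <- match.arg(mode)
  positives <- unique(matrix(as.integer(as.matrix(positives)), ncol = 2,
                             dimnames = list(NULL, c("drug", "target"))))
  negatives <- unique(matrix(as.integer(as.matrix(negatives)), ncol = 2,
                             dimnames = list(NULL, c("drug", "target"))))
  drugs <- sort(unique(positives[, 1]))
  rows <- vector("list", length(drugs))
  for (d in seq_along(drugs)) {
    i <- drugs[d]
    pj <- sort(positives[positives[, 1] == i, 2])
    nk <- sort(negatives[negatives[, 1] == i, 2])
    if (length(pj) == 0 || length(nk) == 0) next
    if (mode == "cross") {
      grid <- expand.grid(pos = pj, neg = nk, KEEP.OUT.ATTRS = FALSE)
      rows[[d]] <- cbind(drug = i, pos = grid$pos, neg = grid$neg)
    } else {
      nk_rec <- rep_len(nk, length(pj))
      rows[[d]] <- cbind(drug = i, pos = pj, neg = nk_rec)
    }
  }
  ts <- do.call(rbind, rows)
  if (is.null(ts)) ts <- matrix(integer(0), 0, 3,
                                dimnames = list(NULL, c("drug", "pos", "neg")))
  if (any(ts[, 2] == ts[, 3])) {
    stop("a positive target also appears as a negative for the same drug")
  }
  ts <- unique(ts)
  class(ts) <- c("triple_set", class(ts))
  ts
}

#' Check triples against an interaction matrix
#'
#' Asserts y\[i, j\] = 1 and y\[i, k\] = 0 for every triple.
#'
#' @param ts a `triple_set`.
#' @param im an `interaction_matrix`.
#' @return `TRUE` invisibly, or an error naming the first offending triple.
#' @export
validate_triples <- function(ts, im) {
  if (nrow(ts) == 0) return(invisible(TRUE))
  yj <- im$y[cbind(ts[, 1], ts[, 2])]
  yk <- im$y[cbind(ts[, 1], ts[, 3])]
  bad <- which(yj != 1L | yk != 0L)
  if (length(bad)) {
    stop("triple ", bad[1], " violates the partial order: (",
         paste(ts[bad[1], ], collapse = ", "), ")")
  }
  invisible(TRUE)
}

#' Split triples into cross-validation folds
#'
#' Folds are stratified by drug: each drug's units are dealt to folds
#' round-robin (in seeded random within-drug order, with a seeded random
#' starting fold carried across drugs), so per-drug and global fold sizes
#' both differ by at most one.
#'
#' With `by = "triple"` (default) the unit of splitting is the triple; a
#' positive pair may then appear in triples of different folds, which
#' leaks that pair's identity from training into testing. The strict mode
#' `by = "pair"` assigns each distinct positive (drug, target) pair to one
#' fold and every triple inherits its pair's fold, so a held-out positive
#' pair is never trained on; fold sizes are then balanced over pairs, not
#' triples.
#'
#' @param ts a `triple_set`.
#' @param n_folds number of folds, at least 2 and at most the number of
#'   split units.
#' @param seed integer seed.
#' @param by splitting unit: `"triple"` or `"pair"` (strict mode).
#' @return a `cv_split`: list with `fold` (integer assignment per triple row),
#'   `n_folds`, `by`, and `seed`.
#' @export
split_cv <- function(ts, n_folds = 5L, seed = 1L, by = c("triple", "pair")) {
  by <- match.arg(by)
  nt <- nrow(ts)
  if (nt == 0) stop("triple set is empty")
  if (n_folds < 2) stop("n_folds must be at least 2")
  if (by == "triple") {
    key <- seq_len(nt)
    units <- cbind(drug = ts[, 1], unit = key)
  } else {
    pairs <- unique(ts[, c(1, 2), drop = FALSE])
    key <- match(paste(ts[, 1], ts[, 2]), paste(pairs[, 1], pairs[, 2]))
    units <- cbind(drug = pairs[, 1], unit = seq_len(nrow(pairs)))
  }
  if (n_folds > nrow(units)) {
    stop("n_folds (", n_folds, ") exceeds the number of split units (",
         nrow(units), ")")
  }
  unit_fold <- integer(nrow(units))
  with_seed(seed, {
    offset <- sample.int(n_folds, 1L) - 1L
    pos <- 0L
    uds <- unique(units[, 1])
    for (i in uds[sample.int(length(uds))]) {
      rows <- which(units[, 1] == i)
      rows <- rows[sample.int(length(rows))]
      unit_fold[rows] <- ((pos + seq_along(rows) - 1L + offset) %% n_folds) + 1L
      pos <- pos + length(rows)
    }
  })
  fold <- unit_fold[key]
  structure(list(fold = fold, n_folds = as.integer(n_folds), by = by,
                 seed = as.integer(seed)),
            class = "cv_split")
}
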