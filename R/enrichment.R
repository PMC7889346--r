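#' Sliding-bin overlap curve between ranked predictions and a reference set
#'
#' Walks the ranked prediction list in consecutive bins (stride equal to
#' the bin size by default, i.e. non-overlapping) and counts, per bin, how
#' many predicted pairs appear in the reference edge set. The final
#' partial bin is included with its actual size.
#'
#' @param predicted data frame of ranked (drug, target) pairs, best first,
#'   deduplicated.
#' @param reference data frame of (drug, target) reference pairs.
#' @param bin_size number of consecutive predictions per bin (default 500).
#' @param stride step between bin starts; defaults to `bin_size`.
#' @return data frame with columns `bin_start`, `bin_size`, `overlap`.
#' @export
overlap_curve <- function(predicted, reference, bin_size = 500L,
                          stride = bin_size) {
  if (bin_size < 1) stop("bin_size must be >= 1")
  if (stride < 1) stop("stride must be >= 1")
  np <- nrow(predicted)
  if (np == 0) {
    return(data.frame(bin_start = integer(0), bin_size = integer(0),
                      overlap = integer(0)))
  }
  keys <- paste(predicted[[1]], predicted[[2]], sep = "\r")
  if (anyDuplicated(keys)) stop("predicted pair list contains duplicates")
  rkeys <- paste(reference[[1]], reference[[2]], sep = "\r")
  hit <- keys %in% rkeys
  starts <- seq.int(1L, np, by = stride)
  data.frame(
    bin_start = starts,
    bin_size = pmin(starts + bin_size - 1L, np) - starts + 1L,
    overlap = vapply(starts, function(s) {
      sum(hit[s:min(s + bin_size - 1L, np)])
    }, numeric(1)))
}

#' Fold-enrichment score of an overlap
#'
#' `ES = (k/n) / (m/N)`: the observed fraction of predictions confirmed by
#' the reference set, relative to the fraction expected if predictions and
#' reference were independent draws from the N possible pairs.
#'
#' @param k overlap count; @param N number of possible pairs in scope;
#' @param n number of predicted pairs; @param m number of reference pairs
#'   in scope.
#' @export
enrichment_score <- function(k, N, n, m) {
  check_enrichment_input(k, N, n, m)
  if (n == 0 || m == 0 || N == 0) stop("n, m, and N must be positive")
  (k / n) / (m / N)
}

check_enrichment_input <- function(k, N, n, m) {
  v <- c(k = k, N = N, n = n, m = m)
  if (any(v < 0) || any(v != round(v))) {
    stop("k, N, n, m must be non-negative integers")
  }
  if (n > N || m > N) stop("n and m cannot exceed N")
  invisible(TRUE)
}

#' Hypergeometric tail probability of an overlap
#'
#' `P(X >= k)` where X is the overlap between a random size-n subset and a
#' fixed size-m subset of N pairs. Computed through the hypergeometric
#' distribution function (log-space internally, so large N is safe).
#'
#' @inheritParams enrichment_score
#' @return probability in \[0, 1\].
#' @export
hypergeom_pvalue <- function(k, N, n, m) {
  check_enrichment_input(k, N, n, m)
  if (k == 0) return(1)
  if (k > min(n, m)) return(0)
  stats::phyper(k - 1, m, N - m, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values, order-preserving and clipped to 1.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @export
fdr_correct <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Enrichment of predicted edges against reference interaction sets
#'
#' For each reference set: restrict it to the in-scope drug x target
#' universe, count the overlap k with the predicted set, and report the
#' fold-enrichment score, the hypergeometric tail p-value, and the
#' BH-adjusted p-value across all references.
#'
#' @param predicted data frame of predicted (drug, target) pairs.
#' @param references named list of reference edge data frames.
#' @param universe_drugs,universe_targets character vectors defining the
#'   in-scope pair universe (N = |drugs| x |targets|). Predicted pairs and
#'   reference pairs outside the universe are dropped.
#' @return data frame with one row per reference: `reference`, `k`, `N`,
#'   `n`, `m`, `es`, `p_value`, `p_adjusted`.
#' @export
enrichment_test <- function(predicted, references, universe_drugs,
                            universe_targets) {
  N <- length(universe_drugs) * length(universe_targets)
  in_universe <- function(df) {
    df[df[[1]] %in% universe_drugs & df[[2]] %in% universe_targets, ,
       drop = FALSE]
  }
  predicted <- in_universe(predicted)
  pkeys <- unique(paste(predicted[[1]], predicted[[2]], sep = "\r"))
  n <- length(pkeys)
  rows <- lapply(names(references), function(nm) {
    ref <- in_universe(references[[nm]])
    rkeys <- unique(paste(ref[[1]], ref[[2]], sep = "\r"))
    m <- length(rkeys)
    k <- sum(pkeys %in% rkeys)
    data.frame(reference = nm, k = k, N = N, n = n, m = m,
               es = if (n > 0 && m > 0) enrichment_score(k, N, n, m) else NA_real_,
               p_value = hypergeom_pvalue(k, N, n, m),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- fdr_correct(out$p_value)
  out
}
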