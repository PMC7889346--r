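#' Similarity kernels on expression profiles
#'
#' Four pairwise kernels used to compare two expression vectors:
#'
#' * `sim_tanimoto()` — continuous Tanimoto coefficient
#'   \eqn{x \cdot y / (\|x\|^2 + \|y\|^2 - x \cdot y)}, an extension of
#'   intersection-over-union to real-valued features. A non-positive
#'   denominator (both vectors zero, or pathologically anti-parallel) is
#'   an error.
#' * `sim_cosine()` — \eqn{x \cdot y / (\|x\| \|y\|)}; zero-norm input is
#'   an error.
#' * `sim_ssim()` — structural similarity computed globally over the whole
#'   vector (no sliding window): the means, variances and covariance are
#'   interpreted as overall level, spread, and co-trend of expression
#'   change. Population (1/n) moments are used. Constants `c1`, `c2`
#'   (default 0.001) keep the denominator away from zero.
#' * `sim_spearman()` — rank correlation
#'   \eqn{1 - 6 \sum g_i^2 / (n(n^2-1))} where \eqn{g_i} is the difference
#'   of the ranks of \eqn{x_i} and \eqn{y_i}; ties receive average ranks.
#'
#' @param x,y numeric vectors of equal length.
#' @param c1,c2 positive SSIM stabilizing constants.
#' @return a single numeric similarity score.
#' @examples
#' sim_tanimoto(c(2, 0), c(1, 0))   # 2/3
#' sim_spearman(c(1, 0, 3), c(1, 5, 2))  # -0.5
#' @name similarity_kernels
NULL

check_pair <- function(x, y, min_len = 1L) {
  if (length(x) != length(y)) {
    stop("vectors have different lengths (", length(x), " vs ", length(y), ")")
  }
  if (length(x) < min_len) {
    stop("vectors must have length at least ", min_len)
  }
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop("vectors must be finite")
  }
  invisible(TRUE)
}

#' @rdname similarity_kernels
#' @export
sim_tanimoto <- function(x, y) {
  check_pair(x, y)
  num <- sum(x * y)
  den <- sum(x * x) + sum(y * y) - num
  if (den <= 0) {
    stop("Tanimoto denominator is non-positive (zero or anti-parallel vectors)")
  }
  num / den
}

#' @rdname similarity_kernels
#' @export
sim_cosine <- function(x, y) {
  check_pair(x, y)
  nx <- sqrt(sum(x * x)); ny <- sqrt(sum(y * y))
  if (nx == 0 || ny == 0) stop("cosine similarity undefined for a zero vector")
  sum(x * y) / (nx * ny)
}

#' @rdname similarity_kernels
#' @export
sim_ssim <- function(x, y, c1 = 0.001, c2 = 0.001) {
  check_pair(x, y, min_len = 2L)
  if (c1 <= 0 || c2 <= 0) stop("c1 and c2 must be positive")
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  vx <- sum((x - mx)^2) / n
  vy <- sum((y - my)^2) / n
  cxy <- sum((x - mx) * (y - my)) / n
  ((2 * mx * my + c1) * (2 * cxy + c2)) /
    ((mx^2 + my^2 + c1) * (vx + vy + c2))
}

#' @rdname similarity_kernels
#' @export
sim_spearman <- function(x, y) {
  check_pair(x, y, min_len = 2L)
  n <- length(x)
  g <- rank(x) - rank(y)
  1 - 6 * sum(g * g) / (n * (n^2 - 1))
}

sim_kernel <- function(method) {
  switch(method,
         tanimoto = sim_tanimoto,
         cosine = sim_cosine,
         ssim = sim_ssim,
         spearman = sim_spearman,
         stop("unknown similarity method: ", method))
}

#' Pairwise similarity matrix of a profile matrix
#'
#' Applies one of the four kernels to every pair of rows. The result is
#' symmetric with unit diagonal (for non-degenerate rows). Because the
#' Gaussian latent-distance kernel the trainer matches against lies in
#' (0, 1], negative similarities have no attainable counterpart; by default
#' they are clamped to 0.
#'
#' @param pm a [profile_matrix()] (or plain numeric matrix with row names).
#' @param method one of `"tanimoto"`, `"cosine"`, `"ssim"`, `"spearman"`.
#' @param clamp clamp negative values to 0 (default `TRUE`).
#' @return a `similarity_matrix`: square symmetric matrix with entity ids as
#'   dimnames and attributes `method` and `clamped`.
#' @export
similarity_matrix <- function(pm, method = c("tanimoto", "cosine", "ssim",
                                             "spearman"),
                              clamp = TRUE) {
  method <- match.arg(method)
  X <- unclass(as.matrix(pm))
  if (nrow(X) == 0) stop("profile matrix is empty")
  ids <- rownames(X)
  S <- switch(method,
    tanimoto = {
      P <- tcrossprod(X)
      sq <- diag(P)
      den <- outer(sq, sq, "+") - P
      if (any(den <= 0)) {
        bad <- which(den <= 0, arr.ind = TRUE)[1, ]
        stop("Tanimoto denominator non-positive for pair (",
             ids[bad[1]], ", ", ids[bad[2]], ")")
      }
      P / den
    },
    cosine = {
      nr <- sqrt(rowSums(X^2))
      if (any(nr == 0)) {
        stop("cosine similarity undefined for zero-profile entity ",
             ids[which(nr == 0)[1]])
      }
      tcrossprod(X / nr)
    },
    ssim = {
      n <- ncol(X)
      if (n < 2) stop("SSIM requires at least 2 features")
      mu <- rowMeans(X)
      Xc <- X - mu
      v <- rowSums(Xc^2) / n
      Cv <- tcrossprod(Xc) / n
      c1 <- 0.001; c2 <- 0.001
      ((2 * outer(mu, mu) + c1) * (2 * Cv + c2)) /
        ((outer(mu^2, mu^2, "+") + c1) * (outer(v, v, "+") + c2))
    },
    spearman = {
      n <- ncol(X)
      if (n < 2) stop("Spearman requires at least 2 features")
      R <- t(apply(X, 1, rank))
      q <- rowSums(R^2)
      ssq <- outer(q, q, "+") - 2 * tcrossprod(R)
      1 - 6 * ssq / (n * (n^2 - 1))
    })
  S <- (S + t(S)) / 2
  if (clamp) S[S < 0] <- 0
  dimnames(S) <- list(ids, ids)
  structure(S, method = method, clamped = clamp,
            class = c("similarity_matrix", class(S)))
}

#' Read / write similarity matrices as square TSV
#'
#' Entity ids appear both as the header and as the first column.
#'
#' @param path file path.
#' @param method,clamped kernel metadata to attach on read.
#' @export
read_similarity <- function(path, method = NA_character_, clamped = NA) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          row.names = 1)
  S <- as.matrix(df)
  structure(S, method = method, clamped = clamped,
            class = c("similarity_matrix", class(S)))
}

#' @rdname read_similarity
#' @param S a `similarity_matrix`.
#' @export
write_similarity <- function(S, path) {
  df <- data.frame(id = rownames(S), unclass(S), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
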