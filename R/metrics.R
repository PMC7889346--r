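#' Evaluation context for per-drug ranking metrics
#'
#' Packages a score table together with the test positives, the candidate
#' pool per drug, and (optionally) the test triples, so the metric
#' functions share one consistent view of what is being evaluated.
#'
#' All metrics are per-drug quantities averaged over drugs with equal
#' weight; drugs lacking the required test data are excluded with a
#' warning.
#'
#' @param scores m x n numeric matrix of predicted pair scores.
#' @param positives two-column integer matrix of (drug, target) test
#'   positives.
#' @param candidates candidate target pool: `NULL` (all targets for every
#'   drug), an integer vector shared by all drugs, or a list of integer
#'   vectors indexed by drug. Each drug's test positives must belong to its
#'   pool.
#' @param triples optional test `triple_set` for [metric_auc()]; defaults
#'   to none.
#' @return an `eval_context` list.
#' @export
eval_context <- function(scores, positives, candidates = NULL,
                         triples = NULL) {
  scores <- as.matrix(scores)
  if (!all(is.finite(scores))) stop("all scores must be finite")
  positives <- matrix(as.integer(as.matrix(positives)), ncol = 2)
  drugs <- sort(unique(c(positives[, 1],
                         if (!is.null(triples)) triples[, 1])))
  cand <- vector("list", nrow(scores))
  for (i in drugs) {
    ci <- if (is.null(candidates)) seq_len(ncol(scores))
          else if (is.list(candidates)) candidates[[i]]
          else as.integer(candidates)
    pos_i <- positives[positives[, 1] == i, 2]
    if (!all(pos_i %in% ci)) {
      stop("test positives of drug ", i, " missing from its candidate pool")
    }
    cand[[i]] <- ci
  }
  structure(list(scores = scores, positives = positives, candidates = cand,
                 triples = triples, drugs = drugs),
            class = "eval_context")
}

#' Build an evaluation context from a fitted model
#'
#' Test positives are the positive targets appearing in the fit's held-out
#' triples. With `pool = "filtered"` (default) each drug's candidate pool
#' is every target except its training positives, so recovering a training
#' edge is not penalized; `pool = "full"` ranks against all targets.
#'
#' @param fit a [bpr_dti()] fit with held-out triples (see `cv_fold`).
#' @param pool `"filtered"` or `"full"`.
#' @export
eval_context_from_fit <- function(fit, pool = c("filtered", "full")) {
  pool <- match.arg(pool)
  tt <- fit$test_triples
  if (is.null(tt) || nrow(tt) == 0) stop("fit has no held-out triples")
  scores <- fitted(fit)
  positives <- unique(tt[, c(1, 2), drop = FALSE])
  cand <- NULL
  if (pool == "filtered") {
    train_pos <- unique(fit$train_triples[, c(1, 2), drop = FALSE])
    ## a pair may sit in triples of both folds; keep test positives ranked
    keys_test <- paste(positives[, 1], positives[, 2])
    cand <- lapply(seq_len(nrow(scores)), function(i) {
      tp <- train_pos[train_pos[, 1] == i, 2]
      tp <- tp[!(paste(i, tp) %in% keys_test)]
      setdiff(seq_len(ncol(scores)), tp)
    })
  }
  eval_context(scores, positives, candidates = cand, triples = tt)
}

## pessimistic rank of each test positive of drug i within its candidate
## pool: 1 + number of *other* candidates scoring >= the positive
positive_ranks <- function(ctx, i) {
  ci <- ctx$candidates[[i]]
  s <- ctx$scores[i, ci]
  pos <- ctx$positives[ctx$positives[, 1] == i, 2]
  vapply(pos, function(j) {
    sj <- ctx$scores[i, j]
    sum(s >= sj) - 1L + 1L   # drop the positive itself, add rank offset
  }, numeric(1))
}

drugs_with_positives <- function(ctx) {
  ds <- sort(unique(ctx$positives[, 1]))
  all_ds <- ctx$drugs
  skipped <- setdiff(all_ds, ds)
  if (length(skipped)) {
    warning("drug(s) without test positives excluded: ",
            paste(skipped, collapse = ", "))
  }
  ds
}

#' Per-drug pairwise AUC over test triples
#'
#' For each drug, the fraction of its test triples whose positive outscores
#' its negative strictly (ties count zero); averaged over drugs with equal
#' weight.
#'
#' @param ctx an [eval_context()] with test triples.
#' @export
metric_auc <- function(ctx) {
  tt <- ctx$triples
  if (is.null(tt) || nrow(tt) == 0) stop("context has no test triples")
  rj <- ctx$scores[cbind(tt[, 1], tt[, 2])]
  rk <- ctx$scores[cbind(tt[, 1], tt[, 3])]
  ok <- as.numeric(rj > rk)
  per_drug <- tapply(ok, tt[, 1], mean)
  skipped <- setdiff(ctx$drugs, as.integer(names(per_drug)))
  if (length(skipped)) {
    warning("drug(s) without test triples excluded: ",
            paste(skipped, collapse = ", "))
  }
  mean(per_drug)
}

#' Top-k recall per drug
#'
#' A test positive is recovered when at most k-1 evaluated candidates
#' (itself excluded) score greater than or equal to it — ties push a
#' positive down, the pessimistic convention. The per-drug count is
#' divided by the drug's number of test positives, then averaged over
#' drugs.
#'
#' @param ctx an [eval_context()].
#' @param k ranking cutoff (>= 1).
#' @export
metric_top_k <- function(ctx, k) {
  if (k < 1) stop("k must be >= 1")
  ds <- drugs_with_positives(ctx)
  mean(vapply(ds, function(i) {
    r <- positive_ranks(ctx, i)
    sum(r <= k) / length(r)
  }, numeric(1)))
}

#' Precision at k per drug
#'
#' Number of test positives within the top k of the drug's candidate
#' ranking, divided by k; averaged over drugs.
#'
#' @inheritParams metric_top_k
#' @export
metric_prec_k <- function(ctx, k) {
  if (k < 1) stop("k must be >= 1")
  ds <- drugs_with_positives(ctx)
  mean(vapply(ds, function(i) {
    r <- positive_ranks(ctx, i)
    sum(r <= k) / k
  }, numeric(1)))
}

#' Area under the per-drug recall-precision curve
#'
#' For each drug, k sweeps 1..(pool size), tracing (recall, precision)
#' points; the curve is closed on the left with an implicit point at
#' recall 0 and the precision of k = 1, and integrated by the trapezoid
#' rule over the recall axis. Per-drug areas are averaged.
#'
#' @param ctx an [eval_context()].
#' @export
metric_aupr <- function(ctx) {
  ds <- drugs_with_positives(ctx)
  mean(vapply(ds, function(i) {
    r <- positive_ranks(ctx, i)
    nc <- length(ctx$candidates[[i]])
    ks <- seq_len(nc)
    hits <- vapply(ks, function(k) sum(r <= k), numeric(1))
    rec <- hits / length(r)
    prec <- hits / ks
    rec <- c(0, rec); prec <- c(prec[1], prec)
    sum(diff(rec) * (utils::head(prec, -1) + utils::tail(prec, -1)) / 2)
  }, numeric(1)))
}

#' Normalized discounted cumulative gain per drug
#'
#' Binary gains at the pessimistic ranks of the test positives, discount
#' 1/log2(rank + 1), normalized by the ideal ordering (all positives at
#' the top); averaged over drugs.
#'
#' @param ctx an [eval_context()].
#' @param k optional truncation depth (default: the full pool).
#' @export
metric_ndcg <- function(ctx, k = NULL) {
  ds <- drugs_with_positives(ctx)
  mean(vapply(ds, function(i) {
    r <- positive_ranks(ctx, i)
    nc <- length(ctx$candidates[[i]])
    depth <- if (is.null(k)) nc else min(k, nc)
    dcg <- sum(1 / log2(r[r <= depth] + 1))
    ideal <- seq_len(min(length(r), depth))
    dcg / sum(1 / log2(ideal + 1))
  }, numeric(1)))
}

#' Evaluate a fitted model on its held-out triples
#'
#' Convenience wrapper assembling an evaluation context from the fit and
#' computing the full metric suite.
#'
#' @param fit a [bpr_dti()] fit with held-out triples.
#' @param ks integer cutoffs for Top-k and precision-at-k.
#' @param pool see [eval_context_from_fit()].
#' @return named numeric vector: `auc`, `top_<k>`, `prec_<k>`, `aupr`,
#'   `ndcg`.
#' @export
evaluate_model <- function(fit, ks = c(1L, 10L), pool = c("filtered", "full")) {
  ctx <- eval_context_from_fit(fit, pool = match.arg(pool))
  out <- c(auc = metric_auc(ctx))
  for (k in ks) {
    out[paste0("top_", k)] <- metric_top_k(ctx, k)
    out[paste0("prec_", k)] <- metric_prec_k(ctx, k)
  }
  out["aupr"] <- metric_aupr(ctx)
  out["ndcg"] <- metric_ndcg(ctx)
  out
}
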