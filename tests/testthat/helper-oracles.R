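# Independent oracles used across the suite. These deliberately use the
# most direct (loop-based / enumerative) formulation of each quantity so
# they stay independent of the vectorized implementation paths.

## central finite differences of a scalar function of a vector
fd_gradient <- function(fun, x, h = 1e-6) {
  vapply(seq_along(x), function(d) {
    xp <- x; xm <- x
    xp[d] <- xp[d] + h
    xm[d] <- xm[d] - h
    (fun(xp) - fun(xm)) / (2 * h)
  }, numeric(1))
}

rel_err <- function(a, b) {
  max(abs(a - b)) / max(1e-8, max(abs(a)), max(abs(b)))
}

## ranking (unregularized) part of the triple loss at explicit factor rows
rank_loss_at <- function(fi, fj, fk) {
  g <- sum(fi * (fj - fk))
  if (-g > 0) -g + log1p(exp(g)) else log1p(exp(-g))
}

## plain BPR SGD reference: the trajectory the trainer must reproduce
## bit-for-bit when the adversarial and similarity terms are switched off
reference_bpr <- function(ts, m, n, f, lambda_theta, lr, n_epochs, seed) {
  set.seed(seed)
  F_D <- matrix(rnorm(m * f, sd = 0.01), m, f)
  F_T <- matrix(rnorm(n * f, sd = 0.01), n, f)
  for (ep in seq_len(n_epochs)) {
    ord <- sample.int(nrow(ts))
    for (idx in ord) {
      i <- ts[idx, 1]; j <- ts[idx, 2]; k <- ts[idx, 3]
      fi <- F_D[i, ]; fj <- F_T[j, ]; fk <- F_T[k, ]
      diff <- fj - fk
      s <- 1 / (1 + exp(sum(fi * diff)))
      F_D[i, ] <- fi - lr * (-s * diff + 2 * lambda_theta * fi)
      F_T[j, ] <- fj - lr * (-s * fi + 2 * lambda_theta * fj)
      F_T[k, ] <- fk - lr * (s * fi + 2 * lambda_theta * fk)
    }
  }
  list(F_D = F_D, F_T = F_T)
}

## ---- metric oracles: explicit loops over candidates --------------------

## pessimistic rank by explicit counting
oracle_rank <- function(s_cand, cand, j, s_j) {
  cnt <- 0L
  for (a in seq_along(cand)) {
    if (cand[a] != j && s_cand[a] >= s_j) cnt <- cnt + 1L
  }
  cnt + 1L
}

oracle_drug_metrics <- function(scores_i, cand, pos, k) {
  s_cand <- scores_i[cand]
  ranks <- vapply(pos, function(j) oracle_rank(s_cand, cand, j, scores_i[j]),
                  integer(1))
  hits <- sum(ranks <= k)
  c(top = hits / length(pos), prec = hits / k)
}

oracle_top_k <- function(scores, positives, candidates, k) {
  ds <- sort(unique(positives[, 1]))
  mean(vapply(ds, function(i) {
    oracle_drug_metrics(scores[i, ], candidates[[i]],
                        positives[positives[, 1] == i, 2], k)["top"]
  }, numeric(1)))
}

oracle_prec_k <- function(scores, positives, candidates, k) {
  ds <- sort(unique(positives[, 1]))
  mean(vapply(ds, function(i) {
    oracle_drug_metrics(scores[i, ], candidates[[i]],
                        positives[positives[, 1] == i, 2], k)["prec"]
  }, numeric(1)))
}

oracle_aupr <- function(scores, positives, candidates) {
  ds <- sort(unique(positives[, 1]))
  mean(vapply(ds, function(i) {
    cand <- candidates[[i]]
    pos <- positives[positives[, 1] == i, 2]
    pts <- t(vapply(seq_along(cand), function(k) {
      oracle_drug_metrics(scores[i, ], cand, pos, k)
    }, numeric(2)))
    rec <- c(0, pts[, "top"]); prec <- c(pts[1, "prec"], pts[, "prec"])
    area <- 0
    for (a in 2:length(rec)) {
      area <- area + (rec[a] - rec[a - 1]) * (prec[a] + prec[a - 1]) / 2
    }
    area
  }, numeric(1)))
}

oracle_ndcg <- function(scores, positives, candidates, k = NULL) {
  ds <- sort(unique(positives[, 1]))
  mean(vapply(ds, function(i) {
    cand <- candidates[[i]]
    pos <- positives[positives[, 1] == i, 2]
    depth <- if (is.null(k)) length(cand) else min(k, length(cand))
    s_cand <- scores[i, cand]
    dcg <- 0
    for (j in pos) {
      r <- oracle_rank(s_cand, cand, j, scores[i, j])
      if (r <= depth) dcg <- dcg + 1 / log2(r + 1)
    }
    idcg <- sum(1 / log2(seq_len(min(length(pos), depth)) + 1))
    dcg / idcg
  }, numeric(1)))
}

## AUC as the rank statistic: positive>negative pairs over all pairs
oracle_auc_pairs <- function(scores, pos_sets, neg_sets) {
  ds <- seq_along(pos_sets)
  mean(vapply(ds, function(i) {
    cnt <- 0L; tot <- 0L
    for (j in pos_sets[[i]]) for (k in neg_sets[[i]]) {
      tot <- tot + 1L
      if (scores[i, j] > scores[i, k]) cnt <- cnt + 1L
    }
    cnt / tot
  }, numeric(1)))
}

## exact hypergeometric upper tail by rational enumeration
oracle_hyper_tail <- function(k, N, n, m) {
  if (k <= 0) return(1)
  hi <- min(n, m)
  if (k > hi) return(0)
  sum(vapply(k:hi, function(x) {
    choose(m, x) * choose(N - m, n - x)
  }, numeric(1))) / choose(N, n)
}

## brute-force pairwise similarity matrix
naive_similarity <- function(X, kernel) {
  n <- nrow(X)
  S <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    S[i, j] <- kernel(X[i, ], X[j, ])
  }
  S
}

## random small evaluation instance shared by metric tests
random_eval_instance <- function(n_drugs = 4, n_cand = 30, n_pos = 3,
                                 ties = FALSE) {
  scores <- matrix(rnorm(n_drugs * n_cand), n_drugs, n_cand)
  if (ties) {
    scores <- matrix(sample(seq_len(8), n_drugs * n_cand, replace = TRUE),
                     n_drugs, n_cand) / 4
  }
  positives <- do.call(rbind, lapply(seq_len(n_drugs), function(i) {
    cbind(i, sample(n_cand, n_pos))
  }))
  list(scores = scores, positives = positives,
       candidates = replicate(n_drugs, seq_len(n_cand), simplify = FALSE))
}
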