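#' Strict held-out evaluation experiment
#'
#' Runs one train/test experiment with a leakage-free design, suitable for
#' recovery benchmarks on synthetic data and for permuted-label negative
#' controls:
#'
#' 1. Positive pairs are split into `n_folds` drug-stratified folds at the
#'    pair level (strict mode of [split_cv()]), and fold `fold` is held
#'    out: a held-out pair never appears in any training triple.
#' 2. Training negatives (one per training positive) are sampled from the
#'    drug x non-target pool; training triples are the per-drug cross
#'    product.
#' 3. Held-out AUC is computed on fresh test triples that pair each
#'    held-out positive with cross-drug decoys: targets of *other* drugs'
#'    held-out positives that do not interact with the drug at hand.
#'    Decoy columns are drawn from the same popularity-biased column
#'    distribution as the positives, so a model trained on permuted labels
#'    scores 0.5 on average — popularity leakage cancels by
#'    exchangeability.
#' 4. The remaining metrics rank each drug's held-out positives against
#'    the full target pool minus that drug's training positives.
#'
#' @param syn a dataset list as returned by [synthetic_dti()] (components
#'   `drug_profiles`, `target_profiles`, `interactions`), or any list with
#'   those fields.
#' @param hp a [bpr_hyperparams()] object; its `seed` is overridden by
#'   `seed`.
#' @param sim_method similarity kernel (see [similarity_matrix()]).
#' @param n_folds,fold strict pair-level fold scheme and held-out fold.
#' @param seed integer seed governing the split, the negative sample, the
#'   label permutation (if any), and training.
#' @param permute train on labels permuted with [permute_labels()]
#'   (negative control).
#' @param ks cutoffs for Top-k / precision-at-k.
#' @return list with `metrics` (named vector: auc, top_k, prec_k, aupr,
#'   ndcg), `n_test_triples`, `n_test_positives`, and `model` (the trained
#'   factor matrices and loss trace).
#' @export
holdout_experiment <- function(syn, hp = bpr_hyperparams(factor_size = 5L),
                               sim_method = "tanimoto", n_folds = 5L,
                               fold = 1L, seed = 1L, permute = FALSE,
                               ks = c(1L, 10L)) {
  im <- syn$interactions
  if (permute) im <- permute_labels(im, seed = seed)
  hp$seed <- as.integer(seed)
  pos <- positive_pairs(im)
  pair_ts <- cbind(pos, neg = pos[, 2])  # fold unit is the (drug, target) pair
  fold_of <- split_cv(pair_ts, n_folds = n_folds, seed = seed, by = "pair")$fold
  tr_pos <- pos[fold_of != fold, , drop = FALSE]
  te_pos <- pos[fold_of == fold, , drop = FALSE]
  if (nrow(te_pos) == 0 || nrow(tr_pos) == 0) {
    stop("fold scheme left the training or test positives empty")
  }
  tr_neg <- sample_negatives(im, n_negatives = nrow(tr_pos), seed = seed)
  tr <- generate_triples(tr_pos, tr_neg)

  ## cross-drug decoy test triples (fresh pairs, exchangeable under a
  ## label permutation)
  te_neg <- do.call(rbind, lapply(unique(te_pos[, 1]), function(i) {
    k <- unique(te_pos[te_pos[, 1] != i, 2])
    k <- k[im$y[i, k] == 0L]
    if (length(k)) cbind(drug = i, target = k) else NULL
  }))
  if (is.null(te_neg)) stop("no cross-drug decoys available for the test fold")
  te <- generate_triples(te_pos, te_neg)

  S_D <- similarity_matrix(syn$drug_profiles, sim_method)
  S_T <- similarity_matrix(syn$target_profiles, sim_method)
  model <- train_factors(tr, S_D, S_T, hp)
  scores <- model$F_D %*% t(model$F_T)

  auc <- metric_auc(eval_context(scores, te[, c(1, 2)], triples = te))
  keys_test <- paste(te_pos[, 1], te_pos[, 2])
  cand <- lapply(seq_len(nrow(scores)), function(i) {
    tp <- tr_pos[tr_pos[, 1] == i, 2]
    tp <- tp[!(paste(i, tp) %in% keys_test)]
    setdiff(seq_len(ncol(scores)), tp)
  })
  ctx <- eval_context(scores, te_pos, candidates = cand)
  metrics <- c(auc = auc)
  for (k in ks) {
    metrics[paste0("top_", k)] <- metric_top_k(ctx, k)
    metrics[paste0("prec_", k)] <- metric_prec_k(ctx, k)
  }
  metrics["aupr"] <- metric_aupr(ctx)
  metrics["ndcg"] <- metric_ndcg(ctx)
  list(metrics = metrics, n_test_triples = nrow(te),
       n_test_positives = nrow(te_pos), model = model)
}
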