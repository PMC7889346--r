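make_ctx <- function(scores_row, pos, triples = NULL) {
  scores <- matrix(scores_row, nrow = 1)
  eval_context(scores, cbind(1, pos), triples = triples)
}

test_that("triple AUC counts strict orderings per drug", {
  scores <- rbind(c(0.9, 0.8, 0.1, 0.2))
  ## 3 triples, 2 correctly ordered
  tri <- cbind(drug = 1, pos = c(1, 2, 2), neg = c(3, 4, 4))
  tri[3, ] <- c(1, 3, 1)  # mis-ordered: 0.1 < 0.9
  ctx <- eval_context(scores, cbind(1, c(1, 2)), triples = tri)
  expect_equal(metric_auc(ctx), 2 / 3)

  ## perfect separation
  tri2 <- cbind(1, c(1, 1, 2), c(3, 4, 3))
  expect_equal(metric_auc(eval_context(scores, cbind(1, 1:2), triples = tri2)), 1)

  ## ties count zero
  tied <- rbind(c(0.5, 0.5))
  trit <- cbind(1, 1, 2)
  expect_equal(metric_auc(eval_context(tied, cbind(1, 1), triples = trit)), 0)
})

test_that("AUC averages drugs equally and equals the rank statistic on
           full cross-product triples", {
  set.seed(12)
  for (rep in 1:10) {
    nd <- 3; nc <- sample(10:50, 1)
    scores <- matrix(rnorm(nd * nc), nd, nc)
    pos_sets <- lapply(1:nd, function(i) sample(nc, 3))
    neg_sets <- lapply(1:nd, function(i) {
      setdiff(sample(nc, 8), pos_sets[[i]])
    })
    tri <- do.call(rbind, lapply(1:nd, function(i) {
      expand.grid(drug = i, pos = pos_sets[[i]], neg = neg_sets[[i]])
    }))
    tri <- as.matrix(tri)
    ctx <- eval_context(scores, unique(tri[, 1:2]), triples = tri)
    expect_equal(metric_auc(ctx), oracle_auc_pairs(scores, pos_sets, neg_sets),
                 tolerance = 1e-12)
  }
})

test_that("random scores give chance-level AUC", {
  set.seed(99)
  nd <- 200; nc <- 40
  scores <- matrix(rnorm(nd * nc), nd, nc)
  tri <- do.call(rbind, lapply(1:nd, function(i) {
    cbind(i, sample(1:10, 5), sample(11:40, 5))
  }))
  ctx <- eval_context(scores, unique(tri[, 1:2]), triples = tri)
  expect_equal(metric_auc(ctx), 0.5, tolerance = 0.03)
})

test_that("top-k recall follows the pessimistic rank convention", {
  ## single positive ranked first of five
  ctx <- make_ctx(c(5, 4, 3, 2, 1), pos = 1)
  expect_equal(metric_top_k(ctx, 1), 1)
  ## positives at ranks 2 and 11 among 20 candidates
  s <- seq(20, 1)  # score 20 ranks 1st ... score 1 ranks 20th
  ctx2 <- make_ctx(s, pos = c(2, 11))
  expect_equal(metric_top_k(ctx2, 10), 0.5)
  expect_equal(metric_prec_k(ctx2, 10), 0.1)
  ## k at least the pool size captures everything
  expect_equal(metric_top_k(ctx2, 20), 1)
  expect_equal(metric_top_k(ctx2, 50), 1)
  ## both positives inside the top 10
  ctx3 <- make_ctx(s, pos = c(3, 7))
  expect_equal(metric_prec_k(ctx3, 10), 0.2)
  expect_equal(metric_prec_k(ctx3, 1), 0)
  ctx4 <- make_ctx(s, pos = 1)
  expect_equal(metric_prec_k(ctx4, 1), 1)
  ## a tied competitor pushes the positive down
  tied <- make_ctx(c(1, 1, 0), pos = 1)
  expect_equal(metric_top_k(tied, 1), 0)
  expect_equal(metric_top_k(tied, 2), 1)
})

test_that("top-k and precision oracles agree on randomized instances and
           the counting identity holds exactly", {
  set.seed(31)
  for (rep in 1:25) {
    inst <- random_eval_instance(n_drugs = 3, n_cand = sample(10:50, 1),
                                 n_pos = sample(2:4, 1),
                                 ties = rep %% 3 == 0)
    ctx <- eval_context(inst$scores, inst$positives,
                        candidates = inst$candidates)
    for (k in c(1, 3, 7, 15)) {
      expect_equal(metric_top_k(ctx, k),
                   oracle_top_k(inst$scores, inst$positives,
                                inst$candidates, k), tolerance = 1e-12)
      expect_equal(metric_prec_k(ctx, k),
                   oracle_prec_k(inst$scores, inst$positives,
                                 inst$candidates, k), tolerance = 1e-12)
    }
    ## per-drug identity: prec_k * k == top_k * (#positives)
    for (i in unique(inst$positives[, 1])) {
      ctx1 <- eval_context(inst$scores, inst$positives[inst$positives[, 1] == i, ,
                                                       drop = FALSE],
                           candidates = inst$candidates)
      np <- sum(inst$positives[, 1] == i)
      for (k in c(2, 9)) {
        expect_equal(metric_prec_k(ctx1, k) * k, metric_top_k(ctx1, k) * np,
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("top-k is non-decreasing in k, as is k times precision", {
  set.seed(41)
  inst <- random_eval_instance(n_drugs = 5, n_cand = 30, n_pos = 4)
  ctx <- eval_context(inst$scores, inst$positives, candidates = inst$candidates)
  tk <- vapply(1:30, function(k) metric_top_k(ctx, k), numeric(1))
  pk <- vapply(1:30, function(k) metric_prec_k(ctx, k) * k, numeric(1))
  expect_true(all(diff(tk) >= -1e-12))
  expect_true(all(diff(pk) >= -1e-12))
})

test_that("AUPR matches the exhaustive sweep oracle and its closed cases", {
  ## single positive at rank 1
  expect_equal(metric_aupr(make_ctx(c(9, 5, 4, 3), pos = 1)), 1)
  ## single positive at arbitrary ranks: oracle sweep
  set.seed(51)
  for (rep in 1:10) {
    nc <- sample(5:40, 1)
    s <- rnorm(nc)
    pos <- sample(nc, 1)
    ctx <- make_ctx(s, pos)
    expect_equal(metric_aupr(ctx),
                 oracle_aupr(matrix(s, 1), cbind(1, pos), list(seq_len(nc))),
                 tolerance = 1e-12)
  }
  ## random instances, several positives
  for (rep in 1:10) {
    inst <- random_eval_instance(n_drugs = 3, n_cand = 25, n_pos = 3,
                                 ties = rep %% 2 == 0)
    ctx <- eval_context(inst$scores, inst$positives,
                        candidates = inst$candidates)
    expect_equal(metric_aupr(ctx),
                 oracle_aupr(inst$scores, inst$positives, inst$candidates),
                 tolerance = 1e-12)
  }
})

test_that("AUPR of random scores approaches the positive prevalence", {
  set.seed(61)
  nd <- 150; nc <- 40; np <- 4
  scores <- matrix(rnorm(nd * nc), nd, nc)
  positives <- do.call(rbind, lapply(1:nd, function(i) cbind(i, sample(nc, np))))
  ctx <- eval_context(scores, positives)
  ## random rankings sit at the prevalence up to the small upward bias of
  ## short candidate lists
  prevalence <- np / nc
  expect_lt(abs(metric_aupr(ctx) - prevalence), 0.05)
})

test_that("NDCG closed forms, truncation, and oracle agreement", {
  ## all positives on top
  ctx <- make_ctx(c(9, 8, 1, 0), pos = c(1, 2))
  expect_equal(metric_ndcg(ctx), 1)
  ## single positive at rank 2 of 3
  ctx2 <- make_ctx(c(3, 2, 1), pos = 2)
  expect_equal(metric_ndcg(ctx2), 1 / log2(3))
  ## truncation below the positive's rank zeroes the gain
  expect_equal(metric_ndcg(ctx2, k = 1), 0)
  set.seed(71)
  for (rep in 1:15) {
    inst <- random_eval_instance(n_drugs = 4, n_cand = 20, n_pos = 3,
                                 ties = rep %% 3 == 0)
    ctx <- eval_context(inst$scores, inst$positives,
                        candidates = inst$candidates)
    expect_equal(metric_ndcg(ctx),
                 oracle_ndcg(inst$scores, inst$positives, inst$candidates),
                 tolerance = 1e-12)
    expect_lte(metric_ndcg(ctx), 1 + 1e-12)
  }
})

test_that("all metrics are invariant under strictly monotone score
           transformations", {
  set.seed(81)
  inst <- random_eval_instance(n_drugs = 4, n_cand = 25, n_pos = 3)
  tri <- do.call(rbind, lapply(1:4, function(i) {
    pos <- inst$positives[inst$positives[, 1] == i, 2]
    cbind(i, pos, sample(setdiff(1:25, pos), 3))
  }))
  eval_all <- function(scores) {
    ctx <- eval_context(scores, inst$positives, candidates = inst$candidates,
                        triples = tri)
    c(metric_auc(ctx), metric_top_k(ctx, 5), metric_prec_k(ctx, 5),
      metric_aupr(ctx), metric_ndcg(ctx))
  }
  base <- eval_all(inst$scores)
  expect_equal(eval_all(exp(2 * inst$scores)), base, tolerance = 1e-12)
  expect_equal(eval_all(atan(inst$scores) * 7 + 3), base, tolerance = 1e-12)
})

test_that("drugs without the required test data are excluded with a warning", {
  scores <- matrix(rnorm(8), 2, 4)
  tri <- cbind(1, 1, 3)   # only drug 1 has triples
  ctx <- eval_context(scores, rbind(c(1, 1), c(2, 2)), triples = tri)
  expect_warning(a <- metric_auc(ctx), "excluded")
  expect_true(a %in% c(0, 1))
})
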