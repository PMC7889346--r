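toy_model <- function(m = 3, n = 5, f = 4, sd = 0.5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  list(F_D = matrix(rnorm(m * f, sd = sd), m, f),
       F_T = matrix(rnorm(n * f, sd = sd), n, f))
}

test_that("pair score is the inner product of the factor rows", {
  mod <- list(F_D = rbind(c(1, 0), c(1, 1)), F_T = rbind(c(0, 1), c(1, 1)))
  expect_equal(dti_score(mod, 1, 1), 0)
  expect_equal(dti_score(mod, 2, 2), 2)
  expect_error(dti_score(mod, 3, 1), "out of range")
  expect_error(dti_score(mod, 1, 9), "out of range")
  set.seed(1)
  mod <- toy_model(f = 5)
  s <- 0
  for (d in 1:5) s <- s + mod$F_D[2, d] * mod$F_T[3, d]
  expect_equal(dti_score(mod, 2, 3), s)
})

test_that("triple loss matches its closed forms and stays stable in the tails", {
  ## equal scores: -ln sigma(0) = ln 2
  mod <- list(F_D = rbind(c(1, 0)), F_T = rbind(c(0, 1), c(0, 1)))
  expect_equal(bpr_loss(mod, c(1, 1, 2), lambda_theta = 0), log(2))
  ## unit-norm rows, zero gap, lambda_theta = 1 -> ln 2 + 3
  mod2 <- list(F_D = rbind(c(1, 0)), F_T = rbind(c(0, 1), c(0, 1)))
  expect_equal(bpr_loss(mod2, c(1, 1, 2), lambda_theta = 1), log(2) + 3)
  ## softplus tail at gap +20
  mod3 <- list(F_D = rbind(c(20, 0)), F_T = rbind(c(1, 0), c(0, 0)))
  expect_equal(bpr_loss(mod3, c(1, 1, 2), lambda_theta = 0),
               log1p(exp(-20)), tolerance = 1e-12)
  expect_equal(log1p(exp(-20)), 2.061e-9, tolerance = 1e-3)
  ## extreme gaps stay finite in both directions
  mod4 <- list(F_D = rbind(c(500, 0)), F_T = rbind(c(1, 0), c(0, 0)))
  expect_true(is.finite(bpr_loss(mod4, c(1, 1, 2), 0)))
  expect_true(is.finite(bpr_loss(mod4, c(1, 2, 1), 0)))
  expect_equal(bpr_loss(mod4, c(1, 2, 1), 0), 500, tolerance = 1e-10)
})

test_that("sigmoid score comparison is antisymmetric", {
  set.seed(4)
  g <- c(rnorm(50, sd = 5), -30, 30, 0)
  s <- 1 / (1 + exp(-g))
  expect_equal(s + 1 / (1 + exp(g)), rep(1, length(g)), tolerance = 1e-12)
})

test_that("BPR gradients match finite differences and their symmetries", {
  ## identical pos/neg rows: ranking term cancels in the drug gradient
  mod <- list(F_D = rbind(c(0.3, -0.2)), F_T = rbind(c(0.5, 0.1), c(0.5, 0.1)))
  gr <- bpr_gradients(mod, c(1, 1, 2), lambda_theta = 0.25)
  expect_equal(gr$drug, 2 * 0.25 * mod$F_D[1, ])

  set.seed(11)
  for (rep in 1:20) {
    mod <- toy_model(m = 3, n = 4, f = 4)
    tri <- c(sample(3, 1), 1, 2)
    lt <- runif(1, 0, 0.5)
    gr <- bpr_gradients(mod, tri, lt)
    fd_d <- fd_gradient(function(v) {
      m2 <- mod; m2$F_D[tri[1], ] <- v; bpr_loss(m2, tri, lt)
    }, mod$F_D[tri[1], ])
    fd_j <- fd_gradient(function(v) {
      m2 <- mod; m2$F_T[tri[2], ] <- v; bpr_loss(m2, tri, lt)
    }, mod$F_T[tri[2], ])
    fd_k <- fd_gradient(function(v) {
      m2 <- mod; m2$F_T[tri[3], ] <- v; bpr_loss(m2, tri, lt)
    }, mod$F_T[tri[3], ])
    expect_lt(rel_err(gr$drug, fd_d), 1e-5)
    expect_lt(rel_err(gr$pos, fd_j), 1e-5)
    expect_lt(rel_err(gr$neg, fd_k), 1e-5)
  }

  ## swapping the positive and negative targets flips the sigmoid factor
  mod <- toy_model(seed = 21)
  g12 <- bpr_gradients(mod, c(1, 1, 2), 0)
  g21 <- bpr_gradients(mod, c(1, 2, 1), 0)
  fi <- mod$F_D[1, ]; diff <- mod$F_T[1, ] - mod$F_T[2, ]
  gap <- sum(fi * diff)
  s <- 1 / (1 + exp(gap))
  expect_equal(g12$drug, -s * diff, tolerance = 1e-12)
  expect_equal(g21$drug, (1 - s) * diff, tolerance = 1e-12)
})

test_that("adversarial perturbation is the normalized fast gradient", {
  ## direct normalization example: block (3,4), eps = 0.1 -> (0.06, 0.08)
  mod <- list(F_D = rbind(c(1, 1)), F_T = rbind(c(-3, -4) / 2, c(3, 4) / 2))
  ## drug gradient block = -sigma(-g) (fj - fk) proportional to (3,4)
  d <- adversarial_delta(mod, c(1, 1, 2), epsilon = 0.1)
  expect_equal(d$drug / sqrt(sum(d$drug^2)), c(3, 4) / 5, tolerance = 1e-12)
  expect_equal(sqrt(sum(d$drug^2)), 0.1, tolerance = 1e-12)

  z <- adversarial_delta(mod, c(1, 1, 2), epsilon = 0)
  expect_equal(z$drug, c(0, 0))
  expect_equal(z$pos, c(0, 0))

  set.seed(31)
  for (rep in 1:20) {
    mod <- toy_model()
    d <- adversarial_delta(mod, c(1, 1, 2), epsilon = 0.37)
    for (blk in d) {
      expect_equal(sqrt(sum(blk^2)), 0.37, tolerance = 1e-12)
    }
  }
})

test_that("adversarial direction increases the ranking loss more than random
           same-norm perturbations", {
  set.seed(55)
  eps <- 0.1
  wins <- sapply(1:5, function(inst) {
    mod <- toy_model(f = 5, sd = 0.6)
    tri <- c(1, 1, 2)
    d <- adversarial_delta(mod, tri, eps)
    fi <- mod$F_D[tri[1], ]; fj <- mod$F_T[tri[2], ]; fk <- mod$F_T[tri[3], ]
    l_adv <- rank_loss_at(fi + d$drug, fj + d$pos, fk + d$neg)
    mean(replicate(100, {
      rnd <- lapply(1:3, function(z) {
        v <- rnorm(5); eps * v / sqrt(sum(v^2))
      })
      l_adv >= rank_loss_at(fi + rnd[[1]], fj + rnd[[2]], fk + rnd[[3]])
    }))
  })
  expect_true(all(wins >= 0.95))
})

test_that("similarity regularizer term and gradient match finite differences", {
  ## identical factors with all-ones similarity: exact zero
  Fm <- matrix(0.4, 4, 3)
  S1 <- matrix(1, 4, 4)
  expect_equal(simgaus_term(S1, Fm, 2), 0)
  expect_equal(simgaus_gradient(S1, Fm, 2), c(0, 0, 0))

  ## single pair at distance^2 = ln 2 with S = 0.5: the Gaussian matches
  Fp <- rbind(c(0, 0), c(sqrt(log(2)), 0))
  Sp <- matrix(c(1, 0.5, 0.5, 1), 2, 2)
  expect_equal(simgaus_term(Sp, Fp, 1), 0, tolerance = 1e-12)

  ## dissimilar pair: penalty vanishes as the factors separate
  Sfar <- matrix(c(1, 0, 0, 1), 2, 2)
  d1 <- simgaus_term(Sfar, rbind(c(0, 0), c(1, 0)), 1)
  d2 <- simgaus_term(Sfar, rbind(c(0, 0), c(3, 0)), 1)
  expect_gt(d1, d2)
  expect_lt(d2, 1e-6)
  ## a descent step (-gradient) pushes the entity away from a dissimilar
  ## near neighbor sitting at +x
  g <- simgaus_gradient(Sfar, rbind(c(0, 0), c(0.5, 0)), 1)
  expect_gt(g[1], 0)

  set.seed(77)
  for (rep in 1:20) {
    ne <- sample(3:6, 1); f <- sample(2:4, 1)
    Fm <- matrix(rnorm(ne * f, sd = 0.7), ne, f)
    S <- matrix(runif(ne * ne), ne, ne)
    S <- (S + t(S)) / 2; diag(S) <- 1
    idx <- sample(ne, 1)
    gr <- simgaus_gradient(S, Fm, idx)
    fd <- fd_gradient(function(v) {
      F2 <- Fm; F2[idx, ] <- v; simgaus_term(S, F2, idx)
    }, Fm[idx, ])
    expect_lt(rel_err(gr, fd), 1e-5)
  }
})

test_that("with adversarial and similarity terms off, training reproduces the
           plain BPR trajectory bit for bit", {
  set.seed(13)
  pos <- do.call(rbind, lapply(1:6, function(i) cbind(i, sample(1:8, 2))))
  neg <- do.call(rbind, lapply(1:6, function(i) cbind(i, sample(9:20, 2))))
  ts <- generate_triples(pos, neg)
  hp <- bpr_hyperparams(factor_size = 4, lambda_sim = 0, lambda_adv = 0,
                        n_epochs = 15, seed = 101)
  got <- train_factors(ts, hp = hp, m = 6, n = 20)
  ref <- reference_bpr(ts, m = 6, n = 20, f = 4, lambda_theta = 0.1,
                       lr = 0.03, n_epochs = 15, seed = 101)
  expect_identical(got$F_D, ref$F_D)
  expect_identical(got$F_T, ref$F_T)
})

test_that("training is seed-deterministic and its loss trace decreases", {
  set.seed(17)
  syn <- synthetic_dti(synthetic_config(m_drugs = 15, n_targets = 10,
                                        n_nontargets = 40, F_dim = 25,
                                        interaction_rate = 0.2, seed = 2))
  im <- syn$interactions
  ts <- generate_triples(positive_pairs(im), sample_negatives(im, seed = 2))
  S_D <- similarity_matrix(syn$drug_profiles, "tanimoto")
  S_T <- similarity_matrix(syn$target_profiles, "tanimoto")
  hp <- bpr_hyperparams(factor_size = 4, n_epochs = 40, seed = 3)
  a <- train_factors(ts, S_D, S_T, hp)
  b <- train_factors(ts, S_D, S_T, hp)
  expect_identical(a$F_D, b$F_D)
  expect_identical(a$loss_trace, b$loss_trace)
  ## at the reference learning rate the mean loss is non-increasing in at
  ## least 80% of consecutive epoch pairs
  expect_gte(mean(diff(a$loss_trace) <= 0), 0.8)
})

test_that("ranking predictions sort by score with deterministic tie-breaks", {
  mod <- list(F_D = rbind(c(1, 0)),
              F_T = rbind(c(0.9, 0), c(0.1, 0), c(0.9, 0), c(0.5, 0)))
  rownames(mod$F_T) <- paste0("t", 1:4)
  rk <- predict_ranking(mod, 1)
  expect_equal(rk$target_index, c(1, 3, 4, 2))  # tie 1 vs 3 -> lower index
  rk2 <- predict_ranking(mod, 1, exclude = c(1))
  expect_equal(rk2$target_index[1], 3)
  expect_error(predict_ranking(mod, 1, candidates = 2, exclude = 2), "left")

  set.seed(23)
  mod <- list(F_D = matrix(rnorm(6), 2, 3), F_T = matrix(rnorm(300), 100, 3))
  rk <- predict_ranking(mod, 2)
  s <- as.numeric(mod$F_T %*% mod$F_D[2, ])
  expect_equal(rk$score, sort(s, decreasing = TRUE))
  expect_equal(rk$target_index, order(-s, seq_along(s)))
})

test_that("top-fraction cut removes known pairs before cutting", {
  ranked <- data.frame(drug = "d1", target = sprintf("t%03d", 1:1000),
                       score = seq(1000, 1))
  expect_equal(nrow(top_fraction(ranked, 0.01)), 10)
  expect_equal(nrow(top_fraction(ranked, 1)), 1000)
  ## the two known pairs sit inside the head: cut-then-remove would return
  ## 8 rows starting at t001; remove-then-cut returns 10 rows without them
  known <- data.frame(drug = "d1", target = c("t001", "t005"))
  out <- top_fraction(ranked, 0.01, known = known)
  expect_equal(nrow(out), 10)
  expect_false(any(out$target %in% known$target))
  expect_equal(out$target[1], "t002")
  expect_equal(out$target[10], "t012")
  expect_error(top_fraction(ranked, 0), "fraction")
})
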