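#' Hyperparameters for the ranking factorization
#'
#' Defaults follow the experimental settings the method was developed with:
#' perturbation budget `epsilon = 0.1`, L2 weight `lambda_theta = 0.1`,
#' learning rate 0.03; `factor_size = 25` sits at the point where held-out
#' performance stabilizes, and `lambda_sim = 0.5`, `lambda_adv = 0.3` are
#' mid-grid values that performed best overall.
#'
#' @param factor_size latent dimension f (>= 1).
#' @param lambda_theta L2 regularization weight on the three factor rows of
#'   a triple (>= 0).
#' @param lambda_sim weight of the Gaussian dual-similarity regularizer
#'   (>= 0).
#' @param lambda_adv weight of the adversarially perturbed ranking loss
#'   (>= 0).
#' @param epsilon L2 budget of each adversarial perturbation block (>= 0).
#' @param learning_rate SGD step size (> 0).
#' @param n_epochs number of passes over the triple set.
#' @param seed integer seed governing initialization and shuffling.
#' @return a validated `bpr_hyperparams` list.
#' @export
bpr_hyperparams <- function(factor_size = 25L, lambda_theta = 0.1,
                            lambda_sim = 0.5, lambda_adv = 0.3,
                            epsilon = 0.1, learning_rate = 0.03,
                            n_epochs = 100L, seed = 1L) {
  hp <- list(factor_size = as.integer(factor_size),
             lambda_theta = lambda_theta, lambda_sim = lambda_sim,
             lambda_adv = lambda_adv, epsilon = epsilon,
             learning_rate = learning_rate, n_epochs = as.integer(n_epochs),
             seed = as.integer(seed))
  if (hp$factor_size < 1) stop("factor_size must be >= 1")
  if (hp$lambda_theta < 0 || hp$lambda_sim < 0 || hp$lambda_adv < 0) {
    stop("regularization weights must be non-negative")
  }
  if (hp$epsilon < 0) stop("epsilon must be >= 0")
  if (hp$learning_rate <= 0) stop("learning_rate must be positive")
  if (hp$n_epochs < 1) stop("n_epochs must be >= 1")
  class(hp) <- "bpr_hyperparams"
  hp
}

#' Predicted interaction score of one drug-target pair
#'
#' The score is the inner product of the drug's and the target's latent
#' factor rows.
#'
#' @param model a fitted [bpr_dti()] object, or any list with matrices
#'   `F_D` and `F_T`.
#' @param i drug row index; @param j target row index.
#' @export
dti_score <- function(model, i, j) {
  if (i < 1 || i > nrow(model$F_D)) stop("drug index out of range: ", i)
  if (j < 1 || j > nrow(model$F_T)) stop("target index out of range: ", j)
  sum(model$F_D[i, ] * model$F_T[j, ])
}

#' Ranking loss of one triple
#'
#' \eqn{-\ln\sigma(r_{ij} - r_{ik}) + \lambda_\theta(\|F_i^D\|^2 +
#' \|F_j^T\|^2 + \|F_k^T\|^2)}, evaluated through the softplus form so that
#' large score gaps neither overflow nor underflow.
#'
#' @param model list with factor matrices `F_D`, `F_T`.
#' @param triple integer vector (drug, positive target, negative target).
#' @param lambda_theta L2 weight.
#' @export
bpr_loss <- function(model, triple, lambda_theta = 0.1) {
  fi <- model$F_D[triple[1], ]; fj <- model$F_T[triple[2], ]
  fk <- model$F_T[triple[3], ]
  g <- sum(fi * (fj - fk))
  softplus(-g) + lambda_theta * (sum(fi^2) + sum(fj^2) + sum(fk^2))
}

#' Analytic gradients of the triple loss
#'
#' Returns the gradient blocks with respect to the three factor rows
#' touched by the triple. Writing \eqn{g = r_{ij} - r_{ik}}:
#' \deqn{\partial/\partial F_i^D = -\sigma(-g)(F_j^T - F_k^T) +
#'   2\lambda_\theta F_i^D}
#' and analogously for the positive and negative target rows.
#'
#' @inheritParams bpr_loss
#' @return list with components `drug`, `pos`, `neg` (length-f vectors).
#' @export
bpr_gradients <- function(model, triple, lambda_theta = 0.1) {
  fi <- model$F_D[triple[1], ]; fj <- model$F_T[triple[2], ]
  fk <- model$F_T[triple[3], ]
  diff <- fj - fk
  s <- sigmoid(-sum(fi * diff))
  list(drug = -s * diff + 2 * lambda_theta * fi,
       pos  = -s * fi + 2 * lambda_theta * fj,
       neg  =  s * fi + 2 * lambda_theta * fk)
}

norm_block <- function(v, epsilon) {
  nv <- sqrt(sum(v * v))
  if (nv > 0) epsilon * v / nv else v * 0
}

#' Adversarial perturbation of a triple's factor rows
#'
#' The fast-gradient perturbation: the gradient of the unregularized
#' ranking term with respect to each factor block, normalized to L2 norm
#' `epsilon` per block (a zero gradient block yields a zero perturbation).
#' The perturbation is treated as a constant thereafter.
#'
#' @inheritParams bpr_loss
#' @param epsilon perturbation budget (>= 0).
#' @return list with components `drug`, `pos`, `neg`.
#' @export
adversarial_delta <- function(model, triple, epsilon = 0.1) {
  if (epsilon < 0) stop("epsilon must be >= 0")
  fi <- model$F_D[triple[1], ]; fj <- model$F_T[triple[2], ]
  fk <- model$F_T[triple[3], ]
  diff <- fj - fk
  s <- sigmoid(-sum(fi * diff))
  list(drug = norm_block(-s * diff, epsilon),
       pos  = norm_block(-s * fi, epsilon),
       neg  = norm_block(s * fi, epsilon))
}

#' Gaussian dual-similarity penalty for one entity
#'
#' \eqn{\sum_j (S_{ij} - e^{-\|F_i - F_j\|^2})^2}: the profile similarity
#' of entity i to every entity j is matched against the Gaussian kernel of
#' their latent distance. The self term vanishes when the diagonal of S
#' is 1.
#'
#' @param S square similarity matrix aligned with `F`.
#' @param F factor matrix (one row per entity).
#' @param idx entity row index.
#' @export
simgaus_term <- function(S, F, idx) {
  if (nrow(S) != nrow(F)) stop("similarity and factor matrices misaligned")
  dm <- F - rep(F[idx, ], each = nrow(F))
  e <- exp(-rowSums(dm * dm))
  r <- as.numeric(S[, idx]) - e
  sum(r * r)
}

#' @rdname simgaus_term
#' @details `simgaus_gradient()` returns the gradient with respect to the
#'   row `F[idx, ]`:
#'   \eqn{\sum_j 4 (S_{ij} - e^{-d^2}) e^{-d^2} (F_i - F_j)} with
#'   \eqn{d^2 = \|F_i - F_j\|^2}.
#' @export
simgaus_gradient <- function(S, F, idx) {
  if (nrow(S) != nrow(F)) stop("similarity and factor matrices misaligned")
  dm <- F - rep(F[idx, ], each = nrow(F))   # rows F_j - F_i
  e <- exp(-rowSums(dm * dm))
  w <- 4 * (as.numeric(S[, idx]) - e) * e
  -colSums(dm * w)
}

#' Train latent factors by adversarial BPR with similarity regularization
#'
#' Stochastic gradient descent over the triple set: each epoch visits the
#' triples in a freshly seeded random order; for each triple the update
#' accumulates (1) the BPR gradient (ranking term plus the L2 regularizer,
#' applied once, at the unperturbed parameters), (2) `lambda_adv` times the
#' ranking gradient evaluated at the adversarially perturbed factors
#' (perturbation recomputed per update, constant within the update), and
#' (3) `lambda_sim` times the Gaussian dual-similarity gradients of the
#' three touched rows, then applies one simultaneous learning-rate step.
#'
#' Factors are initialized from N(0, 0.01^2) under the seed in `hp`.
#'
#' @param ts a `triple_set` (integer matrix drug/pos/neg).
#' @param m,n numbers of drugs and of targets+non-targets; inferred from
#'   the similarity matrices when those are supplied.
#' @param S_D,S_T drug-drug and target-target [similarity_matrix()]
#'   objects; may be `NULL` when `lambda_sim = 0`.
#' @param hp a [bpr_hyperparams()] object.
#' @return list with `F_D`, `F_T`, and `loss_trace` (mean per-triple
#'   objective per epoch, evaluated at the pre-update parameters).
#' @export
train_factors <- function(ts, S_D = NULL, S_T = NULL, hp = bpr_hyperparams(),
                          m = if (!is.null(S_D)) nrow(S_D) else max(ts[, 1]),
                          n = if (!is.null(S_T)) nrow(S_T) else max(ts[, 2:3])) {
  nt <- nrow(ts)
  if (nt == 0) stop("triple set is empty")
  f <- hp$factor_size
  lt <- hp$lambda_theta; ls <- hp$lambda_sim; la <- hp$lambda_adv
  eps <- hp$epsilon; lr <- hp$learning_rate
  if (ls > 0 && (is.null(S_D) || is.null(S_T))) {
    stop("lambda_sim > 0 requires both similarity matrices")
  }
  if (!is.null(S_D) && nrow(S_D) != m) stop("S_D misaligned with drug count")
  if (!is.null(S_T) && nrow(S_T) != n) stop("S_T misaligned with target count")
  if (!is.null(S_D)) S_D <- unclass(S_D)
  if (!is.null(S_T)) S_T <- unclass(S_T)
  ti <- ts[, 1]; tj <- ts[, 2]; tk <- ts[, 3]
  trace <- numeric(hp$n_epochs)
  with_seed(hp$seed, {
    F_D <- matrix(stats::rnorm(m * f, sd = 0.01), m, f)
    F_T <- matrix(stats::rnorm(n * f, sd = 0.01), n, f)
    for (ep in seq_len(hp$n_epochs)) {
      ord <- sample.int(nt)
      tot <- 0
      for (idx in ord) {
        i <- ti[idx]; j <- tj[idx]; k <- tk[idx]
        fi <- F_D[i, ]; fj <- F_T[j, ]; fk <- F_T[k, ]
        diff <- fj - fk
        g <- sum(fi * diff)
        s <- sigmoid(-g)
        l <- softplus(-g) +
          lt * (sum(fi * fi) + sum(fj * fj) + sum(fk * fk))
        gi <- -s * diff + 2 * lt * fi
        gj <- -s * fi + 2 * lt * fj
        gk <-  s * fi + 2 * lt * fk
        if (la > 0) {
          pfi <- fi + norm_block(-s * diff, eps)
          pfj <- fj + norm_block(-s * fi, eps)
          pfk <- fk + norm_block(s * fi, eps)
          pdiff <- pfj - pfk
          pg <- sum(pfi * pdiff)
          psig <- sigmoid(-pg)
          l <- l + la * softplus(-pg)
          gi <- gi + la * (-psig * pdiff)
          gj <- gj + la * (-psig * pfi)
          gk <- gk + la * (psig * pfi)
        }
        if (ls > 0) {
          dmD <- F_D - rep(fi, each = m)
          eD <- exp(-rowSums(dmD * dmD))
          rD <- S_D[, i] - eD
          l <- l + ls * sum(rD * rD)
          gi <- gi + ls * (-colSums(dmD * (4 * rD * eD)))
          dmJ <- F_T - rep(fj, each = n)
          eJ <- exp(-rowSums(dmJ * dmJ))
          rJ <- S_T[, j] - eJ
          l <- l + ls * sum(rJ * rJ)
          gj <- gj + ls * (-colSums(dmJ * (4 * rJ * eJ)))
          dmK <- F_T - rep(fk, each = n)
          eK <- exp(-rowSums(dmK * dmK))
          rK <- S_T[, k] - eK
          l <- l + ls * sum(rK * rK)
          gk <- gk + ls * (-colSums(dmK * (4 * rK * eK)))
        }
        if (!is.finite(l)) {
          stop("training diverged (non-finite loss) at epoch ", ep,
               ", triple ", idx)
        }
        tot <- tot + l
        F_D[i, ] <- fi - lr * gi
        F_T[j, ] <- fj - lr * gj
        F_T[k, ] <- fk - lr * gk
      }
      trace[ep] <- tot / nt
    }
    list(F_D = F_D, F_T = F_T, loss_trace = trace)
  })
}
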