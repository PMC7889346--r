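#' Configuration of the planted-factor synthetic dataset
#'
#' The generator emulates the structure the ranking model assumes: a
#' low-rank interaction signal, expression profiles correlated with the
#' planted factors, and a large non-target pool with no positive edges.
#' Defaults are a desk-scale version of a typical cell-line dataset
#' (hundreds of drugs, a few hundred targets, thousands of non-targets)
#' shrunk so the full pipeline runs in seconds: 60 drugs, 40 true targets,
#' 300 non-targets, planted rank 5, 978 features, 5% positive rate.
#'
#' @param m_drugs,n_targets,n_nontargets entity counts (>= 1).
#' @param f_true planted latent rank.
#' @param F_dim feature dimension of the profiles (978 emulates the L1000
#'   landmark genes).
#' @param signal_noise standard deviation of the additive Gaussian feature
#'   noise (profile entries are approximately unit-variance, so 0.3 is a
#'   high signal-to-noise setting).
#' @param interaction_rate fraction of drug x true-target pairs made
#'   positive (0 < rate < 1).
#' @param seed integer seed; generation is fully reproducible.
#' @export
synthetic_config <- function(m_drugs = 60L, n_targets = 40L,
                             n_nontargets = 300L, f_true = 5L, F_dim = 978L,
                             signal_noise = 0.3, interaction_rate = 0.05,
                             seed = 1L) {
  cfg <- list(m_drugs = as.integer(m_drugs), n_targets = as.integer(n_targets),
              n_nontargets = as.integer(n_nontargets),
              f_true = as.integer(f_true), F_dim = as.integer(F_dim),
              signal_noise = signal_noise,
              interaction_rate = interaction_rate, seed = as.integer(seed))
  if (any(unlist(cfg[1:5]) < 1)) stop("all counts and dimensions must be >= 1")
  if (cfg$interaction_rate <= 0 || cfg$interaction_rate >= 1) {
    stop("interaction_rate must lie strictly between 0 and 1")
  }
  if (cfg$signal_noise < 0) stop("signal_noise must be >= 0")
  class(cfg) <- "synthetic_config"
  cfg
}

#' Generate a planted-factor synthetic DTI dataset
#'
#' Draws planted factors `G_D` (drugs) and `G_T` (targets and non-targets)
#' from a standard Gaussian; the positive interactions are the top
#' `interaction_rate` fraction of the planted scores `G_D %*% t(G_T)` among
#' the true-target columns (non-target columns never receive a positive).
#' Profiles embed the planted factors into `F_dim` dimensions through a
#' fixed orthonormal random linear map (scaled so entries are about unit
#' variance) plus Gaussian noise, so profile similarity reflects factor
#' similarity; with `signal_noise = 0` the cosine similarity of two
#' profiles equals that of the planted factors exactly.
#'
#' @param cfg a [synthetic_config()].
#' @return list with `drug_profiles`, `target_profiles`
#'   ([profile_matrix()] objects), `interactions`
#'   (an `interaction_matrix`), `edges` (positive pairs as an id data
#'   frame), and `factors` (the planted `G_D`, `G_T`).
#' @export
synthetic_dti <- function(cfg = synthetic_config()) {
  m <- cfg$m_drugs; nt <- cfg$n_targets; nn <- cfg$n_nontargets
  n <- nt + nn; f <- cfg$f_true; Fd <- cfg$F_dim
  n_pos <- round(cfg$interaction_rate * m * nt)
  if (n_pos < 1) stop("interaction_rate yields zero positive pairs")
  with_seed(cfg$seed, {
    G_D <- matrix(stats::rnorm(m * f), m, f)
    G_T <- matrix(stats::rnorm(n * f), n, f)
    Q <- qr.Q(qr(matrix(stats::rnorm(Fd * f), Fd, f)))  # orthonormal columns
    noise_d <- matrix(stats::rnorm(m * Fd, sd = cfg$signal_noise), m, Fd)
    noise_t <- matrix(stats::rnorm(n * Fd, sd = cfg$signal_noise), n, Fd)
  })
  drug_ids <- sprintf("D%03d", seq_len(m))
  target_ids <- c(sprintf("T%03d", seq_len(nt)), sprintf("N%03d", seq_len(nn)))
  rownames(G_D) <- drug_ids; rownames(G_T) <- target_ids

  planted <- G_D %*% t(G_T[seq_len(nt), , drop = FALSE])
  cut <- sort(planted, decreasing = TRUE)[n_pos]
  y <- matrix(0L, m, n, dimnames = list(drug_ids, target_ids))
  y[, seq_len(nt)][planted >= cut] <- 1L
  ## exact count even if the threshold ties (Gaussian scores: measure zero,
  ## but keep the contract airtight)
  if (sum(y) > n_pos) {
    extra <- which(y == 1L & cbind(planted, matrix(-Inf, m, nn)) == cut)
    y[extra[seq_len(sum(y) - n_pos)]] <- 0L
  }
  im <- interaction_matrix(y, nontarget = c(rep(FALSE, nt), rep(TRUE, nn)))

  scale <- sqrt(Fd / f)
  dp <- profile_matrix(scale * G_D %*% t(Q) + noise_d, drug_ids)
  tp <- profile_matrix(scale * G_T %*% t(Q) + noise_t, target_ids)
  pp <- positive_pairs(im)
  edges <- data.frame(drug = drug_ids[pp[, 1]], target = target_ids[pp[, 2]],
                      stringsAsFactors = FALSE)
  list(drug_profiles = dp, target_profiles = tp, interactions = im,
       edges = edges, factors = list(G_D = G_D, G_T = G_T))
}

#' Permute interaction labels (negative control)
#'
#' Reassigns the positive cells uniformly at random among the
#' drug x true-target cells, preserving the total positive count and the
#' non-target flags. A model trained on permuted labels should rank
#' held-out pairs no better than chance.
#'
#' @param im an `interaction_matrix`.
#' @param seed integer seed.
#' @export
permute_labels <- function(im, seed = 1L) {
  true_cols <- which(!im$nontarget)
  m <- length(im$drug_ids)
  n_pos <- sum(im$y)
  if (n_pos == 0) stop("no positives to permute")
  cells <- with_seed(seed, sample.int(m * length(true_cols), n_pos))
  y <- matrix(0L, m, length(im$target_ids),
              dimnames = dimnames(im$y))
  i <- ((cells - 1L) %% m) + 1L
  k <- true_cols[((cells - 1L) %/% m) + 1L]
  y[cbind(i, k)] <- 1L
  interaction_matrix(y, nontarget = im$nontarget, cell_line = im$cell_line)
}
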