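#' Fit a drug-target interaction ranking model
#'
#' High-level fitting interface. From expression profiles and a positive
#' edge list it (1) builds the interaction matrix and flags non-targets,
#' (2) samples as many negatives as there are positives from the
#' drug x non-target pool, (3) forms partial-order triples, (4) computes
#' drug-drug and target-target similarity matrices from the profiles, and
#' (5) trains latent factors by adversarial Bayesian personalized ranking
#' with Gaussian dual-similarity regularization (see [train_factors()]).
#'
#' When `cv_fold` is given, the triples are split into `n_folds`
#' drug-stratified folds and the chosen fold is held out from training;
#' the held-out triples are stored in the fit for evaluation.
#'
#' @param drug_profiles,target_profiles [profile_matrix()] objects (the
#'   target matrix covers targets and non-targets).
#' @param edges data frame of positive (drug id, target id) pairs.
#' @param sim_method similarity kernel for both sides; see
#'   [similarity_matrix()].
#' @param hp a [bpr_hyperparams()] object. Individual `...` arguments
#'   (e.g. `factor_size = 10`) override its components.
#' @param triple_mode `"cross"` (all positive x negative combinations per
#'   drug) or `"paired"`; see [generate_triples()].
#' @param clamp_similarity clamp negative similarities to 0 (default).
#' @param cv_fold optional fold index in `1..n_folds` to hold out.
#' @param n_folds number of cross-validation folds (used when `cv_fold`
#'   is given).
#' @param cv_by splitting unit for the folds: `"triple"` or the strict
#'   `"pair"` mode in which a held-out positive pair never appears in a
#'   training triple; see [split_cv()].
#' @param seed integer seed for negative sampling and fold assignment
#'   (factor initialization and shuffling are governed by `hp$seed`,
#'   which defaults to this seed).
#' @param ... components of [bpr_hyperparams()] to override.
#' @return an object of class `bpr_dti` with components `F_D`, `F_T`
#'   (latent factors, rownames carrying ids), `loss_trace`, `hp`,
#'   `sim_method`, `im` (interaction matrix), `triples`, `train_triples`,
#'   `test_triples`, `negatives`, and `call`. Methods: `print`, `summary`,
#'   `coef`, `predict`, `plot`, `fitted`.
#' @examples
#' syn <- synthetic_dti(synthetic_config(m_drugs = 12, n_targets = 8,
#'                                       n_nontargets = 20, F_dim = 30,
#'                                       interaction_rate = 0.2, seed = 7))
#' fit <- bpr_dti(syn$drug_profiles, syn$target_profiles, syn$edges,
#'                n_epochs = 5, seed = 7)
#' fit
#' head(predict(fit, type = "ranking", k = 3))
#' @export
bpr_dti <- function(drug_profiles, target_profiles, edges,
                    sim_method = c("tanimoto", "cosine", "ssim", "spearman"),
                    hp = NULL, triple_mode = c("cross", "paired"),
                    clamp_similarity = TRUE, cv_fold = NULL, n_folds = 5L,
                    cv_by = c("triple", "pair"), seed = 1L, ...) {
  sim_method <- match.arg(sim_method)
  triple_mode <- match.arg(triple_mode)
  cl <- match.call()
  if (is.null(hp)) hp <- bpr_hyperparams(seed = seed)
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(unclass(hp)))
    if (length(bad)) stop("unknown hyperparameter(s): ",
                          paste(bad, collapse = ", "))
    hp[names(dots)] <- dots
    hp <- do.call(bpr_hyperparams, unclass(hp))
  }

  im <- build_interaction_matrix(drug_profiles, target_profiles, edges)
  pos <- positive_pairs(im)
  neg <- sample_negatives(im, seed = seed)
  triples <- generate_triples(pos, neg, mode = triple_mode)
  if (nrow(triples) == 0) stop("no training triples could be generated")

  train_idx <- seq_len(nrow(triples))
  test_triples <- NULL
  cv <- NULL
  if (!is.null(cv_fold)) {
    cv <- split_cv(triples, n_folds = n_folds, seed = seed,
                   by = match.arg(cv_by))
    if (cv_fold < 1 || cv_fold > n_folds) stop("cv_fold out of range")
    train_idx <- which(cv$fold != cv_fold)
    test_triples <- triples[cv$fold == cv_fold, , drop = FALSE]
  }

  S_D <- S_T <- NULL
  if (hp$lambda_sim > 0) {
    S_D <- similarity_matrix(drug_profiles, sim_method, clamp = clamp_similarity)
    S_T <- similarity_matrix(target_profiles, sim_method,
                             clamp = clamp_similarity)
  }
  trained <- train_factors(triples[train_idx, , drop = FALSE], S_D, S_T, hp,
                           m = length(im$drug_ids),
                           n = length(im$target_ids))
  rownames(trained$F_D) <- im$drug_ids
  rownames(trained$F_T) <- im$target_ids
  structure(list(F_D = trained$F_D, F_T = trained$F_T,
                 loss_trace = trained$loss_trace, hp = hp,
                 sim_method = sim_method, im = im, triples = triples,
                 train_triples = triples[train_idx, , drop = FALSE],
                 test_triples = test_triples, negatives = neg, cv = cv,
                 seed = as.integer(seed), call = cl),
            class = "bpr_dti")
}

#' @export
print.bpr_dti <- function(x, ...) {
  cat("Adversarial BPR drug-target interaction model\n")
  cat("  drugs:", nrow(x$F_D), " targets/non-targets:", nrow(x$F_T),
      " latent factors:", x$hp$factor_size, "\n")
  cat("  similarity kernel:", x$sim_method,
      " lambda_sim:", x$hp$lambda_sim, " lambda_adv:", x$hp$lambda_adv,
      " epsilon:", x$hp$epsilon, "\n")
  cat("  training triples:", nrow(x$train_triples),
      " epochs:", x$hp$n_epochs,
      " final mean loss:", format(utils::tail(x$loss_trace, 1), digits = 5),
      "\n")
  if (!is.null(x$test_triples)) {
    cat("  held-out triples:", nrow(x$test_triples), "\n")
  }
  invisible(x)
}

#' @export
summary.bpr_dti <- function(object, ...) {
  scores <- fitted(object)
  pos <- positive_pairs(object$im)
  out <- list(
    n_drugs = nrow(object$F_D), n_targets = nrow(object$F_T),
    n_positives = nrow(pos), n_triples = nrow(object$triples),
    hp = object$hp, sim_method = object$sim_method,
    loss_first = object$loss_trace[1],
    loss_last = utils::tail(object$loss_trace, 1),
    score_pos_mean = mean(scores[pos]),
    score_all_mean = mean(scores))
  class(out) <- "summary.bpr_dti"
  out
}

#' @export
print.summary.bpr_dti <- function(x, ...) {
  cat("Adversarial BPR DTI model summary\n")
  cat("  ", x$n_drugs, "drugs, ", x$n_targets, "targets/non-targets, ",
      x$n_positives, "positive pairs, ", x$n_triples, "triples\n")
  cat("  similarity kernel:", x$sim_method, "\n")
  cat("  mean triple loss:", format(x$loss_first, digits = 5), "->",
      format(x$loss_last, digits = 5), "over training\n")
  cat("  mean score, known positives:", format(x$score_pos_mean, digits = 4),
      "  all pairs:", format(x$score_all_mean, digits = 4), "\n")
  invisible(x)
}

#' @export
coef.bpr_dti <- function(object, ...) {
  list(drug = object$F_D, target = object$F_T)
}

#' @export
fitted.bpr_dti <- function(object, ...) {
  object$F_D %*% t(object$F_T)
}

#' @export
plot.bpr_dti <- function(x, ...) {
  graphics::plot(seq_along(x$loss_trace), x$loss_trace, type = "l",
                 xlab = "epoch", ylab = "mean triple loss",
                 main = "Training loss", ...)
  invisible(x)
}

#' Predict interaction scores or rankings
#'
#' @param object a fitted `bpr_dti` model.
#' @param drugs drug ids or indices to predict for (default: all).
#' @param type `"scores"` returns the score matrix; `"ranking"` returns a
#'   long data frame of per-drug rankings.
#' @param k truncate each drug's ranking to its top k candidates.
#' @param exclude_known drop the drug's known (training) positive targets
#'   from its candidate list (default `TRUE` for rankings).
#' @param ... unused.
#' @export
predict.bpr_dti <- function(object, drugs = NULL,
                            type = c("scores", "ranking"), k = NULL,
                            exclude_known = TRUE, ...) {
  type <- match.arg(type)
  di <- if (is.null(drugs)) seq_len(nrow(object$F_D))
        else if (is.character(drugs)) match(drugs, rownames(object$F_D))
        else as.integer(drugs)
  if (anyNA(di) || any(di < 1 | di > nrow(object$F_D))) {
    stop("unknown drug id or index in `drugs`")
  }
  scores <- object$F_D[di, , drop = FALSE] %*% t(object$F_T)
  if (type == "scores") return(scores)
  out <- vector("list", length(di))
  for (a in seq_along(di)) {
    i <- di[a]
    excl <- if (exclude_known) which(object$im$y[i, ] == 1L) else integer(0)
    rk <- predict_ranking(object, i, exclude = excl)
    if (!is.null(k)) rk <- utils::head(rk, k)
    out[[a]] <- data.frame(drug = rownames(object$F_D)[i], rk,
                           rank = seq_len(nrow(rk)),
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Rank candidate targets for one drug
#'
#' Candidates are sorted by descending score; ties are broken by ascending
#' target index (deterministic). Excluded indices (typically the drug's
#' training positives) are removed first.
#'
#' @param model a fitted model (or list with `F_D`, `F_T`).
#' @param drug drug row index.
#' @param candidates integer target indices to rank (default: all).
#' @param exclude integer target indices to omit.
#' @return data frame with columns `target` (id if available, else index)
#'   `target_index`, and `score`, in rank order.
#' @export
predict_ranking <- function(model, drug, candidates = NULL,
                            exclude = integer(0)) {
  n <- nrow(model$F_T)
  if (is.null(candidates)) candidates <- seq_len(n)
  candidates <- setdiff(as.integer(candidates), as.integer(exclude))
  if (length(candidates) == 0) stop("no candidate targets left after exclusion")
  s <- as.numeric(model$F_T[candidates, , drop = FALSE] %*% model$F_D[drug, ])
  ord <- order(-s, candidates)
  ids <- rownames(model$F_T)
  data.frame(target = if (is.null(ids)) candidates[ord] else ids[candidates[ord]],
             target_index = candidates[ord], score = s[ord],
             stringsAsFactors = FALSE)
}

#' Top fraction of a ranked all-pairs prediction list
#'
#' Known interactions are removed first; then the top
#' `ceiling(fraction * remaining)` pairs are kept. Predicting "the top 1%"
#' of all ranked pairs therefore means 1% of the novel (non-training)
#' pairs.
#'
#' @param ranked data frame of ranked pairs with columns `drug`, `target`
#'   (ids), ordered best-first.
#' @param fraction fraction in (0, 1].
#' @param known optional data frame of known (drug, target) pairs to remove
#'   before cutting.
#' @return the head of `ranked` after removal.
#' @export
top_fraction <- function(ranked, fraction, known = NULL) {
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  if (!is.null(known) && nrow(known) > 0) {
    keys <- paste(ranked$drug, ranked$target, sep = "\r")
    kkeys <- paste(known[[1]], known[[2]], sep = "\r")
    ranked <- ranked[!(keys %in% kkeys), , drop = FALSE]
  }
  utils::head(ranked, ceiling(fraction * nrow(ranked)))
}

#' Persist / restore a fitted model as plain text
#'
#' Writes the two factor matrices as TSV (ids in the first column) plus a
#' key-value metadata file with the hyperparameters, seed, similarity
#' kernel, and the loss trace.
#'
#' @param fit a `bpr_dti` object.
#' @param dir directory to write into (created if needed).
#' @export
save_model <- function(fit, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(data.frame(id = rownames(fit$F_D), fit$F_D),
                     file.path(dir, "drug_factors.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(id = rownames(fit$F_T), fit$F_T),
                     file.path(dir, "target_factors.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  hp <- unclass(fit$hp)
  meta <- c(sprintf("%s=%s", names(hp), unlist(hp)),
            paste0("sim_method=", fit$sim_method),
            paste0("seed=", fit$seed),
            paste0("loss_trace=", paste(format(fit$loss_trace, digits = 17),
                                        collapse = ",")))
  writeLines(meta, file.path(dir, "run_metadata.txt"))
  invisible(dir)
}

#' @rdname save_model
#' @param dir directory previously written by `save_model()`.
#' @return `load_model()` returns a list with `F_D`, `F_T`, `hp`,
#'   `sim_method`, and `loss_trace`, usable with [predict_ranking()] and
#'   [dti_score()].
#' @export
load_model <- function(dir) {
  fd <- utils::read.table(file.path(dir, "drug_factors.tsv"), header = TRUE,
                          sep = "\t", row.names = 1)
  ft <- utils::read.table(file.path(dir, "target_factors.tsv"), header = TRUE,
                          sep = "\t", row.names = 1)
  meta <- readLines(file.path(dir, "run_metadata.txt"))
  kv <- strsplit(meta, "=", fixed = TRUE)
  vals <- stats::setNames(vapply(kv, function(x) paste(x[-1], collapse = "="),
                                 ""),
                          vapply(kv, `[[`, "", 1))
  hp <- bpr_hyperparams(
    factor_size = as.integer(vals[["factor_size"]]),
    lambda_theta = as.numeric(vals[["lambda_theta"]]),
    lambda_sim = as.numeric(vals[["lambda_sim"]]),
    lambda_adv = as.numeric(vals[["lambda_adv"]]),
    epsilon = as.numeric(vals[["epsilon"]]),
    learning_rate = as.numeric(vals[["learning_rate"]]),
    n_epochs = as.integer(vals[["n_epochs"]]),
    seed = as.integer(vals[["seed"]]))
  list(F_D = as.matrix(fd), F_T = as.matrix(ft), hp = hp,
       sim_method = vals[["sim_method"]],
       loss_trace = as.numeric(strsplit(vals[["loss_trace"]], ",")[[1]]))
}
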