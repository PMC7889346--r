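#' Run the full prediction workflow
#'
#' Wires the package's stages in order: simulate (when no input files are
#' given) -> similarity -> train -> evaluate -> predict & enrich, writing
#' every artifact as TSV plus a key-value run log. The workflow evaluates
#' by drug-stratified cross-validation over the ranking triples: one model
#' per fold, metrics per fold plus their mean. Predictions and enrichment
#' come from a final model trained on all triples.
#'
#' @param config a named list (or path to a flat `key = value` text file)
#'   with any of: `drug_profiles`, `target_profiles`, `edges` (input
#'   paths; all three absent triggers simulation), `reference_edges`
#'   (optional path for enrichment; defaults to the known positives),
#'   `sim_method`, `factor_size`, `lambda_theta`, `lambda_sim`,
#'   `lambda_adv`, `epsilon`, `learning_rate`, `n_epochs`, `n_folds`,
#'   `eval_pool` (`"filtered"` or `"full"`), `top_fraction`, `bin_size`,
#'   `seed`, and the [synthetic_config()] fields (`m_drugs`, ...) used
#'   when simulating.
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with the per-fold `metrics` data frame, the
#'   final `fit`, the `predictions` kept after the top-fraction cut, and
#'   the `enrichment` table.
#' @export
run_pipeline <- function(config = list(), out_dir) {
  if (is.character(config)) config <- read_run_config(config)
  defaults <- list(sim_method = "tanimoto", factor_size = 25L,
                   lambda_theta = 0.1, lambda_sim = 0.5, lambda_adv = 0.3,
                   epsilon = 0.1, learning_rate = 0.03, n_epochs = 100L,
                   n_folds = 5L, eval_pool = "filtered", top_fraction = 0.01,
                   bin_size = 500L, seed = 1L)
  cfg <- utils::modifyList(defaults, config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  stage <- "load"
  result <- tryCatch({
    if (is.null(cfg$drug_profiles)) {
      stage <- "simulate"
      syn_fields <- intersect(names(cfg), names(formals(synthetic_config)))
      syn <- synthetic_dti(do.call(synthetic_config,
                                   c(cfg[setdiff(syn_fields, "seed")],
                                     list(seed = cfg$seed))))
      dp <- syn$drug_profiles; tp <- syn$target_profiles; edges <- syn$edges
      write_profiles(dp, file.path(out_dir, "drug_profiles.tsv"))
      write_profiles(tp, file.path(out_dir, "target_profiles.tsv"))
      write_edges(edges, file.path(out_dir, "edges.tsv"))
      gt <- data.frame(id = c(rownames(syn$factors$G_D),
                              rownames(syn$factors$G_T)),
                       rbind(syn$factors$G_D, syn$factors$G_T))
      utils::write.table(gt, file.path(out_dir, "true_factors.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    } else {
      dp <- read_profiles(cfg$drug_profiles)
      tp <- read_profiles(cfg$target_profiles)
      edges <- read_edges(cfg$edges)
    }

    stage <- "similarity"
    S_D <- similarity_matrix(dp, cfg$sim_method)
    S_T <- similarity_matrix(tp, cfg$sim_method)
    write_similarity(S_D, file.path(out_dir, "similarity_drug.tsv"))
    write_similarity(S_T, file.path(out_dir, "similarity_target.tsv"))

    stage <- "train"
    fit_fold <- function(fold) {
      bpr_dti(dp, tp, edges, sim_method = cfg$sim_method,
              cv_fold = fold, n_folds = cfg$n_folds, seed = cfg$seed,
              factor_size = cfg$factor_size, lambda_theta = cfg$lambda_theta,
              lambda_sim = cfg$lambda_sim, lambda_adv = cfg$lambda_adv,
              epsilon = cfg$epsilon, learning_rate = cfg$learning_rate,
              n_epochs = cfg$n_epochs)
    }
    stage <- "evaluate"
    fold_metrics <- lapply(seq_len(cfg$n_folds), function(fold) {
      evaluate_model(fit_fold(fold), pool = cfg$eval_pool)
    })
    metrics <- do.call(rbind, fold_metrics)
    metrics <- rbind(metrics, colMeans(metrics))
    metrics <- data.frame(fold = c(seq_len(cfg$n_folds), NA), metrics)
    metrics$fold <- ifelse(is.na(metrics$fold), "mean", metrics$fold)
    utils::write.table(metrics, file.path(out_dir, "metrics.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

    stage <- "predict"
    fit <- bpr_dti(dp, tp, edges, sim_method = cfg$sim_method,
                   seed = cfg$seed, factor_size = cfg$factor_size,
                   lambda_theta = cfg$lambda_theta,
                   lambda_sim = cfg$lambda_sim, lambda_adv = cfg$lambda_adv,
                   epsilon = cfg$epsilon, learning_rate = cfg$learning_rate,
                   n_epochs = cfg$n_epochs)
    save_model(fit, file.path(out_dir, "model"))
    ranked <- predict(fit, type = "ranking", exclude_known = TRUE)
    ranked <- ranked[order(-ranked$score, ranked$drug, ranked$target), ]
    preds <- top_fraction(ranked[, c("drug", "target", "score")],
                          cfg$top_fraction)
    utils::write.table(preds, file.path(out_dir, "predictions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

    stage <- "enrich"
    ref <- if (!is.null(cfg$reference_edges)) read_edges(cfg$reference_edges)
           else edges
    enr <- enrichment_test(preds, list(reference = ref),
                           universe_drugs = profile_ids(dp),
                           universe_targets = profile_ids(tp))
    utils::write.table(enr, file.path(out_dir, "enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    oc <- overlap_curve(preds, ref, bin_size = cfg$bin_size)
    utils::write.table(oc, file.path(out_dir, "overlap_curve.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

    log_lines <- c(
      sprintf("package_version=%s",
              as.character(utils::packageVersion("bprdti"))),
      sprintf("%s=%s", names(cfg),
              vapply(cfg, function(v) paste(format(v), collapse = ","), "")))
    writeLines(log_lines, file.path(out_dir, "run_log.txt"))
    list(metrics = metrics, fit = fit, predictions = preds, enrichment = enr)
  }, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(result)
}

#' Read a flat key-value run configuration file
#'
#' Lines of the form `key = value` (or `key=value`); blank lines and lines
#' starting with `#` are ignored. Numeric-looking values are converted.
#'
#' @param path configuration file path.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- regmatches(lines, regexec("^([^=]+)=(.*)$", lines))
  cfg <- list()
  for (x in kv) {
    if (length(x) != 3) next
    key <- trimws(x[2]); val <- trimws(x[3])
    num <- suppressWarnings(as.numeric(val))
    cfg[[key]] <- if (!is.na(num)) num else val
  }
  cfg
}
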