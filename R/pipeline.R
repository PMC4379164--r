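# End-to-end orchestration: simulate (or load) -> preprocess -> paired
# moderated t -> gene-set scoring & enrichment -> qRT-PCR confirmation ->
# ratio-LDA training -> blinded prediction -> evaluation. One global seed
# deterministically derives a substream per stochastic stage.

#' Default pipeline configuration
#'
#' Study-condition defaults: 14 matched training pairs and 2,000 probes on
#' the array with 150 planted effects (|log2 FC| in [log2 1.5, log2 3]);
#' a 90-gene Ct panel with the V/O,H ratio plant, 14 training pairs,
#' 19 + 19 blinded test samples and one whole-sample PCR failure; a
#' 33-pair confirmation panel with 48 of 90 genes planted at one-cycle
#' effects; 20 gene sets of 30 genes sharing a 10-gene pool.
#'
#' @param seed global integer seed (mandatory for any stochastic stage).
#' @return nested configuration list.
#' @export
pipeline_config <- function(seed) {
  if (missing(seed) || is.null(seed))
    stop("a seed is mandatory: the pipeline has stochastic stages")
  list(
    seed = seed,
    expression = list(n_pairs = 14, n_probes = 2000, n_de = 150,
                      pair_sd = 0.5, noise_sd = 0.5),
    genesets = list(n_sets = 20, set_size = 30, n_shared = 10,
                    n_perm = 500),
    confirm = list(n_pairs = 33, n_genes = 90, n_planted = 48,
                   effect_cycles = 1, loading_sd = 1.0, noise_sd = 0.5,
                   missing_rate = 0.02),
    panel = list(n_pairs_train = 14, n_per_group_test = 19, n_genes = 90,
                 loading_sd = 1.0, noise_sd = 0.5, missing_rate = 0,
                 fail_samples = 1),
    de = list(p_max = 0.05, fc_min = 1.5),
    cv = list(n_repeats = 5, n_folds = 3,
              specificity_cutoffs = c(0.80, 0.85, 0.90),
              fc_min_ratio = 1.2, k_grid = 1:10),
    evaluation = list(n_boot = 2000, threshold_specificity = 0.85),
    comparators = FALSE
  )
}

#' Run the full discovery-and-validation pipeline
#'
#' Executes every stage on seeded synthetic data (or user-supplied files,
#' see Details) and returns an aggregated run report. Identical
#' configuration and seed give identical numeric results.
#'
#' Supply \code{config$expression$matrix_path} / \code{design_path} to use a
#' real expression matrix, \code{config$panel$ct_path} / \code{design_path}
#' for a real Ct panel, and \code{config$genesets$gmt_path} for a real
#' collection; otherwise the corresponding stage simulates its input from
#' the configured study conditions.
#'
#' @param config a configuration list as \code{\link{pipeline_config}}, or
#'   the path to a YAML file holding one.
#' @return list of class \code{"pipeline_report"}.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$seed))
    stop("config$seed is mandatory: the pipeline has stochastic stages")
  base <- pipeline_config(config$seed)
  for (nm in names(base))
    if (is.null(config[[nm]])) config[[nm]] <- base[[nm]]
    else if (is.list(base[[nm]]))
      for (k in names(base[[nm]]))
        if (is.null(config[[nm]][[k]])) config[[nm]][[k]] <- base[[nm]][[k]]
  seed <- config$seed

  # --- microarray stage ----------------------------------------------------
  ex_cfg <- config$expression
  if (!is.null(ex_cfg$matrix_path)) {
    expr <- read_expression_matrix(ex_cfg$matrix_path, ex_cfg$design_path)
    expr_design <- read_design(ex_cfg$design_path)
    expr_truth <- NULL
  } else {
    sim <- simulate_expression(n_pairs = ex_cfg$n_pairs,
                               n_probes = ex_cfg$n_probes,
                               n_de = ex_cfg$n_de,
                               pair_sd = ex_cfg$pair_sd,
                               noise_sd = ex_cfg$noise_sd,
                               seed = derive_seed(seed, "expression"))
    expr <- sim$expr; expr_design <- sim$design; expr_truth <- sim$truth
  }
  norm <- preprocess(expr)
  de_res <- paired_moderated_t(norm, expr_design)
  de_sel <- select_de(de_res, config$de$p_max, config$de$fc_min)

  # --- gene-set stage ------------------------------------------------------
  gs_cfg <- config$genesets
  universe <- rownames(norm)
  collection <- if (!is.null(gs_cfg$gmt_path)) read_gmt(gs_cfg$gmt_path)
  else simulate_genesets(gs_cfg$n_sets, gs_cfg$set_size, gs_cfg$n_shared,
                         universe, seed = derive_seed(seed, "genesets"))
  pathways <- pathway_scores(norm, expr_design, collection,
                             n_perm = gs_cfg$n_perm,
                             seed = derive_seed(seed, "pathways"))
  enrichment <- enrich_hypergeometric(de_sel$selected, universe, collection)

  # --- qRT-PCR confirmation stage -----------------------------------------
  cf <- config$confirm
  cseed <- derive_seed(seed, "confirm")
  planted_signs <- with_seed(cseed, {
    n_up <- ceiling(cf$n_planted / 2)
    sample(rep(c(1, -1), c(n_up, cf$n_planted - n_up)))
  })
  conf_genes_all <- c("V", "O", "H", sprintf("G%03d", seq_len(cf$n_genes - 3)))
  planted <- conf_genes_all[seq_len(cf$n_planted)]
  conf_effects <- stats::setNames(planted_signs * cf$effect_cycles, planted)
  conf_sim <- simulate_ct_panel(n_pairs_train = cf$n_pairs,
                                n_per_group_test = 0,
                                n_genes = cf$n_genes,
                                loading_sd = cf$loading_sd,
                                effects = conf_effects,
                                noise_sd = cf$noise_sd,
                                missing_rate = cf$missing_rate,
                                seed = cseed)
  directions <- with_seed(cseed + 1L, {
    d <- ifelse(conf_effects > 0, "up", "down")
    null_genes <- setdiff(conf_genes_all, planted)
    c(d, stats::setNames(sample(c("up", "down"), length(null_genes),
                                replace = TRUE), null_genes))
  })
  confirmation <- confirm_genes(conf_sim$ct, conf_sim$design, directions)

  # --- classifier training and blinded prediction --------------------------
  pn <- config$panel
  if (!is.null(pn$ct_path)) {
    ct <- read_ct_table(pn$ct_path, pn$design_path)
    panel_design <- read_design(pn$design_path)
    panel_truth <- NULL
  } else {
    psim <- simulate_ct_panel(n_pairs_train = pn$n_pairs_train,
                              n_per_group_test = pn$n_per_group_test,
                              n_genes = pn$n_genes,
                              loading_sd = pn$loading_sd,
                              noise_sd = pn$noise_sd,
                              missing_rate = pn$missing_rate,
                              fail_samples = pn$fail_samples,
                              seed = derive_seed(seed, "ct"))
    ct <- psim$ct; panel_design <- psim$design; panel_truth <- psim$truth
  }
  cvc <- do.call(cv_config, c(config$cv, list(seed = derive_seed(seed, "cv"))))
  model <- ratio_lda(ct, panel_design, cvc,
                     config$evaluation$threshold_specificity)
  comparators <- if (isTRUE(config$comparators)) {
    ratios <- make_ratios(ct[, panel_design$sample_id[
      panel_design$set == "A_train"], drop = FALSE], model$normalizer)
    keep_lab <- panel_design$group[panel_design$set == "A_train" &
                                     panel_design$sample_id %in% colnames(ratios)]
    fit_comparators(ratios, keep_lab, model$k, cvc)
  } else NULL

  test_design <- panel_design[panel_design$set == "B_test", , drop = FALSE]
  pred <- predict(model, ct[, test_design$sample_id, drop = FALSE])
  used <- !pred$excluded
  conf <- confusion(pred$class[used], test_design$group[used])

  # --- evaluation ----------------------------------------------------------
  train_design <- panel_design[panel_design$set == "A_train", , drop = FALSE]
  clin <- clinical_model(train_design, train_design$group,
                         test_design[used, , drop = FALSE])
  gene_scores <- pred$score[used]
  labels_used <- test_design$group[used]
  roc_gene <- roc_auc(gene_scores, labels_used)
  roc_clin <- roc_auc(clin$scores, labels_used)
  auc_cmp <- bootstrap_auc_test(gene_scores, clin$scores, labels_used,
                                n_boot = config$evaluation$n_boot,
                                seed = derive_seed(seed, "boot"))
  subgroup <- subgroup_auc(gene_scores, labels_used,
                           test_design$gestational_age_weeks[used])

  structure(list(
    config = config,
    de = list(results = de_res, selection = de_sel, truth = expr_truth),
    pathways = pathways,
    enrichment = enrichment,
    confirmation = confirmation,
    model = model,
    comparators = comparators,
    prediction = pred,
    confusion = conf,
    evaluation = list(auc_gene = roc_gene$auc, auc_clinical = roc_clin$auc,
                      auc_test = auc_cmp, subgroup = subgroup),
    panel_truth = panel_truth
  ), class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("== pipeline run report ==\n")
  cat(sprintf("differential expression: %d probes selected (%d unique genes)\n",
              x$de$selection$n_probes_selected, x$de$selection$n_unique_genes))
  cat(sprintf("gene sets with q < 0.1: %d of %d\n",
              sum(x$pathways$q < 0.1), nrow(x$pathways)))
  cat(sprintf("qRT-PCR confirmation: %d of %d testable genes\n",
              attr(x$confirmation, "n_confirmed"),
              attr(x$confirmation, "n_testable")))
  cat(sprintf("selected normalizer: %s; ratios: %s (criterion %.3f)\n",
              x$model$normalizer, paste(x$model$ratios, collapse = ", "),
              x$model$criterion))
  cat(sprintf("test set: %d samples scored, %d excluded; ",
              sum(!x$prediction$excluded), sum(x$prediction$excluded)))
  print(x$confusion)
  cat(sprintf("AUC gene model %.3f vs clinical %.3f (D = %.2f, p = %.4g)\n",
              x$evaluation$auc_gene, x$evaluation$auc_clinical,
              x$evaluation$auc_test$D, x$evaluation$auc_test$p))
  invisible(x)
}
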