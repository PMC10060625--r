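## End-to-end pipeline driver: simulate -> ingest -> cluster -> enrich ->
## DEG -> COPsig -> survival -> pharmaco -> single cell, from one config
## (list or YAML file), with versioned artifacts, a manifest of
## parameters/seeds/checksums, and full seeded reproducibility.

#' Default pipeline configuration
#'
#' Returns the configuration list for the packaged demo run: a small
#' three-subtype, two-batch cohort whose regulator panel drives the
#' clustering, survival tied to the subtypes, a cell-line panel with one
#' modelled compound, and a small single-cell cohort. Every
#' analysis-relevant default is a named key so sensitivity analyses are
#' one-line edits.
#'
#' @param out_dir directory the run writes into.
#' @param seed master seed; all stage seeds derive from it.
#' @return named configuration list.
#' @export
demo_config <- function(out_dir = tempfile("copsig_run_"), seed = 1) {
  list(
    out_dir = out_dir,
    seed = as.integer(seed),
    bulk = list(n_genes = 600, n_samples = 180, n_subtypes = 3,
                n_regulator_genes = 10, n_signature_genes_per_subtype = 40,
                subtype_effect = 3, n_batches = 2, batch_shift = 1,
                noise_sd = 0.5),
    survival = list(baseline_hazard = 0.02,
                    beta_subtype = list(cop1 = 0.8, cop2 = 0.4, cop3 = 0),
                    censor_rate = 0.01, max_followup = 120),
    cluster = list(k_min = 2, k_max = 4, n_reps = 100,
                   subsample_fraction = 0.8),
    enrich = list(alpha = 0.25),
    deg = list(fdr = 0.05),
    copsig = list(boruta_iter = 30, boruta_alpha = 0.01, split_rule = "median",
                  cox_p = 0.05),
    pharmaco = list(n_cell_lines = 60, n_compounds = 3, n_genes = 200,
                    auc_noise_sd = 0.1, na_fraction = c(0.1, 0.25, 0),
                    cv_folds = 5, homogenize = FALSE),
    sc = list(n_cells = 500, n_genes = 400, n_hvg = 200, top_fraction = 0.2,
              activity_bimodality = 3)
  )
}

.stage_seed <- function(seed, offset) (as.integer(seed) + offset) %% .Machine$integer.max

#' Run the full cuprotosis-pattern pipeline
#'
#' Executes every stage on synthetic cohorts defined by the configuration,
#' writing TSV/JSON artifacts plus a manifest (parameters, seeds, md5
#' checksums of every artifact) into `config$out_dir`. Re-running with the
#' same configuration reproduces identical artifacts.
#'
#' @param config configuration list (see [demo_config()]) or the path of a
#'   YAML file holding one.
#' @return invisibly, a list with the key in-memory results and
#'   `manifest_path`.
#' @export
run_pipeline <- function(config = demo_config()) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  for (field in c("out_dir", "seed"))
    if (is.null(config[[field]])) stop("config lacks field '", field, "'")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(...) file.path(config$out_dir, ...)
  seed <- as.integer(config$seed)
  artifacts <- character(0)
  note <- function(path) { artifacts <<- c(artifacts, path); path }

  ## -- simulate ------------------------------------------------------------
  bc <- config$bulk
  spec <- bulk_cohort_spec(
    n_genes = bc$n_genes, n_samples = bc$n_samples,
    n_subtypes = bc$n_subtypes, n_regulator_genes = bc$n_regulator_genes,
    n_signature_genes_per_subtype = bc$n_signature_genes_per_subtype,
    subtype_effect = bc$subtype_effect,
    batch_labels = rep_len(sprintf("b%d", seq_len(bc$n_batches)),
                           bc$n_samples),
    batch_shift = seq(0, by = bc$batch_shift, length.out = bc$n_batches),
    noise_sd = bc$noise_sd, seed = .stage_seed(seed, 1))
  cohort <- simulate_bulk_cohort(spec)
  sv <- config$survival
  clin <- simulate_survival(
    setNames(as.character(cohort$subtype), names(cohort$subtype)),
    survival_spec(baseline_hazard = sv$baseline_hazard,
                  beta_subtype = unlist(sv$beta_subtype),
                  censor_rate = sv$censor_rate,
                  max_followup = sv$max_followup,
                  seed = .stage_seed(seed, 2)))

  ## -- ingest: round-trip through real I/O, units, batch correction --------
  write_expression(cohort$expr, note(out("expression_fpkm.tsv")))
  expr <- read_expression(out("expression_fpkm.tsv"), unit = "FPKM")
  lexpr <- log2_tpm(fpkm_to_tpm(expr))
  lexpr <- combat_correct(lexpr, cohort$batch)
  write_expression(lexpr, note(out("expression_log2tpm_corrected.tsv")))
  utils::write.table(clin, note(out("clinical.tsv")), sep = "\t",
                     row.names = FALSE, quote = FALSE)

  ## -- consensus clustering on the regulator panel -------------------------
  cl <- config$cluster
  cons <- consensus_cluster(lexpr, cohort$regulator_genes,
                            k_range = cl$k_min:cl$k_max, n_reps = cl$n_reps,
                            subsample_fraction = cl$subsample_fraction,
                            seed = .stage_seed(seed, 3))
  clusters <- cons$assignments[[as.character(cons$chosen_k)]]
  utils::write.table(
    data.frame(sample_id = names(clusters), cluster = clusters),
    note(out("clusters.tsv")), sep = "\t", row.names = FALSE, quote = FALSE)

  ## -- enrichment: immune/stromal programs stand in for curated GMTs -------
  sets <- list(immune = cohort$program_genes[[3]],
               stromal = cohort$program_genes[[1]])
  write_gmt(sets, note(out("programs.gmt")))
  est <- estimate_scores(lexpr, sets$immune, sets$stromal,
                         alpha = config$enrich$alpha)
  est$tmescore <- tmescore(lexpr, sets$immune, sets$stromal,
                           alpha = config$enrich$alpha)
  utils::write.table(est, note(out("enrichment.tsv")), sep = "\t",
                     row.names = FALSE, quote = FALSE)

  ## -- DEGs between patterns, one vs rest, intersected ---------------------
  degs <- deg_one_vs_rest(lexpr, clusters, fdr = config$deg$fdr)
  shared_degs <- intersect_degs(degs)
  writeLines(shared_degs, note(out("shared_degs.txt")))

  ## -- COPsig --------------------------------------------------------------
  cs <- config$copsig
  prog <- prognostic_filter(lexpr, shared_degs, clin, p_threshold = cs$cox_p)
  if (length(prog) < 10) prog <- shared_degs   # tiny demo cohorts can be sparse
  bor <- boruta_select(t(lexpr[prog, , drop = FALSE]), factor(clusters),
                       n_iter = cs$boruta_iter, alpha = cs$boruta_alpha,
                       seed = .stage_seed(seed, 4))
  kept <- union(bor$confirmed, bor$tentative)
  if (length(kept) < 4) kept <- prog
  part <- partition_signature(lexpr, kept, clusters, clin)
  cop <- compute_copsig(lexpr, part, split_rule = cs$split_rule)
  utils::write.table(cop$scores, note(out("copsig_scores.tsv")), sep = "\t",
                     row.names = FALSE, quote = FALSE)

  ## -- survival of the score groups ----------------------------------------
  idx <- match(cop$scores$sample_id, clin$sample_id)
  lr <- logrank_test(clin[idx, ], cop$scores$group)
  km <- km_fit(clin[idx, ], cop$scores$group)
  utils::write.table(km, note(out("km_curves.tsv")), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  cox_tab <- cox_fit(cbind(clin[idx, ], copsig = cop$scores$score), "copsig",
                     univariate = TRUE)

  ## -- pharmaco ------------------------------------------------------------
  ph <- config$pharmaco
  panel <- simulate_cellline_panel(cellline_panel_spec(
    n_cell_lines = ph$n_cell_lines, n_compounds = ph$n_compounds,
    n_genes = ph$n_genes, auc_noise_sd = ph$auc_noise_sd,
    na_fraction = unlist(ph$na_fraction), seed = .stage_seed(seed, 5)))
  filt <- filter_panel(panel$expr, panel$auc, panel$lineage)
  imp <- knn_impute(filt$auc)
  model <- train_ridge(filt$expr, imp, colnames(imp)[1],
                       cv_folds = ph$cv_folds, seed = .stage_seed(seed, 6))
  ## project onto the tumour cohort via the shared gene namespace
  tum <- lexpr[intersect(rownames(lexpr), model$genes), , drop = FALSE]
  pred <- if (nrow(tum) >= 0.5 * length(model$genes)) {
    predict_response(model, tum, homogenize = isTRUE(ph$homogenize))
  } else {
    ## gene namespaces of the demo simulators overlap by construction;
    ## fall back to the panel itself if a config breaks that
    predict_response(model, filt$expr, homogenize = FALSE)
  }
  assoc <- score_response_association(
    pred, setNames(cop$scores$score, cop$scores$sample_id))
  utils::write.table(
    data.frame(sample_id = names(pred), predicted_response = unname(pred)),
    note(out("predicted_response.tsv")), sep = "\t", row.names = FALSE,
    quote = FALSE)

  ## -- single cell ---------------------------------------------------------
  scc <- config$sc
  sc <- simulate_single_cell(single_cell_spec(
    n_cells = scc$n_cells, n_genes = scc$n_genes,
    activity_bimodality = scc$activity_bimodality,
    seed = .stage_seed(seed, 7)))
  norm <- normalize_cells(sc$counts)
  hvg <- select_hvg(norm, n = scc$n_hvg)
  aus <- aucell_score(norm, sc$signature_genes,
                      top_fraction = scc$top_fraction)
  thr <- aucell_threshold(aus)
  comp <- composition_by_group(sc$cell_type, aus$auc > thr)
  utils::write.table(comp, note(out("sc_composition.tsv")), sep = "\t",
                     row.names = FALSE, quote = FALSE)

  ## -- summary + manifest --------------------------------------------------
  summary <- list(
    n_samples = ncol(lexpr), chosen_k = cons$chosen_k,
    cluster_sizes = as.list(table(clusters)),
    consensus_ari_vs_truth = adjusted_rand_index(clusters, cohort$subtype),
    n_shared_degs = length(shared_degs),
    n_prognostic = length(prog),
    n_boruta_confirmed = length(bor$confirmed),
    n_signature_A = length(part$genes_A), n_signature_B = length(part$genes_B),
    copsig_threshold = cop$threshold,
    logrank_chisq = lr$chisq, logrank_p = lr$p,
    cox_beta_copsig = cox_tab$beta[1],
    ridge_lambda = model$lambda, ridge_cv_spearman = model$cv_correlation,
    response_score_rho = assoc$rho,
    aucell_threshold = as.numeric(thr),
    n_high_activity_cells = sum(aus$auc > thr))
  jsonlite::write_json(summary, note(out("summary.json")), auto_unbox = TRUE,
                       digits = NA)
  manifest <- list(
    config = config,
    artifacts = lapply(setNames(nm = basename(artifacts)), function(f)
      unname(tools::md5sum(out(f)))))
  manifest_path <- out("manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA)
  invisible(list(cohort = cohort, clinical = clin, consensus = cons,
                 clusters = clusters, degs = shared_degs, partition = part,
                 copsig = cop, logrank = lr, cox = cox_tab,
                 ridge = model, association = assoc,
                 aucell_threshold = thr, composition = comp,
                 summary = summary, manifest_path = manifest_path))
}
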