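## Synthetic cohort generators.
##
## These define the study conditions every downstream stage is tested
## under: multi-batch bulk cohorts with K latent cuprotosis-like subtypes
## driven by a small regulator panel plus per-subtype signature programs,
## exponential proportional-hazards survival, cell-line panels with
## expression-linked drug AUC and missingness, and gamma-Poisson
## single-cell counts with a bimodal signature-activity structure.
## Every generator is bit-reproducible under its seed.

#' Specification of a synthetic bulk cohort
#'
#' Expression model: per-gene baseline log2 means with additive subtype
#' effects on that subtype's program genes (regulator panel + signature
#' block), Gaussian residual noise on the log2 scale, then per-batch
#' additive shift and multiplicative noise dispersion, exponentiated to an
#' FPKM-like positive scale.
#'
#' @param n_genes,n_samples matrix dimensions.
#' @param n_subtypes number of latent subtypes K (>= 2).
#' @param n_regulator_genes size of the regulator panel (analogous to the
#'   10 cuprotosis-related genes); regulators are assigned round-robin to
#'   subtypes and shifted in their subtype.
#' @param n_signature_genes_per_subtype size of each subtype's disjoint
#'   downstream signature program.
#' @param subtype_effect log2-scale mean shift a subtype applies to its own
#'   program genes.
#' @param batch_labels per-sample batch ids; default a single batch.
#' @param batch_shift named (or batch-ordered) additive per-batch log2
#'   offset; scalar recycled.
#' @param batch_scale multiplicative per-batch noise dispersion factor.
#' @param noise_sd log2-scale residual standard deviation.
#' @param seed integer RNG seed.
#' @return object of class `bulk_cohort_spec`.
#' @export
bulk_cohort_spec <- function(n_genes = 1000, n_samples = 300, n_subtypes = 3,
                             n_regulator_genes = 10,
                             n_signature_genes_per_subtype = 50,
                             subtype_effect = 2, batch_labels = NULL,
                             batch_shift = 0, batch_scale = 1,
                             noise_sd = 0.5, seed = 1) {
  if (n_subtypes < 2) .cfg_error("n_subtypes", "must be >= 2")
  if (n_regulator_genes < n_subtypes)
    .cfg_error("n_regulator_genes", "must be >= n_subtypes")
  need <- n_regulator_genes + n_subtypes * n_signature_genes_per_subtype
  if (need > n_genes)
    .cfg_error("n_signature_genes_per_subtype",
               sprintf("program genes (%d) exceed n_genes (%d)", need, n_genes))
  if (is.null(batch_labels)) batch_labels <- rep("b1", n_samples)
  if (length(batch_labels) != n_samples)
    .cfg_error("batch_labels", "must have one entry per sample")
  if (noise_sd < 0) .cfg_error("noise_sd", "must be >= 0")
  structure(list(n_genes = n_genes, n_samples = n_samples,
                 n_subtypes = n_subtypes,
                 n_regulator_genes = n_regulator_genes,
                 n_signature_genes_per_subtype = n_signature_genes_per_subtype,
                 subtype_effect = subtype_effect,
                 batch_labels = as.character(batch_labels),
                 batch_shift = batch_shift, batch_scale = batch_scale,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "bulk_cohort_spec")
}

#' Simulate a bulk expression cohort with planted subtypes and batches
#'
#' @param spec a [bulk_cohort_spec()].
#' @return list with `expr` (FPKM-tagged genes x samples matrix),
#'   `subtype` (factor, ground truth), `batch` (factor),
#'   `regulator_genes` (character), and `program_genes` (list of per-subtype
#'   signature gene vectors, regulators included).
#' @export
simulate_bulk_cohort <- function(spec) {
  stopifnot(inherits(spec, "bulk_cohort_spec"))
  set.seed(spec$seed)
  G <- spec$n_genes; N <- spec$n_samples; K <- spec$n_subtypes
  genes <- sprintf("g%04d", seq_len(G))
  samples <- sprintf("s%04d", seq_len(N))
  subtype <- factor(sample(rep_len(sprintf("cop%d", seq_len(K)), N)),
                    levels = sprintf("cop%d", seq_len(K)))
  batch <- factor(spec$batch_labels)
  regulators <- genes[seq_len(spec$n_regulator_genes)]
  reg_owner <- rep_len(seq_len(K), spec$n_regulator_genes)
  program <- vector("list", K)
  names(program) <- levels(subtype)
  off <- spec$n_regulator_genes
  for (k in seq_len(K)) {
    sig <- genes[off + seq_len(spec$n_signature_genes_per_subtype)]
    off <- off + spec$n_signature_genes_per_subtype
    program[[k]] <- c(regulators[reg_owner == k], sig)
  }
  mu <- rnorm(G, mean = 4, sd = 1)
  shift <- rep_len(spec$batch_shift, nlevels(batch))
  scl <- rep_len(spec$batch_scale, nlevels(batch))
  L <- matrix(mu, G, N)
  for (k in seq_len(K)) {
    idx <- match(program[[k]], genes)
    L[idx, subtype == levels(subtype)[k]] <-
      L[idx, subtype == levels(subtype)[k]] + spec$subtype_effect
  }
  bi <- as.integer(batch)
  noise <- matrix(rnorm(G * N, sd = spec$noise_sd), G, N)
  L <- L + sweep(noise, 2, scl[bi], "*")
  L <- sweep(L, 2, shift[bi], "+")
  vals <- 2^L
  dimnames(vals) <- list(genes, samples)
  names(subtype) <- samples
  names(batch) <- samples
  list(expr = expression_matrix(vals, "FPKM"), subtype = subtype,
       batch = batch, regulator_genes = regulators, program_genes = program)
}

#' Specification of a synthetic survival layer
#'
#' Exponential proportional-hazards model: event times are drawn with rate
#' `baseline_hazard * exp(lp)` where the linear predictor `lp` comes from
#' per-subtype log-hazard offsets or from `beta_score` times a numeric
#' score; independent exponential censoring plus administrative censoring
#' at `max_followup`.
#'
#' @param baseline_hazard events per time unit (> 0).
#' @param beta_subtype named per-subtype log-hazard offsets (used when the
#'   input is a label vector).
#' @param beta_score log-hazard per unit of a numeric score.
#' @param censor_rate rate of independent exponential censoring (0 = none).
#' @param max_followup administrative censoring time (may be `Inf`).
#' @param seed integer RNG seed.
#' @return object of class `survival_spec`.
#' @export
survival_spec <- function(baseline_hazard = 0.05, beta_subtype = NULL,
                          beta_score = 0, censor_rate = 0.02,
                          max_followup = 120, seed = 1) {
  if (baseline_hazard <= 0) .cfg_error("baseline_hazard", "must be > 0")
  if (censor_rate < 0) .cfg_error("censor_rate", "must be >= 0")
  if (max_followup <= 0) .cfg_error("max_followup", "must be > 0")
  structure(list(baseline_hazard = baseline_hazard,
                 beta_subtype = beta_subtype, beta_score = beta_score,
                 censor_rate = censor_rate, max_followup = max_followup,
                 seed = as.integer(seed)),
            class = "survival_spec")
}

#' Simulate survival outcomes from labels or a linear score
#'
#' @param x per-sample subtype labels (factor/character; uses
#'   `beta_subtype`) or a numeric score (uses `beta_score`). Names become
#'   sample ids.
#' @param spec a [survival_spec()].
#' @return clinical `data.frame` with columns `sample_id`, `time`, `event`
#'   (1 iff the event time precedes both censoring mechanisms) and `lp`
#'   (true linear predictor, for recovery tests).
#' @export
simulate_survival <- function(x, spec) {
  stopifnot(inherits(spec, "survival_spec"))
  if (is.numeric(x)) {
    if (any(!is.finite(x))) stop("non-finite score values in survival input")
    lp <- spec$beta_score * x
  } else {
    x <- as.character(x)
    if (is.null(spec$beta_subtype))
      stop("beta_subtype must be set when simulating from labels")
    if (!all(x %in% names(spec$beta_subtype)))
      stop("labels without a beta_subtype entry: ",
           paste(setdiff(unique(x), names(spec$beta_subtype)), collapse = ", "))
    lp <- unname(spec$beta_subtype[x])
  }
  n <- length(lp)
  ids <- names(x)
  if (is.null(ids)) ids <- sprintf("s%04d", seq_len(n))
  set.seed(spec$seed)
  tev <- rexp(n, rate = spec$baseline_hazard * exp(lp))
  cen <- if (spec$censor_rate > 0) rexp(n, rate = spec$censor_rate) else rep(Inf, n)
  cen <- pmin(cen, spec$max_followup)
  data.frame(sample_id = ids, time = pmin(tev, cen),
             event = as.integer(tev <= cen), lp = lp,
             stringsAsFactors = FALSE)
}

#' Specification of a synthetic cell-line drug panel
#'
#' Per-compound drug response is a sparse linear function of log-scale
#' expression plus Gaussian noise (`AUC = X'w + e`), so lower AUC means
#' greater sensitivity by construction of the signed weights. A seeded NA
#' mask emulates incomplete screening.
#'
#' @param n_cell_lines,n_compounds,n_genes panel dimensions.
#' @param n_informative_genes non-zero weights per compound.
#' @param lineage_labels per-cell-line tissue label; default draws ~15%
#'   `"haematopoietic_and_lymphoid"` and the rest solid lineages.
#' @param auc_noise_sd response noise SD.
#' @param na_fraction scalar or per-compound missingness rate in `[0, 1]`.
#' @param seed integer RNG seed.
#' @return object of class `cellline_panel_spec`.
#' @export
cellline_panel_spec <- function(n_cell_lines = 200, n_compounds = 10,
                                n_genes = 300, n_informative_genes = 15,
                                lineage_labels = NULL, auc_noise_sd = 0.1,
                                na_fraction = 0, seed = 1) {
  na_fraction <- rep_len(na_fraction, n_compounds)
  if (any(na_fraction < 0 | na_fraction > 1))
    .cfg_error("na_fraction", "must lie in [0, 1]")
  if (!is.null(lineage_labels) && length(lineage_labels) != n_cell_lines)
    .cfg_error("lineage_labels", "must have one entry per cell line")
  structure(list(n_cell_lines = n_cell_lines, n_compounds = n_compounds,
                 n_genes = n_genes, n_informative_genes = n_informative_genes,
                 lineage_labels = lineage_labels,
                 auc_noise_sd = auc_noise_sd, na_fraction = na_fraction,
                 seed = as.integer(seed)),
            class = "cellline_panel_spec")
}

#' Simulate a cell-line expression + drug-response panel
#'
#' @param spec a [cellline_panel_spec()].
#' @return list with `expr` (LOG2TPM-tagged genes x cell lines),
#'   `auc` (cell line x compound matrix with NAs), `lineage` (named
#'   character), `true_weights` (genes x compounds sparse weight matrix)
#'   and `true_auc` (noiseless, unmasked responses).
#' @export
simulate_cellline_panel <- function(spec) {
  stopifnot(inherits(spec, "cellline_panel_spec"))
  set.seed(spec$seed)
  G <- spec$n_genes; n <- spec$n_cell_lines; p <- spec$n_compounds
  genes <- sprintf("g%04d", seq_len(G))
  lines <- sprintf("ccl%03d", seq_len(n))
  compounds <- sprintf("compound_%02d", seq_len(p))
  lineage <- spec$lineage_labels
  if (is.null(lineage))
    lineage <- sample(c("large_intestine", "lung", "breast",
                        "haematopoietic_and_lymphoid"),
                      n, replace = TRUE, prob = c(0.35, 0.3, 0.2, 0.15))
  names(lineage) <- lines
  X <- matrix(rnorm(G * n, mean = 4, sd = 1), G, n,
              dimnames = list(genes, lines))
  W <- matrix(0, G, p, dimnames = list(genes, compounds))
  for (j in seq_len(p)) {
    idx <- sample.int(G, spec$n_informative_genes)
    W[idx, j] <- rnorm(spec$n_informative_genes)
  }
  true_auc <- t(X) %*% W
  auc <- true_auc + matrix(rnorm(n * p, sd = spec$auc_noise_sd), n, p)
  for (j in seq_len(p)) {
    n_na <- round(spec$na_fraction[j] * n)
    if (n_na > 0) auc[sample.int(n, n_na), j] <- NA_real_
  }
  list(expr = expression_matrix(X, "LOG2TPM"), auc = auc, lineage = lineage,
       true_weights = W, true_auc = true_auc)
}

#' Specification of a synthetic single-cell cohort
#'
#' Gamma-Poisson counts with per-cell library size, per-type marker
#' programs, and a designated signature expressed at two activity levels
#' across cells so the per-cell gene-set AUC histogram is bimodal. Each
#' cell's activity mode is Bernoulli with a per-type probability, which is
#' how cell-type enrichment of the low-activity mode (e.g. macrophages) is
#' planted.
#'
#' @param n_cells,n_genes matrix dimensions.
#' @param cell_type_proportions named simplex over cell types (must include
#'   the types referenced by `high_activity_prob`).
#' @param n_program_genes marker genes per cell type (disjoint blocks).
#' @param n_signature_genes size of the designated activity signature.
#' @param activity_bimodality log2 separation of the signature's two
#'   activity modes; larger values give cleaner bimodality.
#' @param high_activity_prob named per-type probability that a cell sits in
#'   the high-activity mode.
#' @param library_size_mean mean per-cell total count.
#' @param seed integer RNG seed.
#' @return object of class `single_cell_spec`.
#' @export
single_cell_spec <- function(n_cells = 1000, n_genes = 800,
                             cell_type_proportions = c(epithelial = 0.5,
                                                       macrophage = 0.3,
                                                       t_cell = 0.2),
                             n_program_genes = 25, n_signature_genes = 20,
                             activity_bimodality = 3,
                             high_activity_prob = c(epithelial = 0.75,
                                                    macrophage = 0.1,
                                                    t_cell = 0.6),
                             library_size_mean = 5000, seed = 1) {
  if (abs(sum(cell_type_proportions) - 1) > 1e-12)
    .cfg_error("cell_type_proportions", "must sum to 1 (tolerance 1e-12)")
  if (any(cell_type_proportions < 0))
    .cfg_error("cell_type_proportions", "must be non-negative")
  if (is.null(names(cell_type_proportions)))
    .cfg_error("cell_type_proportions", "must be named by cell type")
  K <- length(cell_type_proportions)
  need <- K * n_program_genes + n_signature_genes
  if (need > n_genes)
    .cfg_error("n_program_genes",
               sprintf("program + signature genes (%d) exceed n_genes (%d)",
                       need, n_genes))
  if (!all(names(cell_type_proportions) %in% names(high_activity_prob)))
    .cfg_error("high_activity_prob", "must name every cell type")
  structure(list(n_cells = n_cells, n_genes = n_genes,
                 cell_type_proportions = cell_type_proportions,
                 n_program_genes = n_program_genes,
                 n_signature_genes = n_signature_genes,
                 activity_bimodality = activity_bimodality,
                 high_activity_prob = high_activity_prob,
                 library_size_mean = library_size_mean,
                 seed = as.integer(seed)),
            class = "single_cell_spec")
}

#' Simulate single-cell counts with cell-type programs and bimodal
#' signature activity
#'
#' @param spec a [single_cell_spec()].
#' @return list with `counts` (genes x cells integer matrix), `cell_type`
#'   (factor), `signature_genes` (character), `program_genes` (per-type
#'   list) and `activity_high` (logical ground truth per cell).
#' @export
simulate_single_cell <- function(spec) {
  stopifnot(inherits(spec, "single_cell_spec"))
  if (spec$n_cells <= 0) stop("n_cells must be positive: nothing to simulate")
  set.seed(spec$seed)
  G <- spec$n_genes; N <- spec$n_cells
  genes <- sprintf("g%04d", seq_len(G))
  cells <- sprintf("cell%05d", seq_len(N))
  types <- names(spec$cell_type_proportions)
  cell_type <- factor(sample(types, N, replace = TRUE,
                             prob = spec$cell_type_proportions),
                      levels = types)
  program <- vector("list", length(types)); names(program) <- types
  off <- 0
  for (ty in types) {
    program[[ty]] <- genes[off + seq_len(spec$n_program_genes)]
    off <- off + spec$n_program_genes
  }
  signature <- genes[off + seq_len(spec$n_signature_genes)]
  activity_high <- runif(N) < spec$high_activity_prob[as.character(cell_type)]
  base <- rgamma(G, shape = 0.6, rate = 1) + 0.02   # skewed baseline rates
  R <- matrix(base, G, N)
  for (ty in types) {
    idx <- match(program[[ty]], genes)
    R[idx, cell_type == ty] <- R[idx, cell_type == ty] * 2^3
  }
  sidx <- match(signature, genes)
  R[sidx, activity_high] <- R[sidx, activity_high] * 2^spec$activity_bimodality
  ## gamma-Poisson: multiplicative gamma noise gives NB-like overdispersion
  disp <- 10
  R <- R * matrix(rgamma(G * N, shape = disp, rate = disp), G, N)
  lib <- rlnorm(N, meanlog = log(spec$library_size_mean), sdlog = 0.2)
  R <- sweep(R, 2, lib / colSums(R), "*")
  counts <- matrix(rpois(G * N, lambda = R), G, N,
                   dimnames = list(genes, cells))
  names(activity_high) <- cells
  names(cell_type) <- cells
  list(counts = counts, cell_type = cell_type, signature_genes = signature,
       program_genes = program, activity_high = activity_high)
}
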