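## COPsig score construction: partition pattern-associated DEGs into the
## positively (A) and negatively (B) associated signatures, reduce with a
## Boruta shadow-feature selector, extract the first principal component
## of each signature, and score each patient as PC1A - PC1B.

#' Partition signature genes by association with the prognostic cluster
#' ordering
#'
#' Clusters are ordered by their Kaplan-Meier median survival (best
#' prognosis = highest rank; clusters whose curve never reaches 0.5 are
#' treated as best). Each gene's Spearman correlation with the per-sample
#' cluster rank assigns it to signature A (`rho > 0`), signature B
#' (`rho < 0`), or drops it (`rho == 0`, with a warning).
#'
#' @param m expression matrix.
#' @param deg_genes candidate genes (rows of `m`).
#' @param clusters per-sample cluster labels (>= 2 clusters).
#' @param clin clinical data.frame aligned with the samples of `m`
#'   (matched by `sample_id`).
#' @return object of class `signature_partition`: list with `genes_A`,
#'   `genes_B` and `cluster_rank`.
#' @export
partition_signature <- function(m, deg_genes, clusters, clin) {
  miss <- setdiff(deg_genes, rownames(m))
  if (length(miss)) stop("DEG gene(s) absent: ", paste(miss, collapse = ", "))
  g <- factor(clusters)
  if (nlevels(g) < 2) stop("need at least 2 clusters")
  .check_clinical(clin)
  idx <- match(colnames(m), clin$sample_id)
  if (any(is.na(idx))) stop("clinical table lacks sample(s) of the matrix")
  sf <- survival::survfit(survival::Surv(clin$time[idx], clin$event[idx]) ~ g)
  med <- summary(sf)$table[, "median"]
  med[is.na(med)] <- Inf                  # curve never drops below 0.5: best
  cluster_rank <- rank(med)               # best survival -> highest rank
  names(cluster_rank) <- sub("^g=", "", names(med))
  cov <- cluster_rank[as.character(g)]
  rho <- apply(m[deg_genes, , drop = FALSE], 1,
               function(e) spearman_test(e, cov)$rho)
  dropped <- deg_genes[is.na(rho) | rho == 0]
  if (length(dropped))
    warning("gene(s) with zero/undefined association dropped: ",
            paste(dropped, collapse = ", "))
  structure(list(genes_A = deg_genes[!is.na(rho) & rho > 0],
                 genes_B = deg_genes[!is.na(rho) & rho < 0],
                 cluster_rank = cluster_rank),
            class = "signature_partition")
}

#' Keep genes with univariate prognostic value
#'
#' Univariate Cox regression per gene on its expression; genes with Wald
#' `p < p_threshold` are retained (the prognostic prefilter applied before
#' feature reduction).
#'
#' @param m expression matrix.
#' @param genes candidate genes.
#' @param clin clinical data.frame matched by `sample_id`.
#' @param p_threshold Wald p cutoff (default 0.05).
#' @return character vector of prognostic genes.
#' @export
prognostic_filter <- function(m, genes, clin, p_threshold = 0.05) {
  .check_clinical(clin)
  idx <- match(colnames(m), clin$sample_id)
  if (any(is.na(idx))) stop("clinical table lacks sample(s) of the matrix")
  tm <- clin$time[idx]; ev <- clin$event[idx]
  ps <- vapply(genes, function(g) {
    x <- m[g, ]
    if (sd(x) == 0) return(NA_real_)
    fit <- suppressWarnings(
      survival::coxph(survival::Surv(tm, ev) ~ x, ties = "breslow"))
    summary(fit)$coefficients[1, "Pr(>|z|)"]
  }, numeric(1))
  genes[!is.na(ps) & ps < p_threshold]
}

#' Boruta all-relevant feature selection with shadow features
#'
#' Each iteration appends a column-shuffled "shadow" copy of every
#' feature, fits a random forest (via ranger), and records which real
#' features beat the maximal shadow importance. A two-sided binomial test
#' of the hit count against `Binomial(n_iter, 1/2)`, Bonferroni-corrected
#' over features, declares features confirmed or rejected; the rest stay
#' tentative.
#'
#' @param x samples x features numeric matrix with column names.
#' @param y target: factor (classification) or numeric (regression).
#' @param n_iter iterations (default 100).
#' @param alpha binomial test level before Bonferroni (default 0.01).
#' @param seed RNG seed.
#' @param num_trees trees per forest (default 100).
#' @return list with `confirmed`, `rejected`, `tentative` (character) and
#'   `hits` (named integer).
#' @export
boruta_select <- function(x, y, n_iter = 100, alpha = 0.01, seed = 1,
                          num_trees = 100) {
  if (nrow(x) < 20) stop("Boruta needs at least 20 samples")
  if (ncol(x) < 2) stop("Boruta needs at least 2 features")
  if (is.null(colnames(x))) stop("features must be named")
  if (length(unique(y)) < 2) stop("constant target")
  feats <- colnames(x)
  m <- length(feats)
  set.seed(seed)
  hits <- setNames(integer(m), feats)
  for (it in seq_len(n_iter)) {
    sh <- apply(x, 2, sample)
    colnames(sh) <- paste0(".shadow.", feats)
    df <- as.data.frame(cbind(x, sh))
    df$.target. <- y
    fit <- ranger::ranger(dependent.variable.name = ".target.", data = df,
                          num.trees = num_trees, importance = "impurity",
                          seed = .subseed(), num.threads = 1)
    imp <- fit$variable.importance
    max_shadow <- max(imp[paste0(".shadow.", feats)])
    hits <- hits + (imp[feats] > max_shadow)
  }
  thr <- alpha / (2 * m)                 # two-sided + Bonferroni
  p_conf <- pbinom(hits - 1, n_iter, 0.5, lower.tail = FALSE)
  p_rej <- pbinom(hits, n_iter, 0.5)
  confirmed <- feats[p_conf < thr]
  rejected <- feats[p_rej < thr]
  list(confirmed = confirmed, rejected = rejected,
       tentative = setdiff(feats, c(confirmed, rejected)), hits = hits)
}

## first principal component of a z-scored signature block, oriented to
## correlate positively with the mean z-expression of its genes.
.signature_pc1 <- function(m, genes) {
  E <- m[genes, , drop = FALSE]
  sds <- apply(E, 1, sd)
  if (any(sds == 0))
    stop("constant signature gene(s): ",
         paste(genes[sds == 0], collapse = ", "))
  Z <- (E - rowMeans(E)) / sds
  pc <- prcomp(t(Z), center = FALSE, scale. = FALSE)
  pc1 <- pc$x[, 1]
  loadings <- pc$rotation[, 1]
  s <- cor(pc1, colMeans(Z))
  sign_ <- if (!is.na(s) && s < 0) -1 else 1
  list(pc1 = sign_ * pc1, loadings = sign_ * loadings, sign = sign_)
}

#' Compute the COPsig score
#'
#' Each signature's genes are z-scored and reduced to their first
#' principal component over samples; the PC1 sign is fixed so it
#' correlates positively with the signature's mean z-expression (PCA sign
#' is otherwise arbitrary). The per-patient score is `PC1A - PC1B`
#' (`PC1B = 0` when signature B is empty), and patients are split into
#' high/low groups by the median or a fixed cutoff.
#'
#' @param m expression matrix.
#' @param partition a `signature_partition` (or list with `genes_A`,
#'   `genes_B`).
#' @param split_rule `"median"` or `"fixed"`.
#' @param cutoff threshold for `split_rule = "fixed"`.
#' @return object of class `copsig_result`: data.frame-like list with
#'   `scores` (sample_id, pc1_A, pc1_B, score, group), `loadings_A/B`,
#'   `orientation_sign_A/B`, `split_rule`, `threshold`.
#' @export
compute_copsig <- function(m, partition, split_rule = c("median", "fixed"),
                           cutoff = NULL) {
  split_rule <- match.arg(split_rule)
  gA <- partition$genes_A; gB <- partition$genes_B
  if (length(gA) < 2) stop("signature A needs at least 2 genes")
  miss <- setdiff(c(gA, gB), rownames(m))
  if (length(miss)) stop("signature gene(s) absent: ", paste(miss, collapse = ", "))
  A <- .signature_pc1(m, gA)
  if (length(gB) >= 2) {
    B <- .signature_pc1(m, gB)
  } else {
    if (length(gB) == 1) warning("signature B has a single gene; treated as empty")
    B <- list(pc1 = setNames(rep(0, ncol(m)), colnames(m)),
              loadings = numeric(0), sign = 1)
  }
  score <- A$pc1 - B$pc1
  grp <- split_groups(score, rule = split_rule, cutoff = cutoff)
  thr <- attr(grp, "threshold")
  structure(list(scores = data.frame(sample_id = colnames(m),
                                     pc1_A = unname(A$pc1),
                                     pc1_B = unname(B$pc1),
                                     score = unname(score),
                                     group = as.character(grp),
                                     row.names = NULL),
                 loadings_A = A$loadings, loadings_B = B$loadings,
                 orientation_sign_A = A$sign, orientation_sign_B = B$sign,
                 split_rule = split_rule, threshold = thr),
            class = "copsig_result")
}

#' Split samples into high/low score groups
#'
#' `high` means `score > threshold`; ties at the threshold go low. The
#' median rule uses the sample median; the fixed rule uses `cutoff`.
#'
#' @param score numeric per-sample scores (>= 2 samples).
#' @param rule `"median"` or `"fixed"`.
#' @param cutoff threshold for the fixed rule.
#' @return factor of `"low"`/`"high"` with attribute `threshold`.
#' @export
split_groups <- function(score, rule = c("median", "fixed"), cutoff = NULL) {
  rule <- match.arg(rule)
  if (length(score) < 2) stop("need at least 2 samples")
  if (length(unique(score)) < 2) stop("all scores are equal; cannot split")
  thr <- if (rule == "median") median(score) else {
    if (is.null(cutoff)) stop("fixed split rule needs a cutoff")
    cutoff
  }
  out <- factor(ifelse(score > thr, "high", "low"), levels = c("low", "high"))
  names(out) <- names(score)
  attr(out, "threshold") <- thr
  out
}

#' Random-forest gene importance ranking
#'
#' Permutation importance from a ranger forest, ranked descending — used
#' to pick the top signature genes carried into the single-cell stage.
#'
#' @param x samples x features numeric matrix with column names.
#' @param y target (factor or numeric).
#' @param seed RNG seed.
#' @param num_trees trees (default 500).
#' @return data.frame with `gene`, `importance`, sorted descending.
#' @export
rf_gene_importance <- function(x, y, seed = 1, num_trees = 500) {
  if (is.null(colnames(x))) stop("features must be named")
  if (length(unique(y)) < 2) stop("constant target")
  df <- as.data.frame(x)
  df$.target. <- y
  fit <- ranger::ranger(dependent.variable.name = ".target.", data = df,
                        num.trees = num_trees, importance = "permutation",
                        seed = seed, num.threads = 1)
  imp <- sort(fit$variable.importance, decreasing = TRUE)
  data.frame(gene = names(imp), importance = unname(imp), row.names = NULL)
}
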