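## Minimal single-cell stage: library-size normalisation, highly variable
## gene selection, AUCell-style per-cell gene-set activity with bimodal
## thresholding, and group composition summaries.

#' Library-size normalise single-cell counts
#'
#' Counts per 10,000 followed by `log1p` — the field-standard light
#' normalisation before variance ranking.
#'
#' @param counts genes x cells count matrix.
#' @param scale_factor target library size (default 1e4).
#' @return normalised matrix of the same shape.
#' @export
normalize_cells <- function(counts, scale_factor = 1e4) {
  lib <- colSums(counts)
  bad <- colnames(counts)[lib == 0]
  if (length(bad)) stop("cell(s) with zero counts: ", paste(bad, collapse = ", "))
  log1p(sweep(counts, 2, lib, "/") * scale_factor)
}

#' Select highly variable genes
#'
#' Top `n` genes by variance of the (log-normalised) expression; ties are
#' broken by lexicographic gene id so the selection is deterministic.
#'
#' @param m normalised expression matrix (genes x cells).
#' @param n number of genes to keep (default 1500).
#' @return character vector of gene ids.
#' @export
select_hvg <- function(m, n = 1500) {
  if (n <= 0) stop("n must be positive")
  if (n > nrow(m)) stop("n exceeds the number of genes")
  v <- apply(m, 1, var)
  ord <- order(-v, rownames(m))
  rownames(m)[ord][seq_len(n)]
}

#' AUCell-style per-cell gene-set activity
#'
#' Per cell, genes are ranked by decreasing expression (ties broken stably
#' by gene id); the recovery curve counts set genes among the top ranks up
#' to `ceiling(top_fraction * n_genes)`, and the activity score is the
#' area under that curve divided by its maximum possible value (all set
#' genes at the very top). Scores lie in `[0, 1]` and depend only on
#' ranks, hence are invariant to monotone transforms of a cell's
#' expression.
#'
#' @param m expression matrix (genes x cells); counts or normalised.
#' @param gene_set character vector (must overlap the matrix).
#' @param top_fraction fraction of top-ranked genes integrated (default
#'   0.05).
#' @return object of class `aucell_scores`: list with `auc` (named
#'   per-cell vector), `top_fraction`, `n_set_genes`.
#' @export
aucell_score <- function(m, gene_set, top_fraction = 0.05) {
  genes <- rownames(m)
  S <- intersect(gene_set, genes)
  if (!length(S)) stop("gene set does not overlap the matrix")
  cutoff <- ceiling(top_fraction * length(genes))
  if (cutoff < 1) stop("top_fraction too small: cutoff below one gene")
  max_area <- sum(pmin(seq_len(cutoff), length(S)))
  inS <- genes %in% S
  auc <- vapply(seq_len(ncol(m)), function(j) {
    ord <- order(-m[, j], genes)
    sum(cumsum(inS[ord][seq_len(cutoff)])) / max_area
  }, numeric(1))
  names(auc) <- colnames(m)
  structure(list(auc = auc, top_fraction = top_fraction,
                 n_set_genes = length(S)),
            class = "aucell_scores")
}

#' Bimodal threshold for AUCell scores
#'
#' Fits a two-component Gaussian mixture to the per-cell activity scores
#' and returns the equal-posterior crossing point between the component
#' means. If the mixture degenerates (fit failure, vanishing component, or
#' no crossing between the means) the fall-back is the deepest density
#' valley between the two highest modes; genuinely unimodal score
#' distributions take the fall-back with a warning.
#'
#' @param scores an `aucell_scores` object or numeric vector (>= 20
#'   values, non-constant).
#' @return numeric threshold with attribute `method`
#'   (`"mixture"`/`"valley"`) — cells with `auc > threshold` are the
#'   high-activity group.
#' @export
aucell_threshold <- function(scores) {
  a <- if (inherits(scores, "aucell_scores")) scores$auc else scores
  if (length(a) < 20) stop("need at least 20 cells")
  if (sd(a) == 0) stop("constant activity scores")
  fit <- tryCatch(
    suppressWarnings(mclust::Mclust(a, G = 2, modelNames = "V",
                                    verbose = FALSE)),
    error = function(e) NULL)
  if (!is.null(fit)) {
    pro <- fit$parameters$pro
    mu <- fit$parameters$mean
    sg <- sqrt(fit$parameters$variance$sigmasq)
    if (length(sg) == 1) sg <- rep(sg, 2)
    ok <- !is.null(pro) && min(pro) > 0.02 && abs(diff(mu)) > 1e-6 &&
      all(sg > 0) && all(is.finite(sg))
    if (ok) {
      lo <- min(mu); hi <- max(mu)
      f <- function(x) {
        dnorm(x, mu[1], sg[1], log = TRUE) + log(pro[1]) -
          dnorm(x, mu[2], sg[2], log = TRUE) - log(pro[2])
      }
      if (sign(f(lo)) != sign(f(hi))) {
        thr <- uniroot(f, c(lo, hi))$root
        return(structure(thr, method = "mixture"))
      }
    }
  }
  ## density-valley fall-back
  d <- density(a)
  y <- d$y
  locmax <- which(diff(sign(diff(y))) == -2) + 1
  if (length(locmax) >= 2) {
    top2 <- sort(locmax[order(-y[locmax])][1:2])
    seg <- seq(top2[1], top2[2])
    thr <- d$x[seg][which.min(y[seg])]
    return(structure(thr, method = "valley"))
  }
  warning("activity distribution looks unimodal; threshold set at the median")
  structure(unname(median(a)), method = "valley")
}

#' Cell-type composition of activity groups
#'
#' Fraction of each cell type within the high- and low-activity groups;
#' fractions within a group sum to 1. Empty groups are reported with
#' missing fractions.
#'
#' @param cell_type_labels per-cell type labels.
#' @param high_flag per-cell logical (TRUE = high-activity group).
#' @return data.frame with `group`, `cell_type`, `fraction`.
#' @export
composition_by_group <- function(cell_type_labels, high_flag) {
  if (length(cell_type_labels) != length(high_flag))
    stop("labels and flags differ in length")
  ty <- factor(cell_type_labels)
  grp <- factor(ifelse(high_flag, "high", "low"), levels = c("low", "high"))
  out <- expand.grid(group = levels(grp), cell_type = levels(ty),
                     stringsAsFactors = FALSE)
  out$fraction <- mapply(function(g, t) {
    ing <- grp == g
    if (!any(ing)) return(NA_real_)
    mean(ty[ing] == t)
  }, out$group, out$cell_type)
  if (anyNA(out$fraction)) message("empty activity group: fractions undefined")
  out
}
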