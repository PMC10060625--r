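## Single-sample gene-set scoring: rank-weighted integrated running-sum
## ssGSEA, ESTIMATE-style immune/stromal scores, TMEscore, z-score pathway
## activity, and gene-to-infiltration correlation tables.

## integrated running-sum enrichment for one sample.
## r: rank values of all genes (higher expression -> higher rank, ties
## mid-ranked); ord: positions of genes sorted by decreasing expression;
## inset: logical in set, in matrix order.
.ssgsea_es <- function(r, ord, inset, alpha) {
  ra <- r[ord]^alpha
  inso <- inset[ord]
  denom_in <- sum(ra[inso])
  n_out <- sum(!inso)
  p_in <- cumsum(ra * inso) / denom_in
  p_out <- cumsum(!inso) / n_out
  sum(p_in - p_out)
}

#' Single-sample gene-set enrichment (ssGSEA)
#'
#' Per sample, genes are ranked by expression (ties mid-ranked) and each
#' set's enrichment score is the integrated difference between the
#' cumulative `rank^alpha` mass of in-set genes and the cumulative uniform
#' mass of out-of-set genes, summed over all gene positions (the
#' integrated running sum, not its maximal deviation). Scores are
#' rank-based and therefore invariant to any strictly monotone transform
#' of a sample's expression values.
#'
#' @param m expression matrix (genes x samples).
#' @param sets named list of gene sets.
#' @param alpha rank-weight exponent (default 0.25, the classic ssGSEA
#'   choice).
#' @param normalize min-max scale the score matrix over all entries to
#'   `[0, 1]`.
#' @param min_size sets with fewer matrix genes than this are dropped with
#'   a warning.
#' @return matrix of scores, sets x samples, with attributes `method`,
#'   `alpha` and `normalized`.
#' @export
ssgsea_score <- function(m, sets, alpha = 0.25, normalize = TRUE,
                         min_size = 2) {
  if (!length(sets)) stop("empty gene set collection")
  if (is.null(names(sets))) stop("gene sets must be named")
  genes <- rownames(m)
  ov <- lapply(sets, function(s) intersect(s, genes))
  keep <- lengths(ov) >= min_size
  if (!all(keep))
    warning("dropping set(s) with < ", min_size, " matrix genes: ",
            paste(names(sets)[!keep], collapse = ", "))
  if (!any(keep)) stop("no gene set overlaps the matrix sufficiently")
  ov <- ov[keep]
  inset <- lapply(ov, function(s) genes %in% s)
  scores <- matrix(NA_real_, length(ov), ncol(m),
                   dimnames = list(names(ov), colnames(m)))
  for (j in seq_len(ncol(m))) {
    e <- m[, j]
    r <- rank(e, ties.method = "average")
    ord <- order(e, decreasing = TRUE)
    for (i in seq_along(inset))
      scores[i, j] <- .ssgsea_es(r, ord, inset[[i]], alpha)
  }
  if (normalize) {
    rng <- range(scores)
    if (rng[2] > rng[1]) scores <- (scores - rng[1]) / (rng[2] - rng[1])
    else scores[] <- 0
  }
  structure(scores, method = "ssgsea", alpha = alpha, normalized = normalize)
}

#' ESTIMATE-style immune/stromal infiltration scores
#'
#' Immune and stromal scores are unnormalised ssGSEA enrichments of the
#' respective signatures; the combined score is their per-sample sum.
#'
#' @param m expression matrix.
#' @param immune_set,stromal_set character gene vectors.
#' @param alpha rank-weight exponent passed to [ssgsea_score()].
#' @return data.frame with `sample_id`, `immune_score`, `stromal_score`,
#'   `estimate_score`.
#' @export
estimate_scores <- function(m, immune_set, stromal_set, alpha = 0.25) {
  s <- ssgsea_score(m, list(immune = immune_set, stromal = stromal_set),
                    alpha = alpha, normalize = FALSE)
  data.frame(sample_id = colnames(m),
             immune_score = s["immune", ],
             stromal_score = s["stromal", ],
             estimate_score = s["immune", ] + s["stromal", ],
             row.names = NULL)
}

#' TMEscore: difference of two opposing enrichment signatures
#'
#' `tmescore = ssGSEA(setA) - ssGSEA(setB)` per sample, on unnormalised
#' components, so swapping the signatures negates the score.
#'
#' @param m expression matrix.
#' @param setA,setB character gene vectors.
#' @param alpha rank-weight exponent.
#' @return named numeric vector of per-sample scores.
#' @export
tmescore <- function(m, setA, setB, alpha = 0.25) {
  s <- ssgsea_score(m, list(A = setA, B = setB), alpha = alpha,
                    normalize = FALSE)
  drop(s["A", ] - s["B", ])
}

#' Pathway activity matrices
#'
#' `method = "zscore"` scores a set in a sample as the mean of its genes'
#' per-gene z-scores (a light surrogate for kernel-based set variation
#' scoring); `method = "ssgsea"` delegates to [ssgsea_score()].
#'
#' @param m expression matrix.
#' @param sets named list of gene sets.
#' @param method `"ssgsea"` or `"zscore"`.
#' @param ... passed to [ssgsea_score()].
#' @return sets x samples score matrix.
#' @export
pathway_activity <- function(m, sets, method = c("ssgsea", "zscore"), ...) {
  method <- match.arg(method)
  if (method == "ssgsea") return(ssgsea_score(m, sets, ...))
  if (!length(sets)) stop("empty gene set collection")
  Z <- t(scale(t(m)))
  Z[!is.finite(Z)] <- 0                  # constant genes carry no signal
  genes <- rownames(m)
  keep <- vapply(sets, function(s) any(s %in% genes), logical(1))
  if (!all(keep))
    warning("dropping set(s) with no matrix genes: ",
            paste(names(sets)[!keep], collapse = ", "))
  if (!any(keep)) stop("no gene set overlaps the matrix")
  out <- t(vapply(sets[keep], function(s) {
    colMeans(Z[intersect(s, genes), , drop = FALSE])
  }, numeric(ncol(m))))
  dimnames(out) <- list(names(sets[keep]), colnames(m))
  structure(out, method = "zscore")
}

#' Correlate panel genes with infiltration scores
#'
#' Spearman rho and BH-adjusted p for every (panel gene, score row) pair.
#'
#' @param m expression matrix.
#' @param gene_panel genes of interest (rows of `m`).
#' @param scores score matrix (cell types / sets x samples), e.g. from
#'   [ssgsea_score()].
#' @return data.frame with `gene`, `set`, `rho`, `p`, `padj`.
#' @export
gene_infiltration_correlation <- function(m, gene_panel, scores) {
  miss <- setdiff(gene_panel, rownames(m))
  if (length(miss)) stop("panel gene(s) absent: ", paste(miss, collapse = ", "))
  shared <- intersect(colnames(m), colnames(scores))
  if (length(shared) < 3) stop("fewer than 3 shared samples")
  grid <- expand.grid(gene = gene_panel, set = rownames(scores),
                      stringsAsFactors = FALSE)
  res <- mapply(function(g, s) {
    st <- spearman_test(m[g, shared], scores[s, shared])
    c(st$rho, st$p)
  }, grid$gene, grid$set)
  grid$rho <- res[1, ]
  grid$p <- res[2, ]
  grid$padj <- NA_real_
  ok <- !is.na(grid$p)
  grid$padj[ok] <- p.adjust(grid$p[ok], method = "BH")
  grid
}
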