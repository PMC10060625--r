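## Monti-style consensus clustering over resampled samples, PAC-based
## selection of the cluster number, and the adjusted Rand index used to
## compare partitions.

## base clusterer: k-means with 10 restarts on sample profiles (rows =
## samples). Falls back to grouping identical points when there are fewer
## distinct profiles than centres.
.base_cluster <- function(D, k) {
  nu <- nrow(unique(D))
  if (nu <= k) {
    key <- apply(D, 1, paste, collapse = "\r")
    return(match(key, unique(key)))
  }
  kmeans(D, centers = k, nstart = 10, iter.max = 50)$cluster
}

#' Consensus clustering by sample resampling
#'
#' For each of `n_reps` repetitions a fraction of samples is drawn without
#' replacement and the base clusterer (k-means with 10 restarts on
#' per-gene z-scored feature rows) is run for every candidate `k`. The
#' consensus index of a sample pair is the number of times it co-clustered
#' divided by the number of times it was co-sampled; pairs never co-sampled
#' get consensus 0 (conservative, and the count is reported in a message).
#' The final partition for each `k` cuts an average-linkage hierarchical
#' tree of `1 - consensus` into `k` groups.
#'
#' @param m expression matrix (genes x samples).
#' @param feature_genes genes to cluster on (e.g. the regulator panel).
#' @param k_range candidate cluster counts (all >= 2, < n_samples).
#' @param n_reps number of resampling repetitions (the reference analysis
#'   used 1,000; smaller values are fine for well-separated data).
#' @param subsample_fraction fraction of samples per repetition, in (0, 1].
#' @param seed integer RNG seed.
#' @return object of class `consensus_result`: per-k `consensus` matrices,
#'   `assignments`, `pac`, `cdf` (ecdf functions), `chosen_k`,
#'   `low_confidence` flag and the run parameters.
#' @export
consensus_cluster <- function(m, feature_genes, k_range = 2:6, n_reps = 100,
                              subsample_fraction = 0.8, seed = 1) {
  miss <- setdiff(feature_genes, rownames(m))
  if (length(miss))
    stop("feature gene(s) absent from matrix: ", paste(miss, collapse = ", "))
  k_range <- sort(unique(as.integer(k_range)))
  n <- ncol(m)
  if (min(k_range) < 2) stop("all k must be >= 2")
  if (max(k_range) >= n) stop("k must be smaller than the number of samples")
  if (subsample_fraction <= 0 || subsample_fraction > 1)
    stop("subsample_fraction must lie in (0, 1]")
  if (n_reps < 1) stop("n_reps must be >= 1")
  Z <- t(scale(t(m[feature_genes, , drop = FALSE])))
  Z[!is.finite(Z)] <- 0
  set.seed(seed)
  msub <- ceiling(subsample_fraction * n)
  cosample <- matrix(0, n, n)
  cocluster <- lapply(k_range, function(k) matrix(0, n, n))
  names(cocluster) <- as.character(k_range)
  for (r in seq_len(n_reps)) {
    idx <- sort(sample.int(n, msub))
    cosample[idx, idx] <- cosample[idx, idx] + 1
    D <- t(Z[, idx, drop = FALSE])
    for (k in k_range) {
      cl <- .base_cluster(D, k)
      cocluster[[as.character(k)]][idx, idx] <-
        cocluster[[as.character(k)]][idx, idx] + outer(cl, cl, "==")
    }
  }
  never <- sum(cosample[upper.tri(cosample)] == 0)
  if (never > 0)
    message(never, " sample pair(s) never co-sampled; consensus set to 0")
  ids <- colnames(m)
  consensus <- lapply(cocluster, function(cc) {
    cons <- ifelse(cosample > 0, cc / pmax(cosample, 1), 0)
    diag(cons) <- 1
    dimnames(cons) <- list(ids, ids)
    cons
  })
  assignments <- lapply(seq_along(k_range), function(i) {
    hc <- hclust(as.dist(1 - consensus[[i]]), method = "average")
    cl <- cutree(hc, k = k_range[i])
    names(cl) <- ids
    cl
  })
  names(assignments) <- as.character(k_range)
  res <- structure(list(k_range = k_range, consensus = consensus,
                        assignments = assignments,
                        n_reps = n_reps,
                        subsample_fraction = subsample_fraction,
                        seed = seed, never_cosampled = never),
                   class = "consensus_result")
  sel <- select_k(res)
  res$pac <- sel$pac
  res$cdf <- sel$cdf
  res$delta_area <- sel$delta_area
  res$chosen_k <- sel$chosen_k
  res$low_confidence <- sel$low_confidence
  res
}

#' Select the cluster number from a consensus result
#'
#' Chooses `k` minimising the proportion of ambiguous clustering,
#' `PAC_k = F_k(0.9) - F_k(0.1)` where `F_k` is the empirical CDF of the
#' off-diagonal consensus entries. PAC saturates at 0 for every `k` at or
#' below the true cluster count when separation is strong (merging two
#' well-separated clusters is itself a stable operation), so exact PAC
#' ties are broken by the secondary diagnostic, the area under the
#' consensus CDF: the tied `k` with the larger area (lower mean consensus,
#' i.e. the finer stable partition) wins, and only a full degeneracy where
#' the areas tie too falls back to the smallest `k` (e.g. a single point
#' mass, where every pair always co-clusters at every `k`). A
#' `low_confidence` flag is raised when even the best PAC exceeds 0.25 (no
#' clearly stable partition, e.g. pure noise).
#'
#' @param result a `consensus_result`.
#' @return list with `chosen_k`, `pac` (named vector), `cdf` (list of ecdf
#'   functions), `delta_area` and `low_confidence`.
#' @export
select_k <- function(result) {
  stopifnot(inherits(result, "consensus_result"))
  ks <- result$k_range
  offdiag <- lapply(result$consensus, function(cons) cons[upper.tri(cons)])
  cdf <- lapply(offdiag, ecdf)
  pac <- vapply(cdf, function(f) f(0.9) - f(0.1), numeric(1))
  names(pac) <- as.character(ks)
  ## area under the consensus CDF on [0,1]; 1 - mean(consensus)
  area <- vapply(offdiag, function(v) 1 - mean(v), numeric(1))
  delta_area <- c(area[1], diff(area) / pmax(area[-length(area)], .Machine$double.eps))
  names(delta_area) <- as.character(ks)
  tied <- which(pac <= min(pac) + 1e-8)
  best_area <- max(area[tied])
  chosen <- ks[tied[area[tied] >= best_area - 1e-8][1]]
  if (best_area <= 1e-8) chosen <- ks[tied[1]]   # fully degenerate: smallest k
  list(chosen_k = chosen, pac = pac, cdf = cdf, delta_area = delta_area,
       low_confidence = min(pac) > 0.25)
}

#' Adjusted Rand index (Hubert-Arabie)
#'
#' Chance-corrected agreement between two partitions of the same items,
#' computed from the pair-counting contingency table. Equals 1 for
#' identical partitions and has expectation 0 under random labelling.
#'
#' @param a,b label vectors of equal length.
#' @return ARI value in `[-1, 1]`.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("label vectors differ in length")
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(0)   # e.g. one of the partitions is trivial
  (sum_ij - expected) / (max_index - expected)
}
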