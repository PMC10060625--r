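## Drug-response prediction from expression: panel filtering, kNN
## imputation of AUC tables, ridge regression with cross-validated
## penalty selection, projection onto tumour cohorts, and association of
## predicted response with a patient score.

#' Filter a cell-line drug panel
#'
#' Cell lines from excluded lineages are dropped first; then compounds
#' whose NA fraction (computed after the lineage exclusion) strictly
#' exceeds `max_na` are removed — a compound at exactly the threshold is
#' retained.
#'
#' @param expr cell-line expression matrix (genes x cell lines).
#' @param auc cell line x compound response matrix (AUC; lower = more
#'   sensitive), rownames = cell lines.
#' @param lineage named per-cell-line tissue label.
#' @param max_na maximal tolerated NA fraction per compound (default 0.2).
#' @param excluded_lineages lineages to drop entirely (default
#'   haematopoietic and lymphoid lines).
#' @return list with filtered `expr`, `auc`, `lineage`.
#' @export
filter_panel <- function(expr, auc, lineage, max_na = 0.2,
                         excluded_lineages = "haematopoietic_and_lymphoid") {
  lines <- intersect(colnames(expr), rownames(auc))
  if (!length(lines)) stop("no shared cell lines between expression and AUC")
  keep_lines <- lines[!(lineage[lines] %in% excluded_lineages)]
  if (!length(keep_lines)) stop("all cell lines excluded by lineage")
  auc <- auc[keep_lines, , drop = FALSE]
  na_frac <- colMeans(is.na(auc))
  keep_comp <- na_frac <= max_na
  if (!any(keep_comp)) stop("all compounds removed by the NA filter")
  list(expr = expr[, keep_lines, drop = FALSE],
       auc = auc[, keep_comp, drop = FALSE],
       lineage = lineage[keep_lines])
}

#' k-nearest-neighbour imputation of a response table
#'
#' A missing (cell line, compound) entry is filled with the mean of that
#' compound among the `k` cell lines nearest by Euclidean distance over
#' mutually observed compounds; neighbours that also lack the compound are
#' skipped, and if none of the `k` qualifies the column mean is used (with
#' a message).
#'
#' @param auc cell line x compound matrix with missing entries.
#' @param k neighbourhood size (default 5, must be < number of rows).
#' @return complete matrix of the same shape.
#' @export
knn_impute <- function(auc, k = 5) {
  n <- nrow(auc)
  if (k >= n) stop("k must be smaller than the number of cell lines")
  if (any(colSums(!is.na(auc)) == 0))
    stop("fully missing compound column(s): ",
         paste(colnames(auc)[colSums(!is.na(auc)) == 0], collapse = ", "))
  if (any(rowSums(!is.na(auc)) == 0))
    stop("fully missing cell line row(s): ",
         paste(rownames(auc)[rowSums(!is.na(auc)) == 0], collapse = ", "))
  if (!anyNA(auc)) return(auc)
  out <- auc
  colmean <- colMeans(auc, na.rm = TRUE)
  dist_to <- function(i) {
    di <- rep(Inf, n)
    xi <- auc[i, ]
    for (j in seq_len(n)) {
      if (j == i) next
      shared <- !is.na(xi) & !is.na(auc[j, ])
      if (any(shared)) di[j] <- sqrt(sum((xi[shared] - auc[j, shared])^2))
    }
    di
  }
  for (i in seq_len(n)) {
    miss <- which(is.na(auc[i, ]))
    if (!length(miss)) next
    nb <- order(dist_to(i))[seq_len(k)]
    for (cc in miss) {
      vals <- auc[nb, cc]
      vals <- vals[!is.na(vals)]
      if (length(vals)) {
        out[i, cc] <- mean(vals)
      } else {
        message("no neighbour observed for (", rownames(auc)[i], ", ",
                colnames(auc)[cc], "); using column mean")
        out[i, cc] <- colmean[cc]
      }
    }
  }
  out
}

#' Ridge solution of the normal equations
#'
#' `w = (X'X + lambda I)^-1 X'y`, with no centring or scaling — the raw
#' penalised least-squares solution. `lambda = 0` on full-rank designs
#' reproduces ordinary least squares.
#'
#' @param X design matrix (observations x predictors).
#' @param y response vector.
#' @param lambda non-negative penalty.
#' @return coefficient vector.
#' @export
ridge_solve <- function(X, y, lambda) {
  stopifnot(lambda >= 0)
  p <- ncol(X)
  drop(solve(crossprod(X) + diag(lambda, p), crossprod(X, y)))
}

#' Train a ridge drug-response model on a cell-line panel
#'
#' Genes are standardised and the response is standardised per compound;
#' the penalty is chosen from `lambda_grid` to maximise the mean
#' cross-validated Spearman correlation of observed vs predicted response
#' (folds are seeded). Predictions are reported on the original response
#' scale.
#'
#' @param expr cell-line expression matrix (log scale, genes x lines).
#' @param auc complete cell line x compound response matrix.
#' @param compound compound (column) to model.
#' @param lambda_grid candidate penalties (default `10^(-2:4)`).
#' @param cv_folds folds (default 10).
#' @param seed RNG seed for the fold assignment.
#' @return object of class `ridge_model`: weights, intercept parameters,
#'   chosen `lambda`, `cv_correlation`, gene standardisation constants and
#'   a reference to the training matrix (for cross-cohort homogenisation).
#' @export
train_ridge <- function(expr, auc, compound, lambda_grid = 10^(-2:4),
                        cv_folds = 10, seed = 1) {
  if (!compound %in% colnames(auc)) stop("unknown compound: ", compound)
  lines <- intersect(colnames(expr), rownames(auc))
  if (length(lines) < 20) stop("need at least 20 cell lines after filtering")
  y0 <- auc[lines, compound]
  if (anyNA(y0)) stop("response contains NAs; impute first")
  if (sd(y0) == 0) stop("constant response for ", compound)
  X0 <- t(expr[, lines, drop = FALSE])
  xm <- colMeans(X0); xs <- apply(X0, 2, sd); xs[xs == 0] <- 1
  Xs <- sweep(sweep(X0, 2, xm, "-"), 2, xs, "/")
  ym <- mean(y0); ys <- sd(y0)
  yz <- (y0 - ym) / ys
  n <- length(yz)
  set.seed(seed)
  folds <- sample(rep_len(seq_len(cv_folds), n))
  cv_cor <- vapply(lambda_grid, function(lam) {
    cs <- vapply(seq_len(cv_folds), function(f) {
      tr <- folds != f
      w <- ridge_solve(Xs[tr, , drop = FALSE], yz[tr], lam)
      pred <- Xs[!tr, , drop = FALSE] %*% w
      if (sd(pred) == 0) return(0)
      cor(pred, yz[!tr], method = "spearman")
    }, numeric(1))
    mean(cs)
  }, numeric(1))
  lam <- lambda_grid[which.max(cv_cor)]
  w <- ridge_solve(Xs, yz, lam)
  structure(list(compound = compound, genes = rownames(expr),
                 weights = setNames(w, rownames(expr)),
                 lambda = lam, cv_correlation = max(cv_cor),
                 cv_grid = setNames(cv_cor, lambda_grid),
                 x_center = xm, x_scale = xs, y_center = ym, y_scale = ys,
                 train_expr = expr),
            class = "ridge_model")
}

#' Predict drug response for tumour samples
#'
#' Projects tumour expression onto a trained ridge model. With
#' `homogenize = TRUE` the cell-line and tumour matrices are concatenated,
#' batch-corrected with a two-level batch label (see [combat_correct()]),
#' and the corrected cell-line columns supply the standardisation
#' constants; otherwise the model's training constants are used directly.
#' Model genes missing from the tumour matrix contribute zero after
#' standardisation (a message reports how many).
#'
#' @param model a `ridge_model`.
#' @param tumor_expr tumour expression matrix (same log scale as the
#'   training panel).
#' @param homogenize cross-cohort batch correction before projection.
#' @return named numeric vector of predicted responses (original response
#'   scale; lower = more sensitive).
#' @export
predict_response <- function(model, tumor_expr, homogenize = TRUE) {
  shared <- intersect(model$genes, rownames(tumor_expr))
  if (length(shared) < 0.5 * length(model$genes))
    stop(sprintf("insufficient gene overlap: %d of %d model genes present",
                 length(shared), length(model$genes)))
  n_missing <- length(model$genes) - length(shared)
  if (n_missing > 0)
    message(n_missing, " model gene(s) absent; they contribute 0 after standardisation")
  if (homogenize) {
    comb <- cbind(model$train_expr[shared, , drop = FALSE],
                  tumor_expr[shared, , drop = FALSE])
    batch <- rep(c("cellline", "tumor"),
                 c(ncol(model$train_expr), ncol(tumor_expr)))
    attr(comb, "unit") <- NULL
    cc <- combat_correct(comb, batch)
    ccl <- cc[, batch == "cellline", drop = FALSE]
    tum <- cc[, batch == "tumor", drop = FALSE]
    xm <- rowMeans(ccl)
    xs <- apply(ccl, 1, sd); xs[xs == 0] <- 1
  } else {
    tum <- tumor_expr[shared, , drop = FALSE]
    xm <- model$x_center[shared]
    xs <- model$x_scale[shared]
  }
  Z <- (tum - xm) / xs
  pred <- drop(crossprod(Z, model$weights[shared]))
  model$y_center + model$y_scale * pred
}

#' Associate predicted response with a patient score
#'
#' Spearman correlation between predicted response and score, plus a
#' Wilcoxon rank-sum comparison of predicted response between the
#' median-split score groups.
#'
#' @param predicted named per-sample predicted response.
#' @param score named per-sample score (shared samples >= 3).
#' @return list with `rho`, `p`, `wilcox_p`, `n`.
#' @export
score_response_association <- function(predicted, score) {
  shared <- intersect(names(predicted), names(score))
  if (length(shared) < 3) stop("fewer than 3 shared samples")
  st <- spearman_test(predicted[shared], score[shared])
  if (is.na(st$rho)) return(list(rho = NA_real_, p = NA_real_,
                                 wilcox_p = NA_real_, n = length(shared)))
  grp <- split_groups(score[shared], rule = "median")
  w <- suppressWarnings(wilcox.test(predicted[shared][grp == "high"],
                                    predicted[shared][grp == "low"]))
  list(rho = st$rho, p = st$p, wilcox_p = w$p.value, n = length(shared))
}
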