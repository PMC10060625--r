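## Survival machinery: Kaplan-Meier, log-rank, Cox (Breslow ties),
## moderated differential expression, BH adjustment, DEG intersection and
## maximally selected log-rank cutpoint stratification.

.check_clinical <- function(clin) {
  need <- c("sample_id", "time", "event")
  miss <- setdiff(need, names(clin))
  if (length(miss))
    stop("clinical table lacks column(s): ", paste(miss, collapse = ", "))
  if (any(!is.finite(clin$time))) stop("non-finite survival times")
  if (any(clin$time < 0)) stop("negative survival times")
  if (!all(clin$event %in% c(0, 1))) stop("event indicator must be 0/1")
  if (anyDuplicated(clin$sample_id)) stop("duplicate sample ids in clinical table")
  invisible(TRUE)
}

#' Kaplan-Meier product-limit curves
#'
#' @param clin clinical data.frame with `sample_id`, `time`, `event`.
#' @param groups optional per-sample group labels (aligned with `clin`
#'   rows); default a single group.
#' @return data.frame with `group`, `time`, `n_risk`, `n_event`, `surv`
#'   (non-increasing, starting at 1 before the first event time).
#' @export
km_fit <- function(clin, groups = NULL) {
  .check_clinical(clin)
  if (sum(clin$event) < 1) warning("no events: survival curve is constant 1")
  if (is.null(groups)) groups <- rep("all", nrow(clin))
  g <- factor(groups)
  sf <- survival::survfit(survival::Surv(clin$time, clin$event) ~ g)
  if (is.null(sf$strata)) {
    grp <- rep(levels(g)[1], length(sf$time))
  } else {
    grp <- rep(sub("^g=", "", names(sf$strata)), sf$strata)
  }
  data.frame(group = grp, time = sf$time, n_risk = sf$n.risk,
             n_event = sf$n.event, surv = sf$surv, row.names = NULL)
}

#' Log-rank test across groups
#'
#' Standard observed-minus-expected statistic with hypergeometric variance
#' summed over event times (simultaneous-event tie convention);
#' `df = n_groups - 1`.
#'
#' @param clin clinical data.frame.
#' @param groups per-sample group labels (>= 2 groups).
#' @return list with `chisq`, `df`, `p`.
#' @export
logrank_test <- function(clin, groups) {
  .check_clinical(clin)
  g <- factor(groups)
  if (nlevels(g) < 2) stop("log-rank test needs at least 2 groups")
  if (sum(clin$event) < 1) stop("log-rank test needs at least 1 event")
  sd_ <- survival::survdiff(survival::Surv(clin$time, clin$event) ~ g)
  df <- nlevels(g) - 1L
  list(chisq = unname(sd_$chisq), df = df,
       p = pchisq(sd_$chisq, df = df, lower.tail = FALSE))
}

## fast two-group log-rank chi-square used by the cutpoint scan.
## t_sorted/d_sorted are time-ordered; g_sorted is logical group membership.
.logrank2 <- function(t_sorted, d_sorted, g_sorted) {
  n <- length(t_sorted)
  first <- !duplicated(t_sorted)
  tid <- cumsum(first)
  atrisk <- (n:1)[first]
  cg <- cumsum(g_sorted)
  atrisk_g <- (sum(g_sorted) - c(0, cg[-n]))[first]
  d_t <- rowsum(d_sorted, tid)[, 1]
  d1_t <- rowsum(d_sorted * g_sorted, tid)[, 1]
  ev <- d_t > 0
  nn <- atrisk[ev]; n1 <- atrisk_g[ev]; dd <- d_t[ev]; dd1 <- d1_t[ev]
  oe <- sum(dd1 - dd * n1 / nn)
  v <- sum(dd * (n1 / nn) * (1 - n1 / nn) * (nn - dd) / pmax(nn - 1, 1))
  if (v <= 0) return(0)
  oe^2 / v
}

#' Cox proportional-hazards fits
#'
#' Breslow partial likelihood maximised by Newton-Raphson (via
#' \code{survival::coxph} with `ties = "breslow"`). Constant covariates
#' are skipped with a warning; fits with monotone likelihood (perfect
#' separation) are flagged non-converged with the coefficient capped at
#' +/-20.
#'
#' @param clin clinical data.frame; covariate columns are looked up here.
#' @param covariates character vector of covariate column names.
#' @param univariate fit each covariate in its own model instead of one
#'   joint model.
#' @return data.frame with `term`, `beta`, `se`, `hr`, `ci_low`, `ci_high`,
#'   `p`, `converged`.
#' @export
cox_fit <- function(clin, covariates, univariate = FALSE) {
  .check_clinical(clin)
  if (sum(clin$event) < 2) stop("Cox fit needs at least 2 events")
  miss <- setdiff(covariates, names(clin))
  if (length(miss)) stop("covariate(s) absent: ", paste(miss, collapse = ", "))
  keep <- vapply(covariates, function(v) {
    x <- clin[[v]]
    if (length(unique(x[!is.na(x)])) < 2) {
      warning("constant covariate skipped: ", v)
      FALSE
    } else TRUE
  }, logical(1))
  covariates <- covariates[keep]
  if (!length(covariates)) stop("no usable covariates")
  one_fit <- function(vars) {
    fml <- reformulate(vars, response = "survival::Surv(time, event)")
    fit <- suppressWarnings(
      survival::coxph(fml, data = clin, ties = "breslow",
                      control = survival::coxph.control(eps = 1e-9,
                                                        iter.max = 50)))
    sm <- summary(fit)
    beta <- coef(fit)
    se <- sqrt(diag(fit$var))
    conv <- abs(beta) <= 20
    beta <- pmin(pmax(beta, -20), 20)
    if (any(!conv))
      warning("possible monotone likelihood; coefficient capped at +/-20: ",
              paste(names(beta)[!conv], collapse = ", "))
    data.frame(term = names(beta), beta = unname(beta), se = unname(se),
               hr = exp(unname(beta)),
               ci_low = exp(unname(beta) - 1.96 * unname(se)),
               ci_high = exp(unname(beta) + 1.96 * unname(se)),
               p = unname(sm$coefficients[, "Pr(>|z|)"]),
               converged = unname(conv), row.names = NULL)
  }
  if (univariate) {
    do.call(rbind, lapply(covariates, one_fit))
  } else {
    one_fit(covariates)
  }
}

#' Moderated differential expression between groups
#'
#' Linear-model group contrasts with empirical-Bayes variance moderation
#' (residual variances shrunk toward a common prior; moderated t for two
#' groups, moderated F for more), BH adjustment, and a significance flag
#' at the requested FDR. Delegates the model fit and shrinkage to limma.
#'
#' @param m log-scale expression matrix (genes x samples).
#' @param groups per-sample group labels (>= 2 levels, >= 2 samples each).
#' @param fdr adjusted-p significance threshold (default 0.05).
#' @return `deg_result` data.frame with `gene`, `logFC` (two-group case;
#'   `NA` for the F test), `stat`, `p`, `padj`, `significant`.
#' @export
moderated_deg <- function(m, groups, fdr = 0.05) {
  .check_unit(m, "LOG2TPM")
  g <- factor(groups)
  if (nlevels(g) < 2) stop("need at least 2 groups")
  if (any(table(g) < 2)) stop("every group needs at least 2 samples")
  design <- model.matrix(~g)
  fit <- limma::eBayes(limma::lmFit(unclass(m), design))
  if (nlevels(g) == 2) {
    tt <- limma::topTable(fit, coef = 2, number = Inf, sort.by = "none")
    out <- data.frame(gene = rownames(m), logFC = tt$logFC, stat = tt$t,
                      p = tt$P.Value, padj = tt$adj.P.Val, row.names = NULL)
  } else {
    tt <- limma::topTable(fit, coef = 2:nlevels(g), number = Inf,
                          sort.by = "none")
    out <- data.frame(gene = rownames(m), logFC = NA_real_, stat = tt$F,
                      p = tt$P.Value, padj = tt$adj.P.Val, row.names = NULL)
  }
  out$significant <- out$padj < fdr
  class(out) <- c("deg_result", class(out))
  attr(out, "fdr") <- fdr
  out
}

#' One-vs-rest differential expression per pattern
#'
#' Runs [moderated_deg()] once per cluster with the contrast
#' cluster-of-interest minus rest, the construction behind the shared-DEG
#' Venn intersection across patterns.
#'
#' @param m log-scale expression matrix.
#' @param groups per-sample cluster labels.
#' @param fdr significance threshold.
#' @return named list of `deg_result` objects, one per cluster.
#' @export
deg_one_vs_rest <- function(m, groups, fdr = 0.05) {
  g <- factor(groups)
  out <- lapply(levels(g), function(lv) {
    ## "rest" as reference level so the contrast is cluster minus rest
    bin <- factor(ifelse(g == lv, lv, "rest"), levels = c("rest", lv))
    moderated_deg(m, bin, fdr = fdr)
  })
  names(out) <- levels(g)
  out
}

#' Benjamini-Hochberg adjustment with input validation
#'
#' @param p numeric p-values in `[0, 1]`.
#' @return BH step-up adjusted p-values (monotone, capped at 1).
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Intersect significant genes across DEG results
#'
#' @param deg_results list of >= 2 `deg_result` objects over the same gene
#'   universe.
#' @return character vector of genes significant in every result.
#' @export
intersect_degs <- function(deg_results) {
  if (length(deg_results) < 2) stop("need at least 2 DEG results")
  universes <- lapply(deg_results, function(d) sort(d$gene))
  if (!all(vapply(universes[-1], identical, logical(1), universes[[1]])))
    stop("DEG results cover different gene universes")
  Reduce(intersect, lapply(deg_results, function(d) d$gene[d$significant]))
}

#' Maximally selected log-rank cutpoint
#'
#' Scans the unique score values inside a quantile window, computing the
#' standardised two-group log-rank statistic for the split
#' `score > cutoff` at each candidate, and returns the maximiser. The
#' p-value is by permutation of the score against (time, event), which
#' accounts for the selection over candidates.
#'
#' @param clin clinical data.frame.
#' @param score per-sample continuous score aligned with `clin` rows.
#' @param q_window quantile window of candidate cutoffs (default
#'   `c(0.1, 0.9)`).
#' @param n_perm permutations for the p-value.
#' @param seed RNG seed for the permutations.
#' @return list with `cutoff` (midpoint between the best candidate and the
#'   next distinct value), `statistic` (max standardised log-rank, i.e.
#'   sqrt of the chi-square), `p` and `n_candidates`.
#' @export
optimal_cutpoint <- function(clin, score, q_window = c(0.1, 0.9),
                             n_perm = 1000, seed = 1) {
  .check_clinical(clin)
  if (length(score) != nrow(clin)) stop("score must align with clinical rows")
  uv <- sort(unique(score))
  if (length(uv) < 2) stop("all scores are equal; no cutpoint exists")
  qs <- quantile(score, q_window)
  cand <- uv[uv >= qs[1] & uv < max(uv)]
  cand <- cand[cand <= qs[2]]
  if (!length(cand)) cand <- uv[1]       # forced split between two values
  o <- order(clin$time)
  ts <- clin$time[o]; ds <- clin$event[o]
  scan_max <- function(sc) {
    ss <- sc[o]
    best <- 0
    for (cut in cand) {
      chi <- .logrank2(ts, ds, ss > cut)
      if (chi > best) best <- chi
    }
    best
  }
  stats <- vapply(cand, function(cut) .logrank2(ts, ds, score[o] > cut),
                  numeric(1))
  best_i <- which.max(stats)
  best_cut <- cand[best_i]
  nxt <- uv[match(best_cut, uv) + 1]
  cutoff <- (best_cut + nxt) / 2
  obs <- stats[best_i]
  set.seed(seed)
  perm <- vapply(seq_len(n_perm), function(b) scan_max(sample(score)),
                 numeric(1))
  list(cutoff = unname(cutoff), statistic = sqrt(obs),
       p = (1 + sum(perm >= obs)) / (n_perm + 1),
       n_candidates = length(cand))
}
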