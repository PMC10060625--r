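## shared fixtures, built in code

## tiny tagged expression matrix from a plain numeric matrix
as_expr <- function(values, unit = "LOG2TPM") {
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("g%d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("s%d", seq_len(ncol(values)))
  expression_matrix(values, unit)
}

## clinical table from bare vectors
clin_tab <- function(time, event, ids = sprintf("s%d", seq_along(time))) {
  data.frame(sample_id = ids, time = time, event = event,
             stringsAsFactors = FALSE)
}

## small well-separated cohort reused across cluster/copsig tests
small_cohort <- function(effect = 3, n = 90, seed = 7) {
  simulate_bulk_cohort(bulk_cohort_spec(
    n_genes = 200, n_samples = n, n_subtypes = 3, n_regulator_genes = 10,
    n_signature_genes_per_subtype = 20, subtype_effect = effect, seed = seed))
}

## Breslow partial log-likelihood for one covariate, for grid-search oracles
breslow_loglik <- function(beta, time, event, x) {
  ll <- 0
  for (i in which(event == 1)) {
    risk <- time >= time[i]
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}
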