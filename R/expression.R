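#' Tagged expression matrix
#'
#' The pipeline's bulk substrate is a plain numeric matrix (genes in rows,
#' samples in columns) carrying a `unit` attribute so that stages can check
#' they are fed the scale they expect. Units: `"FPKM"`, `"TPM"` (columns
#' summing to 1e6), `"LOG2TPM"` (log2(TPM + 1)), `"COUNTS"`.
#'
#' @param values numeric matrix with unique rownames (gene ids) and unique
#'   colnames (sample ids); all values finite, non-negative unless already
#'   log-scale.
#' @param unit one of `"FPKM"`, `"TPM"`, `"LOG2TPM"`, `"COUNTS"`.
#' @return the validated matrix with a `unit` attribute.
#' @export
expression_matrix <- function(values, unit = c("FPKM", "TPM", "LOG2TPM", "COUNTS")) {
  unit <- match.arg(unit)
  if (!is.matrix(values) || !is.numeric(values))
    stop("expression values must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression matrix needs gene ids (rownames) and sample ids (colnames)")
  dg <- unique(rownames(values)[duplicated(rownames(values))])
  if (length(dg))
    stop("duplicate gene ids: ", paste(dg, collapse = ", "))
  ds <- unique(colnames(values)[duplicated(colnames(values))])
  if (length(ds))
    stop("duplicate sample ids: ", paste(ds, collapse = ", "))
  if (any(!is.finite(values)))
    stop("expression matrix contains non-finite values")
  if (unit != "LOG2TPM" && any(values < 0))
    stop("negative values are not allowed for unit ", unit)
  attr(values, "unit") <- unit
  values
}

#' Get the unit tag of an expression matrix
#' @param m matrix produced by [expression_matrix()] or the readers.
#' @return the unit string, or `NULL` when untagged.
#' @export
expr_unit <- function(m) attr(m, "unit", exact = TRUE)

## check a unit tag when present; unreadable inputs fail loudly, untagged
## matrices are trusted (they may have gone through subsetting, which drops
## attributes in base R)
.check_unit <- function(m, expected) {
  u <- expr_unit(m)
  if (!is.null(u) && !(u %in% expected))
    stop(sprintf("expected expression unit %s but got '%s'",
                 paste(sprintf("'%s'", expected), collapse = " or "), u))
  invisible(TRUE)
}

#' Convert FPKM to TPM
#'
#' `TPM[g, j] = FPKM[g, j] / sum_g FPKM[g, j] * 1e6`, so every sample
#' column sums to one million.
#'
#' @param m FPKM matrix (genes x samples).
#' @return TPM-tagged matrix of the same shape.
#' @export
fpkm_to_tpm <- function(m) {
  .check_unit(m, "FPKM")
  cs <- colSums(m)
  bad <- colnames(m)[cs <= 0]
  if (length(bad))
    stop("all-zero sample column(s): ", paste(bad, collapse = ", "))
  out <- sweep(m, 2, cs, "/") * 1e6
  expression_matrix(out, "TPM")
}

#' Log-transform a TPM matrix
#'
#' Applies `log2(TPM + 1)`; the +1 offset keeps zeros finite and is the
#' conventional choice for downstream linear statistics.
#'
#' @param m TPM matrix.
#' @return LOG2TPM-tagged matrix.
#' @export
log2_tpm <- function(m) {
  .check_unit(m, c("TPM", "FPKM"))
  if (identical(expr_unit(m), "FPKM")) m <- fpkm_to_tpm(m)
  expression_matrix(log2(m + 1), "LOG2TPM")
}
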