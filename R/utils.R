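#' Spearman correlation with t-approximation p-value
#'
#' Computes Spearman's rank correlation between two numeric vectors and a
#' two-sided p-value from the t approximation on mid-ranked data,
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees of freedom.
#' Constant inputs have no defined rank correlation and return `NA` for
#' both fields.
#'
#' @param x,y numeric vectors of equal length (>= 3 pairs after removing
#'   missing values).
#' @return list with elements `rho`, `p` and `n`.
#' @export
spearman_test <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("spearman_test() needs at least 3 complete pairs")
  if (sd(x) == 0 || sd(y) == 0) return(list(rho = NA_real_, p = NA_real_, n = n))
  rho <- cor(rank(x), rank(y))
  if (abs(rho) >= 1) return(list(rho = rho, p = 0, n = n))
  tt <- rho * sqrt((n - 2) / (1 - rho^2))
  list(rho = rho, p = 2 * pt(-abs(tt), df = n - 2), n = n)
}

## error helper: consistent "configuration error naming the field" style
.cfg_error <- function(field, msg) {
  stop(sprintf("invalid configuration: field '%s' %s", field, msg), call. = FALSE)
}

## draw a 32-bit sub-seed from the current RNG stream
.subseed <- function() sample.int(.Machine$integer.max, 1L)
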