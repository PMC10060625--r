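## File formats and preprocessing: TSV expression matrices, GMT gene-set
## collections, MatrixMarket count triplets with sidecars, MAF-like
## mutation tables; batch correction and the regulator-panel summaries.

#' Read an expression matrix from TSV
#'
#' Expects a tab-delimited file whose first column holds gene ids and whose
#' header row holds sample ids. Duplicated ids and negative values are
#' format errors naming the offenders.
#'
#' @param path TSV file path.
#' @param unit unit tag to attach (see [expression_matrix()]).
#' @return tagged expression matrix.
#' @export
read_expression <- function(path, unit = "FPKM") {
  dt <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  if (ncol(dt) < 2) stop("expression TSV needs a gene id column plus samples")
  ids <- as.character(dt[[1]])
  m <- as.matrix(dt[, -1, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- ids
  expression_matrix(m, unit)
}

#' Write an expression matrix to TSV
#' @param m expression matrix.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(m, path) {
  dt <- data.table::data.table(gene_id = rownames(m), m)
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' One set per line: name, description, then member genes, tab-separated.
#' Duplicate genes within a set are dropped; duplicate set names are an
#' error.
#'
#' @param path GMT file path.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nm <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(nm))
    stop("duplicate gene set names: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  sets <- lapply(fields, function(f) unique(f[-(1:2)][nzchar(f[-(1:2)])]))
  names(sets) <- nm
  bad <- nm[lengths(sets) == 0]
  if (length(bad)) stop("empty gene set(s): ", paste(bad, collapse = ", "))
  sets
}

#' Write gene sets in GMT format
#' @param sets named list of character vectors.
#' @param path output file path.
#' @param description description field (recycled).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, description = "na") {
  stopifnot(is.list(sets), !is.null(names(sets)))
  lines <- mapply(function(nm, genes, desc) {
    paste(c(nm, desc, genes), collapse = "\t")
  }, names(sets), sets, rep_len(description, length(sets)))
  writeLines(unname(lines), path)
  invisible(path)
}

#' Read a sparse count matrix (MatrixMarket triplet + sidecars)
#'
#' @param mtx_path MatrixMarket file (1-based triplets, genes x cells).
#' @param features_path text file of gene ids, one per row.
#' @param barcodes_path text file of cell ids, one per row.
#' @return dense integer matrix, genes x cells.
#' @export
read_mtx_counts <- function(mtx_path, features_path, barcodes_path) {
  m <- as.matrix(Matrix::readMM(mtx_path))
  genes <- readLines(features_path)
  cells <- readLines(barcodes_path)
  if (nrow(m) != length(genes) || ncol(m) != length(cells))
    stop("MTX dimensions do not match sidecar files")
  dimnames(m) <- list(genes, cells)
  storage.mode(m) <- "integer"
  m
}

#' Write a count matrix as MatrixMarket triplet + sidecars
#' @param counts genes x cells matrix.
#' @param mtx_path,features_path,barcodes_path output paths.
#' @return `mtx_path`, invisibly.
#' @export
write_mtx_counts <- function(counts, mtx_path, features_path, barcodes_path) {
  Matrix::writeMM(Matrix::Matrix(counts, sparse = TRUE), mtx_path)
  writeLines(rownames(counts), features_path)
  writeLines(colnames(counts), barcodes_path)
  invisible(mtx_path)
}

#' Read a MAF-like mutation table
#'
#' Required columns: `sample_id`, `gene`, `variant_classification`.
#' @param path TSV path.
#' @return data.frame of mutation events.
#' @export
read_mutations <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  need <- c("sample_id", "gene", "variant_classification")
  miss <- setdiff(need, names(dt))
  if (length(miss))
    stop("mutation table lacks column(s): ", paste(miss, collapse = ", "))
  dt
}

#' Empirical-Bayes batch correction (ComBat)
#'
#' Location-scale batch adjustment on log-scale expression via the
#' parametric empirical-Bayes scheme (standardise per gene, shrink
#' per-batch additive and multiplicative effects toward batch-level priors,
#' adjust, restore). Delegates to \code{sva::ComBat}; gene and sample order
#' are preserved. With a single batch the input is returned unchanged with
#' a warning; a batch containing one sample is an error.
#'
#' @param m log-scale expression matrix (genes x samples).
#' @param batch per-sample batch labels.
#' @return corrected matrix with the same dimnames and unit tag.
#' @export
combat_correct <- function(m, batch) {
  .check_unit(m, "LOG2TPM")
  if (length(batch) != ncol(m))
    stop("batch labels must have one entry per sample")
  batch <- factor(batch)
  if (nlevels(batch) < 2) {
    warning("fewer than 2 batches: returning input unchanged")
    return(m)
  }
  sizes <- table(batch)
  if (any(sizes < 2))
    stop("batch(es) with a single sample: ",
         paste(names(sizes)[sizes < 2], collapse = ", "))
  out <- suppressMessages(sva::ComBat(dat = unclass(m), batch = batch,
                                      par.prior = TRUE, prior.plots = FALSE))
  dimnames(out) <- dimnames(m)
  u <- expr_unit(m)
  if (!is.null(u)) attr(out, "unit") <- u
  out
}

#' Summarise mutation frequencies over a gene panel
#'
#' Per-gene frequency = samples with at least one event in that gene over
#' the whole cohort; samples absent from the table count as unaltered.
#' Also reports the fraction of samples with >= 1 alteration anywhere in
#' the panel.
#'
#' @param mutations data.frame with `sample_id`, `gene`,
#'   `variant_classification`.
#' @param gene_panel character vector of panel genes (non-empty).
#' @param cohort_samples character vector of all cohort sample ids.
#' @return list with `frequency` (data.frame gene/n_mutated/frequency),
#'   `altered_fraction` and `n_altered`.
#' @export
summarize_mutations <- function(mutations, gene_panel, cohort_samples) {
  if (!length(gene_panel)) stop("gene_panel must be non-empty")
  unknown <- setdiff(unique(mutations$sample_id), cohort_samples)
  if (length(unknown))
    stop("mutation table sample(s) not in cohort: ",
         paste(unknown, collapse = ", "))
  sub <- mutations[mutations$gene %in% gene_panel, , drop = FALSE]
  n <- length(cohort_samples)
  n_mut <- vapply(gene_panel, function(g)
    length(unique(sub$sample_id[sub$gene == g])), integer(1))
  altered <- unique(sub$sample_id)
  list(frequency = data.frame(gene = gene_panel, n_mutated = n_mut,
                              frequency = n_mut / n, row.names = NULL),
       altered_fraction = length(altered) / n,
       n_altered = length(altered))
}

#' Pairwise Spearman correlation network over a gene panel
#'
#' Symmetric rank-correlation matrix with unit diagonal; p-values from the
#' t approximation on mid-ranked data, BH-adjusted over the distinct
#' off-diagonal pairs. Constant genes yield missing entries.
#'
#' @param m expression matrix.
#' @param gene_panel genes to correlate (must be rows of `m`).
#' @return list of matrices `rho`, `p`, `padj`.
#' @export
spearman_network <- function(m, gene_panel) {
  miss <- setdiff(gene_panel, rownames(m))
  if (length(miss)) stop("panel gene(s) absent: ", paste(miss, collapse = ", "))
  if (ncol(m) < 3) stop("need at least 3 samples")
  X <- m[gene_panel, , drop = FALSE]
  p <- length(gene_panel)
  rho <- pmat <- matrix(NA_real_, p, p, dimnames = list(gene_panel, gene_panel))
  diag(rho) <- 1; diag(pmat) <- 0
  for (i in seq_len(p - 1)) for (j in (i + 1):p) {
    st <- spearman_test(X[i, ], X[j, ])
    rho[i, j] <- rho[j, i] <- st$rho
    pmat[i, j] <- pmat[j, i] <- st$p
  }
  ut <- upper.tri(pmat)
  padj <- matrix(NA_real_, p, p, dimnames = dimnames(pmat))
  adj <- rep(NA_real_, sum(ut))
  ok <- !is.na(pmat[ut])
  adj[ok] <- p.adjust(pmat[ut][ok], method = "BH")
  padj[ut] <- adj
  padj[lower.tri(padj)] <- t(padj)[lower.tri(padj)]
  diag(padj) <- 0
  list(rho = rho, p = pmat, padj = padj)
}
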