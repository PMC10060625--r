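test_that("expression TSV round-trips through real I/O", {
  m <- as_expr(matrix(c(1.5, 2, 0, 3.25), 2, 2), unit = "FPKM")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_expression(m, path)
  back <- read_expression(path, unit = "FPKM")
  expect_identical(dimnames(back), dimnames(m))
  expect_equal(unclass(back), unclass(m), tolerance = 1e-6,
               ignore_attr = TRUE)
  ## syndata fixture round-trip
  co <- simulate_bulk_cohort(bulk_cohort_spec(n_genes = 50, n_samples = 10,
                                              n_signature_genes_per_subtype = 5,
                                              seed = 2))
  write_expression(co$expr, path)
  expect_equal(unclass(read_expression(path, "FPKM")), unclass(co$expr),
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("malformed expression input is rejected naming the offender", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\ts1\ts2", "gA\t1\t2", "gA\t3\t4"), path)
  expect_error(read_expression(path), "gA")
  writeLines(c("gene_id\ts1\ts2", "gA\t1\t-2", "gB\t3\t4"), path)
  expect_error(read_expression(path), "negative")
})

test_that("FPKM to TPM follows the closed form and normalises columns", {
  m <- as_expr(cbind(s1 = c(5, 5), s2 = c(1, 3)), unit = "FPKM")
  tpm <- fpkm_to_tpm(m)
  expect_equal(unname(tpm[, "s1"]), c(5e5, 5e5))
  expect_equal(unname(tpm[, "s2"]), c(2.5e5, 7.5e5))
  m3 <- as_expr(matrix(c(2, 3, 5), 3, 1), unit = "FPKM")
  expect_equal(unname(fpkm_to_tpm(m3)[, 1]), c(2e5, 3e5, 5e5))
  ## every column sums to 1e6 on a random matrix
  r <- as_expr(matrix(runif(60, 0.1, 10), 12, 5), unit = "FPKM")
  expect_equal(unname(colSums(fpkm_to_tpm(r))), rep(1e6, 5))
  bad <- as_expr(cbind(s1 = c(1, 2), s2 = c(0, 0)), unit = "FPKM")
  expect_error(fpkm_to_tpm(bad), "s2")
})

test_that("batch correction shrinks planted shifts and handles degenerate batching", {
  co <- simulate_bulk_cohort(bulk_cohort_spec(
    n_genes = 120, n_samples = 80, n_signature_genes_per_subtype = 10,
    batch_labels = rep(c("a", "b"), each = 40), batch_shift = c(0, 2),
    seed = 8))
  ## TPM renormalisation would absorb a sample-wide scale shift before the
  ## batch correction ever saw it, so the check runs on the log-FPKM scale
  ## where the planted shift persists
  le <- expression_matrix(log2(unclass(co$expr) + 1), "LOG2TPM")
  batch <- co$batch
  gap_before <- mean(abs(rowMeans(le[, batch == "a"]) -
                         rowMeans(le[, batch == "b"])))
  corrected <- combat_correct(le, batch)
  gap_after <- mean(abs(rowMeans(corrected[, batch == "a"]) -
                        rowMeans(corrected[, batch == "b"])))
  expect_lt(gap_after, 0.1 * gap_before)
  expect_identical(dimnames(corrected), dimnames(le))
  ## single batch: identity with a warning
  expect_warning(same <- combat_correct(le, rep("a", ncol(le))), "fewer than 2")
  expect_identical(same, le)
  expect_error(combat_correct(le, c("a", rep("b", ncol(le) - 1))), "single sample")
})

test_that("mutation summaries use set semantics over the cohort", {
  cohort <- sprintf("s%d", 1:10)
  empty <- data.frame(sample_id = character(), gene = character(),
                      variant_classification = character())
  s0 <- summarize_mutations(empty, c("FDX1", "LIAS"), cohort)
  expect_true(all(s0$frequency$frequency == 0))
  mut <- data.frame(
    sample_id = c("s1", "s2", "s3", "s3"),
    gene = c("LIAS", "LIAS", "FDX1", "FDX1"),
    variant_classification = c("missense", "nonsense", "missense",
                               "frameshift_del"))
  s <- summarize_mutations(mut, c("FDX1", "LIAS"), cohort)
  expect_equal(s$altered_fraction, 0.30)
  ## two variants in the same gene of one sample count once
  expect_equal(s$frequency$n_mutated[s$frequency$gene == "FDX1"], 1L)
  bad <- data.frame(sample_id = "zz", gene = "LIAS",
                    variant_classification = "missense")
  expect_error(summarize_mutations(bad, "LIAS", cohort), "zz")
})

test_that("spearman network matches the explicit rank formula", {
  x <- c(1, 2, 3, 4, 5)
  m <- as_expr(rbind(gA = x, gB = 10 - x, gC = c(2, 2, 5, 1, 7)))
  colnames(m) <- sprintf("s%d", 1:5)
  net <- spearman_network(m, c("gA", "gB", "gC"))
  expect_equal(diag(net$rho), rep(1, 3), ignore_attr = TRUE)
  expect_equal(net$rho["gA", "gB"], -1)
  expect_equal(net$rho, t(net$rho))
  ## oracle: Pearson correlation of mid-ranks (gC has a tie)
  oracle <- cor(rank(x), rank(c(2, 2, 5, 1, 7)))
  expect_equal(net$rho["gA", "gC"], oracle, tolerance = 1e-12)
})

test_that("GMT and MTX writers round-trip through their readers", {
  sets <- list(alpha = c("g1", "g2", "g3"), beta = c("g9", "g2"))
  gmt <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(sets, gmt)
  expect_identical(read_gmt(gmt), sets)
  counts <- matrix(rpois(20, 3), 4, 5,
                   dimnames = list(sprintf("g%d", 1:4), sprintf("c%d", 1:5)))
  d <- withr::local_tempdir()
  write_mtx_counts(counts, file.path(d, "m.mtx"), file.path(d, "f.txt"),
                   file.path(d, "b.txt"))
  back <- read_mtx_counts(file.path(d, "m.mtx"), file.path(d, "f.txt"),
                          file.path(d, "b.txt"))
  expect_identical(unname(back), unname(counts))
  expect_identical(dimnames(back), dimnames(counts))
})
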