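test_that("signature partition follows the prognostic ordering sign rule", {
  ## 3 clusters with distinct survival; a gene rising along the prognostic
  ## ordering joins signature A, its negation signature B
  set.seed(71)
  n <- 90
  cluster <- rep(c("c1", "c2", "c3"), each = 30)
  lp <- c(c1 = 1.5, c2 = 0.7, c3 = 0)[cluster]
  clin <- simulate_survival(setNames(lp, sprintf("s%d", 1:n)),
                            survival_spec(beta_score = 1, censor_rate = 0.01,
                                          seed = 73))
  rank_cov <- unname(c(c1 = 1, c2 = 2, c3 = 3)[cluster])  # c3 = best prognosis
  up <- rank_cov + rnorm(n, sd = 0.1)
  m <- as_expr(rbind(up = up, down = -up,
                     noise = rnorm(n)))
  colnames(m) <- clin$sample_id
  part <- partition_signature(m, c("up", "down"), cluster, clin)
  expect_identical(part$genes_A, "up")
  expect_identical(part$genes_B, "down")
  ## planted good-prognosis program lands in signature A
  co <- small_cohort(effect = 3, n = 90, seed = 31)
  le <- log2_tpm(fpkm_to_tpm(co$expr))
  cl2 <- simulate_survival(setNames(as.character(co$subtype), colnames(le)),
                           survival_spec(beta_subtype = c(cop1 = 1.2,
                                                          cop2 = 0.6,
                                                          cop3 = 0),
                                         censor_rate = 0.01, seed = 37))
  part2 <- partition_signature(le, unlist(co$program_genes), co$subtype, cl2)
  prog3 <- co$program_genes[["cop3"]]
  expect_gte(mean(prog3 %in% part2$genes_A), 0.95)
  expect_error(partition_signature(le, rownames(le)[1:3], rep("x", ncol(le)),
                                   cl2),
               "2 clusters")
})

test_that("COPsig score contracts hold exactly", {
  set.seed(79)
  m <- as_expr(matrix(runif(80, 1, 9), 8, 10))
  part <- list(genes_A = rownames(m)[1:3], genes_B = rownames(m)[4:6])
  res <- compute_copsig(m, part)
  ## swap antisymmetry
  swapped <- compute_copsig(m, list(genes_A = part$genes_B,
                                    genes_B = part$genes_A))
  expect_equal(swapped$scores$score, -res$scores$score, tolerance = 1e-12)
  ## empty B reduces to PC1A
  resA <- compute_copsig(m, list(genes_A = part$genes_A,
                                 genes_B = character(0)))
  expect_equal(resA$scores$score, resA$scores$pc1_A)
  ## scale invariance: rescaling one signature's genes leaves PC1 untouched
  m2 <- m; m2[part$genes_A, ] <- m[part$genes_A, ] * 7.3
  res2 <- compute_copsig(as_expr(m2), part)
  expect_equal(res2$scores$score, res$scores$score, tolerance = 1e-10)
  ## constant signature gene is an error
  m3 <- m; m3[part$genes_A[1], ] <- 2
  expect_error(compute_copsig(as_expr(m3), part), "constant")
})

test_that("two perfectly correlated genes give the closed-form PC1", {
  z <- c(-1, 0, 1)
  m <- as_expr(rbind(gA = 5 + 2 * z, gB = 1 + 0.5 * z,
                     gC = c(3, 1, 2), gD = c(2, 2.5, 1)))
  res <- compute_copsig(m, list(genes_A = c("gA", "gB"),
                                genes_B = character(0)))
  ## both rows z-score to the same profile; PC1 = sqrt(2) * z-profile
  zprof <- (z - mean(z)) / sd(z)
  expect_equal(res$scores$pc1_A, sqrt(2) * zprof, tolerance = 1e-10)
  ## orientation contract: a sample with uniformly higher A-expression and
  ## identical B scores strictly higher (coherent signature, so loadings
  ## share a sign)
  set.seed(97)
  f <- rnorm(10)
  m4 <- rbind(a1 = f + rnorm(10, sd = 0.1), a2 = f + rnorm(10, sd = 0.1),
              b1 = rnorm(10), b2 = rnorm(10))
  m4 <- cbind(m4, base_s = m4[, 1], up_s = m4[, 1] + c(1, 1, 0, 0))
  colnames(m4)[1:10] <- sprintf("s%d", 1:10)
  m4 <- as_expr(m4)
  pt <- list(genes_A = c("a1", "a2"), genes_B = c("b1", "b2"))
  sc <- compute_copsig(m4, pt)$scores
  expect_gt(sc$score[sc$sample_id == "up_s"],
            sc$score[sc$sample_id == "base_s"])
})

test_that("group splitting applies thresholds with ties going low", {
  g <- split_groups(c(1, 2, 3, 4), rule = "median")
  expect_identical(as.character(g), c("low", "low", "high", "high"))
  expect_equal(attr(g, "threshold"), 2.5)
  g2 <- split_groups(c(-1, 1), rule = "fixed", cutoff = 0)
  expect_identical(as.character(g2), c("low", "high"))
  g3 <- split_groups(c(1, 2, 2, 5), rule = "fixed", cutoff = 2)
  expect_identical(as.character(g3), c("low", "low", "low", "high"))
  expect_error(split_groups(rep(3, 5)), "equal")
})

test_that("Boruta separates planted features from shadows and noise", {
  set.seed(83)
  n <- 300
  x_inf <- matrix(rnorm(n * 5), n, 5)
  y <- drop(x_inf %*% c(3, 2.5, 2, 1.5, 1)) + rnorm(n, sd = 0.5)
  x <- cbind(x_inf, matrix(rnorm(n * 20), n, 20))
  colnames(x) <- sprintf("f%02d", 1:25)
  res <- boruta_select(x, y, n_iter = 60, seed = 3)
  expect_true(all(sprintf("f%02d", 1:5) %in% res$confirmed))
  expect_gte(sum(sprintf("f%02d", 6:25) %in% res$rejected), 18)
  ## a feature identical to the target is confirmed
  x2 <- cbind(target_copy = y, junk = rnorm(n), junk2 = rnorm(n))
  res2 <- boruta_select(x2, y, n_iter = 40, seed = 5)
  expect_true("target_copy" %in% res2$confirmed)
  expect_error(boruta_select(x, rep(1, n)), "constant target")
})

test_that("random-forest importance ranks planted effects in order", {
  set.seed(89)
  n <- 250
  x <- matrix(rnorm(n * 6), n, 6,
              dimnames = list(NULL, sprintf("g%d", 1:6)))
  y <- drop(x[, 1:3] %*% c(3, 2, 1)) + rnorm(n, sd = 0.3)
  imp <- rf_gene_importance(x, y, seed = 7)
  expect_identical(imp$gene[1:3], c("g1", "g2", "g3"))
  expect_true(all(diff(imp$importance) <= 0))
})

test_that("high COPsig scores stratify survival end to end", {
  co <- small_cohort(effect = 3, n = 120, seed = 41)
  le <- log2_tpm(fpkm_to_tpm(co$expr))
  ## survival tied to the planted patterns: cop3 best, cop1 worst
  clin <- simulate_survival(setNames(as.character(co$subtype), colnames(le)),
                            survival_spec(baseline_hazard = 0.03,
                                          beta_subtype = c(cop1 = 1.4,
                                                           cop2 = 0.7,
                                                           cop3 = 0),
                                          censor_rate = 0.01, seed = 43))
  part <- partition_signature(le, unlist(co$program_genes), co$subtype, clin)
  res <- compute_copsig(le, part)
  lr <- logrank_test(clin, res$scores$group)
  expect_lt(lr$p, 0.01)
  ## and in the protective direction: the high group's curve crosses 0.5
  ## later than the low group's
  km <- km_fit(clin, res$scores$group)
  med_time <- tapply(seq_len(nrow(km)), km$group, function(i) {
    below <- km$time[i][km$surv[i] <= 0.5]
    if (length(below)) min(below) else Inf
  })
  expect_gt(med_time[["high"]], med_time[["low"]])
})
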