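test_that("Kaplan-Meier curves follow the product-limit closed forms", {
  ## no events: survival stays at 1
  none <- suppressWarnings(km_fit(clin_tab(c(2, 4, 6), c(0, 0, 0))))
  expect_true(all(none$surv == 1))
  ## single subject with an event at t = 5
  one <- km_fit(clin_tab(5, 1))
  expect_equal(one$surv[one$time == 5], 0)
  ## 4 subjects, censoring at t = 3: S(1)=3/4, S(2)=1/2, S(4)=0
  km <- km_fit(clin_tab(c(1, 2, 3, 4), c(1, 1, 0, 1)))
  expect_equal(km$surv, c(3/4, 1/2, 1/2, 0))
  expect_true(all(diff(km$surv) <= 0))
  expect_error(km_fit(clin_tab(c(-1, 2), c(1, 1))), "negative")
})

test_that("log-rank equals the hand-tabled O-E/V statistic", {
  ## A events at 1, 2; B at 3, 4; no censoring.
  ## t=1: n=4, nA=2, E=1/2, V=1/4. t=2: n=3, nA=1, E=1/3, V=2/9.
  ## t=3, 4: nA=0 so E and V contribute 0. chi = (2 - 5/6)^2 / (17/36) = 49/17.
  clin <- clin_tab(c(1, 2, 3, 4), rep(1, 4))
  lr <- logrank_test(clin, c("A", "A", "B", "B"))
  expect_equal(lr$chisq, 49 / 17, tolerance = 1e-10)
  expect_identical(lr$df, 1L)
  ## duplicated groups carry no signal
  clin2 <- clin_tab(rep(c(1, 3, 7), 2), rep(c(1, 0, 1), 2))
  lr2 <- logrank_test(clin2, rep(c("A", "B"), each = 3))
  expect_equal(lr2$chisq, 0, tolerance = 1e-10)
  expect_equal(lr2$p, 1, tolerance = 1e-10)
  expect_error(logrank_test(clin, rep("A", 4)), "2 groups")
})

test_that("log-rank is calibrated under the three-group null", {
  set.seed(31)
  rej <- mean(vapply(1:1000, function(b) {
    tm <- rexp(60); ev <- rbinom(60, 1, 0.8)
    g <- rep(c("a", "b", "c"), each = 20)
    logrank_test(clin_tab(tm, ev), g)$p < 0.05
  }, logical(1)))
  expect_gte(rej, 0.03)
  expect_lte(rej, 0.07)
})

test_that("Cox fits maximise the Breslow partial likelihood", {
  ## 6-subject no-tie toy vs grid-search maximisation of the explicit
  ## partial likelihood
  clin <- clin_tab(c(1, 2.5, 3, 4.5, 6, 8), c(1, 1, 0, 1, 1, 1))
  clin$x <- c(0.2, -1, 0.5, 1.4, -0.3, 0.8)
  fit <- cox_fit(clin, "x")
  oracle <- optimize(function(b) breslow_loglik(b, clin$time, clin$event,
                                                clin$x),
                     interval = c(-5, 5), maximum = TRUE, tol = 1e-9)$maximum
  expect_equal(fit$beta, oracle, tolerance = 1e-4)
  ## recovery on a simulated proportional-hazards cohort
  set.seed(17)
  x <- rnorm(1000)
  cl <- simulate_survival(x, survival_spec(beta_score = 0.5,
                                           censor_rate = 0.01, seed = 23))
  cl$x <- x
  rec <- cox_fit(cl, "x")
  expect_lt(abs(rec$beta - 0.5), 0.1)
  ## constant covariates are skipped with a warning
  cl$const <- 1
  expect_warning(both <- cox_fit(cl, c("x", "const"), univariate = TRUE),
                 "constant covariate")
  expect_identical(both$term, "x")
})

test_that("Cox score structure matches log-rank on two-group no-tie data", {
  set.seed(41)
  tm <- sort(rexp(40)) * (1 + runif(40, 0, 1e-3))   # guarantee no ties
  ev <- rbinom(40, 1, 0.9)
  g <- rep(c(0, 1), 20)
  clin <- clin_tab(tm, ev); clin$g <- g
  lr <- logrank_test(clin, g)
  ## Wald chi-square of the binary Cox coefficient approximates the
  ## log-rank chi-square; they agree closely in moderate samples
  fit <- cox_fit(clin, "g")
  expect_equal((fit$beta / fit$se)^2, lr$chisq, tolerance = 0.2)
})

test_that("moderated differential expression behaves on null and signal genes", {
  co <- simulate_bulk_cohort(bulk_cohort_spec(
    n_genes = 120, n_samples = 60, n_signature_genes_per_subtype = 15,
    subtype_effect = 2, seed = 19))
  le <- log2_tpm(fpkm_to_tpm(co$expr))
  bin <- factor(ifelse(co$subtype == "cop1", "cop1", "rest"),
                levels = c("rest", "cop1"))
  deg <- moderated_deg(le, bin)
  ## identical group means: logFC centred at 0 for non-program genes
  prog1 <- co$program_genes[["cop1"]]
  expect_true(all(abs(deg$logFC[match(prog1, deg$gene)]) >
                    max(abs(deg$logFC[!deg$gene %in% unlist(co$program_genes)]))))
  ## program genes of the contrasted cluster are detected
  expect_true(all(deg$significant[match(prog1, deg$gene)]))
  ## moderated t tracks the ordinary t-test closely on this well-behaved data
  tt <- apply(le, 1, function(e) t.test(e[bin == "cop1"], e[bin == "rest"],
                                        var.equal = TRUE)$statistic)
  expect_gt(cor(deg$stat, tt), 0.99)
  ## strict zero-difference case: both groups see the same columns
  v1 <- c(1, 2, 3, 4); v2 <- c(4, 1, 2, 2)
  m0 <- cbind(v1, v1, v2, v2)
  colnames(m0) <- NULL
  m0 <- as_expr(m0)
  d0 <- moderated_deg(m0, c("a", "b", "a", "b"))
  expect_equal(d0$logFC, rep(0, 4))
  expect_error(moderated_deg(le, c("a", rep("b", ncol(le) - 1))),
               "at least 2 samples")
})

test_that("BH adjustment follows the step-up rule and stays monotone", {
  expect_equal(bh_adjust(0.02), 0.02)
  expect_equal(bh_adjust(rep(0.3, 4)), rep(0.3, 4))
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(51)
  for (i in 1:20) {
    p <- runif(50)
    adj <- bh_adjust(p)
    o <- order(p)
    expect_true(all(diff(adj[o]) >= -1e-12))
    expect_true(all(adj >= p - 1e-12) && all(adj <= 1))
  }
})

test_that("DEG intersection respects universes", {
  co <- simulate_bulk_cohort(bulk_cohort_spec(
    n_genes = 80, n_samples = 60, n_signature_genes_per_subtype = 10,
    subtype_effect = 2.5, seed = 29))
  le <- log2_tpm(fpkm_to_tpm(co$expr))
  degs <- deg_one_vs_rest(le, co$subtype)
  shared <- intersect_degs(degs)
  expect_true(all(shared %in% rownames(le)))
  expect_identical(intersect_degs(list(degs[[1]], degs[[1]])),
                   degs[[1]]$gene[degs[[1]]$significant])
  trimmed <- degs[[2]][-1, ]
  expect_error(intersect_degs(list(degs[[1]], trimmed)), "universe")
})

test_that("optimal cutpoint recovers a planted step hazard", {
  set.seed(61)
  score <- runif(200)
  lp <- ifelse(score > 0.5, 0, 1.2)      # low scores carry excess hazard
  cl <- simulate_survival(lp, survival_spec(beta_score = 1,
                                            censor_rate = 0.01, seed = 67))
  res <- optimal_cutpoint(cl, score, n_perm = 200, seed = 3)
  expect_lt(abs(mean(score <= res$cutoff) - 0.5), 0.05)
  expect_lt(res$p, 0.05)
  ## two distinct values force the cutoff between them
  cl2 <- simulate_survival(rep(c(0, 1), 25),
                           survival_spec(beta_score = 1, censor_rate = 0,
                                         seed = 5))
  res2 <- optimal_cutpoint(cl2, rep(c(0, 1), 25), n_perm = 50, seed = 1)
  expect_gt(res2$cutoff, 0)
  expect_lt(res2$cutoff, 1)
  expect_error(optimal_cutpoint(cl2, rep(1, 50)), "equal")
})
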