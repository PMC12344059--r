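test_that("hurdle components hit their closed-form estimates", {
  # intercept-only design, y = (0, 0, 2, 4): detection rate 1/2 so the
  # (unpenalized) logistic intercept is logit(0.5) = 0; the continuous
  # intercept is the mean of the positive values
  y <- c(0, 0, 2, 4)
  X <- cbind("(Intercept)" = rep(1, 4))
  fit <- fit_hurdle(y, X, fit_continuous = TRUE)
  expect_lt(abs(fit$discrete$coef[1]), 1e-6)
  expect_equal(unname(fit$continuous$coef[1]), 3)

  # constant positive values: residual variance floored, no crash
  fit2 <- fit_hurdle(rep(2.5, 6), cbind(rep(1, 6)))
  expect_true(fit2$continuous$present)
  expect_true(is.finite(fit2$continuous$ll))

  # all-zero gene: continuous part absent
  fit3 <- fit_hurdle(rep(0, 5), cbind(rep(1, 5)))
  expect_false(fit3$continuous$present)
  expect_true(fit3$discrete$degenerate)
})

test_that("the likelihood-ratio test follows the chi-square contract", {
  y <- c(0, 1.2, 0, 2.5, 3.1, 0, 1.8, 2.2)
  grp <- rep(c(0, 1), 4)
  Xf <- cbind("(Intercept)" = 1, grp = grp)
  Xr <- cbind("(Intercept)" = rep(1, 8))
  full <- fit_hurdle(y, Xf)
  reduced <- fit_hurdle(y, Xr, fit_continuous = full$continuous$present)
  out <- lrt(full, reduced)
  expect_gte(out$statistic, 0)
  expect_equal(out$df, 2)
  expect_true(out$p >= 0 && out$p <= 1)

  # full against itself: statistic 0, p 1
  self <- lrt(full, full)
  expect_equal(self$statistic, 0)
  expect_equal(self$p, 1)

  # statistic 3.84 on 1 df sits at the classical 5% point
  expect_equal(stats::pchisq(3.84, 1, lower.tail = FALSE), 0.05, tolerance = 1e-2)

  # non-nested designs error
  X2 <- cbind("(Intercept)" = 1, other = rnorm(8))
  expect_error(lrt(fit_hurdle(y, Xr), fit_hurdle(y, X2)), "nested")

  # numerical-noise negative statistic is clamped with a warning
  fake_full <- full
  fake_full$continuous$ll <- reduced$continuous$ll
  fake_full$discrete$ll <- reduced$discrete$ll - 1e-3
  expect_warning(out2 <- lrt(fake_full, reduced, cont_method = "deviance"),
                 "clamped")
  expect_gte(out2$statistic, 0)
})

test_that("with all cells positive the hurdle reduces to classical Gaussian inference", {
  set.seed(31)
  n <- 60
  y <- rnorm(n, 5, 1) + 0.5  # strictly positive
  stopifnot(all(y > 0))
  grp <- rep(c(0, 1), n / 2)
  Xf <- cbind("(Intercept)" = 1, grp = grp)
  Xr <- cbind("(Intercept)" = rep(1, n))
  full <- fit_hurdle(y, Xf, ridge = 0)
  reduced <- fit_hurdle(y, Xr, ridge = 0)

  # deviance route: statistic equals the plain Gaussian LRT n*log(RSS0/RSS1)
  out <- lrt(full, reduced, cont_method = "deviance")
  rss1 <- sum(stats::lm.fit(Xf, y)$residuals^2)
  rss0 <- sum(stats::lm.fit(Xr, y)$residuals^2)
  expect_equal(out$statistic, n * log(rss0 / rss1), tolerance = 1e-8)
  expect_equal(out$df, 1)

  # exact-F route: p equals the classical nested-linear-model F test
  outF <- lrt(full, reduced)
  f_classical <- anova(lm(y ~ 1), lm(y ~ grp))
  expect_equal(outF$p, f_classical$`Pr(>F)`[2], tolerance = 1e-10)
})

test_that("per-age contrasts recover injected effects and respect the 6-cell rule", {
  ex <- make_experiment(seed = 77, n_genes = 200, cells_per_group = 100,
                        base_logmean_range = c(4, 6))
  pool <- setdiff(ex$reference$gene_ids, unlist(ex$reference$marker_map))
  genes <- pool[1:8]
  ent <- data.frame(gene = genes, cell_type = "type01", age = "old", logFC = 2)
  ex2 <- make_experiment(seed = 77, n_genes = 200, cells_per_group = 100,
                         effects = effect_spec(ent),
                         base_logmean_range = c(4, 6))
  de <- de_per_cluster(ex2$norm, ex2$labels)
  old <- de$results[de$results$age == "old", ]
  young <- de$results[de$results$age == "young", ]
  est_old <- old$logFC[match(genes, old$gene)]
  est_young <- young$logFC[match(genes, young$gene)]
  expect_lt(abs(mean(est_old) - 2), 0.3)
  expect_lt(abs(mean(est_young)), 0.3)
  expect_true(all(old$FDR[match(genes, old$gene)] < 0.05))

  # swapping condition labels negates the estimate
  swapped <- ex2$norm
  swapped$cell_data$condition <- ifelse(swapped$cell_data$condition == "associated",
                                        "axenic", "associated")
  de_sw <- de_per_cluster(swapped, ex2$labels)
  old_sw <- de_sw$results[de_sw$results$age == "old", ]
  expect_equal(old_sw$logFC[match(genes, old_sw$gene)], -est_old,
               tolerance = 1e-8)

  # a cluster with 5 cells in one group is excluded
  cpg <- expand.grid(cell_type = "type01", age = c("young", "old"),
                     condition = c("associated", "axenic"),
                     stringsAsFactors = FALSE)
  cpg$n <- c(5L, 20L, 20L, 20L)
  d <- experiment_design(n_cell_types = 1, n_genes = 50, cells_per_group = cpg,
                         n_marker_genes_per_type = 2, seed = 3)
  sim <- simulate_counts(d, effect_spec(), generate_reference(d))
  nm <- normalize_log(qc_filter(sim$counts, min_features = 2, max_features = 50)$counts)
  de3 <- de_per_cluster(nm, nm$cell_data$true_type, min_cells_per_group = 6)
  expect_equal(nrow(de3$results), 0)
  expect_match(de3$excluded$reason, "fewer than 6")
})

test_that("benjamini_hochberg matches the hand step-up rule", {
  p <- c(0.01, 0.02, 0.03, 0.04)
  expect_equal(benjamini_hochberg(p), rep(0.04, 4))
  expect_equal(benjamini_hochberg(0.37), 0.37)
  expect_equal(benjamini_hochberg(rep(1, 5)), rep(1, 5))
  expect_error(benjamini_hochberg(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(2)
  for (i in 1:20) {
    p <- runif(sample(1:30, 1))
    expect_equal(benjamini_hochberg(p), bh_stepup(p))
    expect_true(all(benjamini_hochberg(p) >= p))
  }
})
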