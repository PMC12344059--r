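test_that("reference construction allocates disjoint markers deterministically", {
  d <- experiment_design(n_cell_types = 3, n_genes = 200,
                         n_marker_genes_per_type = 10, cells_per_group = 5,
                         seed = 42)
  ref <- generate_reference(d)
  expect_length(ref$marker_map, 3)
  expect_true(all(lengths(ref$marker_map) == 10))
  all_markers <- unlist(ref$marker_map)
  expect_equal(anyDuplicated(all_markers), 0L)
  expect_true(all(ref$reference$weight > 0))
  # same seed twice: identical output
  ref2 <- generate_reference(d)
  expect_identical(ref, ref2)
})

test_that("infeasible marker allocation raises a sizing error", {
  d <- experiment_design(n_cell_types = 3, n_genes = 25,
                         n_marker_genes_per_type = 10, cells_per_group = 5,
                         mito_gene_fraction = 0, seed = 1)
  expect_error(generate_reference(d), "infeasible marker allocation")
})

test_that("simulated counts are deterministic and match negative-binomial moments", {
  d <- experiment_design(n_cell_types = 1, n_genes = 50, cells_per_group = 25,
                         n_marker_genes_per_type = 5, seed = 11)
  ref <- generate_reference(d)
  s1 <- simulate_counts(d, effect_spec(), ref)
  s2 <- simulate_counts(d, effect_spec(), ref)
  expect_identical(as.matrix(s1$counts$counts), as.matrix(s2$counts$counts))
  expect_identical(s1$truth$cells, s2$truth$cells)

  # moment fidelity: fix a flat profile with mean 5, dispersion 2, no
  # library-size noise; the sample mean over 10,000 draws must fall within
  # three standard errors of 5
  d2 <- experiment_design(n_cell_types = 1, n_genes = 10, cells_per_group = 2500,
                          n_marker_genes_per_type = 1, mito_gene_fraction = 0,
                          seed = 12)
  ref2 <- generate_reference(d2, marker_boost = 0)
  ref2$profiles[] <- log2(5)
  sim <- simulate_counts(d2, effect_spec(dispersion = 2), ref2,
                         library_size_sdlog = 0)
  x <- as.numeric(as.matrix(sim$counts$counts)[1, ])
  se <- sqrt((5 + 5^2 / 2) / length(x))
  expect_lt(abs(mean(x) - 5), 3 * se)
  # variance should reflect overdispersion: var = mu + mu^2/size = 17.5
  expect_gt(stats::var(x), 10)
})

test_that("injected effects scale the associated-condition mean", {
  d <- experiment_design(n_cell_types = 1, n_genes = 40, cells_per_group = 2000,
                         n_marker_genes_per_type = 2, mito_gene_fraction = 0,
                         seed = 5)
  ref <- generate_reference(d, marker_boost = 0)
  ref$profiles[] <- log2(8)
  g <- ref$gene_ids[10]
  ent <- data.frame(gene = g, cell_type = "type01", age = "old", logFC = 2)
  sim <- simulate_counts(d, effect_spec(ent), ref, library_size_sdlog = 0)
  cd <- sim$counts$cell_data
  m <- as.matrix(sim$counts$counts)
  grp_mean <- function(age, cond) mean(m[g, cd$age == age & cd$condition == cond])
  expect_lt(abs(grp_mean("old", "associated") / grp_mean("old", "axenic") - 4), 0.6)
  expect_lt(abs(grp_mean("young", "associated") / grp_mean("young", "axenic") - 1), 0.2)
})

test_that("logistic dropout increases the zero fraction", {
  d <- experiment_design(n_cell_types = 1, n_genes = 50, cells_per_group = 500,
                         n_marker_genes_per_type = 2, seed = 9)
  ref <- generate_reference(d)
  s_plain <- simulate_counts(d, effect_spec(), ref)
  s_drop <- simulate_counts(d, effect_spec(dropout_intercept = 2,
                                           dropout_slope = 0.5), ref)
  z0 <- mean(as.matrix(s_plain$counts$counts) == 0)
  z1 <- mean(as.matrix(s_drop$counts$counts) == 0)
  expect_gt(z1, z0)
})

test_that("community simulation is multinomial with validated proportions", {
  expect_error(simulate_community(list(a = c(0.5, 0.4)), depth = 100),
               "sum to")
  one <- simulate_community(list(g = c(1, 0, 0)), depth = 500, n_samples = 2,
                            seed = 3)
  expect_true(all(one$counts[, 1] == 500))
  expect_true(all(one$counts[, 2:3] == 0))
  # uniform over 4 taxa at large depth: per-taxon share near 0.25
  u <- simulate_community(list(g = rep(0.25, 4)), depth = 100000,
                          n_samples = 1, seed = 4)
  expect_true(all(abs(u$counts / 100000 - 0.25) < 0.01))
  # determinism
  a <- simulate_community(list(g = c(0.7, 0.3)), depth = 1000, n_samples = 3, seed = 8)
  b <- simulate_community(list(g = c(0.7, 0.3)), depth = 1000, n_samples = 3, seed = 8)
  expect_identical(a, b)
})
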