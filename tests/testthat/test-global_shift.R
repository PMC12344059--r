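tiny_norm <- function(V, condition, age = "old") {
  cd <- data.frame(barcode = colnames(V), age = age, condition = condition)
  normalize_log(count_matrix(V, cd))
}

test_that("representative cell and Manhattan distance follow their definitions", {
  expect_equal(representative_cell(rbind(c(0, 2), c(2, 4))), c(1, 3))
  expect_equal(representative_cell(c(5, 1)), c(5, 1))
  r <- rbind(c(1, 2, 3), c(1, 2, 3))
  expect_equal(representative_cell(r), c(1, 2, 3))
  expect_equal(manhattan(c(0, 0, 0), c(1, 2, 3)), 6)
  expect_equal(manhattan(c(4, 4), c(4, 4)), 0)
  expect_equal(manhattan(1, -1), 2)
  expect_error(manhattan(1:2, 1:3), "length mismatch")
})

test_that("identical constant groups are degenerate with p = 1", {
  V <- matrix(3L, nrow = 4, ncol = 6,
              dimnames = list(paste0("g", 1:4), paste0("c", 1:6)))
  nm <- tiny_norm(V, rep(c("associated", "axenic"), each = 3))
  st <- shift_test(nm, rep("k", 6), age_group = "old", n_perm = 200, seed = 1)
  expect_equal(st$results$d_obs, 0)
  expect_true(st$results$degenerate)
  expect_equal(st$results$p_emp, 1)
})

test_that("tiny-instance empirical p matches exhaustive label enumeration", {
  V <- matrix(c(0L, 1L, 2L, 5L, 1L, 0L, 3L, 1L), nrow = 2,
              dimnames = list(c("g1", "g2"), paste0("c", 1:4)))
  cond <- c("associated", "associated", "axenic", "axenic")
  nm <- tiny_norm(V, cond)
  Vn <- as.matrix(nm$values)
  cmb <- utils::combn(4, 2)
  d_all <- apply(cmb, 2, function(i)
    sum(abs(rowMeans(Vn[, i, drop = FALSE]) - rowMeans(Vn[, -i, drop = FALSE]))))
  p_exact <- mean(d_all >= d_all[1] - 1e-12)
  st <- shift_test(nm, rep("k", 4), age_group = "old", n_perm = 4000, seed = 5)
  expect_lt(abs(st$results$p_emp - p_exact), 0.05)
})

test_that("shift results are deterministic, label-swap invariant, and p is never 0", {
  ex <- make_experiment(seed = 55, n_genes = 80, cells_per_group = 15)
  a <- shift_test(ex$norm, ex$labels, age_group = "old", n_perm = 300, seed = 2)
  b <- shift_test(ex$norm, ex$labels, age_group = "old", n_perm = 300, seed = 2)
  expect_identical(a, b)
  expect_true(all(a$results$p_emp >= 1 / 301))

  swapped <- ex$norm
  swapped$cell_data$condition <- ifelse(swapped$cell_data$condition == "associated",
                                        "axenic", "associated")
  s <- shift_test(swapped, ex$labels, age_group = "old", n_perm = 300, seed = 2)
  expect_equal(s$results$d_obs, a$results$d_obs)
  expect_equal(s$results$p_emp, a$results$p_emp)
  expect_equal(s$results$shift, a$results$shift)
})

test_that("clusters missing a condition are skipped with a report entry", {
  V <- matrix(rpois(40, 3), nrow = 4,
              dimnames = list(paste0("g", 1:4), paste0("c", 1:10)))
  V[V == 0] <- 1L
  cond <- c(rep("associated", 5), rep("axenic", 5))
  labels <- c(rep("both", 8), "onlyax", "onlyax")
  nm <- tiny_norm(V, cond)
  st <- shift_test(nm, labels, age_group = "old", n_perm = 100, seed = 3)
  expect_true("onlyax" %in% st$skipped$cluster)
  expect_false("onlyax" %in% st$results$cluster)
  expect_true("both" %in% st$results$cluster)
})

test_that("a planted expression shift is detected", {
  d <- experiment_design(n_cell_types = 1, n_genes = 150, cells_per_group = 80,
                         n_marker_genes_per_type = 5, seed = 88)
  ref <- generate_reference(d)
  genes <- setdiff(ref$gene_ids, unlist(ref$marker_map))[1:15]
  ent <- data.frame(gene = genes, cell_type = "type01", age = "old", logFC = 1)
  sim <- simulate_counts(d, effect_spec(ent), ref)
  nm <- normalize_log(qc_filter(sim$counts, min_features = 2, max_features = 150)$counts)
  st <- shift_test(nm, rep("k", ncol(nm$values)), age_group = "old",
                   n_perm = 500, seed = 6)
  expect_lt(st$results$p_adj, 0.05)
  expect_gt(st$results$shift, 0)
})
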