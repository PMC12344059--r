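test_that("well-separated synthetic types are recovered by clustering", {
  ex <- make_experiment(seed = 21, n_genes = 300, cells_per_group = 25,
                        n_cell_types = 2, marker_boost = 3)
  labels <- cluster_cells(ex$norm, n_pcs = 10, resolution = 0.5, seed = 1)
  expect_equal(length(labels), ncol(ex$norm$values))
  truth <- ex$norm$cell_data$true_type
  # adjusted Rand index against truth
  tab <- table(labels, truth)
  n <- sum(tab)
  a <- sum(choose(tab, 2)); b <- sum(choose(rowSums(tab), 2))
  c2 <- sum(choose(colSums(tab), 2)); e <- b * c2 / choose(n, 2)
  ari <- (a - e) / ((b + c2) / 2 - e)
  expect_gte(ari, 0.95)
  # determinism
  expect_identical(labels, cluster_cells(ex$norm, n_pcs = 10, resolution = 0.5,
                                         seed = 1))
  # one cell errors; n_pcs beyond rank errors
  one <- ex$norm; one$values <- one$values[, 1, drop = FALSE]
  one$cell_data <- one$cell_data[1, ]
  expect_error(cluster_cells(one, n_pcs = 2, resolution = 1, seed = 1),
               "at least 2")
  expect_error(cluster_cells(ex$norm, n_pcs = 10000, resolution = 1, seed = 1),
               "exceeds")
})

test_that("cluster count does not decrease along a resolution ladder", {
  ex <- make_experiment(seed = 22, n_genes = 200, cells_per_group = 15,
                        n_cell_types = 3)
  ks <- vapply(c(0.5, 1, 2, 4),
               function(r) nlevels(cluster_cells(ex$norm, n_pcs = 10,
                                                 resolution = r, seed = 2)),
               integer(1))
  expect_true(all(diff(ks) >= 0))
})

test_that("find_markers flags exclusive genes and agrees with wilcox.test", {
  ex <- make_experiment(seed = 23, n_genes = 200, cells_per_group = 20,
                        n_cell_types = 2, marker_boost = 4)
  truth <- ex$norm$cell_data$true_type
  mk <- find_markers(ex$norm, truth)
  expect_true(all(mk$avg_log2FC > 0))
  # designed markers of each type show up with q < 0.05
  for (t in names(ex$reference$marker_map)) {
    found <- mk$gene[mk$cluster == t & mk$q < 0.05]
    expect_gt(length(intersect(ex$reference$marker_map[[t]], found)), 5)
  }
  # p-values match stats::wilcox.test on a spot-check of genes
  V <- as.matrix(ex$norm$values)
  idx <- which(truth == "type01")
  for (g in sample(mk$gene[mk$cluster == "type01"], 5)) {
    ref_p <- suppressWarnings(stats::wilcox.test(V[g, idx], V[g, -idx],
                                                 exact = FALSE,
                                                 correct = TRUE))$p.value
    expect_equal(mk$p[mk$cluster == "type01" & mk$gene == g], ref_p,
                 tolerance = 1e-8)
  }
  # an all-zero gene is never a marker
  zed <- ex$norm
  zed$values[5, ] <- 0
  mk0 <- find_markers(zed, truth)
  expect_false(rownames(zed$values)[5] %in% mk0$gene)
  # tiny clusters are skipped with a warning
  lab2 <- truth; lab2[1:2] <- "tiny"
  expect_warning(find_markers(ex$norm, lab2), "fewer than")
})

test_that("markers are essentially absent when clusters split one distribution", {
  hits <- integer(3)
  for (s in 1:3) {
    ex <- make_experiment(seed = 300 + s, n_genes = 150, cells_per_group = 25)
    n <- ncol(ex$norm$values)
    set.seed(s)
    lab <- sample(rep(c("a", "b"), length.out = n))
    mk <- find_markers(ex$norm, lab)
    hits[s] <- if (nrow(mk)) sum(mk$q < 0.05) else 0L
  }
  expect_lte(sum(hits > 0), 1)
})

test_that("the correlation-gap rule matches identity cases and forced arithmetic", {
  # gap logic on sorted correlation vectors
  dec <- scshift:::.gap_decision(c(0.9, 0.6, 0.5, 0.4, 0.3, 0.2), 0.15)
  expect_true(dec$matched)
  expect_equal(dec$gap_position, 1L)
  expect_equal(dec$gap_size, 0.3)
  dec2 <- scshift:::.gap_decision(c(0.90, 0.85, 0.80, 0.75, 0.70, 0.65), 0.15)
  expect_false(dec2$matched)

  # identity case: a cluster whose markers equal the reference vector
  w <- seq(1, 3, length.out = 8)
  ref <- data.frame(cell_type = "A", gene = paste0("g", 1:8), weight = w)
  mk <- rbind(data.frame(cluster = "c1", gene = paste0("g", 1:8),
                         avg_log2FC = w, pct_in = 1, pct_out = 0, p = 1e-5, q = 1e-4),
              data.frame(cluster = "c2", gene = paste0("h", 1:8),
                         avg_log2FC = 1, pct_in = 1, pct_out = 0, p = 1e-5, q = 1e-4))
  m <- correlation_gap_match(mk, ref)
  expect_true(m$matched)
  expect_equal(m$matched_clusters, "c1")
  expect_equal(m$top[[1]]$r[1], 1)
  expect_true(!is.unsorted(rev(m$top[[1]]$r)))

  # a type overlapping no cluster reports insufficient overlap
  ref2 <- rbind(ref, data.frame(cell_type = "B", gene = paste0("z", 1:8),
                                weight = 2))
  m2 <- correlation_gap_match(mk, ref2)
  expect_false(m2$matched[m2$cell_type == "B"])
  expect_match(m2$note[m2$cell_type == "B"], "insufficient overlap")
})

test_that("grid search enumerates the grid and applies the stated tie-breaks", {
  ex <- make_experiment(seed = 25, n_genes = 200, cells_per_group = 15,
                        n_cell_types = 2, marker_boost = 3)
  gs <- grid_search(ex$norm, ex$reference$reference, pcs_grid = c(5, 10),
                    resolution_grid = c(0.5, 1), seed = 1)
  expect_equal(nrow(gs$records), 4)
  expect_true(all(gs$records$n_clear_matches <= 2))

  rec <- data.frame(n_pcs = c(30, 20, 20), resolution = c(1, 2, 1),
                    n_clusters = 3, n_clear_matches = c(3, 3, 3), failed = FALSE)
  sel <- scshift:::.select_grid_point(rec)
  expect_equal(sel$n_pcs, 20)
  expect_equal(sel$resolution, 1)
})

test_that("the cluster dendrogram is valid Newick with Ward merge order", {
  emb <- rbind(c(0, 0), c(0.1, 0), c(1, 0), c(1.1, 0), c(10, 0), c(10.1, 0))
  labels <- c("A", "A", "B", "B", "C", "C")
  txt <- cluster_dendrogram(emb, labels)
  tree <- ape::read.tree(text = txt)
  expect_setequal(tree$tip.label, c("A", "B", "C"))
  # collinear centroids at 0.05, 1.05, 10.05: A and B merge first
  pair <- ape::extract.clade(tree, ape::getMRCA(tree, c("A", "B")))
  expect_setequal(pair$tip.label, c("A", "B"))

  # two clusters: single join
  t2 <- ape::read.tree(text = cluster_dendrogram(emb[1:4, ], labels[1:4]))
  expect_equal(ape::Ntip(t2), 2)

  # duplicated centroids merge at height 0 without error
  t0 <- cluster_dendrogram(rbind(c(0, 0), c(0, 0), c(5, 5)),
                           c("A", "B", "C"))
  expect_s3_class(ape::read.tree(text = t0), "phylo")

  expect_error(cluster_dendrogram(emb, rep("A", 6)), "at least 2")
})
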