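# Clustering, marker detection, correlation-gap annotation, grid search,
# cluster dendrogram.

#' Cluster cells by PCA, kNN graph and Leiden community detection
#'
#' Principal components of the centered log-normalized matrix feed a k-nearest
#' neighbour graph (Euclidean metric, union of neighbourhoods) which is
#' partitioned by resolution-parameterized modularity (Leiden). The community
#' detection backend is a pluggable contract; any pre-corrected embedding can
#' be clustered by passing it through `embedding`.
#'
#' @param norm A `normalized_matrix` (ignored if `embedding` is given).
#' @param n_pcs Number of principal components.
#' @param resolution Modularity resolution parameter.
#' @param seed Integer seed (community detection is stochastic).
#' @param k Neighbours per cell for the kNN graph.
#' @param embedding Optional pre-computed cells x dims matrix (e.g. a
#'   batch-corrected embedding); bypasses PCA.
#' @return Factor of cluster labels, one per cell.
#' @export
cluster_cells <- function(norm, n_pcs = 30L, resolution = 1,
                          seed = 1L, k = 20L, embedding = NULL) {
  if (is.null(embedding)) {
    .assert(inherits(norm, "normalized_matrix"), "norm must be a normalized_matrix")
    X <- t(as.matrix(norm$values))
    .assert(nrow(X) >= 2, "clustering needs at least 2 cells")
    if (n_pcs > min(dim(X)))
      stop(sprintf("n_pcs = %d exceeds min(cells, genes) = %d",
                   n_pcs, min(dim(X))), call. = FALSE)
    pcs <- stats::prcomp(X, center = TRUE, scale. = FALSE, rank. = n_pcs)$x
  } else {
    pcs <- as.matrix(embedding)
    .assert(nrow(pcs) >= 2, "clustering needs at least 2 cells")
  }
  n <- nrow(pcs)
  k <- min(k, n - 1L)
  d <- as.matrix(stats::dist(pcs))
  diag(d) <- Inf
  nn <- apply(d, 1, function(r) order(r)[seq_len(k)])
  edges <- cbind(rep(seq_len(n), each = k), as.vector(nn))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::simplify(g)
  set.seed(.stage_seed(seed, 7L))
  comm <- igraph::cluster_leiden(g, objective_function = "modularity",
                                 resolution = resolution, n_iterations = 10L)
  factor(igraph::membership(comm))
}

# Vectorized two-sided Wilcoxon rank-sum (normal approximation with tie and
# continuity corrections, matching stats::wilcox.test(correct = TRUE)).
# V: genes x cells matrix; in_idx: columns of the first sample.
.wilcox_vec <- function(V, in_idx) {
  n <- ncol(V); n1 <- length(in_idx); n2 <- n - n1
  apply(V, 1, function(v) {
    r <- rank(v)
    U <- sum(r[in_idx]) - n1 * (n1 + 1) / 2
    mu <- n1 * n2 / 2
    ties <- table(v)
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sigma2 <= 0) return(1)
    z <- U - mu
    z <- (z - sign(z) * 0.5) / sqrt(sigma2)
    min(1, 2 * stats::pnorm(-abs(z)))
  })
}

#' One-vs-rest positive marker detection
#'
#' Per cluster, genes passing expression-fraction and log-fold-change
#' prefilters are tested against all other cells by a two-sided Wilcoxon
#' rank-sum test; q-values are Benjamini-Hochberg within each cluster's
#' tested genes. Only positive markers (higher in the cluster) are retained.
#'
#' @param norm A `normalized_matrix`.
#' @param labels Cluster label per cell.
#' @param min_fraction Minimum fraction of cluster cells expressing the gene.
#' @param min_logfc Minimum average log2 fold change (cluster vs rest, in
#'   log-normalized space).
#' @param min_cluster_cells Clusters smaller than this are skipped with a
#'   warning.
#' @return data.frame: cluster, gene, avg_log2FC, pct_in, pct_out, p, q.
#' @export
find_markers <- function(norm, labels, min_fraction = 0.10, min_logfc = 0.25,
                         min_cluster_cells = 3L) {
  .assert(inherits(norm, "normalized_matrix"), "norm must be a normalized_matrix")
  labels <- as.character(labels)
  .assert(length(labels) == ncol(norm$values), "one label per cell required")
  .assert(length(unique(labels)) >= 2, "need at least 2 clusters")
  V <- as.matrix(norm$values)
  out <- list()
  for (cl in sort(unique(labels))) {
    idx <- which(labels == cl)
    if (length(idx) < min_cluster_cells) {
      warning(sprintf("cluster %s has fewer than %d cells; markers skipped",
                      cl, min_cluster_cells), call. = FALSE)
      next
    }
    Vin <- V[, idx, drop = FALSE]; Vout <- V[, -idx, drop = FALSE]
    pct_in <- rowMeans(Vin > 0); pct_out <- rowMeans(Vout > 0)
    lfc <- rowMeans(Vin) - rowMeans(Vout)
    tested <- which(pct_in >= min_fraction & lfc >= min_logfc & lfc > 0)
    if (!length(tested)) next
    p <- .wilcox_vec(V[tested, , drop = FALSE], idx)
    out[[cl]] <- data.frame(cluster = cl, gene = rownames(V)[tested],
                            avg_log2FC = lfc[tested],
                            pct_in = pct_in[tested], pct_out = pct_out[tested],
                            p = p, q = benjamini_hochberg(p),
                            row.names = NULL)
  }
  .rbind_all(out, prototype = data.frame(
    cluster = character(), gene = character(), avg_log2FC = numeric(),
    pct_in = numeric(), pct_out = numeric(), p = numeric(), q = numeric()))
}

# Gap decision on a sorted (descending) correlation vector.
.gap_decision <- function(r_sorted, gap_threshold) {
  if (length(r_sorted) < 2)
    return(list(matched = FALSE, gap_position = NA_integer_,
                gap_size = NA_real_, n_above = 0L))
  gaps <- -diff(r_sorted)
  hit <- which(gaps > gap_threshold)
  if (!length(hit))
    return(list(matched = FALSE, gap_position = NA_integer_,
                gap_size = max(gaps), n_above = 0L))
  list(matched = TRUE, gap_position = hit[1], gap_size = gaps[hit[1]],
       n_above = hit[1])
}

#' Match reference cell types to clusters by the Pearson-correlation-gap rule
#'
#' For each reference type, a weight vector over the union of its reference
#' markers and each cluster's markers (absent genes contribute 0) is
#' correlated with the cluster's average log2 fold changes. Clusters are
#' ranked by decreasing correlation; if some consecutive difference among the
#' top `top_k` exceeds `gap_threshold`, the type has a clear match — the
#' cluster(s) above the first such gap.
#'
#' @param markers Marker table from [find_markers()].
#' @param reference data.frame: cell_type, gene, weight.
#' @param gap_threshold Minimum correlation gap for a clear match.
#' @param top_k Number of best-correlated clusters examined.
#' @param min_overlap Minimum shared genes for a correlation to count.
#' @param binary Use 0/1 membership vectors instead of weights.
#' @return data.frame per reference type: cell_type, matched, matched_clusters
#'   (comma-separated), gap_position, gap_size, plus a `top` list-column of
#'   (cluster, r) data.frames sorted by decreasing r.
#' @export
correlation_gap_match <- function(markers, reference, gap_threshold = 0.15,
                                  top_k = 6L, min_overlap = 5L,
                                  binary = FALSE) {
  .assert(nrow(markers) > 0 && nrow(reference) > 0,
          "markers and reference must be non-empty")
  .assert(all(c("cell_type", "gene", "weight") %in% names(reference)),
          "reference needs cell_type, gene, weight")
  clusters <- sort(unique(markers$cluster))
  out <- list()
  for (ct in sort(unique(reference$cell_type))) {
    ref <- reference[reference$cell_type == ct, ]
    rs <- vapply(clusters, function(cl) {
      mk <- markers[markers$cluster == cl, ]
      shared <- length(intersect(ref$gene, mk$gene))
      if (shared < min_overlap) return(NA_real_)
      genes <- union(ref$gene, mk$gene)
      x <- ref$weight[match(genes, ref$gene)]; x[is.na(x)] <- 0
      y <- mk$avg_log2FC[match(genes, mk$gene)]; y[is.na(y)] <- 0
      if (binary) { x <- as.numeric(x != 0); y <- as.numeric(y != 0) }
      if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
      stats::cor(x, y)
    }, numeric(1))
    ok <- !is.na(rs)
    if (!any(ok)) {
      out[[ct]] <- data.frame(cell_type = ct, matched = FALSE,
                              matched_clusters = "",
                              gap_position = NA_integer_, gap_size = NA_real_,
                              note = "no match, insufficient overlap")
      out[[ct]]$top <- list(data.frame(cluster = character(), r = numeric()))
      next
    }
    ord <- order(rs[ok], decreasing = TRUE)
    top <- data.frame(cluster = as.character(clusters[ok][ord]),
                      r = rs[ok][ord])[seq_len(min(top_k, sum(ok))), ]
    # candidates excluded for insufficient overlap (or absent entirely when
    # few clusters exist) contribute a zero correlation to the examined
    # window, so a single strong candidate still yields a measurable gap
    padded <- top
    while (nrow(padded) < top_k) {
      padded <- rbind(padded, data.frame(cluster = NA_character_, r = 0))
    }
    padded <- padded[order(padded$r, decreasing = TRUE), ]
    dec <- .gap_decision(padded$r, gap_threshold)
    above <- if (dec$matched) {
      stats::na.omit(padded$cluster[seq_len(dec$n_above)])
    } else character()
    if (dec$matched && !length(above)) dec$matched <- FALSE
    out[[ct]] <- data.frame(cell_type = ct, matched = dec$matched,
                            matched_clusters = paste(above, collapse = ","),
                            gap_position = dec$gap_position,
                            gap_size = dec$gap_size, note = "")
    out[[ct]]$top <- list(top)
  }
  .rbind_all(out)
}

# Tie-break: most clear matches, then fewer PCs, then lower resolution.
.select_grid_point <- function(records) {
  ord <- order(-records$n_clear_matches, records$n_pcs, records$resolution)
  records[ord[1], c("n_pcs", "resolution")]
}

#' Grid search over clustering parameters scored by clear matches
#'
#' Each (n_pcs, resolution) point is clustered, marker-profiled and matched
#' against the reference; the point maximizing the number of clearly matched
#' reference types wins (ties broken toward fewer PCs, then lower
#' resolution). A failing grid point is recorded with 0 clear matches rather
#' than aborting the search.
#'
#' @param norm A `normalized_matrix`.
#' @param reference Reference marker table.
#' @param pcs_grid,resolution_grid Numeric grids (non-empty).
#' @param seed Integer seed shared by all grid points.
#' @param ... Passed to [correlation_gap_match()].
#' @return List with `records` (one row per grid point) and `selected`.
#' @export
grid_search <- function(norm, reference, pcs_grid = seq(15, 50, 5),
                        resolution_grid = 1:9, seed = 1L, ...) {
  .assert(length(pcs_grid) > 0 && length(resolution_grid) > 0,
          "grids must be non-empty")
  grid <- expand.grid(n_pcs = pcs_grid, resolution = resolution_grid)
  records <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    rec <- data.frame(n_pcs = grid$n_pcs[i], resolution = grid$resolution[i],
                      n_clusters = 0L, n_clear_matches = 0L, failed = FALSE)
    tryCatch({
      labels <- cluster_cells(norm, n_pcs = grid$n_pcs[i],
                              resolution = grid$resolution[i], seed = seed)
      rec$n_clusters <- nlevels(labels)
      mk <- suppressWarnings(find_markers(norm, labels))
      if (nrow(mk)) {
        matches <- correlation_gap_match(mk, reference, ...)
        rec$n_clear_matches <- sum(matches$matched)
      }
      rec
    }, error = function(e) { rec$failed <- TRUE; rec })
  }))
  list(records = records, selected = .select_grid_point(records))
}

#' Cluster dendrogram from embedding centroids
#'
#' Cluster centroids in a 2-D embedding (e.g. UMAP coordinates supplied by
#' the caller) are joined by Ward's method on their pairwise Euclidean
#' distances; the tree is returned as Newick text.
#'
#' @param embedding cells x 2 numeric matrix.
#' @param labels Cluster label per cell.
#' @param file Optional path to also write the Newick string to.
#' @return Newick string (invisibly also written to `file` if given).
#' @export
cluster_dendrogram <- function(embedding, labels, file = NULL) {
  embedding <- as.matrix(embedding)
  labels <- as.character(labels)
  .assert(nrow(embedding) == length(labels), "one label per embedded cell")
  cl <- sort(unique(labels))
  if (length(cl) < 2) stop("need at least 2 clusters", call. = FALSE)
  cent <- t(vapply(cl, function(c)
    colMeans(embedding[labels == c, , drop = FALSE]),
    numeric(ncol(embedding))))
  hc <- stats::hclust(stats::dist(cent), method = "ward.D2")
  hc$labels <- cl
  tree <- ape::as.phylo(hc)
  txt <- ape::write.tree(tree)
  if (!is.null(file)) writeLines(txt, file)
  invisible(txt)
  txt
}
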