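#!/usr/bin/env Rscript
# Stage 3: clustering-parameter grid search, marker detection and
# correlation-gap annotation against the marker reference, plus the cluster
# dendrogram on a PCA-derived 2-D embedding.

suppressPackageStartupMessages(library(scshift))

SEED <- 1L
norm <- normalize_log(qc_filter(read_counts_10x("results/analysis/filtered"),
                                min_features = 200, max_features = 2500)$counts)
reference <- read.table("results/analysis/synthetic/reference.tsv",
                        header = TRUE, sep = "\t")

gs <- grid_search(norm, reference, pcs_grid = c(15, 30, 45),
                  resolution_grid = c(1, 2, 4), seed = SEED)
write.table(gs$records, "results/analysis/grid_search.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("grid search over %d points; selected %d PCs at resolution %g\n",
            nrow(gs$records), gs$selected$n_pcs, gs$selected$resolution))

labels <- cluster_cells(norm, n_pcs = gs$selected$n_pcs,
                        resolution = gs$selected$resolution, seed = SEED)
markers <- suppressWarnings(find_markers(norm, labels))
matches <- correlation_gap_match(markers, reference)
write.table(data.frame(barcode = norm$cell_data$barcode,
                       cluster = as.character(labels)),
            "results/analysis/clusters.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(markers, "results/analysis/markers.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(matches[, setdiff(names(matches), "top")],
            "results/analysis/annotation.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf("%d clusters, %d marker rows, %d of %d reference types clearly matched\n",
            nlevels(labels), nrow(markers), sum(matches$matched),
            nrow(matches)))

# dendrogram on the first two principal components as the 2-D embedding
emb <- stats::prcomp(t(as.matrix(norm$values)), rank. = 2)$x
newick <- cluster_dendrogram(emb, labels,
                             file = "results/analysis/dendrogram.nwk")
cat("cluster dendrogram:", newick, "\n")
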