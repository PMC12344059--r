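#!/usr/bin/env Rscript
# Stage 8: community alpha diversity between age groups.
#
# Observed genus richness and the Shannon index (natural log) per sample,
# compared between young and old with Wilcoxon rank-sum tests (W reported as
# the first group's rank sum).

suppressPackageStartupMessages(library(scshift))

df <- read.table("results/analysis/synthetic/taxa_counts.tsv", header = TRUE,
                 sep = "\t", check.names = FALSE)
m <- as.matrix(df[, setdiff(names(df), c("sample", "group"))])
rownames(m) <- df$sample
taxa <- list(counts = m, group = df$group)

cd <- compare_diversity(taxa)
write.table(cd$diversity, "results/analysis/diversity.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
jsonlite::write_json(list(observed = cd$observed, shannon = cd$shannon,
                          means = cd$means),
                     "results/analysis/diversity_tests.json",
                     auto_unbox = TRUE, digits = NA)

print(cd$means)
cat(sprintf("observed richness: W = %.1f, p = %.3g\n",
            cd$observed$W, cd$observed$p))
cat(sprintf("Shannon index:     W = %.1f, p = %.3g\n",
            cd$shannon$W, cd$shannon$p))
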