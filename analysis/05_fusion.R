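#!/usr/bin/env Rscript
# Stage 5: information fusion of fold change and FDR.
#
# Pi_g sums |pi_g| over a gene's significant cell types (FDR < 0.05 only);
# Pi_c sums |pi_g| over a cell type's DEGs passing both FDR < 0.05 and
# |logFC| > 0.5. Old-group magnitudes are regressed on young-group
# magnitudes where enough pairs exist.

suppressPackageStartupMessages(library(scshift))

de <- read.table("results/analysis/de_results.tsv", header = TRUE, sep = "\t")
pig <- Pi_per_gene(de, fdr_max = 0.05)
pic <- Pi_per_celltype(de, fdr_max = 0.05, logfc_min = 0.5)
write.table(pig, "results/analysis/Pi_gene.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(pic, "results/analysis/Pi_celltype.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

for (a in c("young", "old")) {
  cat(sprintf("%s: %d genes with Pi_g (mean %.3f); mean Pi_c %.3f\n", a,
              sum(pig$age == a), mean(pig$Pi_g[pig$age == a]),
              mean(pic$Pi_c[pic$age == a])))
}

regressions <- list()
pw <- merge(pic[pic$age == "young", c("cluster", "Pi_c")],
            pic[pic$age == "old", c("cluster", "Pi_c")], by = "cluster",
            suffixes = c("_young", "_old"))
if (nrow(pw) >= 3 && var(pw$Pi_c_young) > 0) {
  regressions$Pi_c <- cross_age_regression(pw$Pi_c_young, pw$Pi_c_old)
  cat(sprintf("Pi_c young-vs-old regression: R^2 = %.3f (p = %.3g, n = %d)\n",
              regressions$Pi_c$r_squared, regressions$Pi_c$p,
              regressions$Pi_c$n))
} else {
  cat("Pi_c cross-age regression skipped (young response too sparse)\n")
}
jsonlite::write_json(regressions, "results/analysis/regressions.json",
                     auto_unbox = TRUE, digits = NA)
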