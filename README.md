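# scshift

Microbiome-by-age single-cell transcriptome analysis: hurdle differential
expression, fold-change × FDR information fusion, and permutation-based
global transcriptome shifts.

## The problem

How does the gut microbiome reshape gene expression in the aging brain?
Experiments contrasting **microbiome-associated** and **axenic** (germ-free)
animals at two ages, profiled by droplet scRNA-seq, need an analysis chain
that (i) annotates cell types in a tissue with many poorly demarcated
populations, (ii) quantifies condition effects per cell type despite
dropout-heavy bimodal counts, and (iii) summarises those effects at the
gene, cell-type and whole-transcriptome level so that young and old
responses can be compared. `scshift` implements that chain for R users, with
a ground-truth synthetic generator so every stage is testable offline.

## Core statistics

* **Hurdle differential expression.** Per cluster and gene, log-normalized
  expression is modelled by a logistic component on detection and a Gaussian
  component on positive values, with condition nested within age
  (`~ age + condition:age + CDR`), so each age group's
  associated-vs-axenic contrast is a single-coefficient likelihood-ratio
  test. FDR is Benjamini–Hochberg per (cluster, age).
* **Information fusion.** π_g = log2FC × (−log10 FDR) per (gene, cell type,
  age). Gene-level magnitude Π_g = Σ |π_g| over the gene's significant
  (FDR < 0.05) cell types; cell-type-level magnitude Π_c = Σ |π_g| over the
  cluster's DEGs with FDR < 0.05 and |log2FC| > 0.5.
* **Global transcriptome shift.** Per cluster, the Manhattan distance
  between the two conditions' *representative cells* (per-gene mean
  expression) is compared with a size-preserving label-permutation null;
  shift = log2(observed / null mean), empirical p by the add-one rule, BH
  across clusters within an age group.
* **Correlation-gap annotation.** Reference cell types are matched to
  clusters via Pearson correlation of marker-weight vectors over the union
  of marker sets; a clear match requires a gap > 0.15 among the top six
  correlations. A grid search over (PCs, resolution) maximises the
  clear-match count.
* **Preranked GSEA** (weighted running sum, weight exponent 1, gene-label
  permutation null) on Π_g- or π_g-ranked lists, and **alpha diversity**
  (observed richness, Shannon) with rank-sum comparisons for the companion
  community data.

## Worked example

The `analysis/` directory is a numbered workflow over the package functions;
each stage reads its predecessor's tables under `results/analysis/`:

```sh
Rscript analysis/01_simulate.R            # synthetic study + ground truth
Rscript analysis/02_qc_normalize.R
Rscript analysis/03_annotate.R
Rscript analysis/04_differential_expression.R
Rscript analysis/05_fusion.R
Rscript analysis/06_global_shift.R
Rscript analysis/07_enrichment.R
Rscript analysis/08_diversity.R
```

With the bundled defaults (5 cell types × 1,200 genes, 50 cells per group,
condition effects concentrated in two cell types and 0.3× attenuated in the
young group) the run prints:

```
grid search over 9 points; selected 15 PCs at resolution 1
5 clusters, 213 marker rows, 5 of 5 reference types clearly matched
young: 6000 gene-cluster tests, 2 DEGs at FDR < 0.05
old:   6000 gene-cluster tests, 38 DEGs at FDR < 0.05
young: 2 genes with Pi_g (mean 1.342); mean Pi_c 0.537
old:   38 genes with Pi_g (mean 8.014); mean Pi_c 60.119
young: 1 of 5 clusters significantly shifted (max shift 0.075)
old:   2 of 5 clusters significantly shifted (max shift 0.199)
global/old: 2 sets scored; top response_type01 (NES 1.74, adj p 0.0041)
observed richness: W = 76.0, p = 0.17
Shannon index:     W = 100.0, p = 0.000939
```

Reading these numbers: every reference type finds its cluster through the
correlation gap; differential expression and both fusion magnitudes are an
order of magnitude larger in the old group, exactly as injected; the shift
test flags the responsive clusters in the old group; the injected response
program is recovered by enrichment; and the community's Shannon diversity
rises sharply with age while richness stays statistically comparable.

The same chain is available as one call:

```r
library(scshift)
manifest <- run_all(list(paths = list(output_dir = "results/run"), seed = 1))
```

which writes every stage's tables plus a manifest of parameters, seeds and
per-file checksums; two runs with the same seed are checksum-identical.

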