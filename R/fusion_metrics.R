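# Information fusion of fold change and FDR.
#
# pi_g = log2FC * (-log10 FDR) fuses effect size and significance into one
# signed magnitude per (gene, cell type, age). Summing |pi_g| across a gene's
# significant cell types gives the gene-level response magnitude Pi_g; summing
# across a cell type's qualifying DEGs gives the cell-type-level Pi_c.

#' Fused effect statistic pi_g
#'
#' @param logFC Log2 fold change (vectorized).
#' @param FDR BH-adjusted p-value in (0, 1]; values below `floor` (including
#'   0) are floored so the product stays finite.
#' @param floor FDR floor; set to 0 to disable (then FDR <= 0 errors).
#' @return logFC * (-log10 max(FDR, floor)).
#' @export
pi_g <- function(logFC, FDR, floor = 1e-300) {
  .assert(length(logFC) == length(FDR), "logFC and FDR must have equal length")
  ok <- !is.na(FDR)
  .assert(all(FDR[ok] <= 1), "FDR must not exceed 1")
  if (floor <= 0 && any(FDR[ok] <= 0))
    stop("FDR <= 0 requires a positive floor", call. = FALSE)
  logFC * (-log10(pmax(FDR, floor)))
}

#' Gene-level response magnitude Pi_g
#'
#' Per (gene, age), the sum of |pi_g| over cell-type entries significant at
#' `fdr_max`. Genes with no qualifying entry are omitted. No fold-change
#' filter is applied at the gene level.
#'
#' @param results DE result data.frame with columns gene, cluster, age,
#'   logFC, FDR, pi_g (as produced by [de_per_cluster()]).
#' @param fdr_max Strict FDR cutoff (entries with FDR < fdr_max qualify).
#' @return data.frame: gene, age, n_celltypes_significant, Pi_g.
#' @export
Pi_per_gene <- function(results, fdr_max = 0.05) {
  .assert(all(c("gene", "age", "FDR", "pi_g") %in% names(results)),
          "results must carry gene, age, FDR, pi_g")
  keep <- !is.na(results$FDR) & !is.na(results$pi_g) & results$FDR < fdr_max
  r <- results[keep, , drop = FALSE]
  if (!nrow(r)) {
    return(data.frame(gene = character(), age = character(),
                      n_celltypes_significant = integer(), Pi_g = numeric()))
  }
  agg <- stats::aggregate(abs(r$pi_g), by = list(gene = r$gene, age = r$age),
                          FUN = function(v) c(sum(v), length(v)))
  data.frame(gene = agg$gene, age = agg$age,
             n_celltypes_significant = as.integer(agg$x[, 2]),
             Pi_g = agg$x[, 1])
}

#' Cell-type-level response magnitude Pi_c
#'
#' Per (cluster, age), the sum of |pi_g| over DEGs with FDR < `fdr_max` and
#' |logFC| > `logfc_min` (both strict). Clusters with no qualifying DEG get
#' Pi_c = 0.
#'
#' @param results DE result data.frame (see [Pi_per_gene()]).
#' @param fdr_max Strict FDR cutoff.
#' @param logfc_min Strict absolute log2-fold-change cutoff.
#' @return data.frame: cluster, age, n_degs, Pi_c.
#' @export
Pi_per_celltype <- function(results, fdr_max = 0.05, logfc_min = 0.5) {
  .assert(all(c("cluster", "age", "logFC", "FDR", "pi_g") %in% names(results)),
          "results must carry cluster, age, logFC, FDR, pi_g")
  base <- unique(results[, c("cluster", "age")])
  keep <- !is.na(results$FDR) & !is.na(results$logFC) & !is.na(results$pi_g) &
    results$FDR < fdr_max & abs(results$logFC) > logfc_min
  r <- results[keep, , drop = FALSE]
  out <- base
  out$n_degs <- 0L; out$Pi_c <- 0
  if (nrow(r)) {
    agg <- stats::aggregate(abs(r$pi_g),
                            by = list(cluster = r$cluster, age = r$age),
                            FUN = function(v) c(sum(v), length(v)))
    i <- match(paste(agg$cluster, agg$age), paste(out$cluster, out$age))
    out$Pi_c[i] <- agg$x[, 1]
    out$n_degs[i] <- as.integer(agg$x[, 2])
  }
  rownames(out) <- NULL
  out
}

#' Young-vs-old linear regression of response magnitudes
#'
#' Ordinary least squares of the old-group values on the young-group values,
#' paired by gene or cluster.
#'
#' @param x,y Paired numeric vectors (young and old values).
#' @return List with slope, intercept, r_squared, p (two-sided, slope), n.
#' @export
cross_age_regression <- function(x, y) {
  .assert(is.numeric(x) && is.numeric(y) && length(x) == length(y),
          "x and y must be numeric vectors of equal length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 paired observations", call. = FALSE)
  if (stats::var(x) == 0) stop("zero variance in x", call. = FALSE)
  fit <- stats::lm(y ~ x)
  s <- summary(fit)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = s$r.squared,
       p = unname(s$coefficients[2, 4]),
       n = length(x))
}
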