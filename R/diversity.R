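# Alpha diversity and rank-sum comparisons for the companion community data.

#' Observed richness of one sample
#'
#' @param counts Non-negative numeric vector of taxon counts.
#' @return Number of taxa with positive count (0 with a warning for an
#'   all-zero sample).
#' @export
observed_richness <- function(counts) {
  .assert(is.numeric(counts) && all(counts >= 0), "counts must be non-negative")
  n <- sum(counts > 0)
  if (n == 0) warning("all-zero sample: observed richness is 0", call. = FALSE)
  as.integer(n)
}

#' Shannon diversity index (natural log)
#'
#' @param counts Non-negative numeric vector with positive total.
#' @return -sum(p * ln p) over taxa with positive proportion.
#' @export
shannon <- function(counts) {
  .assert(is.numeric(counts) && all(counts >= 0), "counts must be non-negative")
  if (sum(counts) == 0) stop("zero total count", call. = FALSE)
  unname(vegan::diversity(counts, index = "shannon"))
}

#' Per-sample alpha diversity table
#'
#' @param taxa List with `counts` (samples x taxa matrix) and `group`, as
#'   produced by [simulate_community()], or a bare counts matrix.
#' @return data.frame: sample, group (if available), observed, shannon.
#' @export
alpha_diversity <- function(taxa) {
  counts <- if (is.list(taxa) && !is.data.frame(taxa)) taxa$counts else taxa
  counts <- as.matrix(counts)
  out <- data.frame(sample = rownames(counts) %||% as.character(seq_len(nrow(counts))),
                    observed = apply(counts, 1, observed_richness),
                    shannon = apply(counts, 1, shannon))
  if (is.list(taxa) && !is.null(taxa$group)) out$group <- taxa$group
  rownames(out) <- NULL
  out
}

#' Wilcoxon rank-sum test reporting the first-sample rank sum
#'
#' W is the rank sum of `x` in the pooled ranking (packages differ: the
#' Mann-Whitney U equals W - n1(n1+1)/2). The p-value is exact by enumeration
#' for small tie-free samples (n1 + n2 <= `exact_max`), otherwise a normal
#' approximation with tie and continuity corrections.
#'
#' @param x,y Non-empty numeric samples.
#' @param alternative "two.sided" (default), "less" or "greater".
#' @param exact_max Combined size up to which the exact distribution is used.
#' @return List with `W`, `p`, `method`.
#' @export
rank_sum_test <- function(x, y, alternative = "two.sided", exact_max = 12L) {
  .assert(length(x) > 0 && length(y) > 0, "both samples must be non-empty")
  n1 <- length(x)
  pooled <- c(x, y)
  W <- sum(rank(pooled)[seq_len(n1)])
  ties <- anyDuplicated(pooled) > 0
  exact <- !ties && (length(pooled) <= exact_max)
  ht <- suppressWarnings(stats::wilcox.test(x, y, alternative = alternative,
                                            exact = exact, correct = TRUE))
  p <- ht$p.value
  if (is.nan(p)) p <- 1  # completely tied samples carry no evidence
  list(W = W, p = p,
       method = if (exact) "exact" else "normal approximation")
}

#' Compare alpha diversity between two groups
#'
#' @param taxa As in [alpha_diversity()]; `group` must have exactly two levels.
#' @return List with the diversity table and rank-sum results for observed
#'   richness and Shannon index.
#' @export
compare_diversity <- function(taxa) {
  div <- alpha_diversity(taxa)
  .assert(!is.null(div$group), "taxa must carry group labels")
  g <- sort(unique(div$group))
  .assert(length(g) == 2, "exactly two groups required")
  a <- div[div$group == g[1], ]; b <- div[div$group == g[2], ]
  list(diversity = div,
       groups = g,
       observed = rank_sum_test(a$observed, b$observed),
       shannon = rank_sum_test(a$shannon, b$shannon),
       means = data.frame(group = g,
                          observed = c(mean(a$observed), mean(b$observed)),
                          shannon = c(mean(a$shannon), mean(b$shannon))))
}
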