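# Global transcriptome-shift test.
#
# For each cell type within one age group, the two conditions are collapsed
# to representative cells (per-gene mean log-normalized expression) and the
# Manhattan distance between them is compared against a null distribution
# obtained by shuffling condition labels within the cluster while preserving
# group sizes. The shift magnitude is the log2 ratio of the observed distance
# to the null average.

#' Representative cell of a set of expression profiles
#'
#' @param cells Numeric matrix, cells in rows, genes in columns (a single
#'   profile may be given as a vector).
#' @return Per-gene arithmetic mean vector.
#' @export
representative_cell <- function(cells) {
  if (is.vector(cells)) cells <- matrix(cells, nrow = 1)
  .assert(nrow(cells) >= 1, "representative_cell needs at least one cell")
  colMeans(cells)
}

#' Manhattan (L1) distance
#'
#' @param a,b Numeric vectors of equal length.
#' @return Sum of absolute coordinate differences.
#' @export
manhattan <- function(a, b) {
  if (length(a) != length(b)) stop("length mismatch", call. = FALSE)
  sum(abs(a - b))
}

# Null distances for one cluster: columns of P select a random pseudo-group
# of fixed size m; distances come from group-mean differences. m is the
# smaller condition's size so relabelling conditions is a no-op.
.null_distances <- function(V, m, n_perm, dist_fun, chunk = 2000L) {
  n <- ncol(V)
  tot <- rowSums(V)
  out <- numeric(n_perm)
  done <- 0L
  while (done < n_perm) {
    b <- min(chunk, n_perm - done)
    P <- matrix(0, n, b)
    for (j in seq_len(b)) P[sample.int(n, m), j] <- 1
    S1 <- V %*% P
    D <- dist_fun(S1 / m - (tot - S1) / (n - m))
    out[done + seq_len(b)] <- D
    done <- done + b
  }
  out
}

#' Permutation test for per-cluster global transcriptome shifts
#'
#' @param norm A `normalized_matrix`.
#' @param labels Cluster label per cell (defaults to `cell_data$cluster`).
#' @param age_group Which age group to test ("young" or "old"); cells of the
#'   other age are ignored. NULL uses all cells (single-factor designs).
#' @param n_perm Number of label permutations (the add-one empirical p-value
#'   has resolution 1/(n_perm+1)).
#' @param seed Integer seed for the permutation stream.
#' @param epsilon Guard added to numerator and denominator of the log2
#'   fold-shift.
#' @param min_cells Minimum cells required per condition within a cluster.
#' @param metric Distance between representative cells: "manhattan" (the
#'   method's metric, default) or "euclidean" (the ancestor variant; offered
#'   for comparison, not validated against published values).
#' @return List with `results` (data.frame per cluster: d_obs, null_mean,
#'   null_sd, n_perm, p_emp, p_adj, shift, degenerate) and `skipped`.
#' @export
shift_test <- function(norm, labels = NULL, age_group = NULL, n_perm = 20000L,
                       seed = 1L, epsilon = 1e-12, min_cells = 2L,
                       metric = c("manhattan", "euclidean")) {
  metric <- match.arg(metric)
  obs_dist <- if (metric == "manhattan") manhattan else
    function(a, b) sqrt(sum((a - b)^2))
  null_dist <- if (metric == "manhattan") {
    function(M) colSums(abs(M))
  } else {
    function(M) sqrt(colSums(M^2))
  }
  .assert(inherits(norm, "normalized_matrix"), "norm must be a normalized_matrix")
  labels <- labels %||% norm$cell_data$cluster
  .assert(!is.null(labels) && length(labels) == ncol(norm$values),
          "labels must give one cluster per cell")
  condition <- norm$cell_data$condition
  .assert(!is.null(condition), "cell_data must provide condition")
  .assert(.is_count(n_perm), "n_perm must be a positive integer")

  sel <- if (is.null(age_group)) rep(TRUE, length(labels)) else {
    .assert(age_group %in% AGES, "age_group must be 'young' or 'old'")
    norm$cell_data$age == age_group
  }
  set.seed(.stage_seed(seed, 43L))
  rows <- list(); skipped <- list()
  for (cl in sort(unique(as.character(labels[sel])))) {
    idx <- which(sel & labels == cl)
    cond <- condition[idx]
    n_by <- table(factor(cond, CONDITIONS))
    if (any(n_by == 0)) { skipped[[cl]] <- "single condition present"; next }
    if (any(n_by < min_cells)) {
      skipped[[cl]] <- sprintf("fewer than %d cells in a condition", min_cells)
      next
    }
    V <- as.matrix(norm$values[, idx, drop = FALSE])
    r1 <- representative_cell(t(V[, cond == CONDITIONS[1], drop = FALSE]))
    r0 <- representative_cell(t(V[, cond == CONDITIONS[2], drop = FALSE]))
    d_obs <- obs_dist(r1, r0)
    m <- min(n_by)
    d_null <- .null_distances(V, m, n_perm, null_dist)
    null_mean <- mean(d_null)
    # ties count toward the numerator (conservative); the tolerance absorbs
    # float noise between the observed and re-computed group-mean distances
    tol <- 1e-9 * max(1, d_obs)
    p_emp <- (1 + sum(d_null >= d_obs - tol)) / (1 + n_perm)
    rows[[cl]] <- data.frame(
      cluster = cl, age = age_group %||% NA_character_,
      n_associated = as.integer(n_by[1]), n_axenic = as.integer(n_by[2]),
      d_obs = d_obs, null_mean = null_mean, null_sd = stats::sd(d_null),
      n_perm = n_perm, p_emp = p_emp,
      shift = log2((d_obs + epsilon) / (null_mean + epsilon)),
      degenerate = d_obs == 0 || null_mean == 0,
      row.names = NULL)
  }
  results <- .rbind_all(rows)
  if (nrow(results)) results$p_adj <- benjamini_hochberg(results$p_emp)
  skipped_df <- if (length(skipped)) {
    data.frame(cluster = names(skipped), reason = unlist(skipped),
               row.names = NULL)
  } else data.frame(cluster = character(), reason = character())
  list(results = results, skipped = skipped_df)
}
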