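# Preranked gene-set enrichment.
#
# Classic weighted Kolmogorov-Smirnov running sum (weight exponent 1): hits
# advance by |score|/sum(|score| over hits), misses retreat by 1/(N - Nh);
# ES is the extremum by absolute value. The null permutes gene labels
# (equivalently: random sets of the same size), NES normalizes ES by the mean
# |null ES| of matching sign, and the p-value is the same-sign null fraction
# with the add-one rule.

#' Read a GMT gene-set collection
#'
#' @param path GMT file: name, description, then tab-separated gene ids.
#' @return Named list of unique gene-id character vectors.
#' @export
read_gmt <- function(path) {
  .assert(file.exists(path), paste("missing file:", path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(strsplit(lines, "\t"), function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(strsplit(lines, "\t"), `[`, character(1), 1)
  .assert(!anyDuplicated(names(sets)), "duplicate set names in GMT")
  .assert(all(lengths(sets) > 0), "empty gene set in GMT")
  sets
}

# ES via the hit-position shortcut: the running sum's extrema occur at hit
# positions (after the hit) or just before a hit.
.es_at <- function(absw, Sh, N, hit_idx) {
  Nh <- length(hit_idx)
  Nm <- N - Nh
  cum_hit <- cumsum(absw[hit_idx]) / Sh
  miss_before <- (hit_idx - seq_len(Nh)) / Nm
  after <- cum_hit - miss_before
  before <- c(0, cum_hit[-Nh]) - miss_before
  hi <- max(after)
  lo <- min(before)
  if (abs(hi) >= abs(lo)) hi else lo
}

#' Enrichment score of one gene set on a ranked list
#'
#' @param ranked Named numeric vector of scores sorted in decreasing order
#'   (names are gene ids).
#' @param geneset Character vector of gene ids.
#' @details When the positive and negative running-sum extremes tie exactly
#'   in absolute value, the positive one is reported.
#' @return List with `ES`, `leading_edge` (gene ids), `degenerate` flag
#'   (empty intersection, whole-universe set, or all-zero hit scores).
#' @export
enrichment_score <- function(ranked, geneset) {
  .assert(!is.null(names(ranked)), "ranked must be a named score vector")
  .assert(!is.unsorted(rev(ranked)), "ranked scores must be sorted decreasing")
  N <- length(ranked)
  hit <- names(ranked) %in% geneset
  Nh <- sum(hit)
  if (Nh == 0 || Nh == N)
    return(list(ES = NA_real_, leading_edge = character(), degenerate = TRUE))
  absw <- abs(ranked)
  Sh <- sum(absw[hit])
  if (Sh == 0)
    return(list(ES = NA_real_, leading_edge = character(), degenerate = TRUE))
  hit_idx <- which(hit)
  running <- cumsum(ifelse(hit, absw / Sh, -1 / (N - Nh)))
  es <- .es_at(absw, Sh, N, hit_idx)
  if (es >= 0) {
    peak <- which.max(running)
    le <- names(ranked)[hit_idx[hit_idx <= peak]]
  } else {
    low <- which.min(c(0, running)[seq_len(N)])  # running sum before each rank
    le <- names(ranked)[hit_idx[hit_idx >= low]]
  }
  list(ES = es, leading_edge = le, degenerate = FALSE)
}

#' Preranked GSEA with a gene-label permutation null
#'
#' @param ranked Named numeric score vector (e.g. Pi_g per gene for global
#'   analyses, pi_g for single-cell-type analyses); sorted internally.
#' @param collection Named list of gene sets (see [read_gmt()]).
#' @param n_perm Permutations per set.
#' @param min_size,max_size Bounds on set size after intersection with the
#'   ranked universe.
#' @param seed Integer seed.
#' @return List with `results` (data.frame: set, size, ES, NES, p_perm,
#'   p_adj, leading_edge) and `excluded` (sets outside bounds or degenerate).
#' @export
preranked_gsea <- function(ranked, collection, n_perm = 1000L,
                           min_size = 5L, max_size = 500L, seed = 1L) {
  .assert(is.numeric(ranked) && !is.null(names(ranked)), "ranked must be named numeric")
  .assert(is.list(collection) && !is.null(names(collection)),
          "collection must be a named list")
  ranked <- sort(ranked, decreasing = TRUE)
  N <- length(ranked)
  absw <- abs(ranked)
  set.seed(.stage_seed(seed, 57L))
  rows <- list(); excluded <- list()
  for (nm in names(collection)) {
    idx <- which(names(ranked) %in% collection[[nm]])
    size <- length(idx)
    if (size < min_size || size > max_size) {
      excluded[[nm]] <- sprintf("size %d outside [%d, %d]", size, min_size, max_size)
      next
    }
    obs <- enrichment_score(ranked, collection[[nm]])
    if (obs$degenerate) { excluded[[nm]] <- "degenerate enrichment score"; next }
    null_es <- vapply(seq_len(n_perm), function(b) {
      ri <- sort(sample.int(N, size))
      Sh <- sum(absw[ri])
      if (Sh == 0) return(0)
      .es_at(absw, Sh, N, ri)
    }, numeric(1))
    same <- null_es[sign(null_es) == sign(obs$ES)]
    nes <- if (length(same)) obs$ES / mean(abs(same)) else NA_real_
    p <- (1 + sum(abs(same) >= abs(obs$ES))) / (1 + length(same))
    rows[[nm]] <- data.frame(set = nm, size = size, ES = obs$ES, NES = nes,
                             p_perm = p,
                             leading_edge = paste(obs$leading_edge, collapse = ","),
                             row.names = NULL)
  }
  results <- .rbind_all(rows, prototype = data.frame(
    set = character(), size = integer(), ES = numeric(), NES = numeric(),
    p_perm = numeric(), leading_edge = character()))
  if (nrow(results)) results$p_adj <- benjamini_hochberg(results$p_perm)
  excluded_df <- if (length(excluded)) {
    data.frame(set = names(excluded), reason = unlist(excluded), row.names = NULL)
  } else data.frame(set = character(), reason = character())
  list(results = results, excluded = excluded_df)
}
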