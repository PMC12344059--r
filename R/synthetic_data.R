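# Synthetic data with known ground truth.
#
# The generator emulates the statistical structure of a 2 (age: young/old) x
# 2 (condition: microbiome-associated/axenic) droplet scRNA-seq experiment on
# brain tissue: cell-type-specific expression programs, dropout-heavy
# negative-binomial counts, condition effects concentrated in particular cell
# types and stronger in the old group, plus a companion 16S-style community
# table whose dominant taxon gives way to a more even composition with age.

AGES <- c("young", "old")
CONDITIONS <- c("associated", "axenic")

#' Describe a synthetic microbiome-by-age experiment
#'
#' @param n_cell_types Number of cell types.
#' @param n_genes Number of genes (including mitochondrial-flagged ones).
#' @param n_marker_genes_per_type Markers allocated to each type.
#' @param cells_per_group Either a single count used for every
#'   (type, age, condition) group, or a data.frame with columns
#'   `cell_type`, `age`, `condition`, `n`.
#' @param mito_gene_fraction Fraction of genes flagged mitochondrial via the
#'   `mt:` id prefix.
#' @param batch_count Number of (expression-neutral) batch labels.
#' @param seed Integer seed; identical seeds give identical output everywhere
#'   downstream.
#' @return An object of class `experiment_design`.
#' @export
experiment_design <- function(n_cell_types = 5L, n_genes = 1500L,
                              n_marker_genes_per_type = 20L,
                              cells_per_group = 60L,
                              mito_gene_fraction = 0.02,
                              batch_count = 2L, seed = 1L) {
  .assert(.is_count(n_cell_types), "n_cell_types must be a positive integer")
  .assert(.is_count(n_genes), "n_genes must be a positive integer")
  .assert(.is_count(n_marker_genes_per_type),
          "n_marker_genes_per_type must be a positive integer")
  .assert(is.numeric(mito_gene_fraction) && mito_gene_fraction >= 0 &&
            mito_gene_fraction < 1, "mito_gene_fraction must be in [0, 1)")
  .assert(.is_count(batch_count), "batch_count must be a positive integer")

  types <- sprintf("type%02d", seq_len(n_cell_types))
  groups <- expand.grid(cell_type = types, age = AGES, condition = CONDITIONS,
                        stringsAsFactors = FALSE)
  if (is.data.frame(cells_per_group)) {
    .assert(all(c("cell_type", "age", "condition", "n") %in% names(cells_per_group)),
            "cells_per_group data.frame needs cell_type, age, condition, n")
    groups <- merge(groups, cells_per_group, all.x = TRUE, sort = FALSE)
    groups$n[is.na(groups$n)] <- 0L
  } else {
    .assert(.is_count(cells_per_group), "cells_per_group must be a positive integer")
    groups$n <- as.integer(cells_per_group)
  }
  .assert(sum(groups$n) > 0, "design contains no cells")

  design <- list(n_cell_types = as.integer(n_cell_types),
                 cell_types = types,
                 n_genes = as.integer(n_genes),
                 n_marker_genes_per_type = as.integer(n_marker_genes_per_type),
                 groups = groups,
                 mito_gene_fraction = mito_gene_fraction,
                 batch_count = as.integer(batch_count),
                 seed = as.integer(seed))
  class(design) <- "experiment_design"
  design
}

#' Specify condition effects and the count law
#'
#' `entries` holds the true associated-vs-axenic log2 fold changes injected
#' into specific (gene, cell type, age) strata; everything absent is null.
#' Counts are negative binomial with a shared `dispersion` (size parameter);
#' an optional logistic dropout zeroes counts with probability decreasing in
#' the log mean (disabled by default: desk-scale negative-binomial means are
#' already dropout-heavy).
#'
#' @param entries data.frame with columns `gene`, `cell_type`, `age`, `logFC`
#'   (may have zero rows for a null experiment).
#' @param dispersion Negative-binomial size parameter, positive.
#' @param dropout_intercept,dropout_slope Logistic dropout on log2 mean:
#'   P(drop) = plogis(dropout_intercept - dropout_slope * log2(mu)).
#' @return An object of class `effect_spec`.
#' @export
effect_spec <- function(entries = NULL, dispersion = 2,
                        dropout_intercept = -Inf, dropout_slope = 0) {
  if (is.null(entries)) {
    entries <- data.frame(gene = character(), cell_type = character(),
                          age = character(), logFC = numeric())
  }
  .assert(is.data.frame(entries) &&
            all(c("gene", "cell_type", "age", "logFC") %in% names(entries)),
          "entries needs columns gene, cell_type, age, logFC")
  .assert(all(is.finite(entries$logFC)), "logFC entries must be finite")
  .assert(all(entries$age %in% AGES), "entries$age must be 'young' or 'old'")
  .assert(is.numeric(dispersion) && dispersion > 0, "dispersion must be positive")
  .assert(dropout_slope >= 0, "dropout_slope must be non-negative")
  structure(list(entries = entries, dispersion = dispersion,
                 dropout_intercept = dropout_intercept,
                 dropout_slope = dropout_slope),
            class = "effect_spec")
}

#' Build a marker reference and base expression profiles
#'
#' Allocates disjoint marker-gene sets to each cell type and returns (i) a
#' reference table (cell_type, gene, weight) usable for correlation-gap
#' annotation and (ii) base log2-mean expression profiles per (gene, type).
#' Marker genes get a multiplicative log-mean boost in their own type only,
#' which makes annotation identifiable on synthetic data.
#'
#' @param design An `experiment_design`.
#' @param marker_boost Log2 boost added to a marker gene's base mean in its
#'   own type (default 2, i.e. 4-fold).
#' @param base_logmean_range Range of per-gene baseline log2 means (uniform).
#' @param overlap_markers If TRUE, marker sets are sampled independently per
#'   type and may overlap (default FALSE: disjoint).
#' @return List with `reference` (data.frame), `profiles` (genes x types log2
#'   mean matrix), `marker_map` (named list), `gene_ids`, `is_mito`.
#' @export
generate_reference <- function(design, marker_boost = 2,
                               base_logmean_range = c(-2, 3),
                               overlap_markers = FALSE) {
  .assert(inherits(design, "experiment_design"), "design must be an experiment_design")
  n_mark <- design$n_marker_genes_per_type * design$n_cell_types
  set.seed(.stage_seed(design$seed, 11L))

  n_mito <- round(design$mito_gene_fraction * design$n_genes)
  gene_ids <- sprintf("gene%05d", seq_len(design$n_genes))
  is_mito <- rep(FALSE, design$n_genes)
  if (n_mito > 0) {
    mito_idx <- seq_len(n_mito)  # first genes are mitochondrial
    gene_ids[mito_idx] <- sprintf("mt:gene%05d", mito_idx)
    is_mito[mito_idx] <- TRUE
  }
  eligible <- which(!is_mito)
  if (!overlap_markers && n_mark > length(eligible)) {
    stop(sprintf("infeasible marker allocation: %d markers requested, %d non-mitochondrial genes available",
                 n_mark, length(eligible)), call. = FALSE)
  }

  base <- stats::runif(design$n_genes, base_logmean_range[1], base_logmean_range[2])
  # mitochondrial genes are abundant housekeeping transcripts
  base[is_mito] <- stats::runif(n_mito, 2, 4)

  profiles <- matrix(rep(base, design$n_cell_types),
                     nrow = design$n_genes,
                     dimnames = list(gene_ids, design$cell_types))
  if (overlap_markers) {
    marker_map <- lapply(design$cell_types, function(t)
      sort(sample(eligible, design$n_marker_genes_per_type)))
  } else {
    pool <- sample(eligible, n_mark)
    marker_map <- split(pool, rep(seq_len(design$n_cell_types),
                                  each = design$n_marker_genes_per_type))
    marker_map <- lapply(marker_map, sort)
  }
  names(marker_map) <- design$cell_types
  for (t in design$cell_types) {
    profiles[marker_map[[t]], t] <- profiles[marker_map[[t]], t] + marker_boost
  }
  reference <- do.call(rbind, lapply(design$cell_types, function(t)
    data.frame(cell_type = t, gene = gene_ids[marker_map[[t]]],
               weight = marker_boost)))
  marker_map <- lapply(marker_map, function(i) gene_ids[i])
  list(reference = reference, profiles = profiles,
       marker_map = marker_map, gene_ids = gene_ids, is_mito = is_mito)
}

#' Simulate UMI counts with ground truth
#'
#' Draws negative-binomial counts around the reference profiles, scaling the
#' mean of affected (gene, type, age) strata by 2^logFC in the
#' microbiome-associated condition only, with log-normal per-cell library
#' size factors. Age and condition do not alter size factors, so any global
#' shift is attributable to the injected effects.
#'
#' @param design An `experiment_design`.
#' @param effects An `effect_spec`.
#' @param reference Output of [generate_reference()].
#' @param library_size_sdlog SD of the log-normal library-size factor.
#' @return List with `counts` (a `count_matrix`) and `truth` (per-cell
#'   identities, effect table, marker map).
#' @export
simulate_counts <- function(design, effects = effect_spec(), reference = NULL,
                            library_size_sdlog = 0.3) {
  .assert(inherits(design, "experiment_design"), "design must be an experiment_design")
  .assert(inherits(effects, "effect_spec"), "effects must be an effect_spec")
  if (is.null(reference)) reference <- generate_reference(design)
  ent <- effects$entries
  .assert(all(ent$cell_type %in% design$cell_types),
          "effect entries reference unknown cell types")
  .assert(all(ent$gene %in% reference$gene_ids),
          "effect entries reference unknown genes")

  set.seed(.stage_seed(design$seed, 23L))
  groups <- design$groups
  n_cells <- sum(groups$n)
  counts <- matrix(0L, nrow = design$n_genes, ncol = n_cells)
  meta <- data.frame(barcode = sprintf("cell%06d", seq_len(n_cells)),
                     age = character(n_cells), condition = character(n_cells),
                     batch = character(n_cells), true_type = character(n_cells),
                     stringsAsFactors = FALSE)
  col <- 0L
  for (g in seq_len(nrow(groups))) {
    n <- groups$n[g]
    if (n == 0L) next
    idx <- col + seq_len(n)
    col <- col + n
    type <- groups$cell_type[g]
    mu <- 2^reference$profiles[, type]
    hit <- ent$cell_type == type & ent$age == groups$age[g]
    if (any(hit) && groups$condition[g] == "associated") {
      j <- match(ent$gene[hit], reference$gene_ids)
      mu[j] <- mu[j] * 2^ent$logFC[hit]
    }
    sf <- stats::rlnorm(n, 0, library_size_sdlog)
    m <- matrix(stats::rnbinom(design$n_genes * n,
                               mu = outer(mu, sf), size = effects$dispersion),
                nrow = design$n_genes)
    if (effects$dropout_slope > 0 || is.finite(effects$dropout_intercept)) {
      pdrop <- stats::plogis(effects$dropout_intercept -
                               effects$dropout_slope * log2(mu))
      drop <- matrix(stats::rbinom(design$n_genes * n, 1L, rep(pdrop, n)),
                     nrow = design$n_genes) == 1L
      m[drop] <- 0L
    }
    counts[, idx] <- m
    meta$age[idx] <- groups$age[g]
    meta$condition[idx] <- groups$condition[g]
    meta$true_type[idx] <- type
  }
  meta$batch <- sprintf("batch%d", 1L + (seq_len(n_cells) %% design$batch_count))
  rownames(counts) <- reference$gene_ids
  colnames(counts) <- meta$barcode

  cm <- count_matrix(Matrix::Matrix(counts, sparse = TRUE), meta)
  truth <- list(cells = meta,
                effects = ent,
                dispersion = effects$dispersion,
                marker_map = reference$marker_map)
  list(counts = cm, truth = truth)
}

#' Simulate a samples-by-taxa community table
#'
#' Multinomial (optionally Dirichlet-overdispersed) read counts per sample at
#' fixed depth, one proportion vector per group. Emulates an amplicon
#' community whose dominant taxon recedes with age in favour of a more even
#' composition.
#'
#' @param groups Named list: group label -> taxon proportion vector (all
#'   vectors same length, each summing to 1).
#' @param depth Reads per sample.
#' @param n_samples Samples per group (single integer or per-group vector).
#' @param seed Integer seed.
#' @param dirichlet_concentration If finite, proportions are resampled per
#'   sample from Dirichlet(concentration * p) before the multinomial draw.
#' @return List with `counts` (samples x taxa integer matrix) and `group`
#'   (character vector per sample).
#' @export
simulate_community <- function(groups, depth = 10000L, n_samples = 6L,
                               seed = 1L, dirichlet_concentration = Inf) {
  .assert(is.list(groups) && length(groups) >= 1 && !is.null(names(groups)),
          "groups must be a named list of proportion vectors")
  n_taxa <- length(groups[[1]])
  for (g in names(groups)) {
    p <- groups[[g]]
    .assert(length(p) == n_taxa, "all proportion vectors must have equal length")
    .assert(all(p >= 0), "proportions must be non-negative")
    if (abs(sum(p) - 1) > 1e-8)
      stop(sprintf("proportions for group '%s' sum to %.6f, not 1", g, sum(p)),
           call. = FALSE)
  }
  .assert(.is_count(depth), "depth must be a positive integer")
  if (length(n_samples) == 1L) n_samples <- rep(n_samples, length(groups))
  .assert(all(vapply(n_samples, .is_count, logical(1))),
          "n_samples must be positive integers")

  set.seed(.stage_seed(seed, 31L))
  taxa <- names(groups[[1]]) %||% sprintf("taxon%02d", seq_len(n_taxa))
  counts <- NULL; label <- character()
  for (i in seq_along(groups)) {
    p <- as.numeric(groups[[i]])
    for (s in seq_len(n_samples[i])) {
      ps <- p
      if (is.finite(dirichlet_concentration)) {
        a <- stats::rgamma(n_taxa, shape = dirichlet_concentration * p)
        if (sum(a) > 0) ps <- a / sum(a)
      }
      counts <- rbind(counts, as.integer(stats::rmultinom(1, depth, ps)))
      label <- c(label, names(groups)[i])
    }
  }
  dimnames(counts) <- list(sprintf("%s_s%02d", label,
                                   stats::ave(seq_along(label), label, FUN = seq_along)),
                           taxa)
  list(counts = counts, group = label)
}

#' Write synthetic outputs to disk
#'
#' Writes the 10x-style triplet, cell metadata TSV, reference TSV, a truth
#' JSON, and (optionally) a taxa-count TSV under `dir`.
#'
#' @param sim Output of [simulate_counts()].
#' @param reference Output of [generate_reference()].
#' @param dir Output directory (created if needed).
#' @param community Optional output of [simulate_community()].
#' @return Invisibly, the vector of files written.
#' @export
write_synthetic <- function(sim, reference, dir, community = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- write_counts_10x(sim$counts, dir)
  ref_path <- file.path(dir, "reference.tsv")
  utils::write.table(reference$reference, ref_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  truth_path <- file.path(dir, "truth.json")
  jsonlite::write_json(list(effects = sim$truth$effects,
                            dispersion = sim$truth$dispersion,
                            marker_map = sim$truth$marker_map,
                            cells = sim$truth$cells),
                       truth_path, auto_unbox = TRUE, digits = NA)
  files <- c(files, ref_path, truth_path)
  if (!is.null(community)) {
    taxa_path <- file.path(dir, "taxa_counts.tsv")
    df <- data.frame(sample = rownames(community$counts),
                     group = community$group, community$counts,
                     check.names = FALSE)
    utils::write.table(df, taxa_path, sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, taxa_path)
  }
  invisible(files)
}
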