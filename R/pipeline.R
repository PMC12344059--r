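# End-to-end orchestration with one configuration and derived per-stage seeds.

.default_config <- function() {
  list(
    paths = list(counts = NULL, reference = NULL, gene_sets = NULL,
                 taxa = NULL, output_dir = "results/run"),
    synthesize = TRUE,
    synthesis = list(n_cell_types = 5L, n_genes = 1200L,
                     n_marker_genes_per_type = 20L, cells_per_group = 50L,
                     mito_gene_fraction = 0.02, batch_count = 2L,
                     n_responsive_types = 2L, n_effect_genes_per_type = 25L,
                     logfc_old = 2, young_attenuation = 0.3,
                     dispersion = 2),
    qc = list(min_features = 200, max_features = 2500, max_mito_fraction = 0.20),
    normalization = list(scale = 1e4),
    clustering = list(pcs_grid = c(15, 30, 45), resolution_grid = c(1, 2, 4),
                      k = 20L, gap_threshold = 0.15, top_k = 6L,
                      min_overlap = 5L),
    de = list(fdr_max = 0.05, logfc_min = 0.5, min_cells_per_group = 6L,
              use_cdr = TRUE, ridge = 0.05),
    shift = list(n_perm = 20000L, epsilon = 1e-12, min_cells = 2L),
    gsea = list(n_perm = 1000L, min_size = 5L, max_size = 500L),
    seed = 1L
  )
}

.merge_config <- function(defaults, user, path = "") {
  for (key in names(user)) {
    full <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(defaults))
      stop(sprintf("unknown configuration key: %s", full), call. = FALSE)
    if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]]))) {
      .assert(is.list(user[[key]]), sprintf("%s must be a mapping", full))
      defaults[[key]] <- .merge_config(defaults[[key]], user[[key]], full)
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  defaults
}

#' Validate a pipeline configuration
#'
#' Reads a YAML file (or takes a list), fills defaults, rejects unknown keys
#' and range-checks thresholds. Defaults follow the analysis settings used
#' throughout the package: FDR < 0.05, |logFC| > 0.5, 6 cells per group,
#' 20,000 shift permutations.
#'
#' @param config Path to a YAML file, or a (possibly partial) config list.
#' @return Validated configuration list of class `pipeline_config`.
#' @export
validate_config <- function(config = list()) {
  if (is.character(config)) {
    .assert(file.exists(config), paste("missing config file:", config))
    config <- yaml::read_yaml(config) %||% list()
  }
  .assert(is.list(config), "config must be a list or YAML path")
  cfg <- .merge_config(.default_config(), config)
  with(cfg, {
    .assert(de$fdr_max > 0 && de$fdr_max <= 1, "de.fdr_max must be in (0, 1]")
    .assert(de$logfc_min >= 0, "de.logfc_min must be non-negative")
    .assert(.is_count(de$min_cells_per_group), "de.min_cells_per_group must be a positive integer")
    .assert(.is_count(shift$n_perm), "shift.n_perm must be a positive integer")
    .assert(.is_count(gsea$n_perm), "gsea.n_perm must be a positive integer")
    .assert(qc$min_features > 0 && qc$max_features > qc$min_features,
            "qc feature bounds must satisfy 0 < min < max")
    .assert(qc$max_mito_fraction >= 0 && qc$max_mito_fraction <= 1,
            "qc.max_mito_fraction must be in [0, 1]")
    .assert(clustering$gap_threshold > 0, "clustering.gap_threshold must be positive")
    .assert(length(clustering$pcs_grid) > 0 && length(clustering$resolution_grid) > 0,
            "clustering grids must be non-empty")
    .assert(is.numeric(seed) && length(seed) == 1 && seed == round(seed),
            "seed must be an integer")
  })
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

# Default synthetic study: condition effects concentrated in a subset of
# cell types and attenuated in the young group.
.default_synthesis <- function(cfg, seed) {
  sy <- cfg$synthesis
  design <- experiment_design(n_cell_types = sy$n_cell_types,
                              n_genes = sy$n_genes,
                              n_marker_genes_per_type = sy$n_marker_genes_per_type,
                              cells_per_group = sy$cells_per_group,
                              mito_gene_fraction = sy$mito_gene_fraction,
                              batch_count = sy$batch_count, seed = seed)
  reference <- generate_reference(design)
  set.seed(.stage_seed(seed, 3L))
  marker_genes <- unlist(reference$marker_map, use.names = FALSE)
  pool <- setdiff(reference$gene_ids[!reference$is_mito], marker_genes)
  responsive <- design$cell_types[seq_len(min(sy$n_responsive_types,
                                              design$n_cell_types))]
  entries <- do.call(rbind, lapply(responsive, function(t) {
    genes <- sample(pool, sy$n_effect_genes_per_type)
    sgn <- sample(c(-1, 1), length(genes), replace = TRUE)
    old <- sgn * stats::runif(length(genes), 0.75, 1.25) * sy$logfc_old
    rbind(data.frame(gene = genes, cell_type = t, age = "old", logFC = old),
          data.frame(gene = genes, cell_type = t, age = "young",
                     logFC = old * sy$young_attenuation))
  }))
  effects <- effect_spec(entries, dispersion = sy$dispersion)
  sim <- simulate_counts(design, effects, reference)
  community <- default_community(seed = seed)
  list(design = design, reference = reference, effects = effects,
       sim = sim, community = community)
}

#' Default synthetic community table
#'
#' Two groups of samples: a young community dominated (98%) by one taxon and
#' an old community where the dominant taxon recedes to 23% in favour of a
#' more even composition.
#'
#' @param n_taxa Number of taxa (>= 25).
#' @param depth Reads per sample.
#' @param n_samples Samples per group.
#' @param seed Integer seed.
#' @return Output of [simulate_community()].
#' @export
default_community <- function(n_taxa = 30L, depth = 10000L, n_samples = 8L,
                              seed = 1L) {
  .assert(n_taxa >= 25, "n_taxa must be at least 25")
  rest <- n_taxa - 10L
  # rare young taxa sit just above the detection floor at the default depth,
  # so richness stays comparable between ages while evenness does not
  young <- c(0.98, 0.005, 0.0025, rep(0.0125 / (n_taxa - 3), n_taxa - 3))
  young <- young / sum(young)
  old <- c(0.23, 0.20, 0.15, 0.10, 0.08, 0.06, 0.04, 0.03, 0.02, 0.02,
           rep(0.07 / rest, rest))
  old <- old / sum(old)
  simulate_community(list(young = young, old = old), depth = depth,
                     n_samples = n_samples, seed = seed)
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full pipeline
#'
#' Executes ingest/QC, clustering-parameter grid search, annotation, hurdle
#' differential expression, information fusion, global-shift testing,
#' preranked GSEA and (when a taxa table is available) diversity comparison;
#' writes every stage's tables plus a manifest with parameters, derived
#' seeds, row counts and content checksums. Under a fixed seed, two runs
#' produce checksum-identical outputs.
#'
#' @param config A `pipeline_config`, partial list, or YAML path.
#' @return The manifest, invisibly (also written as `manifest.json`).
#' @export
run_all <- function(config = list()) {
  cfg <- if (inherits(config, "pipeline_config")) config else validate_config(config)
  out <- cfg$paths$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  files <- character(); counts_log <- list()
  seed <- cfg$seed

  # --- inputs -------------------------------------------------------------
  if (isTRUE(cfg$synthesize)) {
    syn <- .default_synthesis(cfg, seed = .stage_seed(seed, 100L))
    synth_dir <- file.path(out, "synthetic")
    files <- c(files, write_synthetic(syn$sim, syn$reference, synth_dir,
                                      community = syn$community))
    cm <- syn$sim$counts
    reference <- syn$reference$reference
    taxa <- syn$community
    gene_sets <- NULL
  } else {
    .assert(!is.null(cfg$paths$counts), "paths.counts is required when synthesize is off")
    .assert(!is.null(cfg$paths$reference), "paths.reference is required when synthesize is off")
    .assert(file.exists(cfg$paths$reference), paste("missing file:", cfg$paths$reference))
    cm <- read_counts_10x(cfg$paths$counts)
    reference <- utils::read.table(cfg$paths$reference, sep = "\t", header = TRUE)
    taxa <- if (!is.null(cfg$paths$taxa)) {
      df <- utils::read.table(cfg$paths$taxa, sep = "\t", header = TRUE,
                              check.names = FALSE)
      m <- as.matrix(df[, setdiff(names(df), c("sample", "group")), drop = FALSE])
      rownames(m) <- df$sample
      list(counts = m, group = df$group)
    } else NULL
    gene_sets <- if (!is.null(cfg$paths$gene_sets)) read_gmt(cfg$paths$gene_sets) else NULL
  }

  # --- QC + normalization -------------------------------------------------
  qc <- qc_filter(cm, min_features = cfg$qc$min_features,
                  max_features = cfg$qc$max_features,
                  max_mito_fraction = cfg$qc$max_mito_fraction)
  files <- c(files, {
    p <- file.path(out, "qc_report.json")
    jsonlite::write_json(qc$report, p, auto_unbox = TRUE, digits = NA)
    p
  })
  norm <- normalize_log(qc$counts, scale = cfg$normalization$scale)
  counts_log$cells_after_qc <- ncol(norm$values)

  # --- clustering + annotation -------------------------------------------
  gs <- grid_search(norm, reference,
                    pcs_grid = cfg$clustering$pcs_grid,
                    resolution_grid = cfg$clustering$resolution_grid,
                    seed = .stage_seed(seed, 200L),
                    gap_threshold = cfg$clustering$gap_threshold,
                    top_k = cfg$clustering$top_k,
                    min_overlap = cfg$clustering$min_overlap)
  files <- c(files, .write_tsv(gs$records, file.path(out, "grid_search.tsv")))
  labels <- cluster_cells(norm, n_pcs = gs$selected$n_pcs,
                          resolution = gs$selected$resolution,
                          seed = .stage_seed(seed, 200L), k = cfg$clustering$k)
  norm$cell_data$cluster <- as.character(labels)
  markers <- suppressWarnings(find_markers(norm, labels))
  files <- c(files, .write_tsv(markers, file.path(out, "markers.tsv")))
  matches <- correlation_gap_match(markers, reference,
                                   gap_threshold = cfg$clustering$gap_threshold,
                                   top_k = cfg$clustering$top_k,
                                   min_overlap = cfg$clustering$min_overlap)
  files <- c(files, .write_tsv(matches[, setdiff(names(matches), "top")],
                               file.path(out, "annotation.tsv")))
  counts_log$n_clusters <- nlevels(labels)
  counts_log$n_clear_matches <- sum(matches$matched)

  # --- differential expression + fusion ----------------------------------
  de <- de_per_cluster(norm, labels,
                       min_cells_per_group = cfg$de$min_cells_per_group,
                       use_cdr = cfg$de$use_cdr, ridge = cfg$de$ridge)
  files <- c(files, .write_tsv(de$results, file.path(out, "de_results.tsv")),
             .write_tsv(de$excluded, file.path(out, "de_excluded.tsv")))
  counts_log$n_de_rows <- nrow(de$results)
  pig <- Pi_per_gene(de$results, fdr_max = cfg$de$fdr_max)
  pic <- Pi_per_celltype(de$results, fdr_max = cfg$de$fdr_max,
                         logfc_min = cfg$de$logfc_min)
  files <- c(files, .write_tsv(pig, file.path(out, "Pi_gene.tsv")),
             .write_tsv(pic, file.path(out, "Pi_celltype.tsv")))
  regressions <- list()
  pw <- merge(pic[pic$age == "young", c("cluster", "Pi_c")],
              pic[pic$age == "old", c("cluster", "Pi_c")],
              by = "cluster", suffixes = c("_young", "_old"))
  if (nrow(pw) >= 3 && stats::var(pw$Pi_c_young) > 0) {
    regressions$Pi_c <- cross_age_regression(pw$Pi_c_young, pw$Pi_c_old)
  }
  gw <- merge(pig[pig$age == "young", c("gene", "Pi_g")],
              pig[pig$age == "old", c("gene", "Pi_g")],
              by = "gene", suffixes = c("_young", "_old"))
  if (nrow(gw) >= 3 && stats::var(gw$Pi_g_young) > 0) {
    regressions$Pi_g <- cross_age_regression(gw$Pi_g_young, gw$Pi_g_old)
  }

  # --- global shift -------------------------------------------------------
  shift_rows <- list()
  for (a in AGES) {
    st <- shift_test(norm, labels, age_group = a, n_perm = cfg$shift$n_perm,
                     seed = .stage_seed(seed, 300L + match(a, AGES)),
                     epsilon = cfg$shift$epsilon, min_cells = cfg$shift$min_cells)
    shift_rows[[a]] <- st$results
  }
  shift_df <- .rbind_all(shift_rows)
  files <- c(files, .write_tsv(shift_df, file.path(out, "shift_results.tsv")))
  counts_log$n_shift_rows <- nrow(shift_df)
  sw <- merge(shift_df[shift_df$age == "young", c("cluster", "shift")],
              shift_df[shift_df$age == "old", c("cluster", "shift")],
              by = "cluster", suffixes = c("_young", "_old"))
  if (nrow(sw) >= 3 && stats::var(sw$shift_young) > 0) {
    regressions$shift <- cross_age_regression(sw$shift_young, sw$shift_old)
  }
  files <- c(files, {
    p <- file.path(out, "regressions.json")
    jsonlite::write_json(regressions, p, auto_unbox = TRUE, digits = NA)
    p
  })

  # --- GSEA on Pi_g-ranked lists ------------------------------------------
  if (is.null(gene_sets) && isTRUE(cfg$synthesize)) {
    # effect genes per responsive type, plus random sets as negatives
    set.seed(.stage_seed(seed, 400L))
    universe <- rownames(cm$counts)
    gene_sets <- lapply(split(syn$effects$entries$gene,
                              syn$effects$entries$cell_type),
                        unique)
    names(gene_sets) <- paste0("response_", names(gene_sets))
    for (i in 1:5) gene_sets[[paste0("random_", i)]] <- sample(universe, 30)
  }
  gsea_rows <- list()
  if (!is.null(gene_sets)) {
    for (a in AGES) {
      tab <- pig[pig$age == a, ]
      if (nrow(tab) < cfg$gsea$min_size) next
      ranked <- stats::setNames(tab$Pi_g, tab$gene)
      gr <- preranked_gsea(ranked, gene_sets, n_perm = cfg$gsea$n_perm,
                           min_size = cfg$gsea$min_size,
                           max_size = cfg$gsea$max_size,
                           seed = .stage_seed(seed, 410L + match(a, AGES)))
      if (nrow(gr$results)) { gr$results$age <- a; gsea_rows[[a]] <- gr$results }
    }
  }
  gsea_df <- .rbind_all(gsea_rows)
  files <- c(files, .write_tsv(gsea_df, file.path(out, "gsea_results.tsv")))

  # --- diversity ----------------------------------------------------------
  if (!is.null(taxa)) {
    cd <- compare_diversity(taxa)
    files <- c(files, .write_tsv(cd$diversity, file.path(out, "diversity.tsv")),
               {
                 p <- file.path(out, "diversity_tests.json")
                 jsonlite::write_json(list(observed = cd$observed,
                                           shannon = cd$shannon,
                                           means = cd$means),
                                      p, auto_unbox = TRUE, digits = NA)
                 p
               })
  }

  # --- manifest -----------------------------------------------------------
  manifest <- list(
    package_version = as.character(utils::packageVersion("scshift")),
    seed = seed,
    parameters = unclass(cfg),
    stage_counts = counts_log,
    selected_clustering = as.list(gs$selected),
    files = data.frame(path = sub(paste0("^", out, "/?"), "", files),
                       md5 = unname(tools::md5sum(files)))
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
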