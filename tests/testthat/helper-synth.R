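# Small synthetic experiments shared across tests.

# One cluster, four age-by-condition groups, optional injected effects.
make_experiment <- function(seed, n_genes = 300, cells_per_group = 50,
                            n_cell_types = 1, effects = effect_spec(),
                            base_logmean_range = c(-2, 3), marker_boost = 2) {
  d <- experiment_design(n_cell_types = n_cell_types, n_genes = n_genes,
                         n_marker_genes_per_type = min(10, n_genes %/% (3 * n_cell_types)),
                         cells_per_group = cells_per_group, seed = seed)
  ref <- generate_reference(d, marker_boost = marker_boost,
                            base_logmean_range = base_logmean_range)
  sim <- simulate_counts(d, effects, ref)
  nm <- normalize_log(qc_filter(sim$counts, min_features = 2,
                                max_features = n_genes)$counts)
  list(design = d, reference = ref, sim = sim, norm = nm,
       truth = sim$truth, labels = nm$cell_data$true_type)
}

# Step-by-step running-sum enrichment score (independent of the hit-position
# shortcut used by the package); positive extreme preferred on exact ties.
es_running_sum <- function(ranked, set) {
  hit <- names(ranked) %in% set
  absw <- abs(ranked)
  run <- cumsum(ifelse(hit, absw / sum(absw[hit]), -1 / sum(!hit)))
  hi <- max(run); lo <- min(c(0, run))
  if (abs(hi) >= abs(lo)) hi else lo
}

# Hand step-up BH.
bh_stepup <- function(p) {
  n <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(n / (n:1) * p[o]))[ro]
}
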