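# Shared fixtures. The small benchmark keeps unit tests fast; acceptance
# tests build the full default benchmark themselves.

small_config <- function(...) {
  benchmark_config(
    n_cells = 600, n_genes = 300, n_drivers = 60, n_regulons = 3,
    targets_per_regulon = 10, depth_per_cell = 3000, ...
  )
}

.fixtures <- new.env(parent = emptyenv())

small_benchmark <- function(seed = 101) {
  key <- paste0("sim", seed)
  if (is.null(.fixtures[[key]])) {
    .fixtures[[key]] <- build_benchmark_dataset(small_config(), seed = seed)
  }
  .fixtures[[key]]
}

# filtered + normalised + corrected expression, PCA/kNN and velocity field
processed_benchmark <- function(seed = 101) {
  key <- paste0("proc", seed)
  if (is.null(.fixtures[[key]])) {
    sim <- small_benchmark(seed)
    ds <- filter_cells(sim$dataset)
    expr <- normalize_log(ds)
    expr <- regress_covariates(
      expr, ds$metadata[c("cell", "mito_fraction", "n_genes", "total_umi")]
    )
    pn <- pca_neighbors(expr, n_pcs = 20, k = 15)
    field <- velocity_field(ds, pn$neighbors)
    .fixtures[[key]] <- list(sim = sim, ds = ds, expr = expr, pn = pn,
                             field = field)
  }
  .fixtures[[key]]
}

# tiny named count matrix
toy_counts <- function(values, n_genes, n_cells) {
  matrix(values, n_genes, n_cells,
         dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                         sprintf("c%02d", seq_len(n_cells))))
}

toy_dataset <- function(n_genes = 6, n_cells = 8, seed = 5) {
  withr::with_seed(seed, {
    s <- toy_counts(rpois(n_genes * n_cells, 8), n_genes, n_cells)
    u <- toy_counts(rpois(n_genes * n_cells, 2), n_genes, n_cells)
    velocity_dataset(s, u)
  })
}

# Full default-benchmark run for the acceptance suite. One pass per seed;
# only small derived results are cached (the matrices are discarded).
benchmark_outcomes <- function(seed) {
  key <- paste0("outcome", seed)
  if (!is.null(.fixtures[[key]])) return(.fixtures[[key]])
  sim <- build_benchmark_dataset(benchmark_config(), seed = seed)
  truth <- sim$truth
  ds <- filter_cells(sim$dataset)
  expr <- normalize_log(ds)
  expr <- regress_covariates(
    expr, ds$metadata[c("cell", "mito_fraction", "n_genes", "total_umi")]
  )
  pn <- pca_neighbors(expr, n_pcs = 30, k = 30)
  field <- velocity_field(ds, pn$neighbors)

  drv <- rank_driver_genes(field, ds, "non_myogenic", top_n = 100)
  precision <- mean(drv$gene %in% truth$driver_genes)

  ann <- annotate_compartments(ds, truth$marker_config)
  # markers per compartment, with compartments taken from the cluster labels
  comp <- ifelse(ds$metadata$cluster == "non_myogenic",
                 "non_myogenic", "myogenic")
  mk_m <- find_markers(expr, comp, "myogenic", n_top = 10)
  mk_n <- find_markers(expr, comp, "non_myogenic", n_top = 10)
  sc <- coexpression_transition(
    signature_scores(expr, mk_m$gene, mk_n$gene), 0.20
  )
  info <- dplyr::inner_join(sc, truth$cells, by = "cell")
  flagged <- info$transition & info$scored

  auc <- regulon_auc(expr, truth$regulon_map, 0.05)
  active <- differential_regulon_activity(auc, ds$metadata$cluster,
                                          "non_myogenic", top_k = 30)
  start_cells <- trajectory_start_cells(sc, ds$metadata, "non_myogenic")
  drv_start <- rank_driver_genes(field, ds, "non_myogenic", top_n = 100,
                                 cells = start_cells)
  net <- build_driver_network(
    drv_start, truth$regulon_map[intersect(active$regulon,
                                           names(truth$regulon_map))]
  )
  dreg <- identify_driver_regulators(net, 1)

  lr <- lr_score(expr, ann, truth$lr_pairs[c("ligand", "receptor", "pathway")])

  .fixtures[[key]] <- list(
    precision = precision,
    n_transition = sum(flagged),
    max_coexpression = max(sc$coexpression, na.rm = TRUE),
    t_dev_flagged = median(abs(info$t[flagged] - truth$t_switch)),
    t_dev_rest = median(abs(info$t[!flagged] - truth$t_switch)),
    top_regulon = active$regulon[1],
    driver_regulators = dreg$tf,
    lr_scores = setNames(lr$score, lr$pathway),
    marker_recall_nonmyo = sum(mk_n$gene %in% truth$signature_genes_nonmyo)
  )
  .fixtures[[key]]
}
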