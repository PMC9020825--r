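#' Pipeline configuration
#'
#' All tunable parameters of the pipeline in one nested list, with defaults
#' mirroring the study design: 0.20 maximum mitochondrial fraction, top 10
#' signature markers, 0.20 coexpression transition threshold, top 100
#' drivers. Round-trips losslessly through YAML.
#'
#' @param ... Named overrides of the defaults, nested as in the return value
#'   (e.g. `qc = list(max_mito_fraction = 0.1)`).
#' @return A named list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    seed = 1L,
    simulate = unclass(benchmark_config()),
    qc = list(max_mito_fraction = 0.20, min_genes = NULL, min_counts = NULL),
    preprocess = list(n_pcs = 30, k = 30,
                      covariates = c("mito_fraction", "n_genes", "total_umi")),
    velocity = list(extreme_quantile = 0.05, min_cells = 10,
                    top_n_drivers = 100, driver_cluster = "non_myogenic"),
    signatures = list(n_top_markers = 10, transition_threshold = 0.20,
                      myogenic_group = "myogenic",
                      non_myogenic_group = "non_myogenic"),
    regulons = list(top_fraction = 0.05, top_k = 30),
    drivers = list(min_driver_targets = 1, start_tercile = TRUE),
    lr = list(pseudocount = 0.01)
  )
  overrides <- list(...)
  bad <- setdiff(names(overrides), names(defaults))
  if (length(bad)) abort(paste0("unknown config section(s): ", toString(bad)))
  merge_cfg <- function(base, val) {
    # unlike modifyList, an explicit NULL keeps the slot (meaning "off")
    for (nm in names(val)) base[nm] <- list(val[[nm]])
    base
  }
  for (nm in names(overrides)) {
    if (is.list(defaults[[nm]]) && is.list(overrides[[nm]])) {
      defaults[[nm]] <- merge_cfg(defaults[[nm]], overrides[[nm]])
    } else {
      defaults[[nm]] <- overrides[[nm]]
    }
  }
  structure(defaults, class = "pipeline_config")
}

#' Read / write a pipeline configuration
#'
#' @param path YAML file path.
#' @return `read_pipeline_config()` returns a `pipeline_config`;
#'   `write_pipeline_config()` returns `path` invisibly.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

#' @rdname read_pipeline_config
#' @param config A [pipeline_config()].
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

config_hash <- function(config) rlang::hash(unclass(config))

write_result_tsv <- function(x, path, config, extra = character()) {
  hdr <- c(
    sprintf("# velodrive config_hash=%s seed=%d", config_hash(config),
            as.integer(config$seed)),
    extra
  )
  writeLines(hdr, path)
  readr::write_tsv(x, path, append = TRUE, col_names = TRUE, progress = FALSE)
  invisible(path)
}

read_result_tsv <- function(path) {
  readr::read_tsv(path, comment = "#", col_types = readr::cols(),
                  progress = FALSE)
}

load_filtered <- function(out_dir) {
  d <- file.path(out_dir, "filtered")
  if (!dir.exists(d)) abort("missing upstream artifact: run the `qc` stage first.")
  read_velocity_dataset(file.path(d, "spliced"), file.path(d, "unspliced"),
                        file.path(d, "metadata.tsv"))
}

# normalised + covariate-corrected expression and the kNN graph; shared by
# several stages
preprocess_expression <- function(dataset, config) {
  expr <- normalize_log(dataset)
  covs <- intersect(config$preprocess$covariates, names(dataset$metadata))
  covs <- covs[vapply(covs, function(cc) {
    v <- dataset$metadata[[cc]]
    is.numeric(v) && stats::sd(v) > 0
  }, logical(1))]
  if (length(covs)) {
    expr <- regress_covariates(expr, dataset$metadata[c("cell", covs)])
  }
  pn <- pca_neighbors(expr, n_pcs = config$preprocess$n_pcs,
                      k = min(config$preprocess$k, ncol(expr) - 1))
  list(expr = expr, pca = pn)
}

run_stage_simulate <- function(config, out_dir) {
  sim <- build_benchmark_dataset(
    do.call(benchmark_config, config$simulate), seed = config$seed
  )
  write_velocity_dataset(sim$dataset, file.path(out_dir, "dataset"))
  write_truth(sim$truth, file.path(out_dir, "truth.json"))
  write_gmt(sim$truth$regulon_map, file.path(out_dir, "regulons.gmt"))
  write_lr_pairs(sim$truth$lr_pairs[c("ligand", "receptor", "pathway")],
                 file.path(out_dir, "lr_pairs.tsv"))
  invisible(sim)
}

run_stage_qc <- function(config, out_dir) {
  d <- file.path(out_dir, "dataset")
  if (!dir.exists(d)) abort("missing upstream artifact: run `simulate` (or place a dataset/) first.")
  ds <- read_velocity_dataset(file.path(d, "spliced"), file.path(d, "unspliced"),
                              file.path(d, "metadata.tsv"))
  filt <- filter_cells(ds, config$qc$max_mito_fraction,
                       config$qc$min_genes, config$qc$min_counts)
  write_velocity_dataset(filt, file.path(out_dir, "filtered"))
  write_result_tsv(attr(filt, "qc_report"), file.path(out_dir, "qc_report.tsv"),
                   config)
  invisible(filt)
}

run_stage_velocity <- function(config, out_dir) {
  ds <- load_filtered(out_dir)
  prep <- preprocess_expression(ds, config)
  field <- velocity_field(ds, prep$pca$neighbors,
                          extreme_quantile = config$velocity$extreme_quantile,
                          min_cells = config$velocity$min_cells)
  conf <- velocity_confidence(field, prep$pca$neighbors)
  write_result_tsv(field$fits, file.path(out_dir, "velocity_fits.tsv"), config)
  write_result_tsv(conf, file.path(out_dir, "velocity_confidence.tsv"), config)
  drv <- rank_driver_genes(field, ds, config$velocity$driver_cluster,
                           top_n = config$velocity$top_n_drivers)
  write_result_tsv(drv, file.path(out_dir, "driver_ranking.tsv"), config)
  invisible(list(field = field, confidence = conf, drivers = drv))
}

run_stage_signatures <- function(config, out_dir) {
  ds <- load_filtered(out_dir)
  prep <- preprocess_expression(ds, config)
  labels <- ds$metadata$cluster
  sg <- config$signatures
  mk_m <- find_markers(prep$expr, labels, sg$myogenic_group, sg$n_top_markers)
  mk_n <- find_markers(prep$expr, labels, sg$non_myogenic_group, sg$n_top_markers)
  scores <- signature_scores(prep$expr, mk_m$gene, mk_n$gene)
  scores <- coexpression_transition(scores, sg$transition_threshold)
  write_result_tsv(mk_m, file.path(out_dir, "markers_myogenic.tsv"), config)
  write_result_tsv(mk_n, file.path(out_dir, "markers_non_myogenic.tsv"), config)
  write_result_tsv(scores, file.path(out_dir, "signature_scores.tsv"), config)
  # heatmap-ready matrix: signature genes x cells, columns in transition order
  ord <- scores$cell[order(scores$order)]
  hm <- prep$expr[c(mk_m$gene, mk_n$gene), ord, drop = FALSE]
  hm_tbl <- as_tibble(as.data.frame(hm), rownames = "gene")
  write_result_tsv(hm_tbl, file.path(out_dir, "signature_matrix.tsv"), config)
  invisible(scores)
}

run_stage_regulons <- function(config, out_dir) {
  ds <- load_filtered(out_dir)
  gmt <- file.path(out_dir, "regulons.gmt")
  if (!file.exists(gmt)) abort("missing upstream artifact: regulons.gmt")
  regs <- prune_regulons(read_gmt(gmt), ds$genes)
  prep <- preprocess_expression(ds, config)
  auc <- regulon_auc(prep$expr, regs, config$regulons$top_fraction)
  diff <- differential_regulon_activity(
    auc, ds$metadata$cluster, config$signatures$non_myogenic_group,
    config$regulons$top_k
  )
  auc_tbl <- as_tibble(as.data.frame(auc), rownames = "regulon")
  write_result_tsv(auc_tbl, file.path(out_dir, "regulon_auc.tsv"), config)
  write_result_tsv(diff, file.path(out_dir, "regulon_activity.tsv"), config)
  invisible(list(auc = auc, differential = diff))
}

run_stage_drivers <- function(config, out_dir) {
  ds <- load_filtered(out_dir)
  gmt <- file.path(out_dir, "regulons.gmt")
  if (!file.exists(gmt)) abort("missing upstream artifact: regulons.gmt")
  sig_path <- file.path(out_dir, "signature_scores.tsv")
  if (!file.exists(sig_path)) abort("missing upstream artifact: run `signatures` first.")
  act_path <- file.path(out_dir, "regulon_activity.tsv")
  if (!file.exists(act_path)) abort("missing upstream artifact: run `regulons` first.")
  prep <- preprocess_expression(ds, config)
  field <- velocity_field(ds, prep$pca$neighbors,
                          extreme_quantile = config$velocity$extreme_quantile,
                          min_cells = config$velocity$min_cells)
  scores <- read_result_tsv(sig_path)
  cl <- config$velocity$driver_cluster
  cells <- NULL
  if (isTRUE(config$drivers$start_tercile)) {
    cells <- trajectory_start_cells(scores, ds$metadata, cl)
  }
  drv <- rank_driver_genes(field, ds, cl, top_n = config$velocity$top_n_drivers,
                           cells = cells)
  regs <- prune_regulons(read_gmt(gmt), ds$genes)
  active <- read_result_tsv(act_path)
  net <- build_driver_network(drv, regs[intersect(active$regulon, names(regs))])
  dreg <- identify_driver_regulators(net, config$drivers$min_driver_targets)
  rec <- cross_dataset_recurrence(setNames(list(dreg$tf), basename(out_dir)))
  nodes <- attr(net, "nodes")
  edge_tbl <- left_join(as_tibble(net), nodes, by = c(gene = "name"))
  write_result_tsv(drv, file.path(out_dir, "driver_ranking_start.tsv"), config)
  write_result_tsv(edge_tbl, file.path(out_dir, "driver_network_edges.tsv"), config)
  write_graphml(net, file.path(out_dir, "driver_network.graphml"))
  write_result_tsv(dreg, file.path(out_dir, "driver_regulators.tsv"), config)
  write_result_tsv(rec, file.path(out_dir, "recurrence.tsv"), config)
  invisible(list(drivers = drv, network = net, regulators = dreg,
                 recurrence = rec))
}

#' Cells at the start of the non-myogenic trajectory
#'
#' Operationalises "the start of the trajectory" as the cluster cells in the
#' lowest tercile of the non-myogenic signature fraction within the cluster.
#'
#' @param scores A scored [coexpression_transition()] tibble.
#' @param metadata Dataset metadata with `cell` and `cluster`.
#' @param cluster Cluster label.
#' @return Character vector of cell identifiers.
#' @export
trajectory_start_cells <- function(scores, metadata, cluster) {
  cl_cells <- metadata$cell[metadata$cluster == cluster]
  sub <- scores[scores$cell %in% cl_cells & scores$scored, ]
  if (nrow(sub) == 0) return(cl_cells)
  cut <- quantile(sub$s_n, 1 / 3, names = FALSE)
  sub$cell[sub$s_n <= cut]
}

run_stage_lr <- function(config, out_dir) {
  ds <- load_filtered(out_dir)
  pairs_path <- file.path(out_dir, "lr_pairs.tsv")
  if (!file.exists(pairs_path)) abort("missing upstream artifact: lr_pairs.tsv")
  pairs <- read_lr_pairs(pairs_path)
  expr <- normalize_log(ds)
  markers <- list(ligand = "Pdgfa_like",
                  myogenic_genes = c("Myf5_like", "Myod_like", "Myog_like"))
  if (!all(c(markers$ligand, markers$myogenic_genes) %in% ds$genes) &&
      "cluster" %in% names(ds$metadata)) {
    # fall back to cluster labels when the marker genes are absent
    ann <- tibble(
      cell = ds$metadata$cell,
      compartment = ifelse(ds$metadata$cluster == "non_myogenic",
                           "non_myogenic", "myogenic")
    )
  } else {
    ann <- annotate_compartments(ds, markers)
  }
  res <- lr_score(expr, ann, pairs, config$lr$pseudocount)
  write_result_tsv(res, file.path(out_dir, "lr_scores.tsv"), config)
  invisible(res)
}

#' Run the pipeline
#'
#' Chains the stages in order: simulate, qc, velocity, signatures, regulons,
#' drivers, lr. Individual stages can be run alone provided their upstream
#' artifacts exist in `out_dir`.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @param stages Character vector of stages, or `"all"`.
#' @return Invisibly, a list of the last stage results.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir,
                         stages = "all") {
  all_stages <- c("simulate", "qc", "velocity", "signatures", "regulons",
                  "drivers", "lr")
  if (identical(stages, "all")) stages <- all_stages
  bad <- setdiff(stages, all_stages)
  if (length(bad)) abort(paste0("unknown stage(s): ", toString(bad)))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  runners <- list(
    simulate = run_stage_simulate, qc = run_stage_qc,
    velocity = run_stage_velocity, signatures = run_stage_signatures,
    regulons = run_stage_regulons, drivers = run_stage_drivers,
    lr = run_stage_lr
  )
  res <- list()
  for (st in all_stages[all_stages %in% stages]) {
    inform(sprintf("[velodrive] stage %s (seed %d)", st, as.integer(config$seed)))
    res[[st]] <- runners[[st]](config, out_dir)
  }
  invisible(res)
}

#' Command-line entry point
#'
#' Thin argument parser over [run_pipeline()], used by the bundled
#' `velodrive` Rscript. Subcommands: `simulate`, `qc`, `velocity`,
#' `signatures`, `regulons`, `drivers`, `lr`, `all`. Flags: `--config
#' <yaml>`, `--out <dir>` (required), `--seed <int>`.
#'
#' @param args Character vector of command-line arguments.
#' @return Exit status, 0 on success (invisibly).
#' @export
velodrive_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: velodrive <simulate|qc|velocity|signatures|regulons|drivers|lr|all>",
    "[--config cfg.yaml] --out DIR [--seed N]"
  )
  fail <- function(msg) { message(msg, "\n", usage); return(invisible(1L)) }
  if (length(args) < 1) return(fail("no subcommand given"))
  sub <- args[[1]]
  if (!sub %in% c("simulate", "qc", "velocity", "signatures", "regulons",
                  "drivers", "lr", "all")) {
    return(fail(paste0("unknown subcommand: ", sub)))
  }
  opts <- list(config = NULL, out = NULL, seed = NULL)
  rest <- args[-1]
  i <- 1
  while (i <= length(rest)) {
    key <- rest[[i]]
    if (!key %in% c("--config", "--out", "--seed")) {
      return(fail(paste0("unknown flag: ", key)))
    }
    if (i == length(rest)) return(fail(paste0("flag ", key, " needs a value")))
    opts[[sub("^--", "", key)]] <- rest[[i + 1]]
    i <- i + 2
  }
  if (is.null(opts$out)) return(fail("--out is required"))
  config <- if (is.null(opts$config)) pipeline_config() else
    read_pipeline_config(opts$config)
  if (!is.null(opts$seed)) config$seed <- as.integer(opts$seed)
  status <- tryCatch({
    run_pipeline(config, opts$out, stages = if (sub == "all") "all" else sub)
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
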