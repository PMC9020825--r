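#' Build a TF-to-driver-gene bipartite network
#'
#' Connects each active regulon's transcription factor to every one of its
#' targets that appears in the driver-gene list: an edge (TF, gene) exists
#' iff the gene is both a regulon target of the TF and a ranked driver.
#' Nodes are annotated as `"Active regulon"` (TFs) or `"driver gene"`.
#'
#' @param drivers Character vector of driver genes (e.g. the `gene` column
#'   of a [rank_driver_genes()] result), or a `driver_ranking` tibble.
#' @param regulons Named list of target vectors for the active regulons.
#' @return A tibble of class `driver_network` with columns `tf`, `gene`;
#'   attributes `nodes` (tibble `name`, `type`) and `tf_edge_counts`.
#' @export
build_driver_network <- function(drivers, regulons) {
  if (is.data.frame(drivers)) drivers <- drivers$gene
  drivers <- unique(drivers)
  edges <- purrr::imap(regulons, function(targets, tf) {
    hits <- intersect(targets, drivers)
    if (length(hits)) tibble(tf = tf, gene = hits) else NULL
  })
  edges <- bind_rows(edges)
  if (nrow(edges) == 0) edges <- tibble(tf = character(), gene = character())
  edges <- dplyr::distinct(edges)
  nodes <- bind_rows(
    tibble(name = unique(edges$tf), type = "Active regulon"),
    tibble(name = setdiff(unique(edges$gene), unique(edges$tf)),
           type = "driver gene")
  )
  counts <- table(factor(edges$tf, levels = names(regulons)))
  attr(edges, "nodes") <- nodes
  attr(edges, "tf_edge_counts") <- setNames(as.integer(counts), names(regulons))
  class(edges) <- c("driver_network", class(edges))
  edges
}

#' Identify driver regulators
#'
#' The driver regulators of a dataset are the transcription factors whose
#' active regulon contains at least `min_driver_targets` driver genes.
#'
#' @param network A [build_driver_network()] result.
#' @param min_driver_targets Minimum TF-to-driver edges (default 1).
#' @return A tibble `tf`, `n_driver_targets`, sorted by decreasing edge
#'   count then name.
#' @export
identify_driver_regulators <- function(network, min_driver_targets = 1) {
  counts <- attr(network, "tf_edge_counts")
  if (is.null(counts)) {
    counts <- table(network$tf)
    counts <- setNames(as.integer(counts), names(counts))
  }
  out <- tibble(tf = names(counts), n_driver_targets = unname(counts))
  out <- filter(out, .data$n_driver_targets >= min_driver_targets)
  arrange(out, desc(.data$n_driver_targets), .data$tf)
}

#' Cross-dataset recurrence of driver regulators
#'
#' Combines the per-dataset driver-regulator sets into a presence/absence
#' matrix and counts, for each TF, the number of datasets in which it was
#' called ("frequency of appearance"). TFs are sorted by decreasing
#' frequency, then name.
#'
#' @param tf_sets A named list of character vectors (one per dataset; names
#'   become column names) or of [identify_driver_regulators()] tibbles.
#' @return A tibble of class `recurrence_table`: `tf`, one logical column
#'   per dataset, and `frequency` (the row sum).
#' @export
cross_dataset_recurrence <- function(tf_sets) {
  if (length(tf_sets) == 0) abort("need at least one dataset.")
  tf_sets <- purrr::map(tf_sets, function(x) {
    if (is.data.frame(x)) x$tf else as.character(x)
  })
  if (is.null(names(tf_sets)) || any(!nzchar(names(tf_sets)))) {
    names(tf_sets) <- paste0("dataset", seq_along(tf_sets))
  }
  all_tfs <- sort(unique(unlist(tf_sets)))
  presence <- vapply(tf_sets, function(s) all_tfs %in% s,
                     logical(length(all_tfs)))
  presence <- matrix(presence, nrow = length(all_tfs),
                     dimnames = list(all_tfs, names(tf_sets)))
  out <- as_tibble(presence)
  out$tf <- all_tfs
  out$frequency <- as.integer(rowSums(presence))
  out <- select(out, "tf", dplyr::all_of(names(tf_sets)), "frequency")
  out <- arrange(out, desc(.data$frequency), .data$tf)
  class(out) <- c("recurrence_table", class(out))
  out
}

#' @method glance recurrence_table
#' @export
glance.recurrence_table <- function(x, ...) {
  mx <- max(x$frequency)
  tibble(
    n_tfs = nrow(x),
    n_datasets = ncol(x) - 2L,
    max_frequency = mx,
    n_at_max = sum(x$frequency == mx),
    total_presence = sum(x$frequency)
  )
}

#' Convert a driver network to an igraph object
#'
#' @param network A [build_driver_network()] result.
#' @return An igraph graph with a `type` vertex attribute
#'   (`"Active regulon"` / `"driver gene"`).
#' @export
as_igraph <- function(network) {
  nodes <- attr(network, "nodes")
  igraph::graph_from_data_frame(
    as.data.frame(network[c("tf", "gene")]),
    directed = TRUE,
    vertices = as.data.frame(nodes)
  )
}

#' Export a driver network as GraphML
#'
#' @param network A [build_driver_network()] result.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(network, path) {
  igraph::write_graph(as_igraph(network), path, format = "graphml")
  invisible(path)
}

#' Bundled driver-gene lists by stage
#'
#' The five published top-100 driver-gene lists for the cranial mesoderm
#' bifurcation study stages (E10.5 anterior somites; E11.5 EOM myogenic and
#' non-myogenic; E12.5 and E14.5 non-myogenic), one column per
#' stage/cluster.
#'
#' @return A tibble with five character columns of equal length.
#' @export
driver_gene_tables <- function() {
  readr::read_tsv(
    system.file("extdata", "driver_genes_by_stage.tsv", package = "velodrive"),
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
}

#' Bundled driver-regulator presence/absence calls
#'
#' Presence (1) or absence (0) of each transcription factor as a driver
#' regulator of non-myogenic fate in the four embryonic-stage datasets
#' (E10.5-E14.5).
#'
#' @return A tibble `tf`, `E10.5`, `E11.5`, `E12.5`, `E14.5`.
#' @export
driver_regulator_presence <- function() {
  readr::read_tsv(
    system.file("extdata", "driver_regulator_presence.tsv", package = "velodrive"),
    col_types = readr::cols(tf = readr::col_character(),
                            .default = readr::col_integer()),
    progress = FALSE
  )
}
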