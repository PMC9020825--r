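#' Paired spliced/unspliced single-cell dataset
#'
#' The central container consumed by every pipeline stage: a spliced and an
#' unspliced gene-by-cell count matrix sharing identical gene and cell
#' identifiers, plus a per-cell metadata tibble. Matrices are stored sparse;
#' genes and cells are addressed by name, never by position.
#'
#' @param spliced,unspliced Gene-by-cell matrices of non-negative counts with
#'   identical dimnames (genes as rownames, cell barcodes as colnames).
#'   Anything coercible to `dgCMatrix` is accepted.
#' @param metadata A data frame with one row per cell. Must contain a `cell`
#'   column matching the matrix colnames; typical columns are `cluster`,
#'   `total_umi`, `n_genes`, `mito_fraction` and optional embedding
#'   coordinates `emb_1`, `emb_2`. If `NULL`, a minimal metadata table
#'   (cell, total_umi, n_genes) is derived from the spliced counts.
#'
#' @return An object of class `velocity_dataset`: a list with elements
#'   `spliced`, `unspliced` (sparse matrices), `genes`, `cells` (character)
#'   and `metadata` (tibble).
#' @export
#' @examples
#' s <- matrix(rpois(12, 4), 3, 4,
#'             dimnames = list(paste0("g", 1:3), paste0("c", 1:4)))
#' u <- matrix(rpois(12, 1), 3, 4, dimnames = dimnames(s))
#' velocity_dataset(s, u)
velocity_dataset <- function(spliced, unspliced, metadata = NULL) {
  spliced <- as_sparse_counts(spliced, "spliced")
  unspliced <- as_sparse_counts(unspliced, "unspliced")
  if (is.null(rownames(spliced)) || is.null(colnames(spliced))) {
    abort("`spliced` must carry gene rownames and cell colnames.")
  }
  if (!identical(dim(spliced), dim(unspliced))) {
    abort("spliced and unspliced layers must have identical dimensions.")
  }
  if (!identical(rownames(spliced), rownames(unspliced)) ||
      !identical(colnames(spliced), colnames(unspliced))) {
    # reconcile by identifier, not position
    if (!setequal(rownames(spliced), rownames(unspliced)) ||
        !setequal(colnames(spliced), colnames(unspliced))) {
      abort("spliced and unspliced layers must cover the same genes and cells.")
    }
    unspliced <- unspliced[rownames(spliced), colnames(spliced), drop = FALSE]
  }
  if (anyDuplicated(rownames(spliced)) || anyDuplicated(colnames(spliced))) {
    abort("gene and cell identifiers must be unique.")
  }
  if (is.null(metadata)) {
    metadata <- tibble(
      cell = colnames(spliced),
      total_umi = as.numeric(Matrix::colSums(spliced)),
      n_genes = as.numeric(Matrix::colSums(spliced > 0))
    )
  }
  metadata <- as_tibble(metadata)
  if (!"cell" %in% names(metadata)) {
    abort("`metadata` must contain a `cell` column.")
  }
  if (!setequal(metadata$cell, colnames(spliced)) ||
      anyDuplicated(metadata$cell)) {
    abort("`metadata$cell` must match the matrix cell identifiers exactly.")
  }
  metadata <- metadata[match(colnames(spliced), metadata$cell), , drop = FALSE]
  structure(
    list(
      spliced = spliced,
      unspliced = unspliced,
      genes = rownames(spliced),
      cells = colnames(spliced),
      metadata = metadata
    ),
    class = "velocity_dataset"
  )
}

as_sparse_counts <- function(x, layer) {
  m <- as(as(as(x, "dMatrix"), "generalMatrix"), "CsparseMatrix")
  if (any(m@x < 0)) abort(sprintf("`%s` counts must be non-negative.", layer))
  m
}

#' @export
print.velocity_dataset <- function(x, ...) {
  cat(sprintf(
    "<velocity_dataset> %d genes x %d cells (spliced + unspliced layers)\n",
    length(x$genes), length(x$cells)
  ))
  if ("cluster" %in% names(x$metadata)) {
    tab <- table(x$metadata$cluster)
    cat("clusters:", paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.velocity_dataset <- function(x) c(length(x$genes), length(x$cells))

#' Subset a velocity dataset by gene and/or cell identifiers
#'
#' Both layers and the metadata are subset consistently.
#'
#' @param dataset A [velocity_dataset()].
#' @param genes,cells Character vectors of identifiers to keep (`NULL` keeps
#'   all).
#' @return A `velocity_dataset`.
#' @export
subset_dataset <- function(dataset, genes = NULL, cells = NULL) {
  stopifnot(inherits(dataset, "velocity_dataset"))
  genes <- genes %||% dataset$genes
  cells <- cells %||% dataset$cells
  missing_g <- setdiff(genes, dataset$genes)
  missing_c <- setdiff(cells, dataset$cells)
  if (length(missing_g)) abort(paste0("unknown genes: ", toString(head(missing_g, 5))))
  if (length(missing_c)) abort(paste0("unknown cells: ", toString(head(missing_c, 5))))
  if (length(cells) == 0) abort("subset would retain no cells")
  velocity_dataset(
    dataset$spliced[genes, cells, drop = FALSE],
    dataset$unspliced[genes, cells, drop = FALSE],
    dataset$metadata[match(cells, dataset$metadata$cell), , drop = FALSE]
  )
}
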