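mm_path <- function(dir) {
  for (f in c("matrix.mtx", "matrix.mtx.gz")) {
    p <- file.path(dir, f)
    if (file.exists(p)) return(p)
  }
  abort(paste0("no matrix.mtx[.gz] in ", dir))
}

tsv_path <- function(dir, stem) {
  for (f in c(paste0(stem, ".tsv"), paste0(stem, ".tsv.gz"))) {
    p <- file.path(dir, f)
    if (file.exists(p)) return(p)
  }
  abort(paste0("no ", stem, ".tsv[.gz] in ", dir))
}

read_layer <- function(dir) {
  path <- mm_path(dir)
  con <- if (grepl("\\.gz$", path)) gzfile(path) else path
  m <- tryCatch(
    Matrix::readMM(con),
    error = function(e) abort(paste0("malformed Matrix Market file ", path, ": ",
                                     conditionMessage(e)))
  )
  genes <- readLines(tsv_path(dir, "features"))
  genes <- vapply(strsplit(genes, "\t"), `[[`, character(1), 1)
  cells <- readLines(tsv_path(dir, "barcodes"))
  if (nrow(m) != length(genes) || ncol(m) != length(cells)) {
    abort(sprintf("layer %s: matrix is %d x %d but %d features / %d barcodes listed.",
                  dir, nrow(m), ncol(m), length(genes), length(cells)))
  }
  m <- as(as(m, "generalMatrix"), "CsparseMatrix")
  dimnames(m) <- list(genes, cells)
  m
}

#' Read a paired spliced/unspliced dataset from disk
#'
#' Each layer lives in its own 10x-style directory holding `matrix.mtx`
#' (optionally gzipped, genes x cells), `features.tsv` and `barcodes.tsv`.
#' The two layers are aligned by identifier, not position; a barcode or
#' feature set mismatch is an error listing the first differences.
#'
#' @param spliced_dir,unspliced_dir Layer directories.
#' @param metadata_path Optional cell metadata TSV with a `cell` column.
#' @return A [velocity_dataset()].
#' @export
read_velocity_dataset <- function(spliced_dir, unspliced_dir,
                                  metadata_path = NULL) {
  s <- read_layer(spliced_dir)
  u <- read_layer(unspliced_dir)
  for (what in c("row", "col")) {
    a <- dimnames(s)[[if (what == "row") 1 else 2]]
    b <- dimnames(u)[[if (what == "row") 1 else 2]]
    if (!setequal(a, b)) {
      diff <- c(setdiff(a, b), setdiff(b, a))
      abort(sprintf("layer %s mismatch between spliced and unspliced: %s",
                    if (what == "row") "feature" else "barcode",
                    toString(head(diff, 5))))
    }
  }
  u <- u[rownames(s), colnames(s), drop = FALSE]
  metadata <- NULL
  if (!is.null(metadata_path)) {
    metadata <- readr::read_tsv(metadata_path, comment = "#",
                                col_types = readr::cols(), progress = FALSE)
  }
  velocity_dataset(s, u, metadata)
}

write_layer <- function(m, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  writeLines(rownames(m), file.path(dir, "features.tsv"))
  writeLines(colnames(m), file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

#' Write a dataset as paired 10x-style layer directories
#'
#' Emits `spliced/` and `unspliced/` directories (Matrix Market triplet +
#' features/barcodes TSVs) and a `metadata.tsv` under `dir`.
#'
#' @param dataset A [velocity_dataset()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_velocity_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "velocity_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_layer(dataset$spliced, file.path(dir, "spliced"))
  write_layer(dataset$unspliced, file.path(dir, "unspliced"))
  readr::write_tsv(dataset$metadata, file.path(dir, "metadata.tsv"),
                   progress = FALSE)
  invisible(dir)
}

#' Write simulation ground truth as JSON
#'
#' Serialises the planted truth (drivers, regulons, signatures, L-R pairs,
#' per-cell branch assignments, kinetic parameters); the latent abundance
#' matrices are not written.
#'
#' @param truth A `simulation_truth` from [build_benchmark_dataset()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  out <- truth[setdiff(names(truth), "latent")]
  out$driver_direction <- as.list(out$driver_direction)
  jsonlite::write_json(out, path, dataframe = "columns", auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read simulation ground truth from JSON
#'
#' @param path Path written by [write_truth()].
#' @return A `simulation_truth` list (without latent matrices).
#' @export
read_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$regulon_map <- purrr::map(x$regulon_map, as.character)
  x$driver_direction <- unlist(x$driver_direction)
  x$cells <- as_tibble(x$cells)
  x$lr_pairs <- as_tibble(x$lr_pairs)
  x$params <- as_tibble(x$params)
  structure(x, class = "simulation_truth")
}
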