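#' Filter cells on QC covariates
#'
#' Removes cells whose mitochondrial fraction exceeds `max_mito_fraction`
#' (strictly greater than, so a cell sitting exactly at the threshold is
#' retained), and optionally cells below minimum detected-gene or total-count
#' thresholds. Both count layers and the metadata are subset consistently.
#' Filtering is idempotent.
#'
#' @param dataset A [velocity_dataset()]. Needs a `mito_fraction` metadata
#'   column, or mito-prefixed (`mt-`) genes from which it can be computed.
#' @param max_mito_fraction Maximum tolerated mitochondrial count fraction
#'   (default 0.20).
#' @param min_genes,min_counts Optional minimum detected genes / total UMI
#'   per cell (default off).
#' @return The filtered `velocity_dataset`, with a `qc_report` attribute: a
#'   tibble of removed cells and the reason each was removed.
#' @export
filter_cells <- function(dataset, max_mito_fraction = 0.20,
                         min_genes = NULL, min_counts = NULL) {
  stopifnot(inherits(dataset, "velocity_dataset"))
  if (max_mito_fraction < 0 || max_mito_fraction > 1) {
    abort("`max_mito_fraction` must lie in [0, 1].")
  }
  md <- dataset$metadata
  if (!"mito_fraction" %in% names(md)) {
    mito <- grepl("^mt-", dataset$genes)
    if (!any(mito)) abort("no `mito_fraction` column and no `mt-` genes to compute it.")
    tot <- Matrix::colSums(dataset$spliced)
    md$mito_fraction <- ifelse(
      tot > 0, Matrix::colSums(dataset$spliced[mito, , drop = FALSE]) / tot, 0
    )
  }
  reason <- rep(NA_character_, nrow(md))
  reason[md$mito_fraction > max_mito_fraction] <- "mito_fraction"
  if (!is.null(min_genes)) {
    reason[is.na(reason) & md$n_genes < min_genes] <- "min_genes"
  }
  if (!is.null(min_counts)) {
    reason[is.na(reason) & md$total_umi < min_counts] <- "min_counts"
  }
  keep <- md$cell[is.na(reason)]
  if (length(keep) == 0) abort("all cells were filtered out.")
  out <- subset_dataset(dataset, cells = keep)
  attr(out, "qc_report") <- tibble(
    cell = md$cell[!is.na(reason)],
    reason = reason[!is.na(reason)]
  )
  out
}

#' Median-depth log normalisation
#'
#' Scales each cell's spliced counts to the median total depth of the
#' dataset, then applies `log1p`. Deterministic; cells with proportional
#' count profiles map to identical normalised profiles.
#'
#' @param dataset A [velocity_dataset()], or a genes-by-cells count matrix.
#' @return A dense genes-by-cells matrix of normalised log expression.
#' @export
normalize_log <- function(dataset) {
  counts <- if (inherits(dataset, "velocity_dataset")) dataset$spliced else dataset
  tot <- Matrix::colSums(counts)
  if (any(tot == 0)) {
    bad <- colnames(counts)[tot == 0]
    abort(paste0("zero-depth cell(s): ", toString(head(bad, 5))))
  }
  target <- median(tot)
  out <- as.matrix(counts %*% Matrix::Diagonal(x = target / tot))
  dimnames(out) <- dimnames(counts)
  log1p(out)
}

#' Regress per-cell covariates out of expression
#'
#' Fits, per gene, an ordinary least-squares model of expression on the
#' given covariates (with intercept) and returns the residuals with the
#' gene mean restored, so per-gene means are unchanged and residuals are
#' orthogonal to every centred covariate. Typical covariates are a cell-cycle
#' score, mitochondrial fraction, detected genes and total UMI.
#'
#' @param expr Genes-by-cells matrix (normalised log expression).
#' @param covariates A data frame or matrix of per-cell covariates, rows
#'   aligned with the columns of `expr` (a `cell` column, if present, is used
#'   to align by identifier).
#' @return A genes-by-cells matrix of corrected expression.
#' @export
regress_covariates <- function(expr, covariates) {
  covariates <- as.data.frame(covariates)
  if ("cell" %in% names(covariates)) {
    if (!setequal(covariates$cell, colnames(expr))) {
      abort("covariate rows do not match the expression cells.")
    }
    covariates <- covariates[match(colnames(expr), covariates$cell), , drop = FALSE]
    covariates$cell <- NULL
  }
  if (nrow(covariates) != ncol(expr)) {
    abort("`covariates` must have one row per cell.")
  }
  x <- cbind(`(Intercept)` = 1, as.matrix(covariates))
  qr_x <- qr(x)
  if (qr_x$rank < ncol(x)) {
    dropped <- colnames(x)[qr_x$pivot[(qr_x$rank + 1):ncol(x)]]
    abort(paste0("collinear covariate columns: ", toString(dropped)))
  }
  # residuals for all genes at once: E - E X (X'X)^{-1} X'
  beta <- qr.coef(qr_x, Matrix::t(expr))
  fitted <- x %*% beta
  resid <- expr - Matrix::t(fitted)
  resid + rowMeans(expr)
}

#' PCA embedding and k-nearest-neighbour graph
#'
#' Centres the expression matrix, projects cells onto the top principal
#' components, and builds a Euclidean k-nearest-neighbour graph on the
#' embedding (self excluded; exact, deterministic).
#'
#' @param expr Genes-by-cells matrix of (corrected) normalised expression.
#' @param n_pcs Number of principal components (`< min(genes, cells)`).
#' @param k Neighbours per cell (`< cells`).
#' @return A list with `embedding` (cells x n_pcs matrix), `neighbors`
#'   (cells x k integer matrix of neighbour column indices, ordered by
#'   distance) and `graph` (sparse cells x cells adjacency, `graph[i, j] = 1`
#'   if j is a neighbour of i).
#' @export
pca_neighbors <- function(expr, n_pcs = 30, k = 30) {
  nc <- ncol(expr)
  if (k >= nc) abort("`k` must be smaller than the number of cells.")
  n_pcs <- min(n_pcs, nc - 1, nrow(expr))
  pc <- prcomp(Matrix::t(expr), center = TRUE, scale. = FALSE, rank. = n_pcs)
  emb <- pc$x
  rownames(emb) <- colnames(expr)
  nn <- knn_index(emb, k)
  graph <- Matrix::sparseMatrix(
    i = rep(seq_len(nc), each = k),
    j = as.vector(Matrix::t(nn)),
    x = 1, dims = c(nc, nc),
    dimnames = list(colnames(expr), colnames(expr))
  )
  list(embedding = emb, neighbors = nn, graph = graph)
}

# exact kNN by full distance computation; rows of `emb` are cells
knn_index <- function(emb, k) {
  n <- nrow(emb)
  g <- emb %*% t(emb)
  sq <- diag(g)
  d2 <- outer(sq, sq, `+`) - 2 * g
  diag(d2) <- Inf
  nn <- t(apply(d2, 1, function(row) order(row)[seq_len(k)]))
  dimnames(nn) <- NULL
  nn
}
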