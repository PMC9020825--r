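#' Per-layer depth normalisation
#'
#' Scales each layer (spliced, unspliced) independently to its median cell
#' depth. Velocity fits run on these (optionally kNN-smoothed) abundances;
#' no log transform is applied, since the steady-state fit is linear in
#' (u, s).
#'
#' @param dataset A [velocity_dataset()].
#' @return A list with dense matrices `u` and `s`.
#' @export
layer_normalize <- function(dataset) {
  stopifnot(inherits(dataset, "velocity_dataset"))
  norm1 <- function(m) {
    tot <- Matrix::colSums(m)
    f <- ifelse(tot > 0, median(tot[tot > 0]) / tot, 0)
    out <- as.matrix(m %*% Matrix::Diagonal(x = f))
    dimnames(out) <- dimnames(m)
    out
  }
  list(u = norm1(dataset$unspliced), s = norm1(dataset$spliced))
}

#' First-order kNN smoothing
#'
#' Replaces each cell's profile by the mean over the cell and its k nearest
#' neighbours, the usual pooling step before phase-portrait fits.
#'
#' @param mat Genes-by-cells matrix.
#' @param neighbors Cells-by-k integer matrix of neighbour indices, as from
#'   [pca_neighbors()].
#' @return The smoothed matrix, same shape.
#' @export
smooth_knn <- function(mat, neighbors) {
  nc <- ncol(mat)
  stopifnot(nrow(neighbors) == nc)
  k <- ncol(neighbors)
  a <- Matrix::sparseMatrix(
    i = c(seq_len(nc), rep(seq_len(nc), k)),
    j = c(seq_len(nc), as.vector(neighbors)),
    x = 1, dims = c(nc, nc)
  )
  w <- a / Matrix::rowSums(a)
  out <- as.matrix(mat %*% Matrix::t(w))
  dimnames(out) <- dimnames(mat)
  out
}

#' Steady-state degradation-rate fit per gene
#'
#' Estimates, for each gene, the steady-state ratio `gamma_hat` (degradation
#' over splicing rate) as the slope of a zero-intercept least-squares fit of
#' unspliced on spliced abundance, restricted to cells in the lower and
#' upper `extreme_quantile` of the gene's spliced abundance — the cells most
#' likely to sit at the extremes of the phase portrait, near steady state.
#' Genes detected in fewer than `min_cells` cells are flagged unfit and
#' excluded from velocity.
#'
#' @param u,s Genes-by-cells matrices of (smoothed, normalised) unspliced
#'   and spliced abundance.
#' @param extreme_quantile Quantile per tail used for the fit (default 0.05).
#' @param min_cells Minimum number of expressing cells (default 10).
#' @return A tibble of class `gamma_fits`: `gene`, `gamma_hat`, `n_expressed`,
#'   `fit_ok`.
#' @export
fit_gamma <- function(u, s, extreme_quantile = 0.05, min_cells = 10) {
  stopifnot(identical(dim(u), dim(s)))
  if (extreme_quantile <= 0 || extreme_quantile > 0.5) {
    abort("`extreme_quantile` must lie in (0, 0.5].")
  }
  ng <- nrow(s)
  gamma_hat <- rep(NA_real_, ng)
  n_expr <- integer(ng)
  for (g in seq_len(ng)) {
    sg <- s[g, ]; ug <- u[g, ]
    expressed <- sg > 0 | ug > 0
    n_expr[g] <- sum(expressed)
    if (n_expr[g] < min_cells) next
    q <- quantile(sg, c(extreme_quantile, 1 - extreme_quantile), names = FALSE)
    sel <- sg <= q[1] | sg >= q[2]
    ss2 <- sum(sg[sel]^2)
    if (ss2 == 0) next
    gamma_hat[g] <- sum(ug[sel] * sg[sel]) / ss2
  }
  out <- tibble(
    gene = rownames(s) %||% as.character(seq_len(ng)),
    gamma_hat = gamma_hat,
    n_expressed = n_expr,
    fit_ok = !is.na(gamma_hat) & gamma_hat > 0
  )
  class(out) <- c("gamma_fits", class(out))
  out
}

#' @method glance gamma_fits
#' @export
glance.gamma_fits <- function(x, ...) {
  tibble(
    n_genes = nrow(x),
    n_fit = sum(x$fit_ok),
    median_gamma = median(x$gamma_hat[x$fit_ok])
  )
}

#' RNA velocity from fitted kinetics
#'
#' The velocity of gene g in cell c is the residual from the steady-state
#' line, `v = u - gamma_hat * s`. Positive velocity means the unspliced pool
#' exceeds its steady-state expectation: the gene is being induced.
#' Only genes with a valid fit are included.
#'
#' @param u,s Genes-by-cells abundance matrices (smoothed recommended).
#' @param fits A [fit_gamma()] result.
#' @return A genes-by-cells velocity matrix over the fitted genes.
#' @export
compute_velocity <- function(u, s, fits) {
  keep <- fits$gene[fits$fit_ok]
  if (length(keep) == 0) abort("no genes with a valid kinetics fit.")
  gam <- setNames(fits$gamma_hat, fits$gene)[keep]
  u[keep, , drop = FALSE] - gam * s[keep, , drop = FALSE]
}

#' Velocity field for a dataset
#'
#' Convenience wrapper: per-layer depth normalisation, kNN smoothing,
#' steady-state fits and the velocity matrix in one call.
#'
#' @param dataset A [velocity_dataset()].
#' @param neighbors Neighbour index matrix from [pca_neighbors()] (or `NULL`
#'   to skip smoothing).
#' @param extreme_quantile,min_cells Passed to [fit_gamma()].
#' @param exclude_pattern Regex of genes excluded from kinetics fitting;
#'   defaults to mitochondrial genes (`"^mt-"`), whose transcripts do not
#'   follow nuclear splicing dynamics.
#' @return A list of class `velocity_field` with `v`, `u`, `s` (smoothed
#'   abundances over all genes) and `fits`.
#' @export
velocity_field <- function(dataset, neighbors = NULL,
                           extreme_quantile = 0.05, min_cells = 10,
                           exclude_pattern = "^mt-") {
  if (!is.null(exclude_pattern)) {
    keep <- dataset$genes[!grepl(exclude_pattern, dataset$genes)]
    if (length(keep) < length(dataset$genes)) {
      dataset <- subset_dataset(dataset, genes = keep)
    }
  }
  layers <- layer_normalize(dataset)
  if (!is.null(neighbors)) {
    layers$u <- smooth_knn(layers$u, neighbors)
    layers$s <- smooth_knn(layers$s, neighbors)
  }
  fits <- fit_gamma(layers$u, layers$s, extreme_quantile, min_cells)
  v <- compute_velocity(layers$u, layers$s, fits)
  structure(list(v = v, u = layers$u, s = layers$s, fits = fits),
            class = "velocity_field")
}

#' @export
print.velocity_field <- function(x, ...) {
  cat(sprintf("<velocity_field> %d fitted genes x %d cells\n",
              nrow(x$v), ncol(x$v)))
  invisible(x)
}

cosine_to_neighbors <- function(ref, target, neighbors) {
  # score[i, j] = cosine(ref[, i], target[, j] - shift)  for j in N(i)
  nc <- ncol(ref)
  k <- ncol(neighbors)
  ii <- rep(seq_len(nc), k)
  jj <- as.vector(neighbors)
  scores <- numeric(length(ii))
  for (i in seq_len(nc)) {
    vi <- ref[, i]
    nrm_v <- sqrt(sum(vi^2))
    idx <- i + nc * (seq_len(k) - 1)
    if (nrm_v == 0) { scores[idx] <- 0; next }
    d <- target[, jj[idx], drop = FALSE] - target[, i]
    nrm_d <- sqrt(.colSums(d^2, nrow(d), ncol(d)))
    sc <- as.vector(crossprod(d, vi)) / (nrm_v * nrm_d)
    sc[nrm_d == 0] <- 0
    scores[idx] <- sc
  }
  list(i = ii, j = jj, x = scores)
}

#' Velocity transition graph
#'
#' For each cell i and each of its k nearest neighbours j, the cosine
#' similarity between the cell's velocity vector and the displacement
#' `x_j - x_i` in (smoothed spliced) gene space, restricted to fitted genes.
#' Scores near 1 mean the velocity points at that neighbour. Cells with zero
#' velocity get score 0.
#'
#' @param field A [velocity_field()] (or a velocity matrix; then `x` must be
#'   given).
#' @param neighbors Neighbour index matrix from [pca_neighbors()].
#' @param x Optional genes-by-cells coordinate matrix; defaults to the
#'   field's smoothed spliced abundance over fitted genes.
#' @return A sparse cells-by-cells matrix with the kNN sparsity pattern.
#' @export
velocity_graph <- function(field, neighbors, x = NULL) {
  if (inherits(field, "velocity_field")) {
    v <- field$v
    x <- x %||% field$s[rownames(v), , drop = FALSE]
  } else {
    v <- field
    if (is.null(x)) abort("`x` is required when `field` is a bare matrix.")
    x <- x[rownames(v), , drop = FALSE]
  }
  nc <- ncol(v)
  stopifnot(nrow(neighbors) == nc)
  tri <- cosine_to_neighbors(v, x, neighbors)
  Matrix::sparseMatrix(
    i = tri$i, j = tri$j, x = tri$x, dims = c(nc, nc),
    dimnames = list(colnames(v), colnames(v))
  )
}

#' Per-cell velocity confidence
#'
#' The mean cosine similarity between a cell's velocity vector and those of
#' its k nearest neighbours. Coherent flow gives confidence near 1;
#' branchpoints, where neighbouring cells pull in different directions,
#' score low. Cells without neighbours are reported as missing.
#'
#' @param field A [velocity_field()] or a genes-by-cells velocity matrix.
#' @param neighbors Neighbour index matrix (rows may contain `NA` for
#'   missing neighbours).
#' @return A tibble `cell`, `confidence`.
#' @export
velocity_confidence <- function(field, neighbors) {
  v <- if (inherits(field, "velocity_field")) field$v else field
  nc <- ncol(v)
  stopifnot(nrow(neighbors) == nc)
  nrm <- sqrt(.colSums(v^2, nrow(v), nc))
  vn <- sweep(v, 2, pmax(nrm, .Machine$double.eps), `/`)
  conf <- vapply(seq_len(nc), function(i) {
    js <- neighbors[i, ]
    js <- js[!is.na(js)]
    if (length(js) == 0) return(NA_real_)
    mean(as.vector(crossprod(vn[, js, drop = FALSE], vn[, i])))
  }, numeric(1))
  tibble(cell = colnames(v) %||% as.character(seq_len(nc)), confidence = conf)
}

# directional consistency of the residual velocity: |mean v| / sd v
velocity_directionality <- function(v) {
  mv <- abs(rowMeans(v))
  sv <- apply(v, 1, sd)
  ifelse(sv > 0, mv / sv, 0)
}

# sum of squared residuals of a straight-line fit of y on x
line_sse <- function(x, y) {
  n <- length(x)
  if (n < 2) return(0)
  vx <- stats::var(x)
  if (vx == 0) return(sum((y - mean(y))^2))
  b <- stats::cov(x, y) / vx
  a <- mean(y) - b * mean(x)
  sum((y - a - b * x)^2)
}

#' Rank cluster-specific driver genes
#'
#' Scores each gene's phase-portrait dynamics within one cluster and returns
#' the top-ranked "driver" genes — the genes whose splicing dynamics best
#' explain the cluster's velocity flow. The score is the product of three
#' cluster-level terms:
#' `fit_r2 * (dynamic_range / max(dynamic_range)) * directionality`, where
#' `fit_r2` is the coefficient of determination of a two-segment
#' piecewise-linear fit of u on s (segments split by the sign of
#' `u - gamma_hat * s`, i.e. induction vs repression), `dynamic_range` is the
#' spread between the upper and lower 5% quantiles of smoothed spliced
#' abundance in the cluster, measured on the log1p scale so that strongly
#' and weakly transcribed genes compete on relative rather than absolute
#' spread, and `directionality = |mean(v)| / sd(v)` rewards
#' a consistent displacement off the steady-state line. The last term is what
#' separates genuinely transcribing/repressing genes from co-regulated
#' modules whose expression merely fluctuates along the steady-state line
#' (which have high r-squared and range but near-zero mean velocity). Genes
#' constant in the cluster score 0.
#'
#' @param field A [velocity_field()] computed on the full dataset.
#' @param clusters Character vector of per-cell cluster labels, aligned with
#'   the field's cells (or a [velocity_dataset()] whose metadata has a
#'   `cluster` column).
#' @param cluster The cluster label to rank within (needs >= `min_cells`
#'   cells).
#' @param top_n Number of drivers to return (default 100); truncated to the
#'   number of eligible genes.
#' @param cells Optional subset of cell identifiers to restrict the cluster
#'   to (e.g. the start of a trajectory).
#' @param min_cells Minimum cluster size (default 20).
#' @return A tibble of class `driver_ranking`: `rank`, `gene`,
#'   `driver_score`, `fit_r2`, `dynamic_range`, `directionality`,
#'   `gamma_hat`.
#' @export
rank_driver_genes <- function(field, clusters, cluster, top_n = 100,
                              cells = NULL, min_cells = 20) {
  stopifnot(inherits(field, "velocity_field"))
  if (inherits(clusters, "velocity_dataset")) {
    clusters <- setNames(clusters$metadata$cluster, clusters$metadata$cell)
  }
  nc <- ncol(field$v)
  if (length(clusters) != nc) abort("`clusters` must label every cell of the field.")
  if (!cluster %in% clusters) abort(sprintf("cluster '%s' not found.", cluster))
  sel <- clusters == cluster
  if (!is.null(cells)) {
    sel <- sel & colnames(field$v) %in% cells
  }
  if (sum(sel) < min_cells) {
    abort(sprintf("cluster '%s' has fewer than %d cells.", cluster, min_cells))
  }
  genes <- rownames(field$v)
  gam <- setNames(field$fits$gamma_hat, field$fits$gene)[genes]
  u <- field$u[genes, sel, drop = FALSE]
  s <- field$s[genes, sel, drop = FALSE]
  v <- field$v[, sel, drop = FALSE]
  r2 <- numeric(length(genes))
  dr <- numeric(length(genes))
  for (g in seq_along(genes)) {
    ug <- u[g, ]; sg <- s[g, ]
    q <- quantile(log1p(sg), c(0.05, 0.95), names = FALSE)
    dr[g] <- q[2] - q[1]
    sst <- sum((ug - mean(ug))^2)
    if (sst == 0 || dr[g] == 0) next
    ind <- v[g, ] > 0
    sse <- line_sse(sg[ind], ug[ind]) + line_sse(sg[!ind], ug[!ind])
    r2[g] <- min(max(1 - sse / sst, 0), 1)
  }
  dr_norm <- if (max(dr) > 0) dr / max(dr) else dr
  direction <- velocity_directionality(v)
  out <- tibble(
    gene = genes,
    driver_score = r2 * dr_norm * direction,
    fit_r2 = r2,
    dynamic_range = dr,
    directionality = unname(direction),
    gamma_hat = unname(gam)
  )
  out <- arrange(out, desc(.data$driver_score), .data$gene)
  out <- mutate(out, rank = row_number())
  out <- select(out, "rank", "gene", "driver_score", "fit_r2",
                "dynamic_range", "directionality", "gamma_hat")
  out <- head(out, top_n)
  class(out) <- c("driver_ranking", class(out))
  out
}
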