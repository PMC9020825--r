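#' Read regulons from a GMT file
#'
#' Each line is `name <TAB> description <TAB> target1 <TAB> target2 ...`.
#' Duplicate regulon names are merged with the union of their targets; lines
#' with an empty target list are skipped with a warning. A trailing
#' `_extended` suffix marks lower-confidence regulons and is preserved in
#' the name.
#'
#' @param path Path to a GMT file (plain or gzipped).
#' @return A named list of character vectors (TF name to targets), class
#'   `regulon_set`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  out <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 2) {
      abort(sprintf("malformed GMT line %d: fewer than 2 fields.", i))
    }
    name <- fields[[1]]
    targets <- unique(fields[-(1:2)])
    targets <- targets[nzchar(targets)]
    if (length(targets) == 0) {
      warn(sprintf("GMT line %d ('%s') has no targets; skipped.", i, name))
      next
    }
    out[[name]] <- union(out[[name]], targets)
  }
  structure(out, class = "regulon_set")
}

#' Write regulons to a GMT file
#'
#' @param regulons A named list of target-gene vectors.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(regulons, path) {
  lines <- vapply(names(regulons), function(nm) {
    paste(c(nm, nm, regulons[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Intersect regulon targets with a gene universe
#'
#' @param regulons A named list of target vectors.
#' @param universe Character vector of genes present in the data.
#' @return The pruned regulon list; regulons left empty are dropped with a
#'   warning naming the dropped genes count.
#' @export
prune_regulons <- function(regulons, universe) {
  out <- lapply(regulons, intersect, universe)
  dropped <- sum(lengths(regulons)) - sum(lengths(out))
  if (dropped > 0) {
    inform(sprintf("%d regulon target(s) absent from the gene universe were dropped.",
                   dropped))
  }
  empty <- lengths(out) == 0
  if (any(empty)) {
    warn(paste0("regulon(s) with no targets in the universe removed: ",
                toString(names(out)[empty])))
    out <- out[!empty]
  }
  structure(out, class = "regulon_set")
}

# per-cell expression ranks, descending, ties broken by gene identifier
# order after value (deterministic)
rank_cells <- function(expr) {
  ord_names <- order(rownames(expr) %||% as.character(seq_len(nrow(expr))))
  pos <- matrix(0L, nrow(expr), ncol(expr), dimnames = dimnames(expr))
  for (j in seq_len(ncol(expr))) {
    o <- ord_names[order(-expr[ord_names, j])] # stable: id order within ties
    pos[o, j] <- seq_len(nrow(expr))
  }
  pos
}

#' Recovery-curve (AUC) regulon activity
#'
#' For each cell, genes are ranked by decreasing expression (ties broken
#' deterministically by gene identifier); the recovery curve counts how many
#' regulon targets appear within the top ranks, up to a cutoff of
#' `ceil(top_fraction * n_genes)`. The activity is the area under this step
#' curve normalised by the maximum achievable area (all targets at the very
#' top), so values lie in `[0, 1]` and depend only on within-cell expression
#' ranks.
#'
#' @param expr Genes-by-cells expression matrix (any monotone scale).
#' @param regulons A named list of target-gene vectors (see [read_gmt()]),
#'   or a single character vector of targets.
#' @param top_fraction Fraction of the gene universe in the ranking cutoff
#'   (default 0.05); must lie in (0, 1].
#' @return A regulons-by-cells matrix of AUC activities.
#' @export
regulon_auc <- function(expr, regulons, top_fraction = 0.05) {
  if (top_fraction <= 0 || top_fraction > 1) {
    abort("`top_fraction` must lie in (0, 1].")
  }
  if (!is.list(regulons)) regulons <- list(regulon = regulons)
  expr <- as.matrix(expr)
  regulons <- prune_regulons(regulons, rownames(expr))
  if (length(regulons) == 0) abort("no regulon has targets in the gene universe.")
  ng <- nrow(expr)
  cutoff <- ceiling(top_fraction * ng)
  pos <- rank_cells(expr)
  auc <- matrix(
    0, length(regulons), ncol(expr),
    dimnames = list(names(regulons), colnames(expr))
  )
  for (r in seq_along(regulons)) {
    targets <- regulons[[r]]
    k <- length(targets)
    max_area <- sum(cutoff - seq_len(min(k, cutoff)) + 1)
    p <- pos[targets, , drop = FALSE]
    contrib <- pmax(cutoff - p + 1, 0)
    auc[r, ] <- .colSums(contrib, nrow(contrib), ncol(contrib)) / max_area
  }
  auc
}

#' Differential regulon activity per cluster
#'
#' Ranks regulons by the difference between their mean AUC activity in the
#' chosen cluster and in all remaining cells ("most active" regulons). A
#' rank-sum z statistic is reported alongside but the ranking uses the mean
#' difference.
#'
#' @param auc Regulons-by-cells AUC matrix from [regulon_auc()].
#' @param labels Per-cell cluster labels aligned with the AUC columns.
#' @param cluster Cluster of interest (>= 3 cells).
#' @param top_k Number of regulons to return (default 30; truncated to the
#'   number available).
#' @return A tibble `rank`, `regulon`, `mean_cluster`, `mean_rest`,
#'   `activity_diff`, `rank_sum_z`.
#' @export
differential_regulon_activity <- function(auc, labels, cluster, top_k = 30) {
  if (length(labels) != ncol(auc)) abort("`labels` must match the AUC cells.")
  if (!cluster %in% labels) abort(sprintf("cluster '%s' not found.", cluster))
  in_c <- labels == cluster
  if (sum(in_c) < 3) abort("cluster has fewer than 3 cells.")
  m_in <- rowMeans(auc[, in_c, drop = FALSE])
  m_out <- rowMeans(auc[, !in_c, drop = FALSE])
  n1 <- sum(in_c); n2 <- sum(!in_c)
  z <- apply(auc, 1, function(a) {
    r <- rank(a)
    w <- sum(r[in_c]) - n1 * (n1 + 1) / 2
    mu <- n1 * n2 / 2
    sig <- sqrt(n1 * n2 * (n1 + n2 + 1) / 12)
    if (sig == 0) 0 else (w - mu) / sig
  })
  out <- tibble(
    regulon = rownames(auc),
    mean_cluster = unname(m_in),
    mean_rest = unname(m_out),
    activity_diff = unname(m_in - m_out),
    rank_sum_z = unname(z)
  )
  out <- arrange(out, desc(.data$activity_diff), .data$regulon)
  out <- mutate(out, rank = row_number())
  head(select(out, "rank", "regulon", "mean_cluster", "mean_rest",
              "activity_diff", "rank_sum_z"), top_k)
}

#' Build test regulons by co-expression
#'
#' A deliberately simple module builder used to derive regulons from
#' synthetic data for testing: for each candidate TF, targets are the genes
#' whose expression correlates with the TF above `min_cor`. It makes no
#' attempt at motif-based pruning and is not meant for real data.
#'
#' @param expr Genes-by-cells expression matrix.
#' @param tfs Candidate TF gene names (must be rows of `expr`).
#' @param min_cor Pearson correlation threshold (default 0.3).
#' @param max_targets Cap on targets per TF (most-correlated first).
#' @return A named list of target vectors, class `regulon_set`.
#' @export
coexpression_regulons <- function(expr, tfs, min_cor = 0.3, max_targets = 50) {
  missing <- setdiff(tfs, rownames(expr))
  if (length(missing)) abort(paste0("TF(s) absent: ", toString(missing)))
  expr <- as.matrix(expr)
  out <- list()
  for (tf in tfs) {
    cc <- suppressWarnings(as.vector(cor(expr[tf, ], Matrix::t(expr))))
    names(cc) <- rownames(expr)
    cc <- cc[setdiff(names(cc), tf)]
    cc <- sort(cc[!is.na(cc) & cc >= min_cor], decreasing = TRUE)
    if (length(cc)) out[[tf]] <- names(head(cc, max_targets))
  }
  structure(out, class = "regulon_set")
}
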