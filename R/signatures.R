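#' Annotate cells as myogenic or non-myogenic
#'
#' Implements the marker rule used to split the two compartments: a cell is
#' myogenic if it expresses the ligand marker (Pdgfa-like) or any myogenic
#' regulator (Myf5/Myod/Myog-like); cells expressing neither are
#' non-myogenic.
#'
#' @param dataset A [velocity_dataset()] (the rule runs on raw spliced
#'   counts: "expressing" means count > 0), or a genes-by-cells count matrix.
#' @param markers A list with elements `ligand` (single gene name) and
#'   `myogenic_genes` (character vector).
#' @return A tibble `cell`, `compartment` (`"myogenic"`/`"non_myogenic"`).
#' @export
annotate_compartments <- function(dataset, markers) {
  counts <- if (inherits(dataset, "velocity_dataset")) dataset$spliced else dataset
  needed <- c(markers$ligand, markers$myogenic_genes)
  missing <- setdiff(needed, rownames(counts))
  if (length(missing)) {
    abort(paste0("marker gene(s) absent from the dataset: ", toString(missing)))
  }
  lig <- counts[markers$ligand, ] > 0
  myo <- Matrix::colSums(counts[markers$myogenic_genes, , drop = FALSE] > 0) > 0
  tibble(
    cell = colnames(counts),
    compartment = ifelse(as.vector(lig) | as.vector(myo),
                         "myogenic", "non_myogenic")
  )
}

#' Rank marker genes of a group
#'
#' Two-sided Wilcoxon rank-sum test of each gene in the group's cells versus
#' all other cells, plus a log2 fold change of group versus rest means.
#' Only positively enriched genes (fold change > 0) are kept; they are
#' ranked by p-value, ties broken by fold change. Small untied samples use
#' the exact rank-sum null distribution; larger or tied samples the normal
#' approximation with continuity correction (the `stats::wilcox.test`
#' conventions). P-values below `p_saturation` are treated as ties when
#' ranking: on datasets of thousands of cells the approximation produces
#' astronomically small values whose ordering carries no information, so the
#' fold change decides among saturated markers.
#'
#' @param expr Genes-by-cells matrix of normalised log expression.
#' @param labels Per-cell group labels aligned with the columns of `expr`.
#' @param group The group to find markers for (>= 3 cells, and >= 3 in the
#'   rest).
#' @param n_top Number of markers to return (default 10).
#' @param pseudocount Added to both means for the fold change (default 0.01).
#' @param p_saturation Ranking floor for p-values (default 1e-250, about a
#'   rank-sum z of 34); set to 0 to rank on raw p-values only.
#' @return A tibble `rank`, `gene`, `p_value`, `log2_fc`.
#' @export
find_markers <- function(expr, labels, group, n_top = 10, pseudocount = 0.01,
                         p_saturation = 1e-250) {
  if (length(labels) != ncol(expr)) abort("`labels` must match the cells.")
  if (!group %in% labels) abort(sprintf("group '%s' not found.", group))
  in_g <- labels == group
  if (sum(in_g) < 3 || sum(!in_g) < 3) {
    abort("need at least 3 cells in the group and in the rest.")
  }
  expr <- as.matrix(expr)
  mg <- rowMeans(expr[, in_g, drop = FALSE])
  mr <- rowMeans(expr[, !in_g, drop = FALSE])
  lfc <- log2((mg + pseudocount) / (mr + pseudocount))
  keep <- which(lfc > 0)
  pv <- vapply(keep, function(g) {
    x <- expr[g, in_g]; y <- expr[g, !in_g]
    if (all(x == x[1]) && all(y == x[1])) return(1)
    suppressWarnings(wilcox.test(x, y, alternative = "two.sided")$p.value)
  }, numeric(1))
  out <- tibble(gene = rownames(expr)[keep], p_value = unname(pv),
                log2_fc = unname(lfc[keep]))
  out$p_rank <- pmax(out$p_value, p_saturation)
  out <- arrange(out, .data$p_rank, desc(.data$log2_fc), .data$gene)
  out <- mutate(out, rank = row_number())
  head(select(out, "rank", "gene", "p_value", "log2_fc"), n_top)
}

#' Compartment signature scores
#'
#' Aggregates, per cell, the total normalised log expression over the
#' myogenic and non-myogenic signature gene sets (`S_m`, `S_n`), then
#' normalises each by their sum to give the two signature fractions
#' `s_m + s_n = 1`. Cells expressing neither set are flagged missing rather
#' than set to 0.5/0.5.
#'
#' @param expr Genes-by-cells matrix of normalised log expression.
#' @param genes_myo,genes_nonmyo Disjoint, non-empty signature gene sets.
#' @return A tibble of class `signature_scores`: `cell`, `S_m`, `S_n`,
#'   `s_m`, `s_n`, `scored` (FALSE where both sums are zero).
#' @export
signature_scores <- function(expr, genes_myo, genes_nonmyo) {
  if (length(genes_myo) == 0 || length(genes_nonmyo) == 0) {
    abort("signature gene sets must be non-empty.")
  }
  if (length(intersect(genes_myo, genes_nonmyo))) {
    abort(paste0("signature sets overlap: ",
                 toString(intersect(genes_myo, genes_nonmyo))))
  }
  missing <- setdiff(c(genes_myo, genes_nonmyo), rownames(expr))
  if (length(missing)) {
    abort(paste0("signature gene(s) absent: ", toString(head(missing, 5))))
  }
  s_m_raw <- colSums(expr[genes_myo, , drop = FALSE])
  s_n_raw <- colSums(expr[genes_nonmyo, , drop = FALSE])
  tot <- s_m_raw + s_n_raw
  scored <- tot > 0
  out <- tibble(
    cell = colnames(expr) %||% as.character(seq_len(ncol(expr))),
    S_m = unname(s_m_raw),
    S_n = unname(s_n_raw),
    s_m = unname(ifelse(scored, s_m_raw / tot, NA_real_)),
    s_n = unname(ifelse(scored, s_n_raw / tot, NA_real_)),
    scored = unname(scored)
  )
  class(out) <- c("signature_scores", class(out))
  out
}

#' Coexpression score and transition-cell calling
#'
#' The coexpression score of a cell is the product of its two signature
#' fractions, `c = s_m * s_n`, maximal (0.25) when both programmes are
#' equally active. Cells with `c` strictly greater than the threshold
#' (default 0.20) are flagged as transition cells — cells caught between the
#' myogenic and non-myogenic programmes. Cells are ordered by increasing
#' non-myogenic signature, ties broken by cell identifier; unscored cells
#' are excluded from transition calling and ordered last.
#'
#' @param scores A [signature_scores()] tibble.
#' @param threshold Transition threshold on the coexpression score
#'   (default 0.20; values outside `[0, 0.25]` are unreachable and trigger a
#'   warning).
#' @return The input tibble with columns `coexpression`, `transition` and
#'   `order` added, class `signature_scores`.
#' @export
coexpression_transition <- function(scores, threshold = 0.20) {
  stopifnot(all(c("s_m", "s_n", "scored") %in% names(scores)))
  if (threshold < 0 || threshold > 0.25) {
    warn("`threshold` outside [0, 0.25]: the coexpression score cannot reach it.")
  }
  out <- mutate(
    scores,
    coexpression = .data$s_m * .data$s_n,
    transition = !is.na(.data$coexpression) & .data$coexpression > threshold
  )
  ord <- order(out$s_n, out$cell, na.last = TRUE)
  out$order <- NA_integer_
  out$order[ord] <- seq_len(nrow(out))
  attr(out, "threshold") <- threshold
  class(out) <- unique(c("signature_scores", class(out)))
  out
}

#' @method glance signature_scores
#' @export
glance.signature_scores <- function(x, ...) {
  tibble(
    n_cells = nrow(x),
    n_scored = sum(x$scored),
    n_transition = if ("transition" %in% names(x)) sum(x$transition) else NA_integer_,
    max_coexpression = if ("coexpression" %in% names(x)) {
      max(x$coexpression, na.rm = TRUE)
    } else NA_real_
  )
}
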