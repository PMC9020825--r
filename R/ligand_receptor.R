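#' Compartment log-ratio of gene expression
#'
#' The log2 ratio of a gene's mean expression in the myogenic versus the
#' non-myogenic compartment, with a pseudocount on both means:
#' `log2((mean_myo + eps) / (mean_nonmyo + eps))`. Positive values mean
#' myogenic-biased expression.
#'
#' @param expr Genes-by-cells matrix of normalised log expression.
#' @param annotation A tibble `cell`, `compartment` from
#'   [annotate_compartments()].
#' @param genes Genes to score (default: all rows of `expr`).
#' @param pseudocount Stabilising pseudocount `eps` (default 0.01).
#' @return A tibble `gene`, `mean_myogenic`, `mean_non_myogenic`, `log2_ratio`.
#' @export
compartment_ratio <- function(expr, annotation, genes = rownames(expr),
                              pseudocount = 0.01) {
  stopifnot(all(c("cell", "compartment") %in% names(annotation)))
  ann <- annotation$compartment[match(colnames(expr), annotation$cell)]
  if (anyNA(ann)) abort("annotation does not cover every cell.")
  myo <- ann == "myogenic"
  if (!any(myo) || all(myo)) abort("both compartments must be non-empty.")
  missing <- setdiff(genes, rownames(expr))
  if (length(missing)) abort(paste0("gene(s) absent: ", toString(head(missing, 5))))
  m_m <- rowMeans(expr[genes, myo, drop = FALSE])
  m_n <- rowMeans(expr[genes, !myo, drop = FALSE])
  tibble(
    gene = genes,
    mean_myogenic = unname(m_m),
    mean_non_myogenic = unname(m_n),
    log2_ratio = unname(log2((m_m + pseudocount) / (m_n + pseudocount)))
  )
}

#' Ligand-receptor complementarity scores
#'
#' For each ligand-receptor pair, the receptor's myogenic/non-myogenic
#' log-ratio is subtracted from the ligand's: a positive score means the
#' ligand sits on the myogenic side and its receptor on the non-myogenic
#' side (signalling myogenic to non-myogenic), a negative score the
#' reverse. The score is exactly antisymmetric under swapping the two
#' compartment labels. Pairs with a missing gene are skipped with a warning.
#'
#' @param expr Genes-by-cells matrix of normalised log expression.
#' @param annotation Compartment annotation tibble (see
#'   [annotate_compartments()]).
#' @param pairs A tibble with columns `ligand`, `receptor` and optionally
#'   `pathway`.
#' @param pseudocount Passed to [compartment_ratio()].
#' @return A tibble `pathway`, `ligand`, `receptor`, `ligand_ratio`,
#'   `receptor_ratio`, `score`.
#' @export
lr_score <- function(expr, annotation, pairs, pseudocount = 0.01) {
  pairs <- as_tibble(pairs)
  stopifnot(all(c("ligand", "receptor") %in% names(pairs)))
  if (any(pairs$ligand == pairs$receptor)) {
    abort("a pair cannot use the same gene as ligand and receptor.")
  }
  if (!"pathway" %in% names(pairs)) pairs$pathway <- pairs$ligand
  present <- pairs$ligand %in% rownames(expr) & pairs$receptor %in% rownames(expr)
  if (any(!present)) {
    warn(paste0("pair(s) skipped, gene not in dataset: ",
                toString(pairs$pathway[!present])))
    pairs <- pairs[present, , drop = FALSE]
  }
  if (nrow(pairs) == 0) return(tibble(
    pathway = character(), ligand = character(), receptor = character(),
    ligand_ratio = numeric(), receptor_ratio = numeric(), score = numeric()
  ))
  ratios <- compartment_ratio(
    expr, annotation, unique(c(pairs$ligand, pairs$receptor)), pseudocount
  )
  lk <- setNames(ratios$log2_ratio, ratios$gene)
  tibble(
    pathway = pairs$pathway,
    ligand = pairs$ligand,
    receptor = pairs$receptor,
    ligand_ratio = unname(lk[pairs$ligand]),
    receptor_ratio = unname(lk[pairs$receptor]),
    score = unname(lk[pairs$ligand] - lk[pairs$receptor])
  )
}

#' Read a ligand-receptor pair table
#'
#' @param path TSV with columns `ligand`, `receptor`, `pathway`.
#' @return A tibble.
#' @export
read_lr_pairs <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                  progress = FALSE)
}

#' Write a ligand-receptor pair table
#'
#' @param pairs Tibble with `ligand`, `receptor` and optional `pathway`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_lr_pairs <- function(pairs, path) {
  readr::write_tsv(pairs, path, progress = FALSE)
  invisible(path)
}
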