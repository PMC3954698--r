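#' Build a signed log10-FDR pathway-by-condition matrix
#'
#' Each cell is `sign(nes) * min(-log10(fdr_q), fdr_zero_cap)`: positive
#' (up-regulated) pathways get positive scores, down-regulated negative,
#' with |score| growing as the FDR shrinks.  An FDR of exactly 0 is capped
#' at `fdr_zero_cap` (default 4, i.e. treated as 1e-4).  Pathways absent
#' from a condition's enrichment run stay `NA` ("not detected").
#'
#' @param enrichments Named list (one element per condition) of enrichment
#'   result data frames with columns `set_name`, `nes`, `fdr_q` (as
#'   returned by [gsea_preranked()] / [gsea_phenotype()]).
#' @param fdr_zero_cap Cap on |score| when `fdr_q = 0`.
#' @return Numeric matrix, pathways x conditions, `NA` for missing cells;
#'   pathway rows ordered by first appearance across conditions.
#' @export
build_signed_matrix <- function(enrichments, fdr_zero_cap = 4) {
  stopifnot(fdr_zero_cap > 0, !is.null(names(enrichments)))
  pathways <- unique(unlist(lapply(enrichments, function(e) e$set_name)))
  out <- matrix(NA_real_, length(pathways), length(enrichments),
                dimnames = list(pathways, names(enrichments)))
  for (cond in names(enrichments)) {
    e <- enrichments[[cond]]
    score <- sign(e$nes) * pmin(-log10(pmax(e$fdr_q, 10^-fdr_zero_cap)),
                                fdr_zero_cap)
    out[e$set_name, cond] <- score
  }
  out
}

#' Exclusion filter for the pathway matrix
#'
#' Drops a pathway when the number of conditions in which it is either not
#' detected (`NA`) or has FDR = 1 (score exactly 0) exceeds `max_missing`.
#'
#' @param matrix Signed score matrix from [build_signed_matrix()].
#' @param max_missing Highest tolerated count of missing/FDR-1 cells per
#'   pathway (default 5; the legend rule "more than five out of the 30").
#' @return The matrix restricted to retained pathways, values unchanged.
#' @export
filter_pathways <- function(matrix, max_missing = 5) {
  bad <- rowSums(is.na(matrix) | matrix == 0)
  matrix[bad <= max_missing, , drop = FALSE]
}

#' Hierarchically cluster pathways by their signed FDR profiles
#'
#' Agglomerative clustering of pathway rows.  Missing cells are filled with
#' `missing_fill` (default 0, neutral) before the distance computation.
#' Rows are pre-sorted by pathway name so that ties in merge heights
#' resolve deterministically.
#'
#' @param matrix Filtered signed score matrix.
#' @param distance `"euclidean"` or `"correlation"` (1 - Pearson r).
#' @param linkage `"average"`, `"complete"` or `"single"`.
#' @param missing_fill Value substituted for `NA` cells.
#' @return An [stats::hclust] tree over the pathway rows.
#' @export
cluster_pathways <- function(matrix, distance = c("euclidean", "correlation"),
                             linkage = c("average", "complete", "single"),
                             missing_fill = 0) {
  distance <- match.arg(distance)
  linkage <- match.arg(linkage)
  if (nrow(matrix) < 2L) stop("need >= 2 pathways after filtering")
  m <- matrix[order(rownames(matrix), method = "radix"), , drop = FALSE]
  m[is.na(m)] <- missing_fill
  d <- if (distance == "euclidean") {
    stats::dist(m)
  } else {
    stats::as.dist(1 - stats::cor(t(m)))
  }
  if (all(d == 0)) message("constant matrix: all pairwise distances are 0")
  stats::hclust(d, method = linkage)
}
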