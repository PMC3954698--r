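#' Load the transcribed common-gene table of the three tumor models
#'
#' A small packaged fixture transcribing the per-model fold changes and
#' p-values of the genes reported as commonly deregulated in the three
#' oncogene tumor models (fold changes are magnitudes; direction is a
#' separate column).
#'
#' @param path Path to the TSV; defaults to the packaged copy.
#' @return Data frame with columns `direction`, `gi`, `symbol`,
#'   `human_symbol`, and `fc_*`/`p_*` per model (`xmrk`, `kras`, `myc`).
#' @export
read_common_gene_table <- function(path = system.file(
  "extdata", "common_genes_three_models.tsv", package = "zfsig")) {
  utils::read.delim(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' Intersect the three models' gene lists from a common-gene table
#'
#' Builds one up- and one down-regulated gene list per model by applying
#' per-model significance (p < `p_max`) and direction consistency to the
#' table, then intersects the three models with [intersect_models()].
#' Fold change is deliberately not re-thresholded here: the table reports
#' genes already selected per model, and one listed entry sits below the
#' usual 1.5 fold-change cutoff.
#'
#' @param table Data frame from [read_common_gene_table()].
#' @param p_max Per-model significance threshold (default 0.05).
#' @return The [intersect_models()] result over the three models.
#' @export
common_gene_intersection <- function(table = read_common_gene_table(),
                                     p_max = 0.05) {
  models <- c("xmrk", "kras", "myc")
  pick <- function(model, dir) {
    table$gi[table$direction == dir & table[[paste0("p_", model)]] < p_max]
  }
  intersect_models(lapply(models, pick, dir = "up"),
                   lapply(models, pick, dir = "down"))
}
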