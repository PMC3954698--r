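#' Signature-derivation workflow
#'
#' Runs the full zebrafish arm for up to three tumor models: TPM
#' normalization, the appropriate DE test per model (unreplicated
#' one-sample t on per-control log2 ratios when the model has a single
#' tumor sample, replicated two-sample t otherwise), selection by the
#' fold-change/p/TPM criteria, and the three-model intersection.
#'
#' @param counts Named list (one element per model) of tag-count matrices
#'   whose column names start with `"tumor"` or `"control"` (as produced by
#'   [simulate_sage_counts()]).
#' @param criteria A [de_criteria()].
#' @param out_dir Optional directory: DE tables (TSV), signatures (GMT),
#'   Venn report and manifest (JSON) are written there.
#' @return List with `de_tables` (per model), `signatures` (per-model
#'   `up`/`down` id vectors), `intersection` (from [intersect_models()],
#'   when all 3 models are present) and `manifest`.
#' @export
run_signature_workflow <- function(counts, criteria = de_criteria(),
                                   out_dir = NULL) {
  stopifnot(length(counts) >= 1L, !is.null(names(counts)))
  de_tables <- list()
  signatures <- list()
  for (model in names(counts)) {
    mat <- counts[[model]]
    tumor_cols <- grep("^tumor", colnames(mat), value = TRUE)
    control_cols <- grep("^control", colnames(mat), value = TRUE)
    if (!length(tumor_cols) || !length(control_cols)) {
      stop("model '", model, "': columns must be named tumor*/control*")
    }
    tpm <- normalize_tpm(mat)
    de <- if (length(tumor_cols) == 1L) {
      de_test_unreplicated(tpm[, tumor_cols], tpm[, control_cols, drop = FALSE],
                           criteria)
    } else {
      de_test_replicated(tpm[, tumor_cols, drop = FALSE],
                         tpm[, control_cols, drop = FALSE], criteria)
    }
    de_tables[[model]] <- de
    signatures[[model]] <- select_deregulated(de, criteria)
  }
  intersection <- if (length(counts) == 3L) {
    intersect_models(lapply(signatures, `[[`, "up"),
                     lapply(signatures, `[[`, "down"))
  }
  manifest <- list(
    stage = "signature_derivation",
    criteria = unclass(criteria),
    models = names(counts),
    n_genes = vapply(counts, nrow, integer(1)),
    n_selected_up = vapply(signatures, function(s) length(s$up), integer(1)),
    n_selected_down = vapply(signatures, function(s) length(s$down), integer(1)),
    common_up = if (!is.null(intersection)) length(intersection$common_up),
    common_down = if (!is.null(intersection)) length(intersection$common_down),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (model in names(counts)) {
      utils::write.table(de_tables[[model]],
                         file.path(out_dir, paste0("de_", model, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    up_sets <- lapply(signatures, `[[`, "up")
    names(up_sets) <- paste0(names(signatures), "_up")
    down_sets <- lapply(signatures, `[[`, "down")
    names(down_sets) <- paste0(names(signatures), "_down")
    write_gene_sets(c(up_sets, down_sets),
                    file.path(out_dir, "signatures.gmt"))
    .write_json_atomic(c(manifest,
                         list(venn_up = if (!is.null(intersection)) as.list(intersection$venn_up),
                              venn_down = if (!is.null(intersection)) as.list(intersection$venn_down))),
                       file.path(out_dir, "signature_manifest.json"))
  }
  list(de_tables = de_tables, signatures = signatures,
       intersection = intersection, manifest = manifest)
}

# Two-group DE on a cohort split (correlated vs rest) giving the signed
# log10-p ranking for the subgroup pathway analysis.
.subgroup_ranking <- function(expr, in_group) {
  stopifnot(sum(in_group) >= 2L, sum(!in_group) >= 2L)
  ga <- expr[, in_group, drop = FALSE]
  gb <- expr[, !in_group, drop = FALSE]
  na <- ncol(ga); nb <- ncol(gb)
  ma <- rowMeans(ga); mb <- rowMeans(gb)
  va <- rowSums((ga - ma)^2) / (na - 1L)
  vb <- rowSums((gb - mb)^2) / (nb - 1L)
  pooled <- ((na - 1L) * va + (nb - 1L) * vb) / (na + nb - 2L)
  pooled <- pmax(pooled, .variance_floor(pooled))
  tstat <- (ma - mb) / sqrt(pooled * (1 / na + 1 / nb))
  p <- 2 * stats::pt(abs(tstat), df = na + nb - 2L, lower.tail = FALSE)
  p <- pmax(p, .Machine$double.xmin)
  rank_preranked(setNames(p, rownames(expr)),
                 ifelse(tstat >= 0, "up", "down"))
}

#' Cohort-classification workflow
#'
#' The human arm: per-sample one-vs-rest classification against every
#' signature, the representation/co-correlation summary, optional
#' stage-wise profiles, and (when a pathway collection is supplied) the
#' signed log10-FDR pathway matrix over the signature-correlated subgroups
#' with its hierarchical clustering.
#'
#' @param expr Cohort expression matrix (genes x samples).
#' @param signatures Named list of signature gene-id vectors.
#' @param config A [gsea_config()].
#' @param criteria A [classification_criteria()].
#' @param stage_labels Optional per-sample stage labels; stage profiles are
#'   computed for every signature when given.
#' @param stage_order Optional explicit stage order.
#' @param pathways Optional named list of pathway gene sets for the
#'   subgroup pathway-matrix stage.
#' @param max_missing Pathway-filter tolerance (see [filter_pathways()]).
#' @param dataset_id Dataset label for the classification table.
#' @param out_dir Optional output directory (TSV/JSON writers).
#' @return List with `classification`, `representation`, `stage_profiles`
#'   (or NULL), `pathway_matrix`, `pathway_tree` (or NULL), `manifest`.
#' @export
run_classification_workflow <- function(expr, signatures,
                                        config = gsea_config(permutation_mode = "gene_set"),
                                        criteria = classification_criteria(),
                                        stage_labels = NULL, stage_order = NULL,
                                        pathways = NULL, max_missing = 5,
                                        dataset_id = "cohort", out_dir = NULL) {
  if (!length(signatures)) stop("at least one signature is required")
  tab <- classify_cohort(expr, signatures, config, criteria, dataset_id)
  rep_sum <- summarize_representation(tab)
  stopifnot(rep_sum$overall$pct_any >=
              max(rep_sum$overall$pct_per_signature) - 1e-9)
  stage_profiles <- NULL
  if (!is.null(stage_labels)) {
    stage_profiles <- lapply(signatures, function(sig) {
      stage_enrichment(expr, stage_labels, sig, config, stage_order,
                       fdr_max = criteria$fdr_max)
    })
  }
  pathway_matrix <- NULL
  pathway_tree <- NULL
  if (!is.null(pathways)) {
    enrichments <- list()
    for (s in names(signatures)) {
      flags <- tab$correlated[tab$signature == s]
      names(flags) <- tab$sample_id[tab$signature == s]
      in_group <- flags[colnames(expr)]
      if (sum(in_group) < 2L || sum(!in_group) < 2L) {
        message("signature ", s, ": subgroup too small for pathway analysis")
        next
      }
      ranked <- .subgroup_ranking(expr, in_group)
      enrichments[[paste0(dataset_id, ".", s)]] <-
        gsea_preranked(ranked, pathways, config)
    }
    if (length(enrichments)) {
      pathway_matrix <- filter_pathways(build_signed_matrix(enrichments),
                                        max_missing)
      if (nrow(pathway_matrix) >= 2L) {
        pathway_tree <- cluster_pathways(pathway_matrix)
      }
    }
  }
  manifest <- list(
    stage = "cohort_classification",
    dataset_id = dataset_id,
    n_samples = ncol(expr), n_genes = nrow(expr),
    signatures = names(signatures),
    config = unclass(config), criteria = unclass(criteria),
    n_correlated = sum(tab$correlated),
    pct_any = rep_sum$overall$pct_any,
    n_pathways_retained = if (!is.null(pathway_matrix)) nrow(pathway_matrix),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(tab, file.path(out_dir, "classification.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    .write_json_atomic(rep_sum, file.path(out_dir, "representation.json"))
    if (!is.null(pathway_matrix)) {
      utils::write.table(data.frame(pathway = rownames(pathway_matrix),
                                    pathway_matrix, check.names = FALSE),
                         file.path(out_dir, "pathway_matrix.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    .write_json_atomic(manifest, file.path(out_dir, "classification_manifest.json"))
  }
  list(classification = tab, representation = rep_sum,
       stage_profiles = stage_profiles, pathway_matrix = pathway_matrix,
       pathway_tree = pathway_tree, manifest = manifest)
}

# Atomic JSON writer: write to a temp file in the target directory, then
# rename, so partially written manifests never appear.
.write_json_atomic <- function(x, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".json.tmp")
  jsonlite::write_json(x, tmp, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  file.rename(tmp, path)
  invisible(path)
}
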