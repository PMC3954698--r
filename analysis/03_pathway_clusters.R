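#!/usr/bin/env Rscript
# Pathway clustering: split the classified cohort into signature-correlated
# vs rest subgroups, run pre-ranked enrichment (signed log10 p ranking) of a
# synthetic pathway collection per subgroup, assemble the signed log10-FDR
# pathway matrix, apply the more-than-five exclusion filter, and cluster the
# retained pathways.  Requires 01 and 02.  Writes results/pathway_clusters/.

suppressPackageStartupMessages(library(zfsig))

cls_path <- "results/cohort_classification/classification.tsv"
if (!file.exists(cls_path)) stop("run analysis/02_classify_cohort.R first")
out_dir <- "results/pathway_clusters"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

gmt <- read_gene_sets("results/signature_derivation/signatures.gmt")
up <- gmt[grep("_up$", names(gmt))]
names(up) <- sub("_up$", "", names(up))
sigs <- lapply(up, unique)

cohort <- simulate_human_cohort(sigs, n_samples = 100, n_genes = 2500,
                                membership_prob = 0.2, effect_size = 3,
                                rng_seed = 77)   # same cohort as script 02
cls <- read.delim(cls_path, stringsAsFactors = FALSE)

# pathway collection: the signatures themselves plus random background sets
set.seed(81)
bg_genes <- setdiff(rownames(cohort$expr), unlist(sigs))
pathways <- c(sigs, setNames(lapply(1:12, function(i) sample(bg_genes, 30)),
                             sprintf("background_%02d", 1:12)))

wf <- run_classification_workflow(
  cohort$expr, sigs,
  gsea_config(permutation_mode = "gene_set", n_permutations = 200,
              rng_seed = 82),
  pathways = pathways, max_missing = 5,
  dataset_id = "synthetic_cohort", out_dir = out_dir)

m <- wf$pathway_matrix
cat(sprintf("Pathway matrix: %d pathways x %d conditions after filtering\n",
            nrow(m), ncol(m)))
print(round(m, 2))
if (!is.null(wf$pathway_tree)) {
  cat("Pathway dendrogram leaf order:\n  ",
      paste(wf$pathway_tree$labels[wf$pathway_tree$order], collapse = ", "), "\n")
  if (requireNamespace("ape", quietly = TRUE)) {
    ape::write.tree(ape::as.phylo(wf$pathway_tree),
                    file.path(out_dir, "pathway_dendrogram.nwk"))
  }
}
cat("wrote", out_dir, "\n")
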