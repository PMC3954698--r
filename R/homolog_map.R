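#' Collapse features to gene clusters by per-sample maximum
#'
#' Shared rule for transcript-to-Unigene and probe-to-Unigene collapsing:
#' when several features (transcripts or probes) map to the same gene
#' cluster, the cluster's expression in each sample is the maximum over its
#' features in that sample.  Features absent from the mapping are dropped
#' with a message.
#'
#' @param values Feature-level expression matrix (features x samples).
#' @param feature_to_cluster Named character vector: names are feature ids,
#'   values are cluster ids.  Each feature maps to at most one cluster.
#' @return Cluster-level matrix (clusters x samples); clusters ordered by
#'   first appearance among the mapped features.  The number of dropped
#'   (unmapped) features is stored in attribute `n_dropped`.
#' @export
collapse_by_max <- function(values, feature_to_cluster) {
  feats <- rownames(values)
  mapped <- feats[feats %in% names(feature_to_cluster)]
  n_dropped <- length(feats) - length(mapped)
  if (n_dropped > 0L) {
    message(n_dropped, " feature(s) without a cluster mapping dropped")
  }
  if (!length(mapped)) stop("no feature maps to any cluster")
  cl <- feature_to_cluster[mapped]
  clusters <- unique(unname(cl))
  out <- matrix(NA_real_, length(clusters), ncol(values),
                dimnames = list(clusters, colnames(values)))
  idx <- split(mapped, factor(unname(cl), levels = clusters))
  for (i in seq_along(idx)) {
    sub <- values[idx[[i]], , drop = FALSE]
    out[i, ] <- apply(sub, 2L, max)
  }
  attr(out, "value_kind") <- attr(values, "value_kind")
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Collapse transcript-level TPM to gene-cluster level
#'
#' @inheritParams collapse_by_max
#' @param transcript_tpm Transcript-level matrix.
#' @param transcript_to_cluster Named character vector mapping transcript id
#'   to cluster id.
#' @return Cluster-level matrix; see [collapse_by_max()].
#' @export
collapse_transcripts <- function(transcript_tpm, transcript_to_cluster) {
  collapse_by_max(transcript_tpm, transcript_to_cluster)
}

#' Collapse microarray probes to gene-cluster level
#'
#' Per sample, the maximum signal intensity over a cluster's probes
#' represents the cluster.
#'
#' @param probe_intensities Probe-level intensity matrix.
#' @param probe_to_cluster Named character vector mapping probe id to
#'   cluster id.
#' @return Cluster-level matrix; see [collapse_by_max()].
#' @export
collapse_probes <- function(probe_intensities, probe_to_cluster) {
  collapse_by_max(probe_intensities, probe_to_cluster)
}

#' Read a zebrafish-to-human homolog mapping table
#'
#' TSV with two columns: zebrafish cluster id, then a comma-separated
#' ordered list of candidate human cluster ids.  The order of the human
#' list is treated as authoritative (the first entry is the representative).
#'
#' @param path Path to the TSV file (no header).
#' @return Named list: names are zebrafish ids, each element an ordered
#'   character vector of human ids.
#' @export
read_homolog_table <- function(path) {
  df <- utils::read.delim(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE,
                          col.names = c("zebrafish", "human"))
  if (anyDuplicated(df$zebrafish)) {
    stop("duplicate zebrafish id(s) in homolog table: ",
         paste(unique(df$zebrafish[duplicated(df$zebrafish)]), collapse = ", "))
  }
  out <- lapply(strsplit(df$human, ",", fixed = TRUE), function(h) {
    h <- trimws(h)
    h <- h[nzchar(h)]
    if (!length(h)) stop("homolog entry with empty human list")
    if (anyDuplicated(h)) stop("duplicate human id within one homolog entry")
    h
  })
  names(out) <- df$zebrafish
  out
}

#' Map a zebrafish signature to human gene identifiers
#'
#' Each signature member is replaced by the first human cluster of its
#' homolog entry (the first-entry rule removes within-family redundancy);
#' the resulting list is deduplicated, since two zebrafish genes may share
#' one human homolog.  Members without any mapping are reported in
#' `dropped`.
#'
#' @param members Character vector of zebrafish cluster ids (a signature).
#' @param homolog_table Named list from [read_homolog_table()].
#' @param name Optional signature name carried through to the result.
#' @return List with `name`, `human_members` (unique, in first-appearance
#'   order), `dropped` (unmapped zebrafish ids) and `n_merged` (members
#'   lost to deduplication).
#' @export
map_to_human <- function(members, homolog_table, name = NULL) {
  members <- unique(members)
  has <- members %in% names(homolog_table)
  first_human <- vapply(homolog_table[members[has]], `[[`, character(1), 1L)
  human <- unique(unname(first_human))
  list(name = name,
       human_members = human,
       dropped = members[!has],
       n_merged = length(first_human) - length(human))
}
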