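#' Significance criteria for per-sample signature classification
#'
#' @param fdr_max FDR threshold below which a (sample, signature) pair is
#'   called correlated (default 0.25, the conventional exploratory GSEA
#'   cutoff).
#' @param require_positive Only positive NES counts as correlated (default
#'   TRUE): the signatures are up-regulated gene lists, so only concordant
#'   up-regulation is a match.
#' @return A `classification_criteria` list.
#' @export
classification_criteria <- function(fdr_max = 0.25, require_positive = TRUE) {
  stopifnot(fdr_max > 0, fdr_max < 1)
  structure(list(fdr_max = fdr_max, require_positive = require_positive),
            class = "classification_criteria")
}

# Singleton one-vs-rest rankings for every sample of a cohort.
# Returns a list of ranked lists (one per sample, in column order).
.singleton_rankings <- function(expr) {
  n <- ncol(expr)
  lapply(seq_len(n), function(j) {
    tgt <- seq_len(n) == j
    .sorted_ranking(.row_tstats(expr, tgt), rownames(expr))
  })
}

#' Classify one cohort sample against one signature
#'
#' The sample is treated as a singleton phenotype class and compared to the
#' rest of the cohort: genes are ranked by the one-vs-rest standardized
#' shift, the signature is scored with the running-sum statistic, and
#' significance comes from the configured permutation null.  In
#' `"gene_set"` mode (the recommended mode for singleton classes) the null
#' is random same-size sets on the sample's own ranking; in `"phenotype"`
#' mode it is the signature scored with every other sample as the
#' singleton.
#'
#' @param expr Cohort expression matrix (genes x samples), >= 4 samples.
#' @param sample_id Column name of the sample to classify.
#' @param signature Character vector of signature gene ids (or the result
#'   of [map_to_human()], whose `human_members` are used).
#' @param config A [gsea_config()].
#' @return One-row data frame `sample_id`, `es`, `nes`, `p_nominal`,
#'   `fdr_q`, `overlap_size`; all-NA statistics (with `reason`) when the
#'   signature's overlap with the platform is below `min_set_overlap`.
#' @export
classify_sample <- function(expr, sample_id, signature,
                            config = gsea_config(permutation_mode = "gene_set")) {
  if (ncol(expr) < 4L) stop("cohort needs >= 4 samples")
  if (!sample_id %in% colnames(expr)) stop("unknown sample: ", sample_id)
  if (is.list(signature)) signature <- signature$human_members
  labels <- ifelse(colnames(expr) == sample_id, "target", "rest")
  ranked <- rank_by_ttest(expr, labels, "target")
  r <- enrichment_score(ranked, signature, config$weight_exponent)
  if (is.null(r) || r$overlap_size < config$min_set_overlap) {
    message("signature overlap below minimum for sample ", sample_id)
    return(data.frame(sample_id = sample_id, es = NA_real_, nes = NA_real_,
                      p_nominal = NA_real_, fdr_q = NA_real_,
                      overlap_size = if (is.null(r)) 0L else r$overlap_size,
                      reason = "low_overlap", stringsAsFactors = FALSE))
  }
  null <- if (config$permutation_mode == "gene_set") {
    .gene_set_null_es(ranked, r$overlap_size, config)
  } else {
    permutation_null(expr, labels, "target", signature, config)
  }
  st <- normalize_and_fdr(c(sig = r$es), list(sig = null))
  data.frame(sample_id = sample_id, es = st$es, nes = st$nes,
             p_nominal = st$p_nominal, fdr_q = st$fdr_q,
             overlap_size = r$overlap_size, reason = NA_character_,
             stringsAsFactors = FALSE)
}

#' One-vs-rest classification of every sample against every signature
#'
#' Runs the [classify_sample()] procedure for every (sample, signature)
#' pair, sharing the per-sample rankings, and flags pairs significant at
#' the FDR threshold (positive NES only, by default).  Each (sample,
#' signature) run keeps its own permutation null; no FDR pooling across
#' signatures.
#'
#' @param expr Cohort expression matrix (genes x samples).
#' @param signatures Named list of signature gene-id vectors (or
#'   [map_to_human()] results).
#' @param config A [gsea_config()]; `rng_seed` fans out to one derived seed
#'   per (sample, signature) run.
#' @param criteria A [classification_criteria()].
#' @param dataset_id Optional dataset label carried into the table.
#' @return Data frame with one row per (sample, signature): `dataset_id`,
#'   `sample_id`, `signature`, `es`, `nes`, `p_nominal`, `fdr_q`,
#'   `correlated`, `reason`.  Pairs with insufficient platform overlap are
#'   retained as non-correlated with `reason = "low_overlap"`.
#' @export
classify_cohort <- function(expr, signatures,
                            config = gsea_config(permutation_mode = "gene_set"),
                            criteria = classification_criteria(),
                            dataset_id = "cohort") {
  if (ncol(expr) < 4L) stop("cohort needs >= 4 samples")
  signatures <- lapply(signatures, function(s) if (is.list(s)) s$human_members else s)
  stopifnot(!is.null(names(signatures)))
  n <- ncol(expr)
  rankings <- .singleton_rankings(expr)
  # observed ES for every (sample, signature)
  es_mat <- matrix(NA_real_, n, length(signatures),
                   dimnames = list(colnames(expr), names(signatures)))
  ov_mat <- matrix(0L, n, length(signatures), dimnames = dimnames(es_mat))
  for (j in seq_len(n)) {
    for (s in seq_along(signatures)) {
      r <- enrichment_score(rankings[[j]], signatures[[s]], config$weight_exponent)
      if (!is.null(r)) {
        es_mat[j, s] <- r$es
        ov_mat[j, s] <- r$overlap_size
      }
    }
  }
  rows <- vector("list", n * length(signatures))
  idx <- 0L
  for (s in seq_along(signatures)) {
    for (j in seq_len(n)) {
      idx <- idx + 1L
      ov <- ov_mat[j, s]
      if (ov < config$min_set_overlap) {
        rows[[idx]] <- data.frame(
          dataset_id = dataset_id, sample_id = colnames(expr)[j],
          signature = names(signatures)[s], es = NA_real_, nes = NA_real_,
          p_nominal = NA_real_, fdr_q = NA_real_, correlated = FALSE,
          reason = "low_overlap", stringsAsFactors = FALSE)
        next
      }
      null <- if (config$permutation_mode == "gene_set") {
        run_cfg <- config
        if (!is.null(config$rng_seed)) {
          # per-run seed keyed on the sample id, not its column position,
          # so results are invariant to sample ordering
          key <- sum(utf8ToInt(colnames(expr)[j]))
          run_cfg$rng_seed <- (config$rng_seed + 7919L * s + key) %% .Machine$integer.max
        }
        .gene_set_null_es(rankings[[j]], ov, run_cfg)
      } else {
        es_mat[-j, s]  # exhaustive singleton arrangements, observed excluded
      }
      st <- normalize_and_fdr(setNames(es_mat[j, s], "sig"), list(sig = null))
      corr <- !is.na(st$fdr_q) && st$fdr_q < criteria$fdr_max &&
        (!criteria$require_positive || (!is.na(st$nes) && st$nes > 0))
      rows[[idx]] <- data.frame(
        dataset_id = dataset_id, sample_id = colnames(expr)[j],
        signature = names(signatures)[s], es = st$es, nes = st$nes,
        p_nominal = st$p_nominal, fdr_q = st$fdr_q, correlated = corr,
        reason = NA_character_, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# Percentage summaries from a logical flag matrix (samples x signatures).
.representation_from_flags <- function(flags) {
  sig_names <- colnames(flags)
  pct <- function(x) 100 * mean(x)
  per_sig <- vapply(sig_names, function(s) pct(flags[, s]), numeric(1))
  pairs <- if (ncol(flags) >= 2L) {
    cmb <- utils::combn(sig_names, 2L, simplify = FALSE)
    setNames(vapply(cmb, function(p) pct(flags[, p[1]] & flags[, p[2]]),
                    numeric(1)),
             vapply(cmb, paste, character(1), collapse = "/"))
  } else {
    numeric(0)
  }
  list(n_samples = nrow(flags),
       pct_per_signature = per_sig,
       pct_any = pct(rowSums(flags) > 0),
       pct_pairs = pairs,
       pct_all = pct(rowSums(flags) == ncol(flags)))
}

#' Representation and co-correlation summary of a classification table
#'
#' Per dataset and overall: the percentage of samples correlated with each
#' signature, with at least one signature (`pct_any`), with each unordered
#' signature pair, and with all signatures.  Overall percentages are
#' sample-weighted across datasets (total flagged over total samples);
#' `weighting = "dataset"` averages the per-dataset percentages instead.
#'
#' @param table Classification table from [classify_cohort()] (tables from
#'   several datasets may be row-bound).
#' @param weighting `"sample"` (default) or `"dataset"` for the overall row.
#' @return List with `per_dataset` (named list of summaries) and `overall`;
#'   each summary has `n_samples`, `pct_per_signature`, `pct_any`,
#'   `pct_pairs`, `pct_all`.
#' @export
summarize_representation <- function(table, weighting = c("sample", "dataset")) {
  weighting <- match.arg(weighting)
  if (!nrow(table)) stop("empty classification table")
  flags_of <- function(tab) {
    sig_names <- unique(tab$signature)
    sample_ids <- unique(tab$sample_id)
    m <- matrix(FALSE, length(sample_ids), length(sig_names),
                dimnames = list(sample_ids, sig_names))
    m[cbind(match(tab$sample_id, sample_ids),
            match(tab$signature, sig_names))] <- tab$correlated
    m
  }
  per_ds <- lapply(split(table, table$dataset_id), function(tab) {
    .representation_from_flags(flags_of(tab))
  })
  overall <- if (weighting == "sample") {
    .representation_from_flags(do.call(rbind, lapply(
      split(table, table$dataset_id), flags_of)))
  } else {
    avg <- function(get) {
      vals <- lapply(per_ds, get)
      Reduce(`+`, vals) / length(vals)
    }
    list(n_samples = sum(vapply(per_ds, `[[`, numeric(1), "n_samples")),
         pct_per_signature = avg(function(x) x$pct_per_signature),
         pct_any = avg(function(x) x$pct_any),
         pct_pairs = avg(function(x) x$pct_pairs),
         pct_all = avg(function(x) x$pct_all))
  }
  stopifnot(overall$pct_any >= max(overall$pct_per_signature) - 1e-9)
  list(per_dataset = per_ds, overall = overall)
}

#' Stage-wise signature enrichment across a disease progression
#'
#' For each stage (in the given order) the stage's samples are compared to
#' the rest of the cohort: two-class ranking when the stage has >= 2
#' samples, the singleton statistic otherwise; the signature is scored and
#' its NES / p / FDR estimated from the configured permutation null.
#'
#' @param expr Cohort expression matrix (genes x samples).
#' @param stage_labels Factor/character of per-sample stage labels aligned
#'   with columns; every label must appear in `stage_order`.
#' @param signature Signature gene ids (or a [map_to_human()] result).
#' @param config A [gsea_config()].
#' @param stage_order Stage labels in progression order; default: order of
#'   first appearance.
#' @param fdr_max Significance threshold for the `significant` flag.
#' @return Data frame, one row per stage in order: `stage`, `n_samples`,
#'   `es`, `nes`, `p_nominal`, `fdr_q`, `significant`.
#' @export
stage_enrichment <- function(expr, stage_labels, signature,
                             config = gsea_config(permutation_mode = "gene_set"),
                             stage_order = NULL, fdr_max = 0.25) {
  if (is.list(signature)) signature <- signature$human_members
  stage_labels <- as.character(stage_labels)
  stopifnot(length(stage_labels) == ncol(expr))
  if (is.null(stage_order)) stage_order <- unique(stage_labels)
  unknown <- setdiff(stage_labels, stage_order)
  if (length(unknown)) stop("unknown stage label(s): ", paste(unknown, collapse = ", "))
  if (length(stage_order) < 2L) stop("need >= 2 stages")
  rows <- lapply(seq_along(stage_order), function(i) {
    stg <- stage_order[i]
    ranked <- rank_by_ttest(expr, stage_labels, stg)
    r <- enrichment_score(ranked, signature, config$weight_exponent)
    if (is.null(r) || r$overlap_size < config$min_set_overlap) {
      return(data.frame(stage = stg, n_samples = sum(stage_labels == stg),
                        es = NA_real_, nes = NA_real_, p_nominal = NA_real_,
                        fdr_q = NA_real_, significant = FALSE,
                        stringsAsFactors = FALSE))
    }
    run_cfg <- config
    if (!is.null(config$rng_seed)) {
      run_cfg$rng_seed <- (config$rng_seed + 104729L * i +
                             sum(utf8ToInt(stg))) %% .Machine$integer.max
    }
    null <- if (config$permutation_mode == "gene_set") {
      .gene_set_null_es(ranked, r$overlap_size, run_cfg)
    } else {
      permutation_null(expr, stage_labels, stg, signature, run_cfg)
    }
    st <- normalize_and_fdr(c(sig = r$es), list(sig = null))
    data.frame(stage = stg, n_samples = sum(stage_labels == stg),
               es = st$es, nes = st$nes, p_nominal = st$p_nominal,
               fdr_q = st$fdr_q,
               significant = !is.na(st$fdr_q) && st$fdr_q < fdr_max &&
                 !is.na(st$nes) && st$nes > 0,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
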