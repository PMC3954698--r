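#' Normalize SAGE tag counts to tags per million (TPM)
#'
#' Each sample column is scaled by its library size (column sum) so that the
#' normalized column sums to one million.
#'
#' @param counts Tag-count matrix (genes x samples), as returned by
#'   [read_expression_table()] with `value_kind = "tag_count"`.
#' @return A TPM matrix of the same shape with `value_kind = "tpm"`.
#' @export
normalize_tpm <- function(counts) {
  lib <- colSums(counts)
  zero <- colnames(counts)[lib == 0]
  if (length(zero)) {
    stop("sample(s) with zero total tag count: ", paste(zero, collapse = ", "))
  }
  tpm <- sweep(counts, 2L, lib, "/") * 1e6
  attr(tpm, "value_kind") <- "tpm"
  tpm
}

#' Differential-expression selection criteria
#'
#' The thresholds applied when selecting deregulated genes: fold-change
#' magnitude > `fc_min`, p-value < `p_max`, and mean TPM > `tpm_min` in the
#' tumor or the control group (whichever is larger).  `pseudocount` is added
#' to both sides of every expression ratio before taking logs, bounding
#' reported fold changes for genes absent from one group.
#'
#' @param fc_min Fold-change magnitude threshold (> 1).
#' @param p_max P-value threshold, in (0, 1).
#' @param tpm_min Expression floor on `max(tumor_tpm, control_tpm)`.
#' @param pseudocount Additive constant (TPM) for ratio computation (> 0).
#' @return A `de_criteria` list.
#' @export
de_criteria <- function(fc_min = 1.5, p_max = 0.05, tpm_min = 10,
                        pseudocount = 1) {
  stopifnot(fc_min > 1, p_max > 0, p_max < 1, tpm_min >= 0, pseudocount > 0)
  structure(list(fc_min = fc_min, p_max = p_max, tpm_min = tpm_min,
                 pseudocount = pseudocount), class = "de_criteria")
}

# Smallest nonzero value of v, used as the default variance floor for genes
# whose per-gene variance is exactly zero (e.g. a tumor at an identical
# multiple of every control).  Dropping such genes would silently discard
# the most consistent candidates.
.variance_floor <- function(v) {
  nz <- v[v > 0]
  if (!length(nz)) 1e-8 else min(nz)
}

.de_result <- function(gene_id, tumor_tpm, control_tpm, p_value, pseudocount) {
  ratio <- (tumor_tpm + pseudocount) / (control_tpm + pseudocount)
  direction <- ifelse(ratio >= 1, "up", "down")
  fc <- ifelse(ratio >= 1, ratio, 1 / ratio)
  data.frame(gene_id = gene_id, fc = fc, direction = direction,
             p_value = p_value, tumor_tpm = tumor_tpm,
             control_tpm = control_tpm, stringsAsFactors = FALSE)
}

#' Unreplicated DE test: one tumor sample against multiple controls
#'
#' For each gene the log2 ratio of the tumor to every control (pseudocount
#' added to both) is computed, and the set of per-control ratios is tested
#' against zero with a two-sided one-sample t-test.  The reported fold
#' change is the ratio of pseudocount-adjusted tumor TPM to mean control
#' TPM, as a magnitude >= 1 with a direction flag.
#'
#' @param tumor Named numeric vector of tumor TPM, or a 1-column matrix.
#' @param controls TPM matrix (genes x >= 2 control samples) with the same
#'   genes in the same order.
#' @param criteria A [de_criteria()] object (only `pseudocount` is used here).
#' @param var_floor Variance floor for zero-variance ratio sets; default is
#'   the smallest nonzero per-gene ratio variance in the data.
#' @return A data frame with one row per gene: `gene_id`, `fc`, `direction`,
#'   `p_value`, `tumor_tpm`, `control_tpm`.
#' @export
de_test_unreplicated <- function(tumor, controls, criteria = de_criteria(),
                                 var_floor = NULL) {
  if (is.matrix(tumor)) tumor <- tumor[, 1L]
  controls <- as.matrix(controls)
  n <- ncol(controls)
  if (n < 2L) stop("at least 2 control samples are required (t-test undefined)")
  stopifnot(length(tumor) == nrow(controls))
  pc <- criteria$pseudocount
  ratios <- log2((tumor + pc) / (controls + pc))  # genes x controls
  m <- rowMeans(ratios)
  v <- apply(ratios, 1L, stats::var)
  if (is.null(var_floor)) var_floor <- .variance_floor(v)
  v <- pmax(v, var_floor)
  tstat <- m / sqrt(v / n)
  p <- 2 * stats::pt(abs(tstat), df = n - 1L, lower.tail = FALSE)
  .de_result(rownames(controls) %||% names(tumor), tumor, rowMeans(controls),
             p, pc)
}

#' Replicated DE test: two-sided Student's t between two groups
#'
#' Two-sided t-test on log2(TPM + pseudocount) per gene; pooled variance by
#' default, Welch by option.  Fold change and direction come from the
#' pseudocount-adjusted group mean TPMs.
#'
#' @param group_a Tumor TPM matrix (genes x >= 2 samples).
#' @param group_b Control TPM matrix (genes x >= 2 samples), same genes.
#' @param criteria A [de_criteria()] object (only `pseudocount` is used here).
#' @param var_floor Variance floor for genes with zero pooled variance;
#'   default: smallest nonzero pooled variance in the data.
#' @param welch Use Welch's unequal-variance test instead of pooled.
#' @return Data frame as in [de_test_unreplicated()].
#' @export
de_test_replicated <- function(group_a, group_b, criteria = de_criteria(),
                               var_floor = NULL, welch = FALSE) {
  group_a <- as.matrix(group_a)
  group_b <- as.matrix(group_b)
  na <- ncol(group_a); nb <- ncol(group_b)
  if (na < 2L || nb < 2L) stop("each group needs >= 2 samples")
  stopifnot(nrow(group_a) == nrow(group_b))
  pc <- criteria$pseudocount
  la <- log2(group_a + pc)
  lb <- log2(group_b + pc)
  ma <- rowMeans(la); mb <- rowMeans(lb)
  va <- apply(la, 1L, stats::var)
  vb <- apply(lb, 1L, stats::var)
  if (welch) {
    if (is.null(var_floor)) var_floor <- .variance_floor(c(va, vb))
    va <- pmax(va, var_floor); vb <- pmax(vb, var_floor)
    se2 <- va / na + vb / nb
    df <- se2^2 / ((va / na)^2 / (na - 1L) + (vb / nb)^2 / (nb - 1L))
  } else {
    pooled <- ((na - 1L) * va + (nb - 1L) * vb) / (na + nb - 2L)
    if (is.null(var_floor)) var_floor <- .variance_floor(pooled)
    pooled <- pmax(pooled, var_floor)
    se2 <- pooled * (1 / na + 1 / nb)
    df <- na + nb - 2L
  }
  tstat <- (ma - mb) / sqrt(se2)
  p <- 2 * stats::pt(abs(tstat), df = df, lower.tail = FALSE)
  .de_result(rownames(group_a), rowMeans(group_a), rowMeans(group_b), p, pc)
}

#' Apply the selection criteria and split by direction
#'
#' A gene is selected iff `fc > fc_min`, `p_value < p_max` and
#' `max(tumor_tpm, control_tpm) > tpm_min`.
#'
#' @param results DE result data frame from one of the DE tests.
#' @param criteria A [de_criteria()] object.
#' @return List with character vectors `up` and `down` of selected gene ids.
#' @export
select_deregulated <- function(results, criteria = de_criteria()) {
  keep <- results$fc > criteria$fc_min &
    results$p_value < criteria$p_max &
    pmax(results$tumor_tpm, results$control_tpm) > criteria$tpm_min
  list(up = results$gene_id[keep & results$direction == "up"],
       down = results$gene_id[keep & results$direction == "down"])
}

#' Venn region counts for three gene sets
#'
#' @param sets List of exactly 3 character vectors.
#' @return Named integer vector over the 7 membership regions, names
#'   `"100"`, `"010"`, `"001"`, `"110"`, `"101"`, `"011"`, `"111"` (digit i
#'   = membership in set i).
#' @export
venn_regions <- function(sets) {
  stopifnot(length(sets) == 3L)
  sets <- lapply(sets, unique)
  universe <- unique(unlist(sets))
  code <- vapply(universe, function(g) {
    paste0(as.integer(c(g %in% sets[[1L]], g %in% sets[[2L]], g %in% sets[[3L]])),
           collapse = "")
  }, character(1))
  regions <- c("100", "010", "001", "110", "101", "011", "111")
  counts <- table(factor(code, levels = regions))
  setNames(as.integer(counts), regions)
}

#' Intersect the up/down gene lists of three tumor models
#'
#' @param up_sets,down_sets Lists of 3 character vectors (one per model) of
#'   up- and down-regulated gene ids.
#' @return List with `common_up`, `common_down` (character vectors) and
#'   `venn_up`, `venn_down` (7-region counts from [venn_regions()]).
#' @export
intersect_models <- function(up_sets, down_sets) {
  common3 <- function(s) Reduce(intersect, s)
  list(common_up = common3(up_sets),
       common_down = common3(down_sets),
       venn_up = venn_regions(up_sets),
       venn_down = venn_regions(down_sets))
}

#' qPCR relative quantification: log2 fold change by the ddCT method
#'
#' `-[(CT_target - CT_reference)_transgenic - (CT_target - CT_reference)_control]`,
#' i.e. the negative delta-delta-CT, which equals the log2 fold change of the
#' target gene in the transgenic sample relative to the control after
#' reference-gene normalization.
#'
#' @param ct_target_tg,ct_ref_tg CT of target and reference gene in the
#'   transgenic sample (cycles).
#' @param ct_target_ctrl,ct_ref_ctrl CT of target and reference gene in the
#'   control sample.
#' @return Log2 fold change (vectorized over inputs).
#' @export
qpcr_log2fc <- function(ct_target_tg, ct_ref_tg, ct_target_ctrl, ct_ref_ctrl) {
  stopifnot(is.finite(ct_target_tg), is.finite(ct_ref_tg),
            is.finite(ct_target_ctrl), is.finite(ct_ref_ctrl))
  -((ct_target_tg - ct_ref_tg) - (ct_target_ctrl - ct_ref_ctrl))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
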