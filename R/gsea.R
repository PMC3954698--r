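#' Configuration for the enrichment engine
#'
#' @param weight_exponent Exponent applied to |ranking score| when a gene-set
#'   hit increments the running sum; 0 gives the classic unweighted
#'   Kolmogorov-Smirnov statistic, 1 (default) the standard weighted form.
#' @param n_permutations Number of null permutations (default 1000).
#' @param permutation_mode `"phenotype"` (permute sample labels) or
#'   `"gene_set"` (score random gene sets of equal size; used for pre-ranked
#'   input and for very small phenotype classes).
#' @param rng_seed Integer seed; `NULL` leaves the RNG state alone.
#' @param min_set_overlap Minimum number of set members present in the
#'   ranked universe for a set to be scored (default 5).
#' @return A `gsea_config` list.
#' @export
gsea_config <- function(weight_exponent = 1, n_permutations = 1000,
                        permutation_mode = c("phenotype", "gene_set"),
                        rng_seed = NULL, min_set_overlap = 5) {
  stopifnot(weight_exponent >= 0, n_permutations >= 1)
  structure(list(weight_exponent = weight_exponent,
                 n_permutations = as.integer(n_permutations),
                 permutation_mode = match.arg(permutation_mode),
                 rng_seed = rng_seed,
                 min_set_overlap = as.integer(min_set_overlap)),
            class = "gsea_config")
}

# Evaluate an expression with a locally seeded RNG, restoring the caller's
# RNG state afterwards.  seed = NULL runs unseeded.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  expr
}

# Per-gene two-class t statistics, vectorized over the rows of expr.
# Pooled variance with a floor equal to the smallest nonzero pooled
# variance (constant genes would otherwise give 0/0).
.row_tstats <- function(expr, in_target, metric = "ttest") {
  xa <- expr[, in_target, drop = FALSE]
  xb <- expr[, !in_target, drop = FALSE]
  na <- ncol(xa); nb <- ncol(xb)
  ma <- rowMeans(xa); mb <- rowMeans(xb)
  if (na == 1L) {
    # singleton target: standardize against the rest-only spread
    vb <- rowSums((xb - mb)^2) / (nb - 1L)
    vb <- pmax(vb, .variance_floor(vb))
    return((ma - mb) / sqrt(vb))
  }
  va <- rowSums((xa - ma)^2) / (na - 1L)
  vb <- rowSums((xb - mb)^2) / (nb - 1L)
  if (metric == "s2n") {
    sa <- pmax(sqrt(va), .variance_floor(sqrt(va)))
    sb <- pmax(sqrt(vb), .variance_floor(sqrt(vb)))
    return((ma - mb) / (sa + sb))
  }
  pooled <- ((na - 1L) * va + (nb - 1L) * vb) / (na + nb - 2L)
  pooled <- pmax(pooled, .variance_floor(pooled))
  (ma - mb) / sqrt(pooled * (1 / na + 1 / nb))
}

# Sort scores into a ranked list: descending score, ties broken by gene id
# (C-locale radix order) for bit-reproducibility.
.sorted_ranking <- function(scores, gene_ids) {
  o <- order(-scores, gene_ids, method = "radix")
  setNames(scores[o], gene_ids[o])
}

#' Rank genes by a target-vs-rest t statistic
#'
#' Builds the ranked gene list for a two-class comparison: per-gene
#' two-sample pooled-variance t statistic (target minus rest).  When the
#' target class is a single sample, the statistic is
#' `(x_target - mean_rest) / sd_rest`, the one-vs-rest standardized shift.
#' Genes are sorted by score, best (most target-up) first; ties are broken
#' lexicographically by gene id.
#'
#' @param expr Expression matrix (genes x samples).
#' @param labels Factor/character of per-sample class labels, aligned with
#'   `colnames(expr)`.
#' @param target_class The label treated as the target phenotype; all other
#'   samples form the rest class.
#' @param metric `"ttest"` (default) or `"s2n"` (signal-to-noise,
#'   mean difference over the sum of class standard deviations).
#' @return Named numeric vector of scores, sorted non-increasing; names are
#'   gene ids.
#' @export
rank_by_ttest <- function(expr, labels, target_class, metric = c("ttest", "s2n")) {
  metric <- match.arg(metric)
  labels <- as.character(labels)
  stopifnot(length(labels) == ncol(expr))
  in_target <- labels == target_class
  if (!any(in_target)) stop("target class has no samples")
  if (sum(!in_target) < 3L) {
    stop("rest class needs >= 3 samples for a stable spread estimate")
  }
  .sorted_ranking(.row_tstats(expr, in_target, metric), rownames(expr))
}

#' Rank genes by signed log10 p-value
#'
#' Pre-ranked input built from per-gene differential-expression results:
#' up-regulated genes score `-log10(p)` (positive), down-regulated genes
#' `+log10(p)` (negative), so the most significantly up-regulated genes
#' head the list and the most significantly down-regulated genes end it.
#'
#' @param p_values Named numeric vector of per-gene p-values in (0, 1];
#'   zeros are clamped to the smallest positive double with a warning.
#' @param direction Character vector (`"up"`/`"down"`) aligned with
#'   `p_values`.
#' @return Named numeric vector of signed scores, sorted non-increasing.
#' @export
rank_preranked <- function(p_values, direction) {
  stopifnot(length(p_values) == length(direction),
            all(direction %in% c("up", "down")))
  if (any(p_values <= 0)) {
    warning("p-value(s) of 0 clamped to the smallest positive double")
    p_values <- pmax(p_values, .Machine$double.xmin)
  }
  stopifnot(all(p_values <= 1))
  score <- -log10(p_values) * ifelse(direction == "up", 1, -1)
  .sorted_ranking(score, names(p_values))
}

# Core running-sum extremum from sorted hit positions.
# pos: strictly increasing 1-based hit ranks; w: hit weights (|score|^alpha);
# N: length of the ranked list.  Evaluates the running sum only at hits and
# immediately before hits (the only candidate extrema) -- identical to the
# full N-step walk.  Returns es and the rank index of the extremum.
.es_core <- function(pos, w, N) {
  k <- length(pos)
  nr <- sum(w)
  if (nr == 0) w <- rep(1, k) else w <- w  # all-zero weights: fall back to equal steps
  nr <- sum(w)
  if (k >= N) {  # set covers the whole list: running sum peaks at +1
    return(list(es = 1, at = N))
  }
  miss_step <- 1 / (N - k)
  hit_cum <- cumsum(w) / nr
  before <- c(0, hit_cum[-k]) - (pos - seq_len(k)) * miss_step  # just before hit i
  at <- hit_cum - (pos - seq_len(k)) * miss_step                # at hit i
  # interleave in walk order: before_1, at_1, before_2, at_2, ...
  # a |deviation| tie (e.g. exact +/-x) resolves to the first-attained
  # extremum; the 1e-12 guard keeps that rule stable under fp noise
  cand <- rbind(before, at)
  i <- which(abs(cand) >= max(abs(cand)) - 1e-12)[1L]
  es <- cand[[i]]
  hit_i <- (i + 1L) %/% 2L
  at_rank <- if (i %% 2L == 0L) pos[hit_i] else pos[hit_i] - 1L
  list(es = es, at = at_rank)
}

#' Running-sum enrichment score
#'
#' Walks the ranked list from best to worst; at each gene-set hit the sum
#' increases by `|score|^weight_exponent` (normalized so hit increments sum
#' to 1), at each miss it decreases by `1/(N - n_hits)`.  The enrichment
#' score is the signed maximum deviation of this running sum from zero, and
#' lies in [-1, 1].  The leading edge is the hits at or before the extremum
#' for a positive score, and at or after it for a negative score.
#'
#' @param ranked Ranked list from [rank_by_ttest()]/[rank_preranked()]
#'   (named scores, non-increasing).
#' @param set_members Character vector of gene ids.
#' @param weight_exponent See [gsea_config()].
#' @return List with `es`, `leading_edge` (character), `overlap_size`, and
#'   `extremum_rank`; `NULL` when the set has no overlap with the ranked
#'   universe.
#' @export
enrichment_score <- function(ranked, set_members, weight_exponent = 1) {
  hits <- names(ranked) %in% set_members
  pos <- which(hits)
  k <- length(pos)
  if (k == 0L) return(NULL)
  w <- abs(ranked[pos])^weight_exponent
  core <- .es_core(pos, w, length(ranked))
  le <- if (core$es >= 0) {
    names(ranked)[pos[pos <= core$at]]
  } else {
    names(ranked)[pos[pos >= core$at]]
  }
  list(es = core$es, leading_edge = le, overlap_size = k,
       extremum_rank = core$at)
}

#' Full running-sum profile
#'
#' The complete N-step running sum underlying [enrichment_score()], mainly
#' for plots and diagnostics.  The walk starts at 0 and returns to 0 after
#' the last gene.
#'
#' @inheritParams enrichment_score
#' @return Numeric vector of length `length(ranked)`: the running sum after
#'   each gene.
#' @export
running_sum_profile <- function(ranked, set_members, weight_exponent = 1) {
  hits <- names(ranked) %in% set_members
  k <- sum(hits)
  if (k == 0L) stop("set has no overlap with the ranked universe")
  w <- abs(ranked)^weight_exponent
  w[!hits] <- 0
  if (sum(w) == 0) w[hits] <- 1
  step <- w / sum(w)
  step[!hits] <- -1 / (length(ranked) - k)
  cumsum(step)
}

# ES values of the observed sets under permuted phenotype labels.
# Returns a matrix: permutations x sets.  When the number of distinct
# label arrangements does not exceed n_permutations, all arrangements are
# enumerated instead of sampled (message logged).
.phenotype_null_es <- function(expr, labels, target_class, sets, config,
                               metric = "ttest") {
  labels <- as.character(labels)
  in_target <- labels == target_class
  n <- length(labels)
  k <- sum(in_target)
  n_distinct <- choose(n, k)
  arrangements <- if (n_distinct <= config$n_permutations) {
    message("exhaustive enumeration of ", n_distinct, " label arrangements")
    utils::combn(n, k, simplify = FALSE)
  } else {
    with_seed(config$rng_seed,
              replicate(config$n_permutations, sample.int(n, k),
                        simplify = FALSE))
  }
  out <- matrix(NA_real_, length(arrangements), length(sets))
  colnames(out) <- names(sets)
  for (i in seq_along(arrangements)) {
    tgt <- logical(n)
    tgt[arrangements[[i]]] <- TRUE
    ranked <- .sorted_ranking(.row_tstats(expr, tgt, metric), rownames(expr))
    for (j in seq_along(sets)) {
      r <- enrichment_score(ranked, sets[[j]], config$weight_exponent)
      out[i, j] <- if (is.null(r)) NA_real_ else r$es
    }
  }
  out
}

# ES values of random same-size gene sets on a fixed ranked list
# (gene-set permutation null).  Returns a numeric vector per set size used.
.gene_set_null_es <- function(ranked, overlap_size, config) {
  N <- length(ranked)
  with_seed(config$rng_seed, {
    vapply(seq_len(config$n_permutations), function(i) {
      pos <- sort.int(sample.int(N, overlap_size))
      .es_core(pos, abs(ranked[pos])^config$weight_exponent, N)$es
    }, numeric(1))
  })
}

#' Normalize enrichment scores and estimate permutation FDR
#'
#' For each set, NES = ES divided by the mean magnitude of same-sign null
#' ES values; nominal p is the add-one-smoothed same-sign permutation
#' rank.  FDR q uses the sign-separated pooled-null ratio estimator:
#' the fraction of pooled normalized null scores at least as extreme as the
#' set's NES (among same-sign nulls) divided by the corresponding fraction
#' of observed NES values, clipped to [0, 1] and made monotone within each
#' sign by a cumulative minimum over decreasing |NES|.
#'
#' @param observed Named numeric vector of observed ES, one per set.
#' @param nulls Named list of numeric null ES vectors, one per set (same
#'   names).  `NA` null entries are dropped.
#' @return Data frame: `set_name`, `es`, `nes`, `p_nominal`, `fdr_q`.
#' @export
normalize_and_fdr <- function(observed, nulls) {
  stopifnot(!is.null(names(observed)), all(names(observed) %in% names(nulls)))
  nms <- names(observed)
  nes <- p_nom <- rep(NA_real_, length(nms))
  pooled_norm <- vector("list", length(nms))
  for (i in seq_along(nms)) {
    es <- observed[[i]]
    null <- nulls[[nms[i]]]
    null <- null[!is.na(null)]
    mpos <- mean(null[null >= 0])
    mneg <- mean(abs(null[null < 0]))
    # normalize each null value by its own-sign mean, for pooling
    nn <- ifelse(null >= 0, null / mpos, null / mneg)
    pooled_norm[[i]] <- nn[is.finite(nn)]
    same <- if (es >= 0) null[null >= 0] else null[null < 0]
    p_nom[i] <- (1 + sum(abs(same) >= abs(es))) / (1 + length(same))
    denom <- if (es >= 0) mpos else mneg
    nes[i] <- if (is.finite(denom) && denom > 0) es / denom else NA_real_
  }
  pooled <- unlist(pooled_norm)
  q <- rep(NA_real_, length(nms))
  pos <- which(!is.na(nes) & nes >= 0)
  neg <- which(!is.na(nes) & nes < 0)
  if (length(pos)) {
    np <- pooled[pooled >= 0]
    q[pos] <- vapply(nes[pos], function(x) {
      num <- if (length(np)) mean(np >= x) else 0
      den <- mean(nes[pos] >= x)
      min(1, num / den)
    }, numeric(1))
    o <- order(-nes[pos])
    q[pos][o] <- cummin(q[pos][o])
  }
  if (length(neg)) {
    nn_ <- pooled[pooled < 0]
    q[neg] <- vapply(nes[neg], function(x) {
      num <- if (length(nn_)) mean(nn_ <= x) else 0
      den <- mean(nes[neg] <= x)
      min(1, num / den)
    }, numeric(1))
    o <- order(nes[neg])
    q[neg][o] <- cummin(q[neg][o])
  }
  data.frame(set_name = nms, es = unname(observed), nes = nes,
             p_nominal = p_nom, fdr_q = q, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Phenotype-permutation null ES sample for one gene set
#'
#' Recomputes the whole ranking + scoring pipeline under permuted sample
#' labels.  When the requested number of permutations is at least the number
#' of distinct label arrangements, all arrangements are enumerated.
#'
#' @inheritParams rank_by_ttest
#' @param set_members Gene-set member ids.
#' @param config A [gsea_config()].
#' @return Numeric vector of null ES values.
#' @export
permutation_null <- function(expr, labels, target_class, set_members, config) {
  if (config$permutation_mode == "gene_set") {
    ranked <- rank_by_ttest(expr, labels, target_class)
    ov <- sum(names(ranked) %in% set_members)
    if (ov == 0L) stop("set has no overlap with the ranked universe")
    return(.gene_set_null_es(ranked, ov, config))
  }
  drop(.phenotype_null_es(expr, labels, target_class,
                          list(set = set_members), config))
}

# Shared tail of the two gsea front-ends: observed ES per set (skipping
# sets below the overlap floor), then normalization/FDR.
.observed_es <- function(ranked, gene_sets, config) {
  obs <- numeric(0)
  keep <- character(0)
  overlap <- integer(0)
  leading <- list()
  for (nm in names(gene_sets)) {
    r <- enrichment_score(ranked, gene_sets[[nm]], config$weight_exponent)
    if (is.null(r) || r$overlap_size < config$min_set_overlap) next
    obs[nm] <- r$es
    overlap[nm] <- r$overlap_size
    leading[[nm]] <- r$leading_edge
    keep <- c(keep, nm)
  }
  list(es = obs, overlap = overlap, leading = leading, keep = keep)
}

#' Phenotype-permutation GSEA over a gene-set collection
#'
#' Ranks genes by the target-vs-rest t statistic, scores every set, and
#' estimates NES / nominal p / FDR q from label-permutation nulls shared
#' across sets.
#'
#' @inheritParams rank_by_ttest
#' @param gene_sets Named list of character vectors.
#' @param config A [gsea_config()].
#' @return Data frame per scored set: `set_name`, `es`, `nes`, `p_nominal`,
#'   `fdr_q`, `overlap_size`, plus a `leading_edges` attribute (named list).
#'   Sets with overlap below `min_set_overlap` are omitted.
#' @export
gsea_phenotype <- function(expr, labels, target_class, gene_sets,
                           config = gsea_config(),
                           metric = c("ttest", "s2n")) {
  metric <- match.arg(metric)
  ranked <- rank_by_ttest(expr, labels, target_class, metric)
  ob <- .observed_es(ranked, gene_sets, config)
  if (!length(ob$keep)) stop("no gene set meets the minimum overlap")
  null_mat <- .phenotype_null_es(expr, labels, target_class,
                                 gene_sets[ob$keep], config, metric)
  nulls <- lapply(ob$keep, function(nm) null_mat[, nm])
  names(nulls) <- ob$keep
  res <- normalize_and_fdr(ob$es, nulls)
  res$overlap_size <- unname(ob$overlap[res$set_name])
  attr(res, "leading_edges") <- ob$leading
  res
}

#' Pre-ranked GSEA with a gene-set permutation null
#'
#' Scores each set on a user-supplied ranked list; the null for a set is
#' the ES of random same-size gene sets drawn from the ranked universe.
#'
#' @param ranked Ranked list (named scores, non-increasing), e.g. from
#'   [rank_preranked()].
#' @param gene_sets Named list of character vectors.
#' @param config A [gsea_config()]; `permutation_mode` is forced to
#'   `"gene_set"`.
#' @return As [gsea_phenotype()].
#' @export
gsea_preranked <- function(ranked, gene_sets, config = gsea_config()) {
  ob <- .observed_es(ranked, gene_sets, config)
  if (!length(ob$keep)) stop("no gene set meets the minimum overlap")
  # one null sample per distinct overlap size, reused across same-size sets
  sizes <- unique(unname(ob$overlap[ob$keep]))
  null_by_size <- lapply(sizes, function(k) .gene_set_null_es(ranked, k, config))
  names(null_by_size) <- as.character(sizes)
  nulls <- lapply(ob$keep, function(nm) null_by_size[[as.character(ob$overlap[[nm]])]])
  names(nulls) <- ob$keep
  res <- normalize_and_fdr(ob$es, nulls)
  res$overlap_size <- unname(ob$overlap[res$set_name])
  attr(res, "leading_edges") <- ob$leading
  res
}
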