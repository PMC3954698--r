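#' Deterministic three-set Venn design
#'
#' Partitions per-model gene-list totals into the 7 Venn regions of a
#' three-model overlap: the common core gets `common`, the pairwise regions
#' the supplied sizes (default 0), and the remainder of each model's total
#' goes to its exclusive region.
#'
#' @param common Size of the triple-overlap region.
#' @param totals Integer vector of 3 per-model list sizes.
#' @param pairwise Named sizes for regions `"110"`, `"101"`, `"011"`
#'   (models 1/2, 1/3, 2/3); missing entries default to 0.
#' @return Named 7-region count vector as in [venn_regions()].
#' @export
venn_design <- function(common, totals, pairwise = c("110" = 0, "101" = 0, "011" = 0)) {
  stopifnot(length(totals) == 3L, common >= 0, all(totals >= 0))
  pw <- c("110" = 0, "101" = 0, "011" = 0)
  pw[names(pairwise)] <- pairwise
  excl <- c(totals[1] - common - pw[["110"]] - pw[["101"]],
            totals[2] - common - pw[["110"]] - pw[["011"]],
            totals[3] - common - pw[["101"]] - pw[["011"]])
  if (any(excl < 0)) {
    stop("infeasible design: per-model total smaller than common + pairwise regions")
  }
  out <- c("100" = excl[1], "010" = excl[2], "001" = excl[3],
           "110" = pw[["110"]], "101" = pw[["101"]], "011" = pw[["011"]],
           "111" = common)
  storage.mode(out) <- "integer"
  out
}

# Materialize a Venn design into three member-id sets over fresh gene ids.
.design_to_sets <- function(design, prefix) {
  regions <- names(design)
  ids <- unlist(lapply(regions, function(r) {
    if (design[[r]] == 0) character(0)
    else paste0(prefix, "_", r, "_", seq_len(design[[r]]))
  }))
  membership <- function(model_digit) {
    unlist(lapply(regions, function(r) {
      n <- design[[r]]
      if (n == 0 || substr(r, model_digit, model_digit) != "1") character(0)
      else paste0(prefix, "_", r, "_", seq_len(n))
    }))
  }
  list(all = ids, sets = lapply(1:3, membership))
}

#' Configuration for the zebrafish SAGE simulator
#'
#' Defaults mirror the zebrafish study design at desk scale: three tumor
#' models sharing a planted common core of 21 up- and 16 down-regulated
#' genes, one tumor against 3 pooled controls (unreplicated) or 2 vs 2
#' replicates (replicated), overdispersed negative-binomial tag counts.
#'
#' @param n_genes Number of simulated genes (planted + background).
#' @param library_size Tags per sample; default 1e5 (a 1/100 desk scaling of
#'   the 1e7-scale real libraries; pass e.g. `c(1e7, 2.3e7)` as a range to
#'   draw full-scale sizes).
#' @param n_controls Controls per model (default 3).
#' @param n_tumors Tumor samples per model (1 unreplicated, 2 replicated).
#' @param fold_change Planted fold-change magnitude (default 8).
#' @param common_up,common_down Common-core sizes (defaults 21 and 16).
#' @param up_totals,down_totals Per-model planted list sizes.
#' @param pairwise_up,pairwise_down Pairwise Venn region sizes.
#' @param dispersion Negative-binomial dispersion (default 0.2).
#' @param rng_seed Seed for reproducibility.
#' @return A `zebrafish_sim_config` list including the two resolved Venn
#'   designs (`design_up`, `design_down`).
#' @export
zebrafish_sim_config <- function(n_genes = 2000, library_size = 1e5,
                                 n_controls = 3, n_tumors = 1,
                                 fold_change = 8,
                                 common_up = 21, common_down = 16,
                                 up_totals = c(120, 60, 40),
                                 down_totals = c(30, 60, 50),
                                 pairwise_up = c("110" = 5, "101" = 5, "011" = 5),
                                 pairwise_down = c("110" = 4, "101" = 4, "011" = 4),
                                 dispersion = 0.2, rng_seed = 1) {
  du <- venn_design(common_up, up_totals, pairwise_up)
  dd <- venn_design(common_down, down_totals, pairwise_down)
  n_planted <- sum(du) + sum(dd)
  if (n_planted > n_genes) stop("Venn design larger than n_genes")
  structure(list(n_genes = n_genes, library_size = library_size,
                 n_controls = n_controls, n_tumors = n_tumors,
                 fold_change = fold_change, design_up = du, design_down = dd,
                 dispersion = dispersion, rng_seed = rng_seed),
            class = "zebrafish_sim_config")
}

#' Simulate SAGE tag-count tables for the three tumor models
#'
#' Baseline gene abundances are drawn from a heavy-tailed log-normal and
#' normalized to proportions shared by all models.  Per model, the planted
#' up (down) genes have their tumor-sample proportions multiplied (divided)
#' by the configured fold change, proportions are renormalized, and counts
#' drawn from a negative binomial at the configured library size.
#'
#' @param config A [zebrafish_sim_config()].
#' @return List with `counts` (named list of 3 gene x sample tag-count
#'   matrices, columns `tumor*` then `control*`) and `truth` (planted up /
#'   down gene ids per model, the Venn designs, and the fold change).
#' @export
simulate_sage_counts <- function(config = zebrafish_sim_config()) {
  models <- c("xmrk", "kras", "Myc")
  up <- .design_to_sets(config$design_up, "up")
  dn <- .design_to_sets(config$design_down, "dn")
  n_bg <- config$n_genes - length(up$all) - length(dn$all)
  gene_ids <- c(up$all, dn$all,
                if (n_bg > 0) sprintf("bg_%05d", seq_len(n_bg)))
  n_planted <- length(up$all) + length(dn$all)
  with_seed(config$rng_seed, {
    base <- stats::rlnorm(config$n_genes, meanlog = 0, sdlog = 2)
    # planted genes are drawn from the tag-detectable expression range
    # (roughly 100-3000 TPM): real signatures are defined over genes that
    # clear the TPM detection floor, so the truth must be detectable too
    base[seq_len(n_planted)] <- sum(base) * 10^stats::runif(n_planted, -4, -2.5)
    base <- base / sum(base)
    names(base) <- gene_ids
    size <- 1 / config$dispersion
    draw_lib <- function() {
      if (length(config$library_size) == 2L) {
        round(stats::runif(1, config$library_size[1], config$library_size[2]))
      } else {
        config$library_size
      }
    }
    counts <- lapply(1:3, function(m) {
      tprop <- base
      tprop[up$sets[[m]]] <- tprop[up$sets[[m]]] * config$fold_change
      tprop[dn$sets[[m]]] <- tprop[dn$sets[[m]]] / config$fold_change
      tprop <- tprop / sum(tprop)
      cols <- c(paste0("tumor", seq_len(config$n_tumors)),
                paste0("control", seq_len(config$n_controls)))
      mat <- vapply(seq_along(cols), function(j) {
        p <- if (j <= config$n_tumors) tprop else base
        stats::rnbinom(config$n_genes, size = size, mu = p * draw_lib())
      }, numeric(config$n_genes))
      dimnames(mat) <- list(gene_ids, cols)
      validate_expression_table(mat, "tag_count")
    })
    names(counts) <- models
    truth <- list(up = setNames(up$sets, models),
                  down = setNames(dn$sets, models),
                  design_up = config$design_up,
                  design_down = config$design_down,
                  fold_change = config$fold_change)
    list(counts = counts, truth = truth)
  })
}

#' Simulate a human cohort with planted signature-active subgroups
#'
#' Log2-scale microarray-like intensities: per-gene baseline means drawn
#' around 7 (typical log2 intensity), Gaussian noise, and for every sample
#' that carries a signature membership an additive shift of
#' `effect_size * noise_sd` on that signature's genes.  Memberships are
#' independent Bernoulli draws per (sample, signature) and may overlap,
#' giving the co-correlation structure of real cohorts.
#'
#' @param signatures Named list of signature gene-id vectors.
#' @param n_samples Cohort size (default 100).
#' @param n_genes Total gene universe (signature genes plus background).
#' @param membership_prob Per-signature activation probability (default
#'   0.2), or a named vector per signature.  Ignored when `membership` is
#'   supplied.
#' @param membership Optional logical matrix (n_samples x signatures) of
#'   planted memberships.
#' @param effect_size Shift on active-signature genes, in noise-sd units.
#' @param noise_sd Residual log2-scale standard deviation (default 1).
#' @param rng_seed Seed.
#' @return List with `expr` (gene x sample intensity matrix) and `truth`
#'   (the membership matrix).
#' @export
simulate_human_cohort <- function(signatures, n_samples = 100, n_genes = 2000,
                                  membership_prob = 0.2, membership = NULL,
                                  effect_size = 3, noise_sd = 1, rng_seed = 1) {
  stopifnot(!is.null(names(signatures)), effect_size >= 0, noise_sd > 0)
  sig_genes <- unique(unlist(signatures))
  n_bg <- n_genes - length(sig_genes)
  if (n_bg < 0) stop("n_genes smaller than the signature gene universe")
  gene_ids <- c(sig_genes, if (n_bg > 0) sprintf("hbg_%05d", seq_len(n_bg)))
  missing <- setdiff(sig_genes, gene_ids)
  if (length(missing)) stop("unknown signature gene(s): ", paste(missing, collapse = ", "))
  k <- length(signatures)
  if (is.null(membership)) {
    prob <- if (length(membership_prob) == 1L) {
      rep(membership_prob, k)
    } else {
      membership_prob[names(signatures)]
    }
  }
  with_seed(rng_seed, {
    if (is.null(membership)) {
      membership <- vapply(seq_len(k), function(s) {
        stats::runif(n_samples) < prob[s]
      }, logical(n_samples))
      dimnames(membership) <- list(sprintf("s%03d", seq_len(n_samples)),
                                   names(signatures))
    } else {
      stopifnot(nrow(membership) == n_samples, ncol(membership) == k)
      if (is.null(rownames(membership))) {
        rownames(membership) <- sprintf("s%03d", seq_len(n_samples))
      }
      colnames(membership) <- names(signatures)
    }
    baseline <- stats::rnorm(length(gene_ids), mean = 7, sd = 1)
    expr <- matrix(stats::rnorm(length(gene_ids) * n_samples,
                                mean = baseline, sd = noise_sd),
                   nrow = length(gene_ids), ncol = n_samples,
                   dimnames = list(gene_ids, rownames(membership)))
    for (s in seq_len(k)) {
      g <- signatures[[s]]
      active <- which(membership[, s])
      if (length(active)) {
        expr[g, active] <- expr[g, active] + effect_size * noise_sd
      }
    }
    expr <- pmax(expr, 0)
    list(expr = validate_expression_table(expr, "intensity"),
         truth = membership)
  })
}
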