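make_planted_cohort <- function(n_samples = 8, n_genes = 120, n_sig = 15,
                                hot_samples = 1, shift = 6, seed = 41) {
  set.seed(seed)
  expr <- matrix(rnorm(n_genes * n_samples, 7), n_genes, n_samples,
                 dimnames = list(sprintf("g%03d", 1:n_genes),
                                 sprintf("s%02d", 1:n_samples)))
  sig <- rownames(expr)[1:n_sig]
  expr[sig, hot_samples] <- expr[sig, hot_samples] + shift
  expr <- pmax(expr, 0)
  list(expr = validate_expression_table(expr, "intensity"), sig = sig)
}

test_that("a sample with the signature at its extreme is flagged", {
  ch <- make_planted_cohort()
  cfg <- gsea_config(permutation_mode = "gene_set", n_permutations = 200,
                     rng_seed = 1)
  res <- classify_sample(ch$expr, "s01", ch$sig, cfg)
  expect_gt(res$es, 0.8)
  expect_lt(res$fdr_q, 0.25)
  expect_gt(res$nes, 1)
})

test_that("a signature absent from the platform yields a no-result marker", {
  ch <- make_planted_cohort()
  cfg <- gsea_config(permutation_mode = "gene_set", n_permutations = 50)
  expect_message(res <- classify_sample(ch$expr, "s01",
                                        paste0("missing", 1:10), cfg),
                 "overlap")
  expect_true(is.na(res$es))
  expect_identical(res$reason, "low_overlap")
})

test_that("cohort classification flags exactly the planted sample", {
  ch <- make_planted_cohort(n_samples = 6)
  cfg <- gsea_config(permutation_mode = "gene_set", n_permutations = 200,
                     rng_seed = 3)
  tab <- classify_cohort(ch$expr, list(sig = ch$sig), cfg)
  flagged <- tab$sample_id[tab$correlated]
  expect_identical(flagged, "s01")
})

test_that("classification is invariant to sample and gene ordering", {
  ch <- make_planted_cohort(n_samples = 8, hot_samples = c(2, 5))
  cfg <- gsea_config(permutation_mode = "gene_set", n_permutations = 200,
                     rng_seed = 11)
  tab1 <- classify_cohort(ch$expr, list(sig = ch$sig), cfg)
  perm_s <- sample(ncol(ch$expr))
  perm_g <- sample(nrow(ch$expr))
  tab2 <- classify_cohort(ch$expr[perm_g, perm_s], list(sig = ch$sig), cfg)
  f1 <- setNames(tab1$correlated, tab1$sample_id)
  f2 <- setNames(tab2$correlated, tab2$sample_id)
  expect_identical(f1[sort(names(f1))], f2[sort(names(f2))])
})

test_that("a signature planted down is never flagged when positivity is required", {
  ch <- make_planted_cohort(shift = -6)
  cfg <- gsea_config(permutation_mode = "gene_set", n_permutations = 200,
                     rng_seed = 5)
  tab <- classify_cohort(ch$expr, list(sig = ch$sig), cfg,
                         classification_criteria(require_positive = TRUE))
  expect_false(any(tab$correlated[tab$sample_id == "s01"]))
})

test_that("representation summary matches brute-force set counting", {
  tab <- data.frame(
    dataset_id = "d1",
    sample_id = rep(paste0("s", 1:4), times = 3),
    signature = rep(c("A", "B", "C"), each = 4),
    correlated = c(TRUE, TRUE, FALSE, FALSE,   # A = {s1, s2}
                   FALSE, TRUE, FALSE, FALSE,  # B = {s2}
                   rep(FALSE, 4)),             # C = {}
    stringsAsFactors = FALSE)
  s <- summarize_representation(tab)$overall
  expect_equal(unname(s$pct_per_signature), c(50, 25, 0))
  expect_equal(s$pct_any, 50)
  expect_equal(unname(s$pct_pairs[["A/B"]]), 25)
  expect_equal(s$pct_all, 0)

  set.seed(42)
  for (rep_i in 1:5) {
    flags <- matrix(runif(20 * 3) < 0.4, 20, 3,
                    dimnames = list(sprintf("s%02d", 1:20), c("A", "B", "C")))
    tab2 <- data.frame(
      dataset_id = "dX",
      sample_id = rep(rownames(flags), 3),
      signature = rep(colnames(flags), each = 20),
      correlated = as.vector(flags), stringsAsFactors = FALSE)
    s2 <- summarize_representation(tab2)$overall
    brute_any <- 0; brute_all <- 0
    for (i in 1:20) {
      if (any(flags[i, ])) brute_any <- brute_any + 1
      if (all(flags[i, ])) brute_all <- brute_all + 1
    }
    expect_equal(s2$pct_any, 100 * brute_any / 20)
    expect_equal(s2$pct_all, 100 * brute_all / 20)
    expect_equal(unname(s2$pct_pairs[["A/C"]]),
                 100 * sum(flags[, "A"] & flags[, "C"]) / 20)
    # inclusion-exclusion consistency
    expect_gte(s2$pct_any, max(s2$pct_per_signature))
    expect_lte(s2$pct_all, min(s2$pct_pairs))
  }
  expect_error(summarize_representation(tab[0, ]), "empty")
})

test_that("overall percentages can be sample- or dataset-weighted", {
  one <- function(ds, n, k) data.frame(
    dataset_id = ds, sample_id = paste0(ds, seq_len(n)), signature = "A",
    correlated = c(rep(TRUE, k), rep(FALSE, n - k)), stringsAsFactors = FALSE)
  tab <- rbind(one("big", 90, 45), one("small", 10, 0))
  sw <- summarize_representation(tab, weighting = "sample")$overall
  dw <- summarize_representation(tab, weighting = "dataset")$overall
  expect_equal(unname(sw$pct_per_signature), 45)
  expect_equal(unname(dw$pct_per_signature), 25)
})

test_that("stage enrichment recovers a planted monotone activation", {
  set.seed(43)
  stages <- rep(paste0("st", 1:5), each = 4)
  n_genes <- 150
  expr <- matrix(rnorm(n_genes * 20, 7), n_genes, 20,
                 dimnames = list(sprintf("g%03d", 1:n_genes), sprintf("s%02d", 1:20)))
  sig <- rownames(expr)[1:20]
  for (i in 1:5) {
    expr[sig, stages == paste0("st", i)] <-
      expr[sig, stages == paste0("st", i)] + (i - 1) * 1.5
  }
  prof <- stage_enrichment(validate_expression_table(expr, "intensity"),
                           stages, sig,
                           gsea_config(permutation_mode = "gene_set",
                                       n_permutations = 100, rng_seed = 2),
                           stage_order = paste0("st", 1:5))
  expect_identical(prof$stage, paste0("st", 1:5))
  # NES non-decreasing allowing a single Monte-Carlo inversion
  expect_lte(sum(diff(prof$nes) < 0), 1)
  expect_true(prof$significant[5])
  expect_false(prof$significant[1])

  expect_error(stage_enrichment(expr, rep("only", 20), sig), ">= 2 stages")
  expect_error(stage_enrichment(expr, stages, sig,
                                stage_order = paste0("st", 1:4)),
               "unknown stage")
})
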