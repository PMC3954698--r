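test_that("t-statistic ranking matches an independent formula and tie rules", {
  set.seed(31)
  expr <- random_expr(50, 10, seed = 31)
  labels <- rep(c("t", "r"), each = 5)
  ranked <- rank_by_ttest(expr, labels, "t")
  oracle <- vapply(rownames(expr), function(g) {
    a <- expr[g, 1:5]; b <- expr[g, 6:10]
    sp <- sqrt(((4) * var(a) + (4) * var(b)) / 8)
    (mean(a) - mean(b)) / (sp * sqrt(1 / 5 + 1 / 5))
  }, numeric(1))
  expect_equal(unname(ranked[names(oracle)[order(-oracle)]]),
               unname(sort(oracle, decreasing = TRUE)), tolerance = 1e-10)
  expect_true(all(diff(ranked) <= 1e-12))

  # constant gene scores 0 after the variance floor; perfect separation tops
  expr2 <- expr
  expr2["g0001", ] <- 5
  expr2["g0002", ] <- c(rep(10, 5), rep(0, 5))
  r2 <- rank_by_ttest(expr2, labels, "t")
  expect_equal(unname(r2["g0001"]), 0)
  expect_identical(names(r2)[1], "g0002")

  expect_error(rank_by_ttest(expr[, 1:3], c("t", "r", "r"), "t"), ">= 3")
})

test_that("ties in ranking scores break lexicographically by gene id", {
  scores <- c(zz = 1, aa = 1, mm = 2, bb = 1)
  ranked <- zfsig:::.sorted_ranking(scores, names(scores))
  expect_identical(names(ranked), c("mm", "aa", "bb", "zz"))
})

test_that("signed log10-p pre-ranking follows the formula", {
  p <- c(gu = 0.01, gd = 0.01, g1 = 1)
  ranked <- rank_preranked(p, c("up", "down", "up"))
  expect_equal(unname(ranked["gu"]), 2)
  expect_equal(unname(ranked["gd"]), -2)
  expect_equal(unname(ranked["g1"]), 0)
  expect_identical(names(ranked), c("gu", "g1", "gd"))

  expect_warning(rank_preranked(c(a = 0, b = 0.5), c("up", "down")), "clamped")

  set.seed(32)
  p2 <- setNames(runif(100, min = 1e-6), sprintf("g%03d", 1:100))
  dir2 <- sample(c("up", "down"), 100, TRUE)
  ranked2 <- rank_preranked(p2, dir2)
  scores <- -log10(p2) * ifelse(dir2 == "up", 1, -1)
  expect_identical(names(ranked2), names(sort(scores, decreasing = TRUE)))
})

test_that("enrichment score equals brute-force enumeration and hits extremes", {
  # weight 0, all hits at the top -> ES = 1; at the bottom -> ES = -1
  r <- setNames(seq(10, 1), paste0("g", 1:10))
  expect_equal(enrichment_score(r, paste0("g", 1:3), 0)$es, 1)
  expect_equal(enrichment_score(r, paste0("g", 8:10), 0)$es, -1)

  # N = 10, hits at ranks {2, 5, 9}, weight 0, vs explicit enumeration
  hits <- names(r)[c(2, 5, 9)]
  e <- enrichment_score(r, hits, 0)
  expect_equal(e$es, oracle_es(unname(r), names(r) %in% hits, 0),
               tolerance = 1e-12)
  expect_equal(e$overlap_size, 3L)

  # all subsets of a random N = 8 list, weights 0 and 1
  set.seed(33)
  scores <- sort(rnorm(8), decreasing = TRUE)
  names(scores) <- paste0("g", 1:8)
  for (mask in 1:(2^8 - 1)) {
    is_hit <- as.logical(bitwAnd(mask, 2^(0:7)))
    members <- names(scores)[is_hit]
    for (w in c(0, 1)) {
      got <- enrichment_score(scores, members, w)$es
      expect_equal(got, oracle_es(unname(scores), is_hit, w),
                   tolerance = 1e-10)
    }
  }

  expect_null(enrichment_score(r, c("absent1", "absent2")))
})

test_that("running sum starts/ends at zero and reversal negates the ES", {
  set.seed(34)
  scores <- sort(rnorm(40), decreasing = TRUE)
  names(scores) <- sprintf("g%02d", 1:40)
  members <- sample(names(scores), 8)
  for (w in c(0, 1)) {
    prof <- running_sum_profile(scores, members, w)
    expect_equal(unname(prof[40]), 0, tolerance = 1e-12)
    expect_true(max(abs(prof)) <= 1 + 1e-12)
    es_fwd <- enrichment_score(scores, members, w)$es
    rev_scores <- rev(-scores)
    es_rev <- enrichment_score(rev_scores, members, w)$es
    expect_equal(es_rev, -es_fwd, tolerance = 1e-12)
  }
})

test_that("the ES agrees with an established reference implementation", {
  skip_if_not_installed("fgsea")
  set.seed(71)
  for (i in 1:10) {
    N <- sample(50:200, 1)
    stats <- sort(rnorm(N), decreasing = TRUE)
    names(stats) <- sprintf("g%03d", seq_len(N))
    idx <- sort(sample(N, sample(5:20, 1)))
    mine <- enrichment_score(stats, names(stats)[idx], 1)$es
    ref <- fgsea::calcGseaStat(stats, idx, gseaParam = 1)
    expect_equal(mine, ref, tolerance = 1e-10)
  }
})

test_that("leading edge contains the hits on the extremum side", {
  r <- setNames(seq(10, 1), paste0("g", 1:10))
  pos <- enrichment_score(r, c("g1", "g2", "g9"), 0)
  expect_true(all(pos$leading_edge %in% c("g1", "g2")))
  neg <- enrichment_score(r, c("g8", "g9", "g10"), 0)
  expect_identical(sort(neg$leading_edge), sort(c("g8", "g9", "g10")))
})

test_that("phenotype permutation enumerates exhaustively and is seeded", {
  expr <- random_expr(30, 6, seed = 35)
  labels <- c("t", rep("r", 5))
  cfg <- gsea_config(n_permutations = 1000, rng_seed = 1)
  members <- rownames(expr)[1:6]
  expect_message(null1 <- permutation_null(expr, labels, "t", members, cfg),
                 "6 label arrangements")
  expect_length(null1, 6)

  # sampled mode: same seed, same null
  expr2 <- random_expr(30, 12, seed = 36)
  labels2 <- rep(c("t", "r"), each = 6)
  cfg2 <- gsea_config(n_permutations = 50, rng_seed = 7)
  n1 <- permutation_null(expr2, labels2, "t", members, cfg2)
  n2 <- permutation_null(expr2, labels2, "t", members, cfg2)
  expect_identical(n1, n2)
  expect_length(n1, 50)
})

test_that("NES normalization and empirical p behave at their identities", {
  nulls <- list(s = c(0.5, 0.3, 0.4, -0.2, -0.6))
  # observed equal to the mean of the same-sign nulls -> NES = 1
  res <- normalize_and_fdr(c(s = 0.4), nulls)
  expect_equal(res$nes, 1)
  # observed above every null -> p = 1 / (n_same_sign + 1)
  res2 <- normalize_and_fdr(c(s = 0.9), nulls)
  expect_equal(res2$p_nominal, 1 / 4)
  # no same-sign nulls
  res3 <- normalize_and_fdr(c(s = -0.5), list(s = c(0.1, 0.2)))
  expect_equal(res3$p_nominal, 1)
  expect_true(is.na(res3$nes))
})

test_that("gene-set permutation p-values are super-uniform on null data", {
  set.seed(37)
  scores <- sort(rnorm(200), decreasing = TRUE)
  names(scores) <- sprintf("g%03d", 1:200)
  sets <- lapply(1:30, function(i) sample(names(scores), 15))
  names(sets) <- paste0("s", 1:30)
  res <- gsea_preranked(scores, sets, gsea_config(n_permutations = 200,
                                                  rng_seed = 5))
  for (alpha in c(0.1, 0.25, 0.5)) {
    se <- sqrt(alpha * (1 - alpha) / nrow(res))
    expect_lt(mean(res$p_nominal < alpha), alpha + 3 * se + 0.05)
  }
  expect_true(all(res$fdr_q >= 0 & res$fdr_q <= 1))
})
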