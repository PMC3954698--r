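test_that("TPM normalization follows the counts/library-size formula", {
  m <- matrix(c(5, 10, 35), 3, 1, dimnames = list(c("a", "b", "c"), "s1"))
  m <- validate_expression_table(m, "tag_count")
  expect_equal(unname(normalize_tpm(m)[, 1]), c(100000, 200000, 700000))

  m2 <- matrix(c(0, 10, 30), 3, 1, dimnames = list(c("a", "b", "c"), "s1"))
  expect_equal(unname(normalize_tpm(m2)[1, 1]), 0)

  set.seed(3)
  r <- matrix(rpois(200 * 4, 40), 200, 4,
              dimnames = list(sprintf("g%03d", 1:200), paste0("s", 1:4)))
  tpm <- normalize_tpm(r)
  expect_equal(unname(colSums(tpm)), rep(1e6, 4), tolerance = 1e-9)

  bad <- matrix(c(1, 2, 0, 0), 2, 2,
                dimnames = list(c("a", "b"), c("ok", "empty")))
  expect_error(normalize_tpm(bad), "empty")
})

test_that("unreplicated one-sample ratio t-test matches the closed form", {
  controls <- matrix(c(10, 20, 40), 1, 3,
                     dimnames = list("g1", paste0("c", 1:3)))
  res <- de_test_unreplicated(setNames(80, "g1"), controls)
  ratios <- log2(81 / c(11, 21, 41))
  expect_equal(res$p_value, oracle_one_sample_p(ratios), tolerance = 1e-12)
  expect_equal(res$fc, (80 + 1) / (mean(c(10, 20, 40)) + 1))
  expect_identical(res$direction, "up")

  # tumor identical to every control: all ratios 0, never selected
  ctrl_eq <- matrix(50, 1, 3, dimnames = list("g1", paste0("c", 1:3)))
  null_res <- de_test_unreplicated(setNames(50, "g1"), ctrl_eq)
  expect_equal(null_res$fc, 1)
  sel <- select_deregulated(null_res, de_criteria())
  expect_length(sel$up, 0)
  expect_length(sel$down, 0)

  # zero ratio variance (tumor at an exact pseudocount-scale multiple of
  # identical controls): the variance floor keeps the gene reportable
  resc <- de_test_unreplicated(setNames(39, "g1"),
                               matrix(9, 1, 3, dimnames = list("g1", paste0("c", 1:3))))
  expect_true(is.finite(resc$p_value))
  expect_equal(resc$fc, 4)   # (39+1)/(9+1)
  expect_identical(resc$direction, "up")

  expect_error(de_test_unreplicated(setNames(5, "g1"),
                                    matrix(3, 1, 1, dimnames = list("g1", "c1"))),
               "2 control")
})

test_that("replicated test equals the textbook pooled t and its conventions", {
  # identical groups -> t = 0, p = 1
  ga <- matrix(8, 2, 2, dimnames = list(c("g1", "g2"), c("a1", "a2")))
  gb <- matrix(8, 2, 2, dimnames = list(c("g1", "g2"), c("b1", "b2")))
  res <- de_test_replicated(ga, gb)
  expect_equal(res$p_value, c(1, 1))

  # (16,16) vs (4,4): direction up, pseudocount-bounded fc = 17/5
  ga2 <- matrix(16, 1, 2, dimnames = list("g1", c("a1", "a2")))
  gb2 <- matrix(4, 1, 2, dimnames = list("g1", c("b1", "b2")))
  res2 <- de_test_replicated(ga2, gb2, var_floor = 1e-4)
  expect_identical(res2$direction, "up")
  expect_equal(res2$fc, 17 / 5)

  # random 2v2 data agrees with t.test(var.equal = TRUE) to 1e-10
  set.seed(21)
  a <- matrix(rlnorm(50 * 2, 5), 50, 2,
              dimnames = list(sprintf("g%02d", 1:50), c("a1", "a2")))
  b <- matrix(rlnorm(50 * 2, 5), 50, 2,
              dimnames = list(sprintf("g%02d", 1:50), c("b1", "b2")))
  res3 <- de_test_replicated(a, b, var_floor = 0)
  oracle <- vapply(1:50, function(i) {
    t.test(log2(a[i, ] + 1), log2(b[i, ] + 1), var.equal = TRUE)$p.value
  }, numeric(1))
  expect_equal(res3$p_value, oracle, tolerance = 1e-10)

  expect_error(de_test_replicated(ga2[, 1, drop = FALSE], gb2), ">= 2 samples")
})

test_that("label swap flips direction and preserves p-values", {
  set.seed(5)
  tumor <- setNames(rlnorm(30, 4), sprintf("g%02d", 1:30))
  controls <- matrix(rlnorm(30 * 3, 4), 30, 3,
                     dimnames = list(names(tumor), paste0("c", 1:3)))
  fwd <- de_test_unreplicated(tumor, controls, var_floor = 1e-8)
  # swapping roles in the replicated test
  a <- matrix(rlnorm(30 * 2, 4), 30, 2, dimnames = list(names(tumor), c("a1", "a2")))
  b <- matrix(rlnorm(30 * 2, 4), 30, 2, dimnames = list(names(tumor), c("b1", "b2")))
  r1 <- de_test_replicated(a, b, var_floor = 1e-8)
  r2 <- de_test_replicated(b, a, var_floor = 1e-8)
  expect_equal(r1$p_value, r2$p_value, tolerance = 1e-12)
  swapped <- ifelse(r1$direction == "up", "down", "up")
  ties <- r1$fc == 1
  expect_identical(r2$direction[!ties], swapped[!ties])
  expect_true(all(fwd$fc >= 1))
})

test_that("selection filter equals brute-force enumeration and is monotone", {
  crit <- de_criteria()
  gart <- data.frame(gene_id = "gart", fc = 3.32, direction = "up",
                     p_value = 1.42e-3, tumor_tpm = 120, control_tpm = 35)
  expect_identical(select_deregulated(gart, crit)$up, "gart")
  weak <- within(gart, fc <- 1.2)
  expect_length(select_deregulated(weak, crit)$up, 0)

  set.seed(9)
  n <- 1000
  res <- data.frame(
    gene_id = sprintf("g%04d", 1:n),
    fc = exp(abs(rnorm(n))),
    direction = sample(c("up", "down"), n, TRUE),
    p_value = runif(n),
    tumor_tpm = rlnorm(n, 3), control_tpm = rlnorm(n, 3),
    stringsAsFactors = FALSE)
  got <- select_deregulated(res, crit)
  brute_up <- character(0); brute_down <- character(0)
  for (i in 1:n) {
    if (res$fc[i] > 1.5 && res$p_value[i] < 0.05 &&
        max(res$tumor_tpm[i], res$control_tpm[i]) > 10) {
      if (res$direction[i] == "up") brute_up <- c(brute_up, res$gene_id[i])
      else brute_down <- c(brute_down, res$gene_id[i])
    }
  }
  expect_identical(got$up, brute_up)
  expect_identical(got$down, brute_down)

  relaxed <- select_deregulated(res, de_criteria(fc_min = 1.2, p_max = 0.1,
                                                 tpm_min = 5))
  expect_true(all(got$up %in% relaxed$up))
  expect_true(all(got$down %in% relaxed$down))
})

test_that("three-model intersection matches enumeration and sums to the union", {
  disjoint <- list(c("a", "b"), c("c"), c("d", "e"))
  ix <- intersect_models(disjoint, disjoint)
  expect_length(ix$common_up, 0)
  expect_equal(unname(ix$venn_up[c("110", "101", "011", "111")]), rep(0L, 4))

  set.seed(2)
  pool <- sprintf("G%03d", 1:100)
  s1 <- sample(pool, 50); s2 <- sample(pool, 30); s3 <- sample(pool, 20)
  got <- venn_regions(list(s1, s2, s3))
  expect_identical(got, oracle_venn(s1, s2, s3))
  expect_equal(sum(got), length(unique(c(s1, s2, s3))))
})

test_that("ddCT log2 fold change follows the formula and its symmetries", {
  expect_equal(qpcr_log2fc(20, 20, 20, 20), 0)
  expect_equal(qpcr_log2fc(20, 15, 24, 15), 4)
  expect_equal(qpcr_log2fc(24, 15, 20, 15), -4)
})
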