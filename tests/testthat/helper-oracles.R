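# Independent oracles, deliberately written as plain loops / enumerations so
# they share no code with the implementation they check.

# Step-by-step running-sum walk; returns the signed maximum deviation.
oracle_es <- function(scores, is_hit, weight) {
  n <- length(scores)
  nh <- sum(is_hit)
  w <- abs(scores)^weight
  nr <- sum(w[is_hit])
  if (nr == 0) {
    w[is_hit] <- 1
    nr <- nh
  }
  running <- 0
  best <- 0
  for (i in seq_len(n)) {
    running <- running + if (is_hit[i]) w[i] / nr else -1 / (n - nh)
    # strict improvement beyond fp noise: the first-attained extremum wins a tie
    if (abs(running) > abs(best) + 1e-12) best <- running
  }
  best
}

# Closed-form one-sample t-test p-value on a vector against mean 0.
oracle_one_sample_p <- function(x) {
  n <- length(x)
  t <- mean(x) / (sd(x) / sqrt(n))
  2 * pt(abs(t), df = n - 1, lower.tail = FALSE)
}

# Brute-force 7-region Venn counts by direct membership enumeration.
oracle_venn <- function(a, b, c) {
  all_ids <- unique(c(a, b, c))
  counts <- setNames(integer(7), c("100","010","001","110","101","011","111"))
  for (g in all_ids) {
    key <- paste0(as.integer(g %in% a), as.integer(g %in% b), as.integer(g %in% c))
    counts[key] <- counts[key] + 1L
  }
  counts
}

# Group-by maximum, one cell at a time.
oracle_groupby_max <- function(values, mapping) {
  clusters <- unique(unname(mapping[rownames(values)[rownames(values) %in% names(mapping)]]))
  out <- matrix(NA_real_, length(clusters), ncol(values),
                dimnames = list(clusters, colnames(values)))
  for (cl in clusters) {
    feats <- names(mapping)[mapping == cl]
    feats <- intersect(feats, rownames(values))
    for (j in seq_len(ncol(values))) {
      out[cl, j] <- max(values[feats, j])
    }
  }
  out
}

# Naive agglomerative clustering (average/complete/single linkage) over a
# precomputed distance matrix; returns the sorted merge heights.
oracle_agglo_heights <- function(d_mat, linkage = "average") {
  n <- nrow(d_mat)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  link <- function(ci, cj) {
    vals <- d_mat[ci, cj, drop = FALSE]
    switch(linkage,
           average = mean(vals),
           complete = max(vals),
           single = min(vals))
  }
  while (length(clusters) > 1L) {
    best <- Inf; bi <- bj <- NA
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (i < j) {
          h <- link(clusters[[i]], clusters[[j]])
          if (h < best) { best <- h; bi <- i; bj <- j }
        }
      }
    }
    heights <- c(heights, best)
    clusters[[bi]] <- c(clusters[[bi]], clusters[[bj]])
    clusters[[bj]] <- NULL
  }
  sort(heights)
}

# Random expression matrix with unique padded gene / sample ids.
random_expr <- function(n_genes, n_samples, seed = 1, kind = "intensity") {
  set.seed(seed)
  m <- matrix(abs(rnorm(n_genes * n_samples, mean = 7)), n_genes, n_samples,
              dimnames = list(sprintf("g%04d", seq_len(n_genes)),
                              sprintf("s%03d", seq_len(n_samples))))
  validate_expression_table(m, kind)
}

# Pivot a classify_cohort table into a samples x signatures flag matrix.
flags_matrix <- function(tab) {
  samples <- unique(tab$sample_id)
  sigs <- unique(tab$signature)
  m <- matrix(FALSE, length(samples), length(sigs),
              dimnames = list(samples, sigs))
  m[cbind(match(tab$sample_id, samples), match(tab$signature, sigs))] <-
    tab$correlated
  m
}
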