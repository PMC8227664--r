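# Shared fixtures and independent oracles for the test suite.

# tiny feature table from explicit vectors; abundance rows are features
tiny_table <- function(rt, mz, ab, is_standard = NULL) {
  nf <- length(rt)
  feats <- data.frame(feature_id = sprintf("f%02d", seq_len(nf)),
                      rt_s = rt, mz = mz,
                      is_standard = if (is.null(is_standard))
                        rep(FALSE, nf) else is_standard)
  rownames(ab) <- feats$feature_id
  colnames(ab) <- sprintf("s%02d", seq_len(ncol(ab)))
  feature_table(feats, ab)
}

# exact zero-mean orthogonal design vectors for correlation fixtures
z1 <- c(1, -1, 1, -1, 1, -1, 1, -1)
z2 <- c(1, 1, -1, -1, 1, 1, -1, -1)

# adjusted Rand index (independent contingency-table formula)
ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  maxi <- (sum_a + sum_b) / 2
  (sum_ij - expected) / (maxi - expected)
}

# brute-force total effects on a DAG by route enumeration
enumerate_total_effect <- function(B, src, tgt) {
  v <- rownames(B)
  total <- 0
  walk <- function(node, prod) {
    for (nxt in v) {
      co <- B[nxt, node]
      if (co != 0) {
        if (nxt == tgt) total <<- total + prod * co
        walk(nxt, prod * co)
      }
    }
  }
  walk(src, 1)
  total
}

# small default-world synthetic bundle for module-level tests
synthetic_bundle <- function(seed = 1L, plots_per_subsite = 3,
                             individuals_mean = 3, months = 3,
                             individuals_dispersion = 5, ...) {
  md <- make_hierarchy(hierarchy_config(
    plots_per_subsite = plots_per_subsite,
    individuals_mean = individuals_mean,
    individuals_dispersion = individuals_dispersion,
    months = months, seed = seed))
  truth <- make_feature_truth(metadata = md, seed = seed + 1L, ...)
  ft <- make_feature_table(truth, md, seed = seed + 2L)
  list(metadata = md, truth = truth, table = ft)
}
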