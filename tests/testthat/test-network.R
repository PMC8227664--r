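test_that("TOM matches hand arithmetic and stays bounded", {
  # 3-node toy, all adjacencies 0.5:
  # TOM_12 = (0.25 + 0.5) / (1 + 1 - 0.5) = 0.5
  a <- matrix(0.5, 3, 3); diag(a) <- 0
  tom <- tom_from_adjacency(a)
  expect_equal(tom[1, 2], 0.5, tolerance = 1e-12)
  expect_equal(diag(tom), rep(1, 3))

  # zero adjacency -> zero off-diagonal overlap
  tom0 <- tom_from_adjacency(matrix(0, 4, 4))
  expect_true(all(tom0[upper.tri(tom0)] == 0))

  # symmetry, unit diagonal, [0,1] range on random adjacencies
  for (seed in 1:20) {
    set.seed(seed)
    n <- sample(5:15, 1)
    a <- matrix(runif(n * n), n)
    a <- (a + t(a)) / 2; diag(a) <- 0
    tom <- tom_from_adjacency(a)
    expect_true(isSymmetric(tom))
    expect_equal(diag(tom), rep(1, n))
    expect_true(all(tom >= 0 & tom <= 1))
  }
})

test_that("scale-free fit index behaves and picks a power", {
  # planted power-law connectivity: high fit index (closed-form regression)
  set.seed(1)
  k <- (1 - runif(2000))^(-1 / 1.5)        # Pareto tail, alpha ~ 2.5
  expect_gte(scale_free_fit(k, 10), 0.8)
  # hand-binned regression equals normal equations on a 5-bin toy
  k5 <- rep(c(1, 2, 4, 8, 16), times = c(160, 80, 40, 20, 10))
  bins <- cut(k5, 5)
  pk <- as.numeric(table(bins)) / length(k5)
  km <- tapply(k5, bins, mean)
  ok <- pk > 0
  Xr <- cbind(1, log10(km[ok])); yr <- log10(pk[ok])
  beta <- solve(t(Xr) %*% Xr, t(Xr) %*% yr)
  fit <- lm(yr ~ log10(km[ok]))
  expect_equal(unname(coef(fit)), as.numeric(beta), tolerance = 1e-10)
  expect_equal(scale_free_fit(k5, 5),
               sign(-beta[2]) * summary(fit)$r.squared, tolerance = 1e-10)

  # modular data: some candidate power gives a usable fit and ties break low
  bench <- make_module_benchmark(seed = 2)
  pick <- pick_soft_power(bench$X, powers = c(2, 4, 6, 8))
  expect_true(pick$power %in% c(2, 4, 6, 8))
  expect_equal(nrow(pick$fit_table), 4)

  # exactly orthogonal features (identity correlation): zero connectivity,
  # zero fit at every power, flagged
  set.seed(3)
  ortho <- qr.Q(qr(scale(matrix(rnorm(100 * 30), 100), scale = FALSE)))[, 1:30]
  pick2 <- pick_soft_power(ortho, powers = c(2, 6, 10))
  expect_true(pick2$flagged)
  expect_true(all(pick2$fit_table$fit_index == 0))
})

test_that("module detection recovers planted blocks", {
  aris <- vapply(1:10, function(seed) {
    bench <- make_module_benchmark(seed = seed)
    tom <- tom_from_correlation(bench$X, beta = 8)
    mods <- detect_modules(tom, min_size = 5)
    ari(mods$labels[names(bench$labels)], bench$labels)
  }, numeric(1))
  expect_gte(mean(aris), 0.9)

  bench <- make_module_benchmark(seed = 4)
  tom <- tom_from_correlation(bench$X, beta = 8)
  mods <- detect_modules(tom, min_size = 5)
  # noise features mostly grey; largest module is turquoise
  noise_ids <- names(bench$labels)[bench$labels == "noise"]
  expect_gte(mean(mods$labels[noise_ids] == "grey"), 0.8)
  expect_true("turquoise" %in% mods$labels)
  # deterministic
  expect_identical(detect_modules(tom, 5)$labels, mods$labels)
  # min_size larger than every cluster -> all grey
  expect_warning(all_grey <- detect_modules(tom, min_size = 1000), "grey")
  expect_true(all(all_grey$labels == "grey"))
})

test_that("module eigenvalues match an independent decomposition", {
  # rank-1 module: explained variance 1, all |kME| = 1
  set.seed(5)
  f <- rnorm(100)
  X1 <- outer(f, c(1, 2, 3, 4))
  colnames(X1) <- paste0("f", 1:4)
  ev1 <- module_eigenvalues(X1, setNames(rep("turquoise", 4), colnames(X1)))
  expect_equal(unname(ev1$explained["turquoise"]), 1, tolerance = 1e-10)
  expect_equal(abs(unname(ev1$kme)), rep(1, 4), tolerance = 1e-10)
  expect_equal(abs(cor(ev1$me[, 1], f)), 1, tolerance = 1e-10)

  # eigenvalue equals the first PC from eigen() on the correlation matrix
  bench <- make_module_benchmark(seed = 6)
  lab <- setNames(ifelse(bench$labels == "noise", "grey", bench$labels),
                  names(bench$labels))
  ev <- module_eigenvalues(bench$X, lab)
  members <- names(lab)[lab == "block1"]
  Z <- scale(bench$X[, members])
  e <- eigen(cor(bench$X[, members]))
  pc1 <- Z %*% e$vectors[, 1]
  pc1 <- pc1 / sd(pc1)
  expect_equal(abs(as.numeric(cor(ev$me[, "block1"], pc1))), 1, tolerance = 1e-8)
  expect_equal(unname(ev$explained["block1"]), e$values[1] / sum(e$values),
               tolerance = 1e-8)

  # orientation: eigenvalue correlates non-negatively with the mean profile
  for (seed in 1:20) {
    set.seed(seed)
    Xr <- matrix(rnorm(50 * 6), 50)
    colnames(Xr) <- paste0("f", 1:6)
    evr <- module_eigenvalues(Xr, setNames(rep("blue", 6), colnames(Xr)))
    expect_gte(cor(evr$me[, "blue"], rowMeans(scale(Xr))), 0)
  }
  expect_equal(unname(apply(ev$me, 2, sd)), rep(1, ncol(ev$me)))
})

test_that("merging is height-bounded, terminating, and idempotent", {
  # two modules planted from one factor merge; orthogonal ones do not
  set.seed(7)
  f1 <- rnorm(200); f2 <- rnorm(200)
  X <- cbind(sapply(1:6, function(i) f1 + rnorm(200, 0, 0.2)),
             sapply(1:6, function(i) f1 + rnorm(200, 0, 0.2)),
             sapply(1:6, function(i) f2 + rnorm(200, 0, 0.2)))
  colnames(X) <- paste0("f", 1:18)
  lab <- setNames(rep(c("turquoise", "blue", "brown"), each = 6),
                  colnames(X))
  ms <- structure(list(labels = lab, merge_history = list()),
                  class = "module_set")
  merged <- merge_close_modules(X, ms, 0.25)
  expect_equal(length(setdiff(unique(merged$labels), "grey")), 2)
  expect_true("brown" %in% merged$labels)       # orthogonal survives
  # final pairwise eigenvalue dissimilarities all >= merge height
  dis <- 1 - cor(merged$me)
  expect_gte(min(dis[upper.tri(dis)]), 0.25)
  # idempotent
  again <- merge_close_modules(X, merged, 0.25)
  expect_identical(again$labels, merged$labels)
  expect_lte(length(merged$merge_history), 3)
})

test_that("module dispersion ranks the plot-structured module first", {
  ranked_first <- vapply(1:10, function(seed) {
    set.seed(seed)
    n_plot <- 12; per <- 4; n <- n_plot * per
    plot_id <- rep(paste0("p", seq_len(n_plot)), each = per)
    # module A: strong plot-level signal; B and C exchangeable
    fA <- rep(rnorm(n_plot, sd = 2), each = per) + rnorm(n)
    fB <- rnorm(n); fC <- rnorm(n)
    mk <- function(f, k) sapply(seq_len(k), function(i) exp(f + rnorm(n, 0, 0.3)))
    ab <- t(cbind(mk(fA, 6), mk(fB, 6), mk(fC, 6)))
    ft <- tiny_table(seq(100, by = 20, length.out = 18),
                     200.1 + 1:18, ab)
    colnames(ft$abundance) <- paste0("s", seq_len(n))
    md <- data.frame(sample_id = colnames(ft$abundance), plot = plot_id)
    lab <- setNames(rep(c("turquoise", "blue", "brown"), each = 6),
                    ft$features$feature_id)
    ms <- structure(list(labels = lab, merge_history = list()),
                    class = "module_set")
    rk <- module_dispersion(ft, ms, md, "plot")
    rk$module[1] == "turquoise"
  }, logical(1))
  expect_gte(mean(ranked_first), 0.9)
})

test_that("hub features sort by |kME| with id tie-breaks", {
  set.seed(8)
  f <- rnorm(300)
  # loadings increase with index: f4 is the planted top hub
  X <- sapply(c(0.4, 0.7, 1.0, 1.6), function(l) l * f + rnorm(300, 0, 0.5))
  colnames(X) <- paste0("f", 1:4)
  lab <- setNames(rep("turquoise", 4), colnames(X))
  ev <- module_eigenvalues(X, lab)
  ms <- structure(list(labels = lab, kme = ev$kme, me = ev$me),
                  class = "module_set")
  hubs <- hub_features(ms, top_n = 4)$turquoise
  expect_equal(hubs$feature_id[1], "f4")
  expect_equal(hubs$feature_id[4], "f1")   # weakest loading ranks last
  # rank-1 module: ties broken by feature id
  X1 <- outer(f, c(1, 1, 1)); colnames(X1) <- c("b", "a", "c")
  ev1 <- module_eigenvalues(X1, setNames(rep("blue", 3), colnames(X1)))
  ms1 <- structure(list(labels = setNames(rep("blue", 3), colnames(X1)),
                        kme = ev1$kme, me = ev1$me), class = "module_set")
  expect_equal(hub_features(ms1)$blue$feature_id, c("a", "b", "c"))
})
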