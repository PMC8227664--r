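sim_chain <- function(n, a = 0.6, b = 0.5, seed = 1) {
  set.seed(seed)
  x <- rnorm(n)
  m <- a * x + rnorm(n, 0, sqrt(1 - a^2))
  y <- b * m + rnorm(n, 0, sqrt(1 - b^2))
  data.frame(x = x, m = m, y = y)
}

test_that("parse_model builds the declared structure", {
  m <- parse_model("y ~ x")
  expect_equal(nrow(m$paths), 1)
  expect_equal(m$exogenous, "x")
  # free parameters: 1 path + 2 variances = 3 (checked through df = 0)
  fit <- fit_path_model(m, sim_chain(50)[c("x", "y")])
  expect_equal(fit$df, 0)

  mc <- parse_model("a ~~ b")
  expect_equal(nrow(mc$covariances), 1)
  expect_equal(nrow(mc$paths), 0)

  med <- parse_model("m ~ x; y ~ m + x")
  expect_equal(nrow(med$paths), 3)
  expect_equal(med$endogenous, c("m", "y"))

  expect_error(parse_model("a ~ b; b ~ c; c ~ a"), "cyclic")
  expect_error(parse_model("y ~ 2x +"), "parse error")
  expect_error(parse_model("   "), "empty")
})

test_that("saturated models have zero discrepancy and exact df accounting", {
  dat <- sim_chain(200, seed = 2)
  fit <- fit_path_model(parse_model("m ~ x; y ~ m + x"), dat)
  expect_equal(fit$df, 0)
  expect_lte(fit$chisq, 1e-6)
  expect_equal(fit$p, 1)
  # over-parameterized model rejected
  expect_error(fit_path_model(parse_model("y ~ x; y ~~ x"), dat),
               "more free parameters")
})

test_that("single-path standardized estimate equals Pearson r", {
  dat <- sim_chain(300, seed = 3)
  fit <- fit_path_model(parse_model("y ~ x"), dat[c("x", "y")])
  est <- fit$parameters$estimate[fit$parameters$label == "y ~ x"]
  expect_equal(est, cor(dat$x, dat$y), tolerance = 1e-6)
  expect_true(fit$converged)
})

test_that("chain coefficients are recovered at large n", {
  dat <- sim_chain(5000, a = 0.6, b = 0.5, seed = 4)
  fit <- fit_path_model(parse_model("m ~ x; y ~ m"), dat)
  pp <- fit$parameters
  expect_equal(pp$estimate[pp$label == "m ~ x"], 0.6, tolerance = 0.05)
  expect_equal(pp$estimate[pp$label == "y ~ m"], 0.5, tolerance = 0.05)
})

test_that("scale equivariance: standardized fit equals rescaled raw fit", {
  dat <- sim_chain(400, seed = 5)
  dat$x <- dat$x * 7 + 100; dat$y <- dat$y * 0.3 - 2   # raw scales
  m <- parse_model("m ~ x; y ~ m")
  fit_std <- fit_path_model(m, dat)
  fit_raw <- fit_path_model(m, dat, standardize = FALSE)
  sds <- vapply(dat, sd, numeric(1))
  raw <- fit_raw$parameters
  b_mx <- raw$estimate[raw$label == "m ~ x"] * sds["x"] / sds["m"]
  b_ym <- raw$estimate[raw$label == "y ~ m"] * sds["m"] / sds["y"]
  std <- fit_std$parameters
  expect_equal(std$estimate[std$label == "m ~ x"], unname(b_mx),
               tolerance = 1e-6)
  expect_equal(std$estimate[std$label == "y ~ m"], unname(b_ym),
               tolerance = 1e-6)
  expect_equal(fit_std$chisq, fit_raw$chisq, tolerance = 1e-4)
})

test_that("effect decomposition equals route enumeration", {
  dat <- sim_chain(500, seed = 6)
  fit <- fit_path_model(parse_model("m ~ x; y ~ m"), dat)
  eff <- effects_decomposition(fit)
  a <- fit$B["m", "x"]; b <- fit$B["y", "m"]
  row <- eff[eff$source == "x" & eff$target == "y", ]
  expect_equal(row$indirect, a * b, tolerance = 1e-10)
  expect_equal(row$direct, 0)
  expect_equal(row$total, row$direct + row$indirect, tolerance = 1e-10)
  # no route -> absent (zero) effect
  expect_equal(nrow(eff[eff$source == "y" & eff$target == "x", ]), 0)

  # 5-variable DAG: matrix formula vs brute-force route enumeration
  set.seed(7)
  v <- c("a", "b", "c", "d", "e")
  B <- matrix(0, 5, 5, dimnames = list(v, v))
  B["b", "a"] <- 0.5; B["c", "a"] <- -0.3; B["c", "b"] <- 0.4
  B["d", "b"] <- 0.6; B["e", "c"] <- 0.7; B["e", "d"] <- -0.2
  fake <- structure(list(B = B), class = "path_fit")
  eff5 <- effects_decomposition(fake)
  for (i in seq_len(nrow(eff5))) {
    expect_equal(eff5$total[i],
                 enumerate_total_effect(B, eff5$source[i], eff5$target[i]),
                 tolerance = 1e-12)
  }
  # non-convergent series rejected
  Bbad <- matrix(0, 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  Bbad["b", "a"] <- 1.2; Bbad["a", "b"] <- 0.9
  expect_error(effects_decomposition(structure(list(B = Bbad),
                                               class = "path_fit")),
               "spectral radius")
})

test_that("pruning removes the planted-irrelevant chemical edge first", {
  hits <- vapply(1:10, function(seed) {
    set.seed(seed)
    n <- 150
    chem_true <- rnorm(n)       # real effect
    chem_null <- rnorm(n)       # no effect
    y <- 0.5 * chem_true + rnorm(n, 0, sqrt(0.75))
    dat <- data.frame(y = y, chem_true = chem_true, chem_null = chem_null)
    m <- parse_model("y ~ chem_true + chem_null")
    res <- prune_chemistry_paths(m, dat, alpha = 0.05,
                                 chemical_vars = c("chem_true", "chem_null"))
    removed <- res$log$edge[res$log$action == "removed"]
    length(removed) >= 1 && removed[1] == "y ~ chem_null" &&
      !"y ~ chem_true" %in% removed
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("pruning is a no-op when everything is significant, and accounts", {
  set.seed(20)
  n <- 400
  x1 <- rnorm(n); x2 <- rnorm(n)
  y <- 0.5 * x1 + 0.4 * x2 + rnorm(n, 0, 0.6)
  dat <- data.frame(y = y, x1 = x1, x2 = x2)
  m <- parse_model("y ~ x1 + x2")
  res <- prune_chemistry_paths(m, dat, alpha = 0.05,
                               chemical_vars = c("x1", "x2"))
  expect_equal(nrow(res$log), 0)
  expect_equal(nrow(res$fit$model$paths), 2)

  # accounting: removals = initial tagged - final tagged
  set.seed(21)
  dat2 <- data.frame(y = rnorm(n), x1 = rnorm(n), x2 = rnorm(n))
  res2 <- prune_chemistry_paths(parse_model("y ~ x1 + x2"), dat2,
                                alpha = 0.05,
                                chemical_vars = c("x1", "x2"),
                                protected = "y ~ x1")
  removed <- sum(res2$log$action == "removed")
  expect_equal(removed, 2 - 1 - nrow(res2$fit$model$paths) + 1)
  expect_true("y ~ x1" %in% paste(res2$fit$model$paths$to, "~",
                                  res2$fit$model$paths$from))
})

test_that("planted tritrophic topology is recovered at n = 300", {
  # generative counterpart of the default planted coefficients
  sim_world <- function(n, seed) {
    set.seed(seed)
    co <- path_coefficients_default()
    cf <- function(f, t) { h <- co$coef[co$from == f & co$to == t]
                           if (length(h)) h else 0 }
    elevation <- rnorm(n)
    leaves <- cf("elevation", "leaves_per_plant") * elevation
    leaves <- leaves + rnorm(n, 0, sqrt(1 - var(leaves)))
    pep <- rnorm(n)
    flav <- cf("elevation", "mod_flavonoid_glycoside") * elevation +
      cf("leaves_per_plant", "mod_flavonoid_glycoside") * leaves
    flav <- flav + rnorm(n, 0, sqrt(1 - var(flav)))
    abund <- cf("mod_peptide", "herbivore_abundance") * pep +
      cf("mod_flavonoid_glycoside", "herbivore_abundance") * flav +
      cf("leaves_per_plant", "herbivore_abundance") * leaves
    abund <- abund + rnorm(n, 0, sqrt(max(0.05, 1 - var(abund))))
    divr <- cf("elevation", "herbivore_diversity") * elevation +
      cf("herbivore_abundance", "herbivore_diversity") * abund +
      cf("mod_flavonoid_glycoside", "herbivore_diversity") * flav
    divr <- divr + rnorm(n, 0, sqrt(max(0.05, 1 - var(divr))))
    para <- cf("elevation", "parasitoid_success") * elevation +
      cf("mod_flavonoid_glycoside", "parasitoid_success") * flav
    para <- para + rnorm(n, 0, sqrt(max(0.05, 1 - var(para))))
    data.frame(elevation = elevation, leaves_per_plant = leaves,
               mod_peptide = pep, mod_flavonoid_glycoside = flav,
               herbivore_abundance = abund, herbivore_diversity = divr,
               parasitoid_success = para)
  }
  model <- parse_model(paste(
    "leaves_per_plant ~ elevation",
    "mod_flavonoid_glycoside ~ elevation + leaves_per_plant",
    "herbivore_abundance ~ mod_peptide + mod_flavonoid_glycoside + leaves_per_plant",
    "herbivore_diversity ~ elevation + herbivore_abundance + mod_flavonoid_glycoside",
    "parasitoid_success ~ elevation + mod_flavonoid_glycoside",
    sep = "\n"))
  co <- path_coefficients_default()
  truth_of <- function(lab) {
    parts <- strsplit(lab, " ~ ")[[1]]
    co$coef[co$from == parts[2] & co$to == parts[1]]
  }
  ok_sign <- logical(10)
  ests <- NULL
  for (seed in 1:10) {
    fit <- fit_path_model(model, sim_world(300, seed))
    pp <- fit$parameters[fit$parameters$type == "path", ]
    truths <- vapply(pp$label, truth_of, numeric(1))
    ests <- rbind(ests, pp$estimate)
    ok_sign[seed] <- all(sign(pp$estimate) == sign(truths))
    expect_lte(max(abs(pp$estimate - truths)), 0.25)  # per-seed sanity
  }
  # averaged over seeds every standardized coefficient sits within 0.10
  truths <- vapply(pp$label, truth_of, numeric(1))
  expect_true(all(abs(colMeans(ests) - truths) <= 0.10))
  expect_true(all(ok_sign))
})
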