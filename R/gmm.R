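# Gaussian-mixture EM engine with BIC model selection.
#
# Six covariance families are fit, mirroring the usual model-based-clustering
# grid at the scale of a feature table: spherical/diagonal/full covariance,
# each either shared across components or component-specific. BIC is defined
# as -2*logLik + npar*log(n), so smaller is better.

GMM_STRUCTURES <- c("spherical_shared", "spherical", "diagonal_shared",
                    "diagonal", "full_shared", "full")

gmm_npar <- function(k, d, structure) {
  cov_par <- switch(structure,
    spherical_shared = 1, spherical = k,
    diagonal_shared = d, diagonal = k * d,
    full_shared = d * (d + 1) / 2, full = k * d * (d + 1) / 2,
    stop("unknown covariance structure: ", structure))
  (k - 1) + k * d + cov_par
}

# log density of rows of x under N(mu, sigma); sigma given as list by type
gmm_logdens <- function(x, mu, sigma, structure) {
  d <- ncol(x)
  xc <- sweep(x, 2, mu)
  if (structure %in% c("spherical_shared", "spherical")) {
    -0.5 * (d * log(2 * pi * sigma) + rowSums(xc^2) / sigma)
  } else if (structure %in% c("diagonal_shared", "diagonal")) {
    -0.5 * (d * log(2 * pi) + sum(log(sigma)) +
              rowSums(sweep(xc^2, 2, sigma, "/")))
  } else {
    ch <- chol(sigma)
    z <- xc %*% chol2inv(ch) * xc
    -0.5 * (d * log(2 * pi) + 2 * sum(log(diag(ch))) + rowSums(z))
  }
}

gmm_mstep_cov <- function(x, resp, mu, structure, ridge = 1e-6) {
  k <- ncol(resp); d <- ncol(x); n <- nrow(x)
  nk <- colSums(resp)
  per <- lapply(seq_len(k), function(j) {
    xc <- sweep(x, 2, mu[j, ])
    w <- resp[, j]
    switch(sub("_shared", "", structure),
      spherical = sum(w * rowSums(xc^2)) / (nk[j] * d) + ridge,
      diagonal = colSums(w * xc^2) / nk[j] + ridge,
      full = crossprod(xc * sqrt(w)) / nk[j] + diag(ridge, d))
  })
  if (grepl("_shared", structure)) {
    pooled <- Reduce(`+`, Map(function(s, w) s * w, per, nk / n))
    rep(list(pooled), k)
  } else per
}

fit_gmm <- function(x, k, structure, seed = 1L, max_iter = 300, tol = 1e-8) {
  x <- as.matrix(x)
  n <- nrow(x); d <- ncol(x)
  if (k > n) stop("k exceeds number of points")
  set.seed(seed)
  if (k == 1) {
    resp <- matrix(1, n, 1)
  } else {
    km <- suppressWarnings(stats::kmeans(x, centers = k, nstart = 10,
                                         iter.max = 50))
    resp <- outer(km$cluster, seq_len(k), `==`) * 1
  }
  pi_k <- pmax(colSums(resp) / n, 1e-10)
  mu <- t(vapply(seq_len(k), function(j)
    colSums(resp[, j] * x) / sum(resp[, j]), numeric(d)))
  sigma <- gmm_mstep_cov(x, resp, mu, structure)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    logd <- vapply(seq_len(k), function(j)
      gmm_logdens(x, mu[j, ], sigma[[j]], structure) + log(pi_k[j]),
      numeric(n))
    if (k == 1) logd <- matrix(logd, ncol = 1)
    m <- apply(logd, 1, max)
    lse <- m + log(rowSums(exp(logd - m)))
    ll <- sum(lse)
    resp <- exp(logd - lse)
    nk <- colSums(resp)
    if (any(nk < 1e-8)) stop("empty component during EM")
    pi_k <- nk / n
    mu <- t(vapply(seq_len(k), function(j)
      colSums(resp[, j] * x) / nk[j], numeric(d)))
    sigma <- gmm_mstep_cov(x, resp, mu, structure)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * (abs(ll) + 1)) break
    ll_old <- ll
  }
  npar <- gmm_npar(k, d, structure)
  list(k = k, structure = structure, weights = pi_k, means = mu,
       sigma = sigma, loglik = ll, npar = npar,
       bic = -2 * ll + npar * log(n),
       classification = max.col(resp), responsibilities = resp,
       iterations = it)
}

#' Gaussian-mixture clustering of features with BIC selection
#'
#' Fits EM Gaussian mixtures over standardized (rt, m/z, RMD) for every
#' candidate component count and covariance family, and returns the model
#' minimizing BIC. Deterministic for a fixed seed (seeded k-means
#' initialization). Candidates whose EM fails (e.g. an emptied component) are
#' skipped and logged.
#'
#' @param subset data.frame with columns `feature_id`, `rt_s`, `mz`, `rmd_ppm`
#' @param k_range candidate component counts (default 1:12)
#' @param structures covariance families, subset of
#'   `c("spherical_shared","spherical","diagonal_shared","diagonal","full_shared","full")`
#' @param partition label recorded on the result ("nitrogenous" or
#'   "non_nitrogenous")
#' @param seed integer seed
#' @return object of class `cluster_model`: classification, per-cluster means
#'   in original units, chosen k/structure, full BIC trace, skipped candidates.
#' @export
cluster_features <- function(subset, k_range = 1:12,
                             structures = GMM_STRUCTURES,
                             partition = NA_character_, seed = 1L) {
  stopifnot(all(c("feature_id", "rt_s", "mz", "rmd_ppm") %in% names(subset)))
  x_raw <- as.matrix(subset[c("rt_s", "mz", "rmd_ppm")])
  n <- nrow(x_raw)
  k_range <- k_range[k_range <= n]
  if (!length(k_range)) stop("subset smaller than every candidate k")
  ctr <- colMeans(x_raw)
  scl <- apply(x_raw, 2, stats::sd)
  scl[scl == 0] <- 1
  x <- sweep(sweep(x_raw, 2, ctr), 2, scl, "/")
  trace <- list(); fits <- list(); skipped <- character()
  for (k in k_range) for (st in structures) {
    key <- paste0("k", k, "_", st)
    fit <- tryCatch(
      fit_gmm(x, k, st, seed = seed + 1000L * k + match(st, GMM_STRUCTURES)),
      error = function(e) e)
    if (inherits(fit, "error")) {
      skipped <- c(skipped, key)
    } else {
      fits[[key]] <- fit
      trace[[key]] <- data.frame(k = k, structure = st, bic = fit$bic,
                                 loglik = fit$loglik, npar = fit$npar)
    }
  }
  if (!length(fits)) stop("all mixture candidates failed")
  trace <- do.call(rbind, trace)
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "bic"))]]
  cl <- best$classification
  centers <- t(vapply(seq_len(best$k), function(j) {
    ix <- cl == j
    colMeans(x_raw[ix, , drop = FALSE])
  }, numeric(3)))
  colnames(centers) <- c("rt_s", "mz", "rmd_ppm")
  structure(list(
    classification = stats::setNames(cl, subset$feature_id),
    k = best$k, covariance_structure = best$structure,
    cluster_means = centers, bic = min(trace$bic), bic_trace = trace,
    partition = partition, skipped = skipped, model = best),
    class = "cluster_model")
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf("cluster_model (%s): k = %d, %s covariance, BIC = %.1f\n",
              x$partition, x$k, x$covariance_structure, x$bic))
  invisible(x)
}
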