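# Multivariate dispersion and PERMANOVA, implemented from first principles on
# an arbitrary distance matrix (principal-coordinate embedding with
# negative-eigenvalue bookkeeping; Anderson's sums-of-squares partition).

# plain one-way ANOVA that tolerates singleton groups and zero variance
anova_oneway <- function(values, groups) {
  g <- factor(groups)
  k <- nlevels(g); n <- length(values)
  gm <- mean(values)
  means <- tapply(values, g, mean)
  counts <- as.vector(table(g))
  ssb <- sum(counts * (means - gm)^2)
  ssw <- sum((values - means[g])^2)
  df <- c(k - 1, n - k)
  if (ssw <= 1e-300) {
    if (ssb <= 1e-300) return(list(F = 0, df = df, p = 1))
    return(list(F = Inf, df = df, p = 0))
  }
  f <- (ssb / df[1]) / (ssw / df[2])
  list(F = f, df = df, p = stats::pf(f, df[1], df[2], lower.tail = FALSE))
}

# PCoA of a distance matrix, retaining negative-eigenvalue ("imaginary") axes.
pcoa_embed <- function(d, tol = 1e-8) {
  d <- as.matrix(d)
  n <- nrow(d)
  a <- -0.5 * d^2
  g <- a - matrix(rowMeans(a), n, n) - matrix(colMeans(a), n, n, byrow = TRUE) +
    mean(a)
  e <- eigen(g, symmetric = TRUE)
  keep <- abs(e$values) > tol * max(abs(e$values), 1)
  lambda <- e$values[keep]
  vec <- e$vectors[, keep, drop = FALSE]
  pos <- lambda > 0
  real <- sweep(vec[, pos, drop = FALSE], 2, sqrt(lambda[pos]), "*")
  imag <- sweep(vec[, !pos, drop = FALSE], 2, sqrt(-lambda[!pos]), "*")
  list(real = real, imag = imag, eigenvalues = lambda)
}

dist_to_center <- function(real, imag, c_real, c_imag) {
  d2r <- rowSums(sweep(real, 2, c_real)^2)
  d2i <- if (ncol(imag)) rowSums(sweep(imag, 2, c_imag)^2) else 0
  sqrt(pmax(0, d2r - d2i))
}

spatial_median <- function(x, max_iter = 200, tol = 1e-10) {
  m <- colMeans(x)
  for (i in seq_len(max_iter)) {
    dd <- sqrt(rowSums(sweep(x, 2, m)^2))
    dd[dd < 1e-12] <- 1e-12
    w <- 1 / dd
    m_new <- colSums(x * w) / sum(w)
    if (sum((m_new - m)^2) < tol) break
    m <- m_new
  }
  m
}

#' Multivariate homogeneity of group dispersions
#'
#' Embeds the distance matrix in principal-coordinate space (keeping
#' negative-eigenvalue axes), computes each sample's distance to its group
#' center as `sqrt(max(0, d2_real - d2_imaginary))`, and tests for equal
#' dispersion among groups with a one-way ANOVA on those distances. With a
#' Euclidean-embeddable metric this reproduces direct centroid geometry
#' exactly. Groups of size 1 contribute a zero distance and are flagged.
#'
#' @param dist a [phyto_dist()] or square symmetric matrix
#' @param groups group label per sample
#' @param center `"centroid"` (closed form, default) or `"median"` (Weiszfeld
#'   spatial median on the real axes; exact for Euclidean embeddings)
#' @return list of class `dispersion_result`: per-sample distances, per-group
#'   mean dispersion, and ANOVA F / df / p
#' @export
dispersion <- function(dist, groups, center = c("centroid", "median")) {
  center <- match.arg(center)
  d <- if (inherits(dist, "phyto_dist")) dist$d else as.matrix(dist)
  groups <- as.character(groups)
  stopifnot(length(groups) == nrow(d))
  emb <- pcoa_embed(d)
  dists <- numeric(nrow(d))
  singletons <- character()
  for (g in unique(groups)) {
    ix <- which(groups == g)
    if (length(ix) == 1) { dists[ix] <- 0; singletons <- c(singletons, g); next }
    r <- emb$real[ix, , drop = FALSE]
    im <- emb$imag[ix, , drop = FALSE]
    if (center == "centroid") {
      cr <- colMeans(r)
      ci <- if (ncol(im)) colMeans(im) else numeric(0)
    } else {
      cr <- spatial_median(r)
      ci <- if (ncol(im)) spatial_median(im) else numeric(0)
    }
    dists[ix] <- dist_to_center(r, im, cr, ci)
  }
  an <- if (length(unique(groups)) >= 2) anova_oneway(dists, groups) else NULL
  structure(list(distances = stats::setNames(dists, rownames(d)),
                 groups = groups,
                 group_means = tapply(dists, groups, mean),
                 center = center, anova = an, singletons = singletons),
            class = "dispersion_result")
}

#' @export
print.dispersion_result <- function(x, ...) {
  cat(sprintf("dispersion (%s): %d groups", x$center,
              length(unique(x$groups))))
  if (!is.null(x$anova)) {
    cat(sprintf("; ANOVA F(%d,%d) = %.3f, p = %.4g",
                x$anova$df[1], x$anova$df[2], x$anova$F, x$anova$p))
  }
  cat("\n")
  invisible(x)
}

# SS_within for one or more label vectors, from the squared distance matrix.
# Anderson's partition: SS_total = sum_{i<j} d2_ij / n,
# SS_within = sum_g sum_{i<j in g} d2_ij / n_g.
permanova_ss_within <- function(d2, labels) {
  total <- 0
  for (g in unique(labels)) {
    ix <- labels == g
    total <- total + sum(d2[ix, ix]) / (2 * sum(ix))
  }
  total
}

# enumerate all distinct assignments of group labels to n positions
enumerate_labelings <- function(groups) {
  counts <- table(groups)
  labs <- names(counts)
  n <- length(groups)
  res <- list()
  recurse <- function(remaining_idx, li, current) {
    if (li == length(labs)) {
      current[remaining_idx] <- labs[li]
      res[[length(res) + 1]] <<- current
      return(invisible())
    }
    k <- counts[[li]]
    combos <- utils::combn(remaining_idx, k, simplify = FALSE)
    for (cb in combos) {
      cur2 <- current
      cur2[cb] <- labs[li]
      recurse(setdiff(remaining_idx, cb), li + 1, cur2)
    }
  }
  recurse(seq_len(n), 1, character(n))
  res
}

n_distinct_relabelings <- function(groups) {
  counts <- as.numeric(table(groups))
  exp(lgamma(sum(counts) + 1) - sum(lgamma(counts + 1)))
}

#' Permutational multivariate analysis of variance (PERMANOVA)
#'
#' Partitions the total sum of squared interpoint distances between and
#' within groups and tests the pseudo-F statistic
#' `(SS_between / (g - 1)) / (SS_within / (n - g))` by permuting group labels.
#' When the number of distinct relabelings is at most `enum_limit` the
#' permutation distribution is enumerated completely and the p-value is exact
#' (`#{F_perm >= F_obs} / #perms`, the observed labeling included); otherwise
#' `n_perm` random permutations are drawn and
#' `p = (1 + #{F_perm >= F_obs}) / (1 + n_perm)`.
#'
#' @param dist a [phyto_dist()] or square symmetric matrix
#' @param groups group label per sample (>= 2 groups)
#' @param n_perm random permutations when not enumerating (default 9999)
#' @param seed seed for the permutation stream
#' @param enum_limit complete-enumeration threshold (default 1e5)
#' @return list of class `permanova_result`: pseudo-F, R2, p, permutation
#'   count, `complete_enumeration` flag
#' @export
permanova <- function(dist, groups, n_perm = 9999, seed = 1L,
                      enum_limit = 1e5) {
  d <- if (inherits(dist, "phyto_dist")) dist$d else as.matrix(dist)
  groups <- as.character(groups)
  n <- length(groups)
  stopifnot(nrow(d) == n)
  g <- length(unique(groups))
  if (g < 2) stop("PERMANOVA needs at least 2 groups")
  if (n_perm < 99) stop("n_perm must be >= 99")
  d2 <- d^2
  ss_total <- sum(d2) / (2 * n)
  f_of <- function(lab) {
    ssw <- permanova_ss_within(d2, lab)
    ((ss_total - ssw) / (g - 1)) / (ssw / (n - g))
  }
  f_obs <- f_of(groups)
  ssw_obs <- permanova_ss_within(d2, groups)
  r2 <- (ss_total - ssw_obs) / ss_total
  if (n_distinct_relabelings(groups) <= enum_limit) {
    labs <- enumerate_labelings(groups)
    f_perm <- vapply(labs, f_of, numeric(1))
    p <- sum(f_perm >= f_obs - 1e-12) / length(f_perm)
    complete <- TRUE
    n_used <- length(f_perm)
  } else {
    set.seed(seed)
    f_perm <- vapply(seq_len(n_perm), function(i) f_of(sample(groups)),
                     numeric(1))
    p <- (1 + sum(f_perm >= f_obs - 1e-12)) / (1 + n_perm)
    complete <- FALSE
    n_used <- n_perm
  }
  structure(list(pseudo_F = f_obs, R2 = r2, p = p, n_perm = n_used,
                 seed = seed, complete_enumeration = complete,
                 df = c(g - 1, n - g)),
            class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf("PERMANOVA: pseudo-F(%d,%d) = %.3f, R2 = %.3f, p = %.4g (%s, %d perms)\n",
              x$df[1], x$df[2], x$pseudo_F, x$R2, x$p,
              if (x$complete_enumeration) "exact" else "sampled", x$n_perm))
  invisible(x)
}

#' Dispersion gate for composition tests
#'
#' PERMANOVA assumes homogeneous within-group dispersion; composition testing
#' proceeds only when the dispersion ANOVA does not reject at `alpha`
#' (non-strict at the boundary: `p == alpha` proceeds).
#'
#' @param dispersion_p p-value from [dispersion()]'s ANOVA
#' @param alpha gate level (default 0.05)
#' @return TRUE when composition testing may proceed
#' @export
dispersion_gate <- function(dispersion_p, alpha = 0.05) {
  stopifnot(is.finite(dispersion_p), dispersion_p >= 0, dispersion_p <= 1)
  dispersion_p >= alpha
}
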