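# Unsigned weighted correlation network over features: soft thresholding,
# topological overlap, average-linkage module detection, module eigenvalues,
# and eigenvalue-correlation merging. Everything here is deterministic.

WGCNA_COLORS <- c("turquoise", "blue", "brown", "yellow", "green", "red",
                  "black", "pink", "magenta", "purple", "greenyellow", "tan",
                  "salmon", "cyan", "midnightblue", "lightcyan", "grey60",
                  "lightgreen", "lightyellow", "royalblue")

drop_constant_features <- function(X) {
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    warning("excluding ", sum(sds == 0), " constant feature(s) from the network")
    X <- X[, sds > 0, drop = FALSE]
  }
  X
}

#' Choose the soft-thresholding power by scale-free topology fit
#'
#' For each candidate power the unsigned adjacency `|cor|^beta` is formed and
#' the connectivity distribution is checked for scale-free behaviour: the fit
#' index is `sign(-slope) * R2` of the regression `log10 p(k) ~ log10 k` over
#' binned connectivities. The power with the highest index wins (ties to the
#' smallest power). Data are mean-centered internally; constant features are
#' excluded with a warning.
#'
#' @param X samples x features matrix
#' @param powers candidate integer powers
#' @param n_bins connectivity histogram bins (default 10)
#' @return list: `power` (chosen beta), `fit_table` (power, fit index, mean
#'   connectivity), `flagged` (TRUE when no candidate exceeds 0.3)
#' @export
pick_soft_power <- function(X, powers = c(1:10, 12, 14, 16, 18, 20),
                            n_bins = 10) {
  X <- scale(as.matrix(X), center = TRUE, scale = FALSE)
  X <- drop_constant_features(X)
  if (ncol(X) < 3) stop("need at least 3 non-constant features")
  ac <- abs(stats::cor(X))
  diag(ac) <- 0
  rows <- lapply(powers, function(b) {
    k <- rowSums(ac^b)
    data.frame(power = b, fit_index = scale_free_fit(k, n_bins),
               mean_k = mean(k))
  })
  tab <- do.call(rbind, rows)
  best <- tab$power[which.max(tab$fit_index)]
  list(power = best, fit_table = tab, flagged = max(tab$fit_index) < 0.3)
}

# signed R^2 of log10 p(k) ~ log10 k over binned connectivity
scale_free_fit <- function(k, n_bins = 10) {
  # degenerate connectivity (disconnected or constant graph) carries no signal
  if (stats::sd(k) <= 1e-12 || mean(k) <= 1e-12) return(0)
  bins <- cut(k, breaks = n_bins)
  pk <- as.numeric(table(bins)) / length(k)
  kmean <- tapply(k, bins, mean)
  ok <- pk > 0 & is.finite(kmean) & kmean > 0
  if (sum(ok) < 3) return(0)
  fit <- stats::lm(log10(pk[ok]) ~ log10(kmean[ok]))
  r2 <- summary(fit)$r.squared
  unname(sign(-stats::coef(fit)[2]) * r2)
}

#' Topological overlap matrix from a data matrix
#'
#' Adjacency `a = |cor|^beta` (zero diagonal);
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with unit
#' diagonal. Symmetric with entries in `[0, 1]`.
#'
#' @param X samples x features matrix
#' @param beta soft-thresholding power (default 8)
#' @return TOM matrix (features x features)
#' @export
tom_from_correlation <- function(X, beta = 8) {
  X <- drop_constant_features(as.matrix(X))
  a <- abs(stats::cor(X))^beta
  diag(a) <- 0
  tom_from_adjacency(a)
}

#' @rdname tom_from_correlation
#' @param a adjacency matrix with zero diagonal
#' @export
tom_from_adjacency <- function(a) {
  stopifnot(isSymmetric(unname(a)))
  diag(a) <- 0
  k <- rowSums(a)
  num <- a %*% a + a
  den <- outer(k, k, pmin) + 1 - a
  tom <- num / den
  diag(tom) <- 1
  tom <- (tom + t(tom)) / 2
  pmin(pmax(tom, 0), 1)
}

#' Detect network modules from a TOM
#'
#' Average-linkage hierarchical clustering on `1 - TOM`, cut statically at an
#' absolute height (TOM dissimilarity lives in `[0, 1]`, so the default 0.99
#' separates anything with essentially no topological overlap); clusters
#' smaller than `min_size` become "grey". Module labels are the conventional
#' colors in decreasing size order (largest = turquoise). Deterministic.
#'
#' @param tom topological overlap matrix
#' @param min_size minimum module size (default 5)
#' @param cut_height absolute static cut height on 1 - TOM (default 0.99)
#' @return object of class `module_set` with `labels` (feature -> color);
#'   eigenvalues are attached by [module_eigenvalues()] /
#'   [merge_close_modules()]
#' @export
detect_modules <- function(tom, min_size = 5, cut_height = 0.99) {
  stopifnot(min_size >= 2)
  ids <- rownames(tom)
  if (is.null(ids)) ids <- paste0("f", seq_len(nrow(tom)))
  h <- stats::hclust(stats::as.dist(1 - tom), method = "average")
  height <- cut_height
  raw <- stats::cutree(h, h = height)
  sizes <- table(raw)
  keep <- names(sizes)[sizes >= min_size]
  if (!length(keep)) {
    warning("all features grey: no cluster reached min_size")
    labels <- stats::setNames(rep("grey", length(raw)), ids)
  } else {
    ord <- keep[order(-sizes[keep])]
    color_of <- stats::setNames(
      c(WGCNA_COLORS, paste0("module", seq_along(ord)))[seq_along(ord)], ord)
    labels <- stats::setNames(
      ifelse(as.character(raw) %in% keep, color_of[as.character(raw)], "grey"),
      ids)
  }
  structure(list(labels = labels, tree = h, cut_height = height,
                 merge_history = list()),
            class = "module_set")
}

#' @export
print.module_set <- function(x, ...) {
  tab <- sort(table(x$labels), decreasing = TRUE)
  cat("module_set:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n")
  invisible(x)
}

#' Module eigenvalues, explained variance, and kME
#'
#' Per non-grey module, the first principal component of the standardized
#' member submatrix, scaled to unit variance and oriented so it correlates
#' non-negatively with the module's mean standardized profile. `kME` is each
#' feature's correlation with its own module eigenvalue; explained variance is
#' `lambda_1 / sum(lambda)`. Zero-variance member features are dropped with a
#' warning.
#'
#' @param X samples x features matrix
#' @param labels named feature -> module color vector
#' @return list: `me` (samples x modules eigenvalue matrix), `explained`
#'   (named fractions), `kme` (named per-feature correlations, NA for grey)
#' @export
module_eigenvalues <- function(X, labels) {
  X <- as.matrix(X)
  mods <- setdiff(unique(labels), "grey")
  me <- matrix(NA_real_, nrow(X), length(mods),
               dimnames = list(rownames(X), mods))
  explained <- stats::setNames(numeric(length(mods)), mods)
  kme <- stats::setNames(rep(NA_real_, length(labels)), names(labels))
  for (m in mods) {
    members <- names(labels)[labels == m]
    sub <- X[, members, drop = FALSE]
    sds <- apply(sub, 2, stats::sd)
    if (any(sds == 0)) {
      warning("dropping ", sum(sds == 0), " zero-variance feature(s) in module ", m)
      sub <- sub[, sds > 0, drop = FALSE]
    }
    if (ncol(sub) < 2) stop("module ", m, " has < 2 usable features")
    sub <- scale(sub)
    sv <- svd(sub, nu = 1, nv = 0)
    score <- sv$u[, 1]
    score <- score / stats::sd(score)
    if (stats::cor(score, rowMeans(sub)) < 0) score <- -score
    me[, m] <- score
    explained[m] <- sv$d[1]^2 / sum(sv$d^2)
    kme[colnames(sub)] <- as.numeric(stats::cor(sub, score))
  }
  list(me = me, explained = explained, kme = kme)
}

#' Merge modules with correlated eigenvalues
#'
#' Iteratively merges the closest pair of module eigenvalues whose
#' dissimilarity `1 - cor` falls below `merge_height` (correlation above
#' 0.75 at the default 0.25), recomputing eigenvalues after each merge until
#' every remaining pair is at least `merge_height` apart. Grey never merges.
#'
#' @param X samples x features matrix
#' @param modules a `module_set`
#' @param merge_height dissimilarity threshold (default 0.25)
#' @return `module_set` with final `labels`, attached `me`, `explained`,
#'   `kme`, and a `merge_history` of (absorbed, into) pairs
#' @export
merge_close_modules <- function(X, modules, merge_height = 0.25) {
  stopifnot(inherits(modules, "module_set"),
            merge_height > 0, merge_height < 1)
  labels <- modules$labels
  history <- modules$merge_history
  repeat {
    mods <- setdiff(unique(labels), "grey")
    if (length(mods) < 2) break
    ev <- module_eigenvalues(X, labels)
    dis <- 1 - stats::cor(ev$me)
    diag(dis) <- Inf
    idx <- which(dis == min(dis), arr.ind = TRUE)[1, ]
    if (dis[idx[1], idx[2]] >= merge_height) break
    a <- colnames(dis)[idx[1]]; b <- colnames(dis)[idx[2]]
    sizes <- table(labels)
    absorbed <- if (sizes[a] < sizes[b]) a else b
    into <- if (absorbed == a) b else a
    labels[labels == absorbed] <- into
    history[[length(history) + 1]] <- c(absorbed = absorbed, into = into)
  }
  ev <- module_eigenvalues(X, labels)
  structure(list(labels = labels, me = ev$me, explained = ev$explained,
                 kme = ev$kme, merge_history = history,
                 tree = modules$tree, cut_height = modules$cut_height),
            class = "module_set")
}

#' Rank modules by plot-level dispersion
#'
#' Restricts the normalized feature table to each module's members, computes
#' Manhattan distances and the group-dispersion ANOVA (see [dispersion()]),
#' and returns modules ranked by the F statistic. Grey is excluded unless
#' `include_grey`.
#'
#' @param table normalized [feature_table()]
#' @param modules a `module_set`
#' @param metadata sample metadata
#' @param grouping metadata column to group by (default "plot")
#' @param include_grey include the grey pseudo-module
#' @return data.frame ranked by F (module, n_features, F, df1, df2, p) with
#'   per-module [dispersion()] results in attribute `details`
#' @export
module_dispersion <- function(table, modules, metadata, grouping = "plot",
                              include_grey = FALSE) {
  stopifnot(inherits(table, "feature_table"), inherits(modules, "module_set"))
  check_samples(table, metadata)
  md <- metadata[match(colnames(table$abundance), metadata$sample_id), ]
  groups <- md[[grouping]]
  mods <- unique(modules$labels)
  if (!include_grey) mods <- setdiff(mods, "grey")
  rows <- list(); details <- list()
  for (m in mods) {
    members <- intersect(names(modules$labels)[modules$labels == m],
                         table$features$feature_id)
    if (length(members) < 2) {
      warning("module ", m, " has < 2 features in the table; skipped")
      next
    }
    dm <- manhattan_distances(ft_subset(table, members))
    disp <- dispersion(dm, groups)
    rows[[m]] <- data.frame(module = m, n_features = length(members),
                            F = disp$anova$F, df1 = disp$anova$df[1],
                            df2 = disp$anova$df[2], p = disp$anova$p)
    details[[m]] <- disp
  }
  out <- do.call(rbind, rows)
  out <- out[order(-out$F), ]
  rownames(out) <- NULL
  attr(out, "details") <- details
  out
}

#' Hub features per module
#'
#' Features sorted by |kME| descending within each module (the module's most
#' connected members); ties break by feature id.
#'
#' @param modules a `module_set` carrying `kme`
#' @param top_n how many hubs per module (default 10)
#' @return named list of data.frames (feature_id, kME)
#' @export
hub_features <- function(modules, top_n = 10) {
  stopifnot(inherits(modules, "module_set"))
  if (is.null(modules$kme)) stop("kME not available; run merge_close_modules()")
  out <- list()
  for (m in setdiff(unique(modules$labels), "grey")) {
    ids <- names(modules$labels)[modules$labels == m]
    k <- modules$kme[ids]
    ord <- order(-abs(k), ids)
    sel <- utils::head(ord, top_n)
    out[[m]] <- data.frame(feature_id = ids[sel], kME = unname(k[sel]))
  }
  out
}
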