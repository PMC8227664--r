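#' Group features into pseudospectra
#'
#' Features presumed to arise from one compound (adducts, isotopes, in-source
#' fragments) co-elute and co-vary across samples. Two features are linked when
#' their retention times differ by at most `rt_window` seconds and their
#' cross-sample Pearson correlation is at least `corr_min`; pseudospectra are
#' the connected components of this pair graph (single linkage). Features with
#' zero abundance variance have undefined correlations and become singleton
#' groups. Internal-standard channels are always singletons.
#'
#' @param table a [feature_table()]
#' @param rt_window maximum retention-time difference, seconds
#' @param corr_min minimum Pearson r across samples
#' @return object of class `pseudospectra`: per-feature group id, per-group
#'   representative (maximum mean abundance), and the feature metadata needed
#'   by downstream adduct removal.
#' @export
group_pseudospectra <- function(table, rt_window = 5, corr_min = 0.7) {
  stopifnot(inherits(table, "feature_table"))
  if (ncol(table$abundance) < 2) stop("need at least 2 samples")
  if (corr_min <= 0 || corr_min >= 1) stop("corr_min must be in (0,1)")
  ab <- table$abundance
  rt <- table$features$rt_s
  n <- nrow(ab)
  sds <- apply(ab, 1, stats::sd)
  constant <- sds == 0
  std <- !constant & !table$features$is_standard
  suppressWarnings(cc <- stats::cor(t(ab)))
  cc[is.na(cc)] <- 0

  # union-find over the thresholded pair graph
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  ord <- order(rt)
  for (a in seq_len(n - 1)) {
    i <- ord[a]
    if (!std[i]) next
    for (b in (a + 1):n) {
      j <- ord[b]
      if (rt[j] - rt[i] > rt_window) break
      if (!std[j]) next
      if (cc[i, j] >= corr_min) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  gid <- match(roots, unique(roots))
  means <- rowMeans(ab)
  rep_of <- vapply(split(seq_len(n), gid), function(ix)
    ix[which.max(means[ix])], integer(1))
  structure(list(
    group = stats::setNames(gid, table$features$feature_id),
    representative = stats::setNames(table$features$feature_id[rep_of],
                                     names(rep_of)),
    features = table$features,
    singletons_constant = table$features$feature_id[constant]),
    class = "pseudospectra")
}

#' @export
print.pseudospectra <- function(x, ...) {
  cat(sprintf("pseudospectra: %d features in %d groups\n",
              length(x$group), length(x$representative)))
  invisible(x)
}

#' Keep one representative feature per pseudospectrum
#'
#' The member with the highest mean abundance represents its group's peak
#' area. Output is ordered by retention time; internal-standard channels are
#' retained.
#'
#' @param grouping a [group_pseudospectra()] result
#' @param table the feature table the grouping was computed on
#' @return reduced [feature_table()] with attribute `group_sizes`
#' @export
select_representatives <- function(grouping, table) {
  stopifnot(inherits(grouping, "pseudospectra"), inherits(table, "feature_table"))
  if (!all(table$features$feature_id %in% names(grouping$group))) {
    stop("grouping does not cover the table")
  }
  keep <- table$features$feature_id %in% grouping$representative
  out <- ft_subset(table, table$features$feature_id[keep])
  out <- ft_subset(out, out$features$feature_id[order(out$features$rt_s)])
  attr(out, "group_sizes") <- as.integer(table(grouping$group))
  out
}

NH4_H_SPACING <- 17.026549  # Da, [M+NH4]+ minus [M+H]+

#' Remove ammonium-adduct features
#'
#' Within each pseudospectrum, a feature whose m/z exceeds another member's by
#' the NH4+/H+ spacing (17.026549 Da) within `mass_tol` is an [M+NH4]+ adduct
#' of that member and would masquerade as a nitrogenous compound; it is
#' removed. Works on any table covered by the grouping, so it can run after
#' representative selection (comparisons use all original group members).
#'
#' @param grouping a [group_pseudospectra()] result
#' @param table feature table to filter
#' @param mass_tol tolerance in Da (default 0.005, ~18 ppm at m/z 273)
#' @return filtered [feature_table()]; removals logged in attribute
#'   `adducts_removed` (feature id, partner id, observed spacing)
#' @export
remove_ammonium_adducts <- function(grouping, table, mass_tol = 0.005) {
  stopifnot(inherits(grouping, "pseudospectra"), mass_tol > 0)
  all_feats <- grouping$features
  gid_all <- grouping$group[all_feats$feature_id]
  removed <- list()
  keep <- rep(TRUE, nrow(table$features))
  for (i in seq_len(nrow(table$features))) {
    fid <- table$features$feature_id[i]
    if (table$features$is_standard[i]) next
    g <- grouping$group[[fid]]
    if (is.null(g) || is.na(g)) next
    members <- all_feats[gid_all == g & all_feats$feature_id != fid, , drop = FALSE]
    if (!nrow(members)) next
    spacing <- table$features$mz[i] - members$mz
    hit <- which(abs(spacing - NH4_H_SPACING) <= mass_tol)
    if (length(hit)) {
      keep[i] <- FALSE
      removed[[fid]] <- data.frame(feature_id = fid,
                                   partner_id = members$feature_id[hit[1]],
                                   spacing = spacing[hit[1]])
    }
  }
  out <- ft_subset(table, table$features$feature_id[keep])
  attr(out, "adducts_removed") <-
    if (length(removed)) do.call(rbind, removed) else
      data.frame(feature_id = character(), partner_id = character(),
                 spacing = numeric())
  out
}

#' Remove features with significant batch effects
#'
#' Per feature, a one-way ANOVA of abundance grouped by extraction batch;
#' features with p below `alpha` are excised. Zero-variance features get p = 1
#' (no evidence of a batch effect) and are retained. Internal-standard
#' channels are never removed.
#'
#' @param table a [feature_table()]
#' @param metadata sample metadata with `sample_id` and `batch`
#' @param alpha significance level (default 0.10)
#' @return filtered [feature_table()] with attribute `batch_removed`
#'   (feature id and p-value of every removed feature) and `batch_p`
#'   (p-values for all tested features)
#' @export
filter_batch_effects <- function(table, metadata, alpha = 0.10) {
  stopifnot(inherits(table, "feature_table"))
  check_samples(table, metadata)
  batch <- metadata$batch[match(colnames(table$abundance), metadata$sample_id)]
  tab <- table(batch)
  if (length(tab) < 2) stop("need >= 2 batches")
  if (any(tab < 2)) stop("batch with < 2 samples: ",
                         paste(names(tab)[tab < 2], collapse = ", "))
  p <- batch_anova_p(table$abundance, batch)
  drop <- !table$features$is_standard & p < alpha
  out <- ft_subset(table, table$features$feature_id[!drop])
  attr(out, "batch_removed") <- data.frame(
    feature_id = table$features$feature_id[drop], p = p[drop])
  attr(out, "batch_p") <- stats::setNames(p, table$features$feature_id)
  out
}

# vectorized one-way ANOVA F-test p-values, rows of `ab` tested against `g`
batch_anova_p <- function(ab, g) {
  g <- factor(g)
  n <- ncol(ab); k <- nlevels(g)
  counts <- as.vector(table(g))
  gm <- rowMeans(ab)
  group_means <- vapply(levels(g), function(l)
    rowMeans(ab[, g == l, drop = FALSE]), numeric(nrow(ab)))
  ss_between <- as.vector((sweep(group_means, 1, gm)^2) %*% counts)
  ss_total <- rowSums(sweep(ab, 1, gm)^2)
  ss_within <- pmax(0, ss_total - ss_between)
  f <- (ss_between / (k - 1)) / (ss_within / (n - k))
  p <- stats::pf(f, k - 1, n - k, lower.tail = FALSE)
  p[ss_total == 0] <- 1            # constant feature: no evidence
  p[ss_within == 0 & ss_total > 0] <- 0
  p
}
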