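#' Shannon effective number (Hill number, q = 1)
#'
#' `exp(-sum p_i log p_i)`: the number of equally abundant peaks that would
#' give the same Shannon entropy. Bounded by 1 and the richness, with
#' equality at a single peak and at perfect evenness. Zeros are dropped.
#'
#' @param abundances non-negative numeric vector with at least one positive
#'   entry
#' @return effective number of peaks
#' @examples
#' shannon_effective(c(1, 1, 1, 1))       # 4
#' shannon_effective(c(0.5, 0.25, 0.25))  # ~2.828
#' @export
shannon_effective <- function(abundances) {
  if (any(abundances < 0)) stop("abundances must be non-negative")
  x <- abundances[abundances > 0]
  if (!length(x)) stop("all-zero abundance vector")
  p <- x / sum(x)
  exp(-sum(p * log(p)))
}

#' Chemodiversity aggregated at a spatiotemporal level
#'
#' Effective numbers are computed per sample (one sample = one individual in
#' one collection month), then grouped at the requested level; a one-way ANOVA
#' tests for differences among groups at that level.
#'
#' @param table normalized [feature_table()]
#' @param metadata sample metadata
#' @param level one of "individual_month" (groups = individuals), "plot",
#'   "subsite", "site"
#' @return list of class `diversity_table`: `samples` (per-sample effective
#'   numbers), `groups` (group id, mean, n, SE), `anova` (F, df, p; NULL and
#'   flagged when there is a single group)
#' @export
diversity_by_level <- function(table, metadata,
                               level = c("plot", "subsite", "site",
                                         "individual_month")) {
  level <- match.arg(level)
  stopifnot(inherits(table, "feature_table"))
  check_samples(table, metadata)
  md <- metadata[match(colnames(table$abundance), metadata$sample_id), ]
  eff <- apply(table$abundance, 2, shannon_effective)
  key <- switch(level,
    individual_month = md$individual,
    plot = md$plot,
    subsite = paste(md$site, md$subsite, sep = ":"),
    site = md$site)
  groups <- data.frame(
    group = names(tapply(eff, key, mean)),
    mean_effective = as.numeric(tapply(eff, key, mean)),
    n = as.integer(table(key)[names(tapply(eff, key, mean))]),
    se = as.numeric(tapply(eff, key, function(v)
      stats::sd(v) / sqrt(length(v)))),
    stringsAsFactors = FALSE)
  an <- NULL; flag <- NULL
  if (length(unique(key)) >= 2) {
    an <- anova_oneway(eff, key)
  } else flag <- "single group: ANOVA skipped"
  structure(list(level = level,
                 samples = data.frame(sample_id = names(eff), effective = eff,
                                      group = key, row.names = NULL),
                 groups = groups, anova = an, flag = flag),
            class = "diversity_table")
}

#' Manhattan distances between samples
#'
#' `d(i, j) = sum_f |x_if - x_jf|` over normalized feature abundances.
#' @param table normalized [feature_table()]
#' @return object of class `phyto_dist` (symmetric matrix + metric tag)
#' @export
manhattan_distances <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  if (anyNA(table$abundance)) stop("missing values not allowed")
  d <- as.matrix(stats::dist(t(table$abundance), method = "manhattan"))
  phyto_dist(d, "manhattan")
}

#' Jaccard distances between communities
#'
#' Counts are reduced to presence/absence; `d = 1 - |A ^ B| / |A v B|`. A pair
#' of empty communities has distance 0 and is flagged.
#'
#' @param counts matrix or data.frame of non-negative counts, rows = units
#' @return `phyto_dist` with attribute `empty_rows`
#' @export
jaccard_distances <- function(counts) {
  m <- as.matrix(counts)
  if (any(m < 0)) stop("counts must be non-negative")
  pa <- m > 0
  inter <- tcrossprod(pa * 1)
  sizes <- rowSums(pa)
  uni <- outer(sizes, sizes, `+`) - inter
  d <- 1 - inter / uni
  d[uni == 0] <- 0                      # two empty communities
  diag(d) <- 0
  if (is.null(rownames(m))) rownames(d) <- colnames(d) <- seq_len(nrow(m))
  out <- phyto_dist(d, "jaccard")
  attr(out, "empty_rows") <- rownames(d)[sizes == 0]
  out
}

phyto_dist <- function(d, metric) {
  d <- as.matrix(d)
  stopifnot(isSymmetric(unname(d), tol = 1e-8), all(diag(d) == 0), all(d >= 0))
  structure(list(d = d, metric = metric, ids = rownames(d)),
            class = "phyto_dist")
}

#' @export
print.phyto_dist <- function(x, ...) {
  cat(sprintf("phyto_dist: %d x %d, metric = %s\n",
              nrow(x$d), ncol(x$d), x$metric))
  invisible(x)
}

#' Parasitoid success per plot
#'
#' The fraction of parasitoid-yielding larvae among those that survived
#' rearing to adult-or-parasitoid emergence; larvae that died are excluded
#' from the denominator. Plots with an empty denominator return NA and are
#' flagged.
#'
#' @param outcomes data.frame with columns `plot` and `outcome`
#'   (`"adult"`, `"parasitoid"`, `"died"`)
#' @return named numeric vector of per-plot fractions, attribute
#'   `empty_plots`
#' @export
parasitoid_success <- function(outcomes) {
  stopifnot(all(c("plot", "outcome") %in% names(outcomes)))
  bad <- setdiff(unique(outcomes$outcome), c("adult", "parasitoid", "died"))
  if (length(bad)) stop("unknown outcome(s): ", paste(bad, collapse = ", "))
  split_out <- split(outcomes$outcome, outcomes$plot)
  frac <- vapply(split_out, function(o) {
    den <- sum(o %in% c("adult", "parasitoid"))
    if (den == 0) NA_real_ else sum(o == "parasitoid") / den
  }, numeric(1))
  attr(frac, "empty_plots") <- names(frac)[is.na(frac)]
  frac
}

#' Ordinary least squares gradient model
#'
#' Fits `response ~ predictors` with an intercept, reporting coefficients,
#' their p-values, R-squared and the pairwise Pearson correlations among all
#' variables (for subsite-level reporting). Errors on exactly collinear
#' predictors, naming the offending pair.
#'
#' @param response numeric vector
#' @param predictors numeric matrix or data.frame
#' @return list of class `gradient_fit`
#' @export
fit_gradient_model <- function(response, predictors) {
  X <- as.matrix(predictors)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  n <- length(response)
  if (n <= ncol(X) + 1) stop("need n > predictors + 1")
  if (ncol(X) > 1) {
    cc <- stats::cor(X)
    cc[upper.tri(cc, diag = TRUE)] <- 0
    hit <- which(abs(cc) > 1 - 1e-10, arr.ind = TRUE)
    if (nrow(hit)) {
      stop("collinear predictors: ", colnames(X)[hit[1, 2]], " and ",
           rownames(cc)[hit[1, 1]])
    }
  }
  df <- data.frame(.y = response, X, check.names = FALSE)
  fit <- stats::lm(.y ~ ., data = df)
  sm <- summary(fit)
  all_vars <- cbind(response = response, X)
  structure(list(coefficients = stats::coef(fit),
                 p_values = sm$coefficients[, "Pr(>|t|)"],
                 r_squared = sm$r.squared,
                 model_p = stats::pf(sm$fstatistic[1], sm$fstatistic[2],
                                     sm$fstatistic[3], lower.tail = FALSE),
                 pearson = stats::cor(all_vars), lm = fit),
            class = "gradient_fit")
}
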