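#' Construct an LC-MS feature table
#'
#' A `feature_table` couples per-feature chromatographic metadata (retention
#' time in seconds, ion m/z in Da) with a features x samples abundance matrix.
#' Sample columns must match a metadata table by `sample_id`.
#'
#' @param features data.frame with columns `feature_id`, `rt_s`, `mz` and
#'   optionally `is_standard` (logical) and `standard_id`.
#' @param abundance numeric matrix, features x samples; rownames are feature
#'   ids, colnames are sample ids. All entries must be non-negative.
#' @return An object of class `feature_table`.
#' @export
feature_table <- function(features, abundance) {
  stopifnot(is.data.frame(features), is.matrix(abundance))
  req <- c("feature_id", "rt_s", "mz")
  missing_cols <- setdiff(req, names(features))
  if (length(missing_cols)) {
    stop("features is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  features$feature_id <- as.character(features$feature_id)
  if (anyDuplicated(features$feature_id)) {
    stop("duplicate feature ids are not allowed")
  }
  if (!all(features$rt_s > 0)) stop("all retention times must be > 0 s")
  if (!all(features$mz > 50)) stop("all m/z must be > 50 Da")
  if (is.null(rownames(abundance))) rownames(abundance) <- features$feature_id
  if (!identical(rownames(abundance), features$feature_id)) {
    stop("abundance rownames must equal features$feature_id in order")
  }
  if (is.null(colnames(abundance))) stop("abundance must have sample ids as colnames")
  if (any(abundance < 0)) stop("abundances must be non-negative")
  if (is.null(features$is_standard)) features$is_standard <- FALSE
  structure(list(features = features, abundance = abundance),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("feature_table: %d features x %d samples (%d internal-standard channels)\n",
              nrow(x$features), ncol(x$abundance), sum(x$features$is_standard)))
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$abundance)

#' Subset a feature table by feature ids
#' @param x feature_table
#' @param ids character vector of feature ids to keep (order preserved)
#' @return feature_table restricted to `ids`
#' @export
ft_subset <- function(x, ids) {
  stopifnot(inherits(x, "feature_table"))
  keep <- match(ids, x$features$feature_id)
  if (anyNA(keep)) stop("unknown feature ids: ", paste(ids[is.na(keep)], collapse = ", "))
  feature_table(x$features[keep, , drop = FALSE],
                x$abundance[keep, , drop = FALSE])
}

#' Write / read a feature table as plain CSV
#'
#' Rows are features (id, rt_s, mz, is_standard) followed by one column per
#' sample.
#' @param x feature_table
#' @param path file path
#' @export
write_feature_table <- function(x, path) {
  stopifnot(inherits(x, "feature_table"))
  out <- cbind(x$features[c("feature_id", "rt_s", "mz", "is_standard")],
               as.data.frame(x$abundance, check.names = FALSE))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @param path file path
#' @export
read_feature_table <- function(path) {
  raw <- utils::read.csv(path, check.names = FALSE)
  meta_cols <- c("feature_id", "rt_s", "mz", "is_standard")
  ab <- as.matrix(raw[, setdiff(names(raw), meta_cols), drop = FALSE])
  rownames(ab) <- as.character(raw$feature_id)
  feature_table(raw[meta_cols], ab)
}

# internal: check samples of a table against a metadata frame
check_samples <- function(x, metadata) {
  if (!all(colnames(x$abundance) %in% metadata$sample_id)) {
    stop("abundance columns contain sample ids absent from metadata")
  }
  invisible(TRUE)
}
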