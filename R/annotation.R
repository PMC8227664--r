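#' Relative mass defect
#'
#' The fractional mass (high-resolution minus nominal mass) divided by the
#' measured ion m/z, in ppm. A proxy for hydrogen saturation: lipids run
#' 600-800 ppm, flavonoids 200-400 ppm. Computed against `round(mz)` when the
#' defect is non-negative, otherwise against `floor(mz)` so the result is
#' always non-negative (a defect of 0.585 at m/z 760 rounds up but still means
#' a hydrogen-rich ion).
#'
#' @param mz numeric vector of ion m/z (Da), must be positive
#' @return RMD in ppm
#' @examples
#' relative_mass_defect(273.0757)  # ~277 ppm, flavonoid window
#' @export
relative_mass_defect <- function(mz) {
  stopifnot(all(mz > 0))
  frac <- mz - round(mz)
  frac <- ifelse(frac >= 0, frac, mz - floor(mz))
  frac / mz * 1e6
}

#' Nominal (integer) mass of an ion
#' @param mz ion m/z
#' @return round(mz)
#' @export
nominal_mass <- function(mz) round(mz)

#' Partition features by the nitrogen rule
#'
#' For protonated ions the nitrogen rule flips: an even nominal ion m/z
#' suggests an odd number of nitrogens in the neutral molecule. Even nominal
#' mass features are flagged nitrogenous, odd ones non-nitrogenous. Ions whose
#' fractional part falls within 0.3 of the half-integer boundary are logged as
#' parity-ambiguous but still assigned.
#'
#' @param table a [feature_table()] (standard channels are excluded)
#' @return list with `nitrogenous` / `non_nitrogenous` data.frames of feature
#'   metadata (including `rmd_ppm`) and `ambiguous` feature ids
#' @export
partition_by_nitrogen_rule <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  f <- table$features[!table$features$is_standard, , drop = FALSE]
  f$rmd_ppm <- relative_mass_defect(f$mz)
  f$nitrogenous <- nominal_mass(f$mz) %% 2 == 0
  frac <- f$mz - floor(f$mz)
  ambiguous <- f$feature_id[abs(frac - 0.5) < 0.3]
  list(nitrogenous = f[f$nitrogenous, , drop = FALSE],
       non_nitrogenous = f[!f$nitrogenous, , drop = FALSE],
       ambiguous = ambiguous)
}

#' Default class-window rule table
#'
#' Ordered first-match-wins rules mapping cluster means to the seven-class
#' vocabulary. Phospholipids are the nitrogenous residents of the lipid
#' windows; peptides are the nitrogenous catch-all (high variance of rt, m/z
#' and RMD); flavonoid glycosides and aglycones share the 200-400 ppm RMD band
#' and are split by elution (350-450 s vs 600-800 s); lipids pair high RMD
#' (600-800 ppm) with m/z 400-900 and rt 750-1050 s. Unmatched clusters fall
#' through to "unknown". `NA` bounds are open; `nitrogen = NA` matches either
#' partition.
#'
#' @return data.frame of ordered rules
#' @export
class_rules_default <- function() {
  data.frame(
    class_label = c("phospholipid", "peptide", "flavonoid_glycoside",
                    "flavonoid_aglycone", "lipid", "other"),
    nitrogen = c(TRUE, TRUE, FALSE, FALSE, FALSE, NA),
    rt_min  = c(750, NA, 350, 600, 750, NA),
    rt_max  = c(1050, NA, 450, 800, 1050, 350),
    mz_min  = c(400, NA, NA, NA, 400, NA),
    mz_max  = c(900, NA, NA, NA, 900, 350),
    rmd_min = c(600, NA, 200, 200, 600, NA),
    rmd_max = c(800, NA, 400, 400, 800, 220),
    stringsAsFactors = FALSE
  )
}

rule_matches <- function(rule, rt, mz, rmd, nitrogenous) {
  ok <- TRUE
  if (!is.na(rule$nitrogen)) ok <- ok && (rule$nitrogen == nitrogenous)
  chk <- function(v, lo, hi) (is.na(lo) || v >= lo) && (is.na(hi) || v <= hi)
  ok && chk(rt, rule$rt_min, rule$rt_max) &&
    chk(mz, rule$mz_min, rule$mz_max) &&
    chk(rmd, rule$rmd_min, rule$rmd_max)
}

#' Assign phytochemical classes to clusters
#'
#' Each cluster is labeled by the first rule its mean (rt, m/z, RMD) and
#' nitrogen partition satisfy, in rule-table order; members inherit the
#' cluster label; unmatched clusters become "unknown".
#'
#' @param clusters a [cluster_features()] result (its `partition` field
#'   supplies the nitrogen flag)
#' @param rules ordered rule table, default [class_rules_default()]
#' @return data.frame: feature_id, nitrogenous, cluster, class_label
#' @export
assign_classes <- function(clusters, rules = class_rules_default()) {
  stopifnot(inherits(clusters, "cluster_model"))
  if (!nrow(rules)) stop("empty rule table")
  nitro <- identical(clusters$partition, "nitrogenous")
  labels <- vapply(seq_len(clusters$k), function(j) {
    m <- clusters$cluster_means[j, ]
    for (r in seq_len(nrow(rules))) {
      if (rule_matches(rules[r, ], m["rt_s"], m["mz"], m["rmd_ppm"], nitro)) {
        return(rules$class_label[r])
      }
    }
    "unknown"
  }, character(1))
  data.frame(feature_id = names(clusters$classification),
             nitrogenous = nitro,
             cluster = paste0(if (nitro) "N" else "nonN",
                              clusters$classification),
             class_label = labels[clusters$classification],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Annotate a QC'd feature table end to end
#'
#' Runs the nitrogen-rule partition, a separate Gaussian-mixture clustering
#' with BIC selection per partition, and class-window assignment, then maps
#' each class to its internal standard. Internal-standard channels are
#' assigned their own class directly.
#'
#' @param table a quality-controlled [feature_table()]
#' @param rules class-window rule table
#' @param standards internal standard set
#' @param k_range,structures passed to [cluster_features()]
#' @param seed integer seed for the mixture initializations
#' @return data.frame of class `class_assignment`: feature_id, nitrogenous,
#'   cluster, class_label, standard_id (NA when the class has no standard)
#' @export
annotate_features <- function(table, rules = class_rules_default(),
                              standards = internal_standards_default(),
                              k_range = 1:12, structures = GMM_STRUCTURES,
                              seed = 1L) {
  parts <- partition_by_nitrogen_rule(table)
  res <- list()
  if (nrow(parts$nitrogenous) >= 2) {
    cm <- cluster_features(parts$nitrogenous, k_range, structures,
                           partition = "nitrogenous", seed = seed)
    res$N <- assign_classes(cm, rules)
    attr(res$N, "model") <- cm
  }
  if (nrow(parts$non_nitrogenous) >= 2) {
    cm <- cluster_features(parts$non_nitrogenous, k_range, structures,
                           partition = "non_nitrogenous", seed = seed + 1L)
    res$nonN <- assign_classes(cm, rules)
    attr(res$nonN, "model") <- cm
  }
  out <- do.call(rbind, lapply(res, function(d) { attributes(d)$model <- NULL; d }))
  is_rows <- table$features[table$features$is_standard, , drop = FALSE]
  if (nrow(is_rows)) {
    sid <- match(is_rows$feature_id, standards$standard_id)
    out <- rbind(out, data.frame(
      feature_id = is_rows$feature_id,
      nitrogenous = nominal_mass(is_rows$mz) %% 2 == 0,
      cluster = "standard",
      class_label = standards$class_served[sid],
      stringsAsFactors = FALSE))
  }
  out$standard_id <- standards$standard_id[
    match(out$class_label, standards$class_served)]
  out <- out[match(table$features$feature_id, out$feature_id), ]
  rownames(out) <- NULL
  attr(out, "models") <- lapply(res, attr, "model")
  attr(out, "ambiguous") <- parts$ambiguous
  class(out) <- c("class_assignment", "data.frame")
  out
}

#' Normalize abundances to internal standards and dry mass
#'
#' Features of classes served by an internal standard are divided by that
#' standard's area in the same sample (cancelling per-sample injection and
#' ionization nuisance); every feature is then divided by the dry extracted
#' plant mass (g). Classes without a standard are mass-normalized only.
#' Internal-standard channels are consumed and dropped from the output.
#'
#' @param table a [feature_table()] containing the standard channels
#' @param assignment a [annotate_features()] result
#' @param standards internal standard set
#' @param metadata sample metadata with `dry_mass_g`
#' @return normalized [feature_table()] (units: area per g dry mass)
#' @export
normalize_abundances <- function(table, assignment,
                                 standards = internal_standards_default(),
                                 metadata) {
  stopifnot(inherits(table, "feature_table"))
  check_samples(table, metadata)
  midx <- match(colnames(table$abundance), metadata$sample_id)
  mass <- metadata$dry_mass_g[midx]
  if (any(!is.finite(mass)) || any(mass <= 0)) stop("dry mass must be > 0 for every sample")
  ab <- table$abundance
  std_rows <- stats::setNames(match(standards$standard_id, table$features$feature_id),
                              standards$standard_id)
  for (s in seq_len(nrow(standards))) {
    sid <- standards$standard_id[s]
    row <- std_rows[[sid]]
    targets <- which(assignment$class_label == standards$class_served[s] &
                       !table$features$is_standard)
    if (!length(targets)) next
    if (is.na(row)) stop("internal standard not located in table: ", sid)
    area <- ab[row, ]
    if (any(!is.finite(area)) || any(area <= 0)) {
      bad <- colnames(ab)[!is.finite(area) | area <= 0]
      stop("standard ", sid, " area missing or zero in sample(s): ",
           paste(bad, collapse = ", "))
    }
    ab[targets, ] <- sweep(ab[targets, , drop = FALSE], 2, area, "/")
  }
  ab <- sweep(ab, 2, mass, "/")
  keep <- !table$features$is_standard
  feature_table(table$features[keep, , drop = FALSE],
                ab[keep, , drop = FALSE])
}
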