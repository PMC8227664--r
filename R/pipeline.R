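#' Pipeline configuration
#'
#' Exactly one of `inputs` (paths to feature table / metadata / herbivore
#' CSVs) or `synthetic` (generator settings) must be supplied. All stage
#' parameters default to the analysis' canonical values: pseudospectrum
#' correlation 0.7, batch-effect alpha 0.10, soft power 8, minimum module
#' size 5, merge height 0.25.
#'
#' @param synthetic list of overrides for [hierarchy_config()] /
#'   [make_feature_truth()] (may be an empty list for all-defaults)
#' @param inputs list with paths `feature_table`, `metadata`,
#'   `herbivore_counts`, `herbivore_outcomes`, optionally `plot_covariates`
#'   (CSV with plot, leaves_per_plant)
#' @param rt_window,corr_min,adduct_tol,batch_alpha feature-QC settings
#' @param k_range annotation mixture component range
#' @param power,min_module_size,merge_height network settings
#' @param n_perm,gate_alpha PERMANOVA settings
#' @param sem_alpha pruning level for chemistry paths
#' @param seed global seed; per-stage seeds are fixed offsets from it
#' @return list of class `pipeline_config`
#' @export
pipeline_config <- function(synthetic = NULL, inputs = NULL,
                            rt_window = 5, corr_min = 0.7,
                            adduct_tol = 0.005, batch_alpha = 0.10,
                            k_range = 1:12,
                            power = 8, min_module_size = 5,
                            merge_height = 0.25,
                            n_perm = 9999, gate_alpha = 0.05,
                            sem_alpha = 0.05, seed = 1L) {
  if (is.null(synthetic) == is.null(inputs)) {
    stop("exactly one of 'synthetic' or 'inputs' must be supplied")
  }
  if (!is.null(inputs)) {
    req <- c("feature_table", "metadata", "herbivore_counts",
             "herbivore_outcomes")
    miss <- setdiff(req, names(inputs))
    if (length(miss)) stop("inputs missing paths: ", paste(miss, collapse = ", "))
    gone <- unlist(inputs)[!file.exists(unlist(inputs))]
    if (length(gone)) stop("input file(s) not found: ",
                           paste(gone, collapse = ", "))
  }
  structure(list(synthetic = synthetic, inputs = inputs,
                 rt_window = rt_window, corr_min = corr_min,
                 adduct_tol = adduct_tol, batch_alpha = batch_alpha,
                 k_range = k_range, power = power,
                 min_module_size = min_module_size,
                 merge_height = merge_height, n_perm = n_perm,
                 gate_alpha = gate_alpha, sem_alpha = sem_alpha,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from JSON
#' @param path JSON file
#' @return `pipeline_config`
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(raw$k_range)) raw$k_range <- as.integer(raw$k_range)
  if (!is.null(raw$synthetic) && length(raw$synthetic) == 0) {
    raw$synthetic <- list()
  }
  do.call(pipeline_config, raw)
}

# gated composition test: dispersion first, PERMANOVA only when homogeneous
gated_composition <- function(dist, groups, gate_alpha, n_perm, seed) {
  disp <- dispersion(dist, groups)
  gate_p <- if (is.null(disp$anova)) 1 else disp$anova$p
  proceed <- dispersion_gate(gate_p, gate_alpha)
  list(dispersion = disp, gate = list(p = gate_p, alpha = gate_alpha,
                                      proceed = proceed),
       permanova = if (proceed) permanova(dist, groups, n_perm = n_perm,
                                          seed = seed) else NULL)
}

#' Cross-tabulate network modules against phytochemical classes
#'
#' Counts features by (module color x class label). Marginals equal the
#' number of features tabulated; grey is excluded by default.
#'
#' @param modules a `module_set`
#' @param assignment a [annotate_features()] result
#' @param include_grey include grey-labeled features
#' @return contingency table (modules x classes)
#' @export
cross_tabulate_modules_classes <- function(modules, assignment,
                                           include_grey = FALSE) {
  stopifnot(inherits(modules, "module_set"))
  ids <- names(modules$labels)
  cls <- assignment$class_label[match(ids, assignment$feature_id)]
  keep <- !is.na(cls)
  if (!include_grey) keep <- keep & modules$labels != "grey"
  table(module = modules$labels[keep], class = cls[keep])
}

#' Run the full analysis pipeline
#'
#' Stage order: synthesize or load data, pseudospectrum QC, class annotation
#' and normalization, chemodiversity and dispersion/composition statistics
#' (with the dispersion gate honoured before any PERMANOVA), covariance
#' network modules, and the plot-level path model with chemistry pruning.
#' A JSON report plus CSV bundle is written when `out_dir` is given.
#'
#' @param config a [pipeline_config()]
#' @param out_dir optional output directory
#' @param stop_after optional stage name in
#'   `c("data", "qc", "annotate", "diversity", "network", "sem")` for partial
#'   runs
#' @return list of class `run_report`
#' @export
run_pipeline <- function(config, out_dir = NULL,
                         stop_after = c("sem", "data", "qc", "annotate",
                                        "diversity", "network")) {
  stopifnot(inherits(config, "pipeline_config"))
  stop_after <- match.arg(stop_after)
  t0 <- proc.time()[["elapsed"]]
  seed <- config$seed
  report <- list(parameters = config[setdiff(names(config),
                                             c("synthetic", "inputs"))],
                 seed = seed,
                 version = as.character(utils::packageVersion("phytocommune")))
  truth <- NULL

  ## stage 1: data ----------------------------------------------------------
  if (!is.null(config$synthetic)) {
    syn <- config$synthetic
    hc_args <- syn[intersect(names(syn),
                             names(formals(hierarchy_config)))]
    hc_args$seed <- seed
    hier <- do.call(hierarchy_config, hc_args)
    metadata <- make_hierarchy(hier)
    truth <- make_feature_truth(
      class_profiles = if (!is.null(syn$class_profiles)) syn$class_profiles
        else class_profiles_default(),
      n_modules = if (!is.null(syn$n_modules)) syn$n_modules else 3,
      metadata = metadata,
      seed = seed + 1L)
    ft <- make_feature_table(truth, metadata, seed = seed + 2L)
    herb <- make_community(truth, metadata, seed = seed + 3L)
    plot_covariates <- truth$plot_vars[c("plot", "elevation_m",
                                         "leaves_per_plant")]
  } else {
    ft <- read_feature_table(config$inputs$feature_table)
    metadata <- utils::read.csv(config$inputs$metadata)
    herb <- structure(list(
      counts = utils::read.csv(config$inputs$herbivore_counts,
                               check.names = FALSE),
      outcomes = utils::read.csv(config$inputs$herbivore_outcomes)),
      class = "herbivore_table")
    plot_covariates <- if (!is.null(config$inputs$plot_covariates)) {
      utils::read.csv(config$inputs$plot_covariates)
    } else NULL
  }
  report$counts <- list(features_in = sum(!ft$features$is_standard),
                        samples = ncol(ft$abundance))
  if (stop_after == "data") {
    return(finish_report(report, ft, metadata, herb, truth, out_dir, t0,
                         stage_objects = list()))
  }

  ## stage 2: QC ------------------------------------------------------------
  grouping <- group_pseudospectra(ft, config$rt_window, config$corr_min)
  ft_rep <- select_representatives(grouping, ft)
  ft_noadd <- remove_ammonium_adducts(grouping, ft_rep, config$adduct_tol)
  ft_qc <- filter_batch_effects(ft_noadd, metadata, config$batch_alpha)
  report$counts$pseudospectra <- length(grouping$representative)
  report$counts$after_adducts <- sum(!ft_noadd$features$is_standard)
  report$counts$after_batch_filter <- sum(!ft_qc$features$is_standard)
  if (stop_after == "qc") {
    return(finish_report(report, ft_qc, metadata, herb, truth, out_dir, t0,
                         stage_objects = list(grouping = grouping)))
  }

  ## stage 3: annotation + normalization ------------------------------------
  assignment <- annotate_features(ft_qc, k_range = config$k_range,
                                  seed = seed + 10L)
  ft_norm <- normalize_abundances(ft_qc, assignment, metadata = metadata)
  report$class_counts <- as.list(table(assignment$class_label))
  if (stop_after == "annotate") {
    return(finish_report(report, ft_norm, metadata, herb, truth, out_dir, t0,
                         stage_objects = list(assignment = assignment)))
  }

  ## stage 4: diversity / dispersion / composition --------------------------
  md <- metadata[match(colnames(ft_norm$abundance), metadata$sample_id), ]
  chem_dist <- manhattan_distances(ft_norm)
  diversity <- lapply(c(plot = "plot", subsite = "subsite", site = "site"),
                      function(l) diversity_by_level(ft_norm, metadata, l))
  chem_comp <- list(
    subsite = gated_composition(chem_dist, paste(md$site, md$subsite),
                                config$gate_alpha, config$n_perm, seed + 20L),
    site = gated_composition(chem_dist, md$site, config$gate_alpha,
                             config$n_perm, seed + 21L))
  # herbivores: plot x morphotype counts aggregated over collections
  mcols <- setdiff(names(herb$counts), c("plot", "month"))
  agg <- rowsum(as.matrix(herb$counts[mcols]), herb$counts$plot)
  plot_meta <- unique(metadata[c("plot", "site", "subsite", "elevation_m")])
  plot_meta <- plot_meta[match(rownames(agg), plot_meta$plot), ]
  herb_dist <- jaccard_distances(agg)
  herb_comp <- list(
    subsite = gated_composition(herb_dist,
                                paste(plot_meta$site, plot_meta$subsite),
                                config$gate_alpha, config$n_perm, seed + 22L),
    site = gated_composition(herb_dist, plot_meta$site, config$gate_alpha,
                             config$n_perm, seed + 23L))
  report$diversity <- lapply(diversity, function(d)
    list(groups = d$groups, anova = d$anova))
  report$chemistry_composition <- lapply(chem_comp, composition_record)
  report$herbivore_composition <- lapply(herb_comp, composition_record)
  if (stop_after == "diversity") {
    return(finish_report(report, ft_norm, metadata, herb, truth, out_dir, t0,
                         stage_objects = list(diversity = diversity,
                                              chem_comp = chem_comp,
                                              herb_comp = herb_comp)))
  }

  ## stage 5: covariance network --------------------------------------------
  X <- scale(t(log(ft_norm$abundance)), center = TRUE, scale = FALSE)
  tom <- tom_from_correlation(X, beta = config$power)
  pre <- detect_modules(tom, min_size = config$min_module_size)
  modules <- merge_close_modules(X, pre, merge_height = config$merge_height)
  confusion <- cross_tabulate_modules_classes(modules, assignment)
  mod_disp <- module_dispersion(ft_norm, modules, metadata, "plot")
  report$module_summary <- list(sizes = as.list(table(modules$labels)),
                         explained = as.list(modules$explained),
                         dispersion_ranking = mod_disp,
                         confusion = as.data.frame.matrix(
                           stats::addmargins(confusion)))
  if (stop_after == "network") {
    return(finish_report(report, ft_norm, metadata, herb, truth, out_dir, t0,
                         stage_objects = list(modules = modules,
                                              assignment = assignment,
                                              confusion = confusion)))
  }

  ## stage 6: path model -----------------------------------------------------
  sem <- NULL
  if (!is.null(plot_covariates)) {
    sem <- pipeline_sem(ft_norm, modules, metadata, herb, plot_covariates,
                        alpha = config$sem_alpha)
    report$sem <- list(
      initial = fit_record(sem$pruned$initial_fit),
      final = fit_record(sem$pruned$fit),
      pruning_log = sem$pruned$log,
      effects = sem$effects)
  } else {
    report$sem <- list(skipped = "no plot covariates available")
  }
  finish_report(report, ft_norm, metadata, herb, truth, out_dir, t0,
                stage_objects = list(modules = modules,
                                     assignment = assignment,
                                     confusion = confusion,
                                     diversity = diversity,
                                     chem_comp = chem_comp,
                                     herb_comp = herb_comp, sem = sem))
}

composition_record <- function(x) {
  list(dispersion_F = x$dispersion$anova$F, dispersion_p = x$dispersion$anova$p,
       gate = x$gate,
       permanova = if (!is.null(x$permanova)) {
         x$permanova[c("pseudo_F", "R2", "p", "n_perm",
                       "complete_enumeration")]
       } else "gated: dispersion differs")
}

fit_record <- function(fit) {
  list(chisq = fit$chisq, df = fit$df, p = fit$p, aic = fit$aic,
       aic_loglik = fit$aic_loglik, converged = fit$converged,
       paths = fit$parameters[fit$parameters$type == "path",
                              c("label", "estimate", "se", "p")])
}

# assemble the plot-level SEM data frame and run the pruning procedure
pipeline_sem <- function(ft_norm, modules, metadata, herb, plot_covariates,
                         alpha = 0.05) {
  md <- metadata[match(colnames(ft_norm$abundance), metadata$sample_id), ]
  me_plot <- apply(modules$me, 2, function(v) tapply(v, md$plot, mean))
  mcols <- setdiff(names(herb$counts), c("plot", "month"))
  agg <- rowsum(as.matrix(herb$counts[mcols]), herb$counts$plot)
  plots <- rownames(me_plot)
  herb_abund <- log1p(rowSums(agg)[plots])
  herb_div <- apply(agg[plots, , drop = FALSE], 1, function(v)
    if (sum(v) > 0) log(shannon_effective(v)) else 0)
  psucc <- parasitoid_success(herb$outcomes)[plots]
  pc <- plot_covariates[match(plots, plot_covariates$plot), ]
  mod_names <- colnames(me_plot)
  dat <- data.frame(elevation = pc$elevation_m,
                    leaves_per_plant = log(pc$leaves_per_plant),
                    herbivore_abundance = herb_abund,
                    herbivore_diversity = herb_div,
                    parasitoid_success = psucc,
                    me_plot, check.names = FALSE)
  keep_mods <- mod_names[vapply(mod_names, function(m)
    stats::sd(dat[[m]], na.rm = TRUE) > 1e-8, logical(1))]
  backbone <- c("leaves_per_plant ~ elevation",
                "herbivore_abundance ~ leaves_per_plant",
                "herbivore_diversity ~ herbivore_abundance + elevation",
                "parasitoid_success ~ elevation")
  chem_lines <- c(
    paste("herbivore_abundance ~", paste(keep_mods, collapse = " + ")),
    paste("herbivore_diversity ~", paste(keep_mods, collapse = " + ")),
    paste("parasitoid_success ~", paste(keep_mods, collapse = " + ")),
    vapply(keep_mods, function(m)
      paste(m, "~ elevation + leaves_per_plant"), character(1)))
  model <- parse_model(paste(c(backbone, chem_lines), collapse = "\n"))
  protected <- c("leaves_per_plant ~ elevation",
                 "herbivore_abundance ~ leaves_per_plant",
                 "herbivore_diversity ~ herbivore_abundance",
                 "herbivore_diversity ~ elevation",
                 "parasitoid_success ~ elevation")
  pruned <- prune_chemistry_paths(model, dat, alpha = alpha,
                                  chemical_vars = keep_mods,
                                  protected = protected)
  effects <- tryCatch(effects_decomposition(pruned$fit),
                      error = function(e) NULL)
  list(data = dat, model = model, pruned = pruned, effects = effects)
}

finish_report <- function(report, ft, metadata, herb, truth, out_dir, t0,
                          stage_objects) {
  report$wall_time_s <- round(proc.time()[["elapsed"]] - t0, 3)
  out <- structure(c(report, list(feature_table = ft, metadata = metadata,
                                  herbivores = herb, truth = truth),
                     stage_objects),
                   class = "run_report")
  if (!is.null(out_dir)) write_report(out, out_dir)
  out
}

#' @export
print.run_report <- function(x, ...) {
  cat("run_report (seed ", x$seed, ")\n", sep = "")
  utils::str(x$counts)
  invisible(x)
}

report_json <- function(report) {
  keep <- setdiff(names(report),
                  c("feature_table", "metadata", "herbivores", "truth",
                    "grouping", "assignment", "modules", "confusion",
                    "diversity", "chem_comp", "herb_comp", "sem"))
  jsonlite::toJSON(report[keep], dataframe = "columns", auto_unbox = TRUE,
                   digits = NA, pretty = TRUE, force = TRUE)
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  writeLines(report_json(report), file.path(out_dir, "report.json"))
  write_feature_table(report$feature_table,
                      file.path(out_dir, "feature_table.csv"))
  utils::write.csv(report$metadata, file.path(out_dir, "metadata.csv"),
                   row.names = FALSE)
  if (!is.null(report$herbivores)) {
    utils::write.csv(report$herbivores$counts,
                     file.path(out_dir, "herbivore_counts.csv"),
                     row.names = FALSE)
    utils::write.csv(report$herbivores$outcomes,
                     file.path(out_dir, "herbivore_outcomes.csv"),
                     row.names = FALSE)
  }
  if (!is.null(report$truth)) {
    write_truth(report$truth, file.path(out_dir, "truth.json"))
  }
  if (!is.null(report$assignment)) {
    utils::write.csv(as.data.frame(report$assignment),
                     file.path(out_dir, "class_assignment.csv"),
                     row.names = FALSE)
  }
  if (!is.null(report$modules)) {
    utils::write.csv(data.frame(feature_id = names(report$modules$labels),
                                module = unname(report$modules$labels)),
                     file.path(out_dir, "feature_modules.csv"),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(report$modules$me),
                     file.path(out_dir, "module_eigenvalues.csv"))
  }
  invisible(out_dir)
}
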