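#' Hierarchical field-design configuration
#'
#' Describes the nested sampling design emulated by the generator: sites along
#' an elevational gradient, each holding elevation-band subsites ("low",
#' "medium", "high"), replicate plots per subsite, tagged plant individuals per
#' plot, and repeated monthly collections. Defaults mirror a two-site,
#' 3-subsite, 3-plot, 3-month design (18 plots).
#'
#' @param n_sites number of sites
#' @param subsites_per_site elevation bands per site
#' @param plots_per_subsite replicate plots per band
#' @param individuals_mean,individuals_dispersion mean and negative-binomial
#'   size of the per-plot individual count (minimum 1 individual per plot)
#' @param months number of monthly collections
#' @param elevation_range numeric length-2, metres a.s.l.
#' @param batches number of extraction/LC-MS batches
#' @param seed integer seed
#' @return list of class `hierarchy_config`
#' @export
hierarchy_config <- function(n_sites = 2, subsites_per_site = 3,
                             plots_per_subsite = 3,
                             individuals_mean = 3, individuals_dispersion = 5,
                             months = 3,
                             elevation_range = c(1600, 2600),
                             batches = 4, seed = 1L) {
  counts <- c(n_sites, subsites_per_site, plots_per_subsite, months, batches)
  if (any(counts < 1) || individuals_mean < 1) {
    stop("configuration error: all counts must be >= 1")
  }
  if (elevation_range[1] >= elevation_range[2]) {
    stop("configuration error: elevation min must be < max")
  }
  structure(list(n_sites = n_sites, subsites_per_site = subsites_per_site,
                 plots_per_subsite = plots_per_subsite,
                 individuals_mean = individuals_mean,
                 individuals_dispersion = individuals_dispersion,
                 months = months, elevation_range = elevation_range,
                 batches = batches, seed = as.integer(seed)),
            class = "hierarchy_config")
}

#' Generate sample metadata for a hierarchical field design
#'
#' One row per (individual, month). Subsites are contiguous elevation bands
#' within the configured range; each plot sits at its band midpoint plus a
#' uniform +/-50 m jitter. Dry extracted mass is drawn near 0.020 g. Batches
#' are assigned in contiguous blocks of the sample sheet.
#'
#' @param config a [hierarchy_config()]
#' @return data.frame with columns sample_id, site, subsite, plot, individual,
#'   month, elevation_m, batch, dry_mass_g
#' @export
make_hierarchy <- function(config = hierarchy_config()) {
  stopifnot(inherits(config, "hierarchy_config"))
  set.seed(config$seed)
  bands <- c("low", "medium", "high")
  n_band <- config$subsites_per_site
  band_names <- if (n_band <= 3) bands[seq_len(n_band)] else paste0("band", seq_len(n_band))
  erange <- config$elevation_range
  band_width <- diff(erange) / n_band
  plots <- expand.grid(plot_rep = seq_len(config$plots_per_subsite),
                       subsite = band_names,
                       site = paste0("site", seq_len(config$n_sites)),
                       stringsAsFactors = FALSE)
  band_idx <- match(plots$subsite, band_names)
  midpoint <- erange[1] + (band_idx - 0.5) * band_width
  plots$elevation_m <- round(midpoint + stats::runif(nrow(plots), -50, 50))
  plots$plot <- sprintf("%s_%s_p%d", plots$site, plots$subsite, plots$plot_rep)
  # dispersion <= 0 is the deterministic limit: every plot gets round(mean)
  n_ind <- if (config$individuals_dispersion <= 0) {
    rep(max(1L, round(config$individuals_mean)), nrow(plots))
  } else {
    pmax(1L, stats::rnbinom(nrow(plots), mu = config$individuals_mean,
                            size = config$individuals_dispersion))
  }
  rows <- do.call(rbind, lapply(seq_len(nrow(plots)), function(i) {
    expand.grid(individual = sprintf("%s_i%d", plots$plot[i], seq_len(n_ind[i])),
                month = seq_len(config$months),
                stringsAsFactors = FALSE)
  }))
  rows$plot <- sub("_i[0-9]+$", "", rows$individual)
  pidx <- match(rows$plot, plots$plot)
  md <- data.frame(sample_id = sprintf("S%04d", seq_len(nrow(rows))),
                   site = plots$site[pidx], subsite = plots$subsite[pidx],
                   plot = rows$plot, individual = rows$individual,
                   month = rows$month, elevation_m = plots$elevation_m[pidx],
                   stringsAsFactors = FALSE)
  md <- md[order(md$site, md$subsite, md$plot, md$individual, md$month), ]
  md$sample_id <- sprintf("S%04d", seq_len(nrow(md)))
  # extraction order is randomized before analysis, so batch membership is
  # independent of the field hierarchy
  run_order <- sample.int(nrow(md))
  md$batch <- paste0("b", ceiling(run_order / ceiling(nrow(md) / config$batches)))
  md$dry_mass_g <- pmax(0.005, stats::rnorm(nrow(md), 0.020, 0.002))
  rownames(md) <- NULL
  md
}

#' Default compound-class profiles
#'
#' Seven phytochemical classes with retention-time, m/z and relative-mass-defect
#' windows matching the field's reversed-phase LC-TOF behaviour: flavonoid
#' glycosides and aglycones share an RMD band of 200-400 ppm but elute at
#' 350-450 s and 600-800 s respectively; lipids and phospholipids occupy
#' high-RMD (600-800 ppm), high-m/z (400-900 Da), late (750-1050 s) windows;
#' peptides are the nitrogenous class with wide rt/m-z/RMD variance. Feature
#' counts default to 40/35/33/31/11/7/18.
#'
#' @return data.frame, one row per class, with window bounds and the
#'   probability that a member carries nitrogen.
#' @export
class_profiles_default <- function() {
  data.frame(
    class_label = c("peptide", "flavonoid_glycoside", "phospholipid", "lipid",
                    "flavonoid_aglycone", "other", "unknown"),
    n_features  = c(40L, 35L, 33L, 31L, 11L, 7L, 18L),
    rt_min  = c(150, 350, 750, 750, 600, 100, 1100),
    rt_max  = c(700, 450, 1050, 1050, 800, 300, 1400),
    mz_min  = c(300, 400, 400, 400, 250, 100, 200),
    mz_max  = c(1200, 800, 900, 900, 350, 300, 1000),
    rmd_min = c(350, 200, 600, 600, 200, 30, 850),
    rmd_max = c(650, 400, 800, 800, 400, 200, 1000),
    p_nitrogen = c(1, 0, 1, 0, 0, 1, 0.25),
    stringsAsFactors = FALSE
  )
}

# truncated-normal draw centred on the window midpoint with sd = width/6,
# clamped to the window so class members never escape their stated range
rtrunc_window <- function(n, lo, hi) {
  x <- stats::rnorm(n, mean = (lo + hi) / 2, sd = (hi - lo) / 6)
  pmin(hi, pmax(lo, x))
}

# build an ion m/z whose nominal (rounded) mass has the requested parity and
# whose relative mass defect is ~rmd ppm under the floor/round convention of
# relative_mass_defect()
mz_from_rmd <- function(nominal, rmd_ppm) {
  delta <- rmd_ppm * nominal / 1e6
  delta <- pmin(delta, 1.45)           # physical ceiling ~1500 ppm
  # keep the fractional offset away from the round-half boundary
  delta <- ifelse(abs(delta - 0.5) < 1e-3, 0.501, delta)
  ifelse(delta < 0.5, nominal + delta, nominal + delta - 1)
}

#' Plant ground truth: classes, covariance modules, and path coefficients
#'
#' Draws per-feature (rt, m/z, RMD) from class profiles with nominal-mass
#' parity consistent with the nitrogen flag, plants block-structured module
#' loadings on the `n_modules` largest classes, generates sample-level latent
#' module factors with plot-level structure and elevation/leaf effects taken
#' from `path_coefficients`, and records everything needed to score any
#' downstream stage.
#'
#' @param class_profiles data.frame as [class_profiles_default()]
#' @param n_modules number of planted covariance modules (assigned to the
#'   largest classes in profile order)
#' @param metadata sample metadata from [make_hierarchy()]
#' @param path_coefficients data.frame (from, to, coef) of standardized
#'   planted effects; see [path_coefficients_default()]
#' @param icc intraclass correlation of module factors at plot level
#' @param noise_sd per-feature log-scale residual sd
#' @param batch_frac fraction of features given real batch offsets
#' @param batch_sd sd of those per-batch log-scale offsets
#' @param seed integer seed
#' @return list of class `synthetic_truth`
#' @export
make_feature_truth <- function(class_profiles = class_profiles_default(),
                               n_modules = 3, metadata,
                               path_coefficients = path_coefficients_default(),
                               icc = 0.5, noise_sd = 0.8,
                               batch_frac = 0.1, batch_sd = 0.75,
                               seed = 1L) {
  if (nrow(class_profiles) == 0) stop("empty class-profile list")
  stopifnot(is.data.frame(metadata), n_modules >= 1)
  min_module_size <- 5L
  if (sum(class_profiles$n_features) < n_modules * min_module_size) {
    stop("too few features for the requested number of modules")
  }
  set.seed(seed)
  feats <- do.call(rbind, lapply(seq_len(nrow(class_profiles)), function(i) {
    p <- class_profiles[i, ]
    n <- p$n_features
    nitro <- stats::runif(n) < p$p_nitrogen
    rt <- rtrunc_window(n, p$rt_min, p$rt_max)
    rmd <- rtrunc_window(n, p$rmd_min, p$rmd_max)
    # nominal protonated mass: even => nitrogenous (nitrogen rule on [M+H]+)
    nominal <- round(rtrunc_window(n, p$mz_min, p$mz_max))
    parity_ok <- (nominal %% 2 == 0) == nitro
    nominal <- ifelse(parity_ok, nominal, nominal + 1)
    data.frame(class_label = p$class_label, nitrogenous = nitro,
               rt_s = rt, mz = mz_from_rmd(nominal, rmd),
               rmd_ppm = rmd, stringsAsFactors = FALSE)
  }))
  feats$feature_id <- sprintf("F%04d", seq_len(nrow(feats)))
  feats <- feats[c("feature_id", "class_label", "nitrogenous", "rt_s", "mz", "rmd_ppm")]

  # modules: block loadings on the n_modules largest classes
  mod_classes <- class_profiles$class_label[
    order(-class_profiles$n_features)][seq_len(n_modules)]
  feats$module <- ifelse(feats$class_label %in% mod_classes,
                         paste0("mod_", feats$class_label), "none")
  modules <- paste0("mod_", mod_classes)
  loadings <- matrix(0, nrow(feats), n_modules,
                     dimnames = list(feats$feature_id, modules))
  for (m in modules) {
    members <- feats$module == m
    loadings[members, m] <- stats::runif(sum(members), 1.0, 1.4)
  }

  # plot-level exogenous world: standardized elevation, leaves per plant
  plots <- unique(metadata[c("plot", "elevation_m")])
  z_elev <- as.numeric(scale(plots$elevation_m))
  b_el <- coef_of(path_coefficients, "elevation", "leaves_per_plant")
  z_leaves <- b_el * z_elev + stats::rnorm(nrow(plots), 0, sqrt(max(1e-8, 1 - b_el^2)))
  plot_vars <- data.frame(plot = plots$plot, elevation_m = plots$elevation_m,
                          z_elevation = z_elev, z_leaves = z_leaves,
                          leaves_per_plant = round(exp(7.3 + 0.6 * z_leaves)))

  # latent module factors per sample: planted plot-level drivers + hierarchical noise
  pidx <- match(metadata$plot, plot_vars$plot)
  factors <- matrix(0, nrow(metadata), n_modules,
                    dimnames = list(metadata$sample_id, modules))
  plot_noise <- matrix(stats::rnorm(nrow(plot_vars) * n_modules), ncol = n_modules)
  for (j in seq_len(n_modules)) {
    m <- modules[j]
    b_e <- coef_of(path_coefficients, "elevation", m)
    b_l <- coef_of(path_coefficients, "leaves_per_plant", m)
    signal <- b_e * plot_vars$z_elevation + b_l * plot_vars$z_leaves
    resid_var <- max(0.05, 1 - stats::var(signal))
    f_plot <- signal + sqrt(icc * resid_var) * plot_noise[, j]
    factors[, j] <- f_plot[pidx] +
      sqrt((1 - icc) * resid_var) * stats::rnorm(nrow(metadata))
  }

  batches <- sort(unique(metadata$batch))
  batch_offsets <- matrix(0, nrow(feats), length(batches),
                          dimnames = list(feats$feature_id, batches))
  affected <- stats::runif(nrow(feats)) < batch_frac
  batch_offsets[affected, ] <- stats::rnorm(sum(affected) * length(batches),
                                            0, batch_sd)
  structure(list(features = feats, loadings = loadings, factors = factors,
                 modules = modules, plot_vars = plot_vars,
                 path_coefficients = path_coefficients,
                 batch_offsets = batch_offsets, batch_affected = affected,
                 noise_sd = rep(noise_sd, nrow(feats)), icc = icc,
                 seed = as.integer(seed)),
            class = "synthetic_truth")
}

coef_of <- function(coefs, from, to) {
  hit <- coefs$coef[coefs$from == from & coefs$to == to]
  if (length(hit)) hit[1] else 0
}

#' Default planted path coefficients
#'
#' Standardized effects of the generative tritrophic world: elevation raises
#' leaves per plant and parasitoid success but depresses herbivore diversity;
#' the peptide module feeds herbivore abundance; the flavonoid-glycoside
#' module suppresses herbivores and parasitoids and itself responds negatively
#' to elevation and plant size. Magnitudes are chosen so the standardized
#' system is well conditioned (each endogenous variable keeps positive
#' residual variance).
#' @return data.frame with columns from, to, coef
#' @export
path_coefficients_default <- function() {
  data.frame(
    from = c("elevation", "elevation", "elevation",
             "elevation", "leaves_per_plant",
             "mod_peptide", "mod_flavonoid_glycoside", "leaves_per_plant",
             "herbivore_abundance", "mod_flavonoid_glycoside",
             "mod_flavonoid_glycoside"),
    to   = c("leaves_per_plant", "herbivore_diversity", "parasitoid_success",
             "mod_flavonoid_glycoside", "mod_flavonoid_glycoside",
             "herbivore_abundance", "herbivore_abundance", "herbivore_abundance",
             "herbivore_diversity", "herbivore_diversity",
             "parasitoid_success"),
    coef = c(0.22, -0.34, 0.45,
             -0.27, -0.19,
             0.60, -0.35, 0.16,
             0.50, -0.30,
             -0.33),
    stringsAsFactors = FALSE
  )
}

#' Internal-standard definitions
#'
#' Three co-injected standards covering the major classes: naringenin (100 uM,
#' flavonoid aglycones, [M+H]+ 273.0757), naringin (101 uM, flavonoid
#' glycosides, [M+H]+ 581.1870) and cholecystokinin fragment 30-33 amide
#' (52 uM, peptides, [M+H]+ 597.2483).
#' @return data.frame with standard_id, name, class_served, mz, conc_uM
#' @export
internal_standards_default <- function() {
  data.frame(
    standard_id = c("IS_naringenin", "IS_naringin", "IS_cck"),
    name = c("naringenin", "naringin", "cholecystokinin fragment 30-33 amide"),
    class_served = c("flavonoid_aglycone", "flavonoid_glycoside", "peptide"),
    mz = c(273.0757, 581.1870, 597.2483),
    rt_s = c(700, 400, 500),
    conc_uM = c(100, 101, 52),
    stringsAsFactors = FALSE
  )
}

#' Simulate the aligned LC-MS feature table
#'
#' Abundance is log-normal: `exp(baseline + loading * factor + batch offset +
#' N(0, noise_sd))`, strictly positive. Internal-standard channels are appended
#' with near-constant areas (5% CV) and flagged `is_standard`.
#'
#' @param truth a [make_feature_truth()] result
#' @param metadata matching sample metadata
#' @param standards data.frame as [internal_standards_default()]
#' @param seed integer seed
#' @return a [feature_table()]
#' @export
make_feature_table <- function(truth, metadata,
                               standards = internal_standards_default(),
                               seed = 1L) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (!identical(rownames(truth$factors), metadata$sample_id)) {
    stop("truth and metadata do not share the same sample universe")
  }
  set.seed(seed)
  nf <- nrow(truth$features); ns <- nrow(metadata)
  baseline <- stats::runif(nf, 8, 12)
  signal <- truth$loadings %*% t(truth$factors)          # features x samples
  boff <- truth$batch_offsets[, metadata$batch, drop = FALSE]
  noise <- matrix(stats::rnorm(nf * ns, 0, truth$noise_sd), nf, ns)
  ab <- exp(baseline + signal + boff + noise)
  dimnames(ab) <- list(truth$features$feature_id, metadata$sample_id)

  is_ab <- exp(matrix(stats::rnorm(nrow(standards) * ns, log(5e4), 0.05),
                      nrow(standards), ns,
                      dimnames = list(standards$standard_id, metadata$sample_id)))
  feats <- rbind(
    data.frame(feature_id = truth$features$feature_id,
               rt_s = truth$features$rt_s, mz = truth$features$mz,
               is_standard = FALSE, stringsAsFactors = FALSE),
    data.frame(feature_id = standards$standard_id, rt_s = standards$rt_s,
               mz = standards$mz, is_standard = TRUE, stringsAsFactors = FALSE))
  feature_table(feats, rbind(ab, is_ab))
}

#' Simulate the herbivore community and rearing outcomes
#'
#' Per plot x collection, total larval counts are negative-binomial with
#' log-mean linear in the planted predictors (module eigensignals aggregated
#' to plot level, leaves per plant, elevation); morphotype identities follow a
#' plot-specific multinomial whose evenness increases with the planted
#' diversity signal; each larva's rearing outcome is died (background rate)
#' or adult/parasitoid with parasitoid logit linear in the planted predictors.
#'
#' @param truth a [make_feature_truth()] result
#' @param metadata sample metadata
#' @param module_signals optional samples x modules matrix (defaults to the
#'   planted latent factors)
#' @param n_morphotypes number of morphotypes (default 19)
#' @param base_count expected larvae per plot-collection when all predictors
#'   are at their mean
#' @param effect_scale multiplier applied to the standardized linear predictor
#'   on the log-count scale
#' @param p_died background probability a larva dies in rearing
#' @param seed integer seed
#' @return list of class `herbivore_table` with `counts` (plot x collection
#'   rows, morphotype columns) and `outcomes` (one row per larva)
#' @export
make_community <- function(truth, metadata, module_signals = NULL,
                           n_morphotypes = 19L, base_count = 10,
                           effect_scale = 0.5, p_died = 0.2, seed = 1L) {
  stopifnot(inherits(truth, "synthetic_truth"))
  coefs <- truth$path_coefficients
  known <- c("elevation", "leaves_per_plant", "herbivore_abundance",
             "herbivore_diversity", "parasitoid_success", truth$modules)
  bad <- setdiff(unique(c(coefs$from, coefs$to)), known)
  if (length(bad)) stop("coefficient references unknown variable: ",
                        paste(bad, collapse = ", "))
  if (is.null(module_signals)) module_signals <- truth$factors
  set.seed(seed)
  pv <- truth$plot_vars
  # plot-level module eigensignals: mean over samples, standardized across plots
  mod_plot <- apply(module_signals, 2, function(f)
    tapply(f, metadata$plot, mean)[pv$plot])
  mod_plot <- scale(mod_plot)
  predictors <- cbind(elevation = pv$z_elevation,
                      leaves_per_plant = pv$z_leaves, mod_plot)

  lin <- function(target, extra = NULL) {
    out <- numeric(nrow(pv))
    for (v in colnames(predictors)) {
      out <- out + coef_of(coefs, v, target) * predictors[, v]
    }
    if (!is.null(extra)) out <- out + extra
    out
  }
  months <- sort(unique(metadata$month))
  abund_sig <- lin("herbivore_abundance")
  counts_list <- list(); outcomes <- list()
  for (mi in seq_along(months)) {
    lambda <- base_count * exp(effect_scale * abund_sig)
    total <- stats::rnbinom(nrow(pv), mu = lambda, size = 5)
    div_sig <- lin("herbivore_diversity",
                   extra = coef_of(coefs, "herbivore_abundance",
                                   "herbivore_diversity") * scale(log1p(total))[, 1])
    decay <- 0.35 * exp(-0.5 * effect_scale * div_sig)   # smaller decay = more even
    para_sig <- lin("parasitoid_success")
    p_para <- stats::plogis(stats::qlogis(0.3) + effect_scale * para_sig)
    cmat <- matrix(0L, nrow(pv), n_morphotypes,
                   dimnames = list(NULL, sprintf("morpho%02d", seq_len(n_morphotypes))))
    for (i in seq_len(nrow(pv))) {
      if (total[i] > 0) {
        pr <- exp(-decay[i] * (seq_len(n_morphotypes) - 1))
        draw <- as.integer(stats::rmultinom(1, total[i], pr / sum(pr)))
        cmat[i, ] <- draw
        n_died <- stats::rbinom(1, total[i], p_died)
        n_surv <- total[i] - n_died
        n_par <- stats::rbinom(1, n_surv, p_para[i])
        outcomes[[length(outcomes) + 1]] <- data.frame(
          plot = pv$plot[i], month = months[mi],
          outcome = rep(c("died", "parasitoid", "adult"),
                        c(n_died, n_par, n_surv - n_par)),
          stringsAsFactors = FALSE)
      }
    }
    counts_list[[mi]] <- data.frame(plot = pv$plot, month = months[mi],
                                    cmat, check.names = FALSE,
                                    stringsAsFactors = FALSE)
  }
  structure(list(counts = do.call(rbind, counts_list),
                 outcomes = do.call(rbind, outcomes)),
            class = "herbivore_table")
}

#' @export
print.herbivore_table <- function(x, ...) {
  cat(sprintf("herbivore_table: %d plot-collections, %d morphotypes, %d reared larvae\n",
              nrow(x$counts), ncol(x$counts) - 2L, nrow(x$outcomes)))
  invisible(x)
}

#' Serialize synthetic truth to JSON
#' @param truth synthetic_truth
#' @param path output path
#' @export
write_truth <- function(truth, path) {
  out <- list(features = truth$features,
              modules = truth$modules,
              path_coefficients = truth$path_coefficients,
              plot_vars = truth$plot_vars,
              noise_sd = truth$noise_sd[1], icc = truth$icc, seed = truth$seed)
  jsonlite::write_json(out, path, dataframe = "columns", digits = NA)
  invisible(path)
}

#' Planted-block benchmark for module detection
#'
#' A samples x features matrix holding `n_modules` disjoint blocks of
#' `block_size` features, each block loading on its own latent factor
#' (loading `loading`, log-scale Gaussian noise `noise_sd`), plus `n_noise`
#' pure-noise features. The benchmark ships its ground truth so module
#' recovery, eigenvalue fidelity and hub ranking can all be scored.
#'
#' @param n_modules number of planted blocks
#' @param block_size features per block
#' @param n_noise unstructured features
#' @param n_samples rows
#' @param loading common factor loading
#' @param noise_sd residual sd
#' @param seed integer seed
#' @return list: `X` (samples x features), `labels` (planted block per
#'   feature, "noise" for the rest), `factors` (samples x modules)
#' @export
make_module_benchmark <- function(n_modules = 3, block_size = 50,
                                  n_noise = 27, n_samples = 300,
                                  loading = 1, noise_sd = 0.6, seed = 1L) {
  set.seed(seed)
  nf <- n_modules * block_size + n_noise
  f <- matrix(stats::rnorm(n_samples * n_modules), n_samples, n_modules,
              dimnames = list(NULL, paste0("block", seq_len(n_modules))))
  labels <- c(rep(colnames(f), each = block_size), rep("noise", n_noise))
  X <- matrix(stats::rnorm(n_samples * nf, 0, noise_sd), n_samples, nf)
  for (j in seq_len(n_modules)) {
    cols <- seq_len(block_size) + (j - 1) * block_size
    X[, cols] <- X[, cols] + loading * f[, j]
  }
  colnames(X) <- sprintf("F%04d", seq_len(nf))
  names(labels) <- colnames(X)
  list(X = X, labels = labels, factors = f)
}
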