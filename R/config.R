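#' Analysis pipeline configuration
#'
#' Collects every tunable constant of the inverse pipeline. Defaults are the
#' published analysis settings: 3-SD single-pass outlier exclusion, 500
#' receptors/cell histogram bins, significance level 0.05, the four-level PE
#' bead standard, and an FL1 positivity threshold at the 99.9th percentile of
#' the unlabeled reference.
#'
#' @param scatter_gate `"auto"` (fit a k-sigma box around the densest scatter
#'   cluster, see [fit_scatter_gate()]) or a gate built with [scatter_gate()].
#' @param fl1_rule `"quantile_of_unlabeled"` or `"fixed"`.
#' @param fl1_quantile Quantile of the unlabeled reference FL1 used when
#'   `fl1_rule = "quantile_of_unlabeled"`; in (0, 1).
#' @param fl1_threshold Fixed FL1 threshold (a.u.) when `fl1_rule = "fixed"`.
#' @param bead_levels A [bead_level_set()].
#' @param outlier_k Outlier exclusion multiplier k (values beyond k SD from
#'   the pooled mean are dropped); `> 0`.
#' @param bin_width Histogram bin width in receptors/cell; `> 0`.
#' @param alpha Significance level, in (0, 1).
#' @param subtract_background Subtract the unlabeled-cell PE background from
#'   each converted event (set `FALSE` to probe sensitivity).
#' @param location Replicate-level location statistic for the ensemble path:
#'   `"geometric"` (geometric mean of per-cell receptor numbers, the
#'   cytometry convention) or `"arithmetic"`.
#' @param excess_kurtosis Report kurtosis as excess kurtosis (normal -> 0);
#'   `FALSE` gives the raw fourth standardized moment.
#' @param corrected_moments Use small-sample (Fisher) corrected skewness and
#'   kurtosis estimators instead of the plain moment estimators.
#' @param seed Optional integer seed threaded to random operations.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(scatter_gate = "auto",
                            fl1_rule = c("quantile_of_unlabeled", "fixed"),
                            fl1_quantile = 0.999,
                            fl1_threshold = NULL,
                            bead_levels = bead_level_set(),
                            outlier_k = 3,
                            bin_width = 500,
                            alpha = 0.05,
                            subtract_background = TRUE,
                            location = c("geometric", "arithmetic"),
                            excess_kurtosis = TRUE,
                            corrected_moments = FALSE,
                            seed = NULL) {
  fl1_rule <- match.arg(fl1_rule)
  location <- match.arg(location)
  cfg <- list(scatter_gate = scatter_gate, fl1_rule = fl1_rule,
              fl1_quantile = fl1_quantile, fl1_threshold = fl1_threshold,
              bead_levels = bead_level_set(bead_levels),
              outlier_k = outlier_k, bin_width = bin_width, alpha = alpha,
              subtract_background = isTRUE(subtract_background),
              location = location,
              excess_kurtosis = isTRUE(excess_kurtosis),
              corrected_moments = isTRUE(corrected_moments),
              seed = seed)
  class(cfg) <- "pipeline_config"
  validate_pipeline_config(cfg)
}

validate_pipeline_config <- function(cfg) {
  if (!is_scalar_number(cfg$outlier_k) || cfg$outlier_k <= 0) {
    stop_validation("invalid pipeline config: outlier_k must be > 0")
  }
  if (!is_scalar_number(cfg$bin_width) || cfg$bin_width <= 0) {
    stop_validation("invalid pipeline config: bin_width must be > 0")
  }
  if (!is_scalar_number(cfg$alpha) || cfg$alpha <= 0 || cfg$alpha >= 1) {
    stop_validation("invalid pipeline config: alpha must be in (0, 1)")
  }
  if (!is_scalar_number(cfg$fl1_quantile) ||
      cfg$fl1_quantile <= 0 || cfg$fl1_quantile >= 1) {
    stop_validation("invalid pipeline config: fl1_quantile must be in (0, 1)")
  }
  if (cfg$fl1_rule == "fixed" &&
      (!is_scalar_number(cfg$fl1_threshold) || cfg$fl1_threshold < 0)) {
    stop_validation("invalid pipeline config: fixed fl1_threshold must be >= 0")
  }
  cfg
}

default_scatter_clusters <- function() {
  list(
    target      = list(fsc_mean = 50000, fsc_sd = 6000, ssc_mean = 30000, ssc_sd = 5000),
    contaminant = list(fsc_mean = 45000, fsc_sd = 8000, ssc_mean = 35000, ssc_sd = 7000),
    debris      = list(fsc_mean = 8000,  fsc_sd = 3000, ssc_mean = 5000,  ssc_sd = 2500),
    bead        = list(fsc_mean = 25000, fsc_sd = 2000, ssc_mean = 60000, ssc_sd = 3000)
  )
}

#' Forward-simulation scenario configuration
#'
#' Describes one biological condition for the event simulator: the per-cell
#' receptor-count distribution, the instrument response, the event-population
#' mixture and the bead standard. See `vignette("receptor-quantification")`
#' for how packaged scenarios are parameterized from published statistics.
#'
#' @param name Scenario name.
#' @param receptor_distribution For a single log-normal:
#'   `list(family = "lognormal", median = , cv = )` (population median in
#'   receptors/cell, population coefficient of variation as a fraction). For
#'   a mixture: `list(family = "lognormal_mixture", components = list(
#'   list(median = , sdlog = , weight = ), ...))`.
#' @param n_cells Collected events per labeled replicate; `> 0`.
#' @param n_replicates Number of biological replicates.
#' @param instrument `list(gain = , noise_cv = , autofluor_gm = ,
#'   autofluor_cv = )`: FL2 a.u. per PE molecule, multiplicative log-normal
#'   instrument noise CV (geometric-mean preserving), and the geometric mean
#'   (a.u.) and CV of the additive FL2 autofluorescence.
#' @param populations `list(contaminant_fraction = , debris_fraction = ,
#'   doublet_fraction = )`, each in `[0, 1)` and summing below 1.
#' @param fl1 `list(positive_gm = , negative_gm = , cv = )`: geometric means
#'   of the CD34-FITC positive and negative FL1 populations and their
#'   log-normal CV.
#' @param scatter Per-population scatter cluster parameters; defaults give
#'   separated debris and bead clusters and an overlapping
#'   target/contaminant singlet region.
#' @param bead `list(levels = , n_per_level = , noise_cv = )`.
#' @param unlabeled_n Events per unlabeled (autofluorescence reference)
#'   sample.
#' @param condition Named list of condition labels (strain, tissue,
#'   receptor, ...).
#' @param published Optional named list of published summary statistics the
#'   scenario emulates (carried for reporting, not used in simulation).
#' @param seed Optional integer seed.
#' @return A list of class `scenario_config`.
#' @export
scenario_config <- function(name = "scenario",
                            receptor_distribution = list(family = "lognormal",
                                                         median = 2000, cv = 1),
                            n_cells = 10000,
                            n_replicates = 6,
                            instrument = list(),
                            populations = list(),
                            fl1 = list(),
                            scatter = default_scatter_clusters(),
                            bead = list(),
                            unlabeled_n = 5000,
                            condition = list(),
                            published = list(),
                            seed = NULL) {
  instrument <- utils::modifyList(
    list(gain = 2, noise_cv = 0.15, autofluor_gm = 600, autofluor_cv = 0.3),
    instrument)
  populations <- utils::modifyList(
    list(contaminant_fraction = 0.10, debris_fraction = 0.05,
         doublet_fraction = 0.05),
    populations)
  fl1 <- utils::modifyList(
    list(positive_gm = 5000, negative_gm = 50, cv = 0.5), fl1)
  bead <- utils::modifyList(
    list(levels = bead_level_set(), n_per_level = 2000, noise_cv = 0.05), bead)
  bead$levels <- bead_level_set(bead$levels)
  scatter <- utils::modifyList(default_scatter_clusters(), scatter)
  cfg <- list(name = name, receptor_distribution = receptor_distribution,
              n_cells = n_cells, n_replicates = n_replicates,
              instrument = instrument, populations = populations, fl1 = fl1,
              scatter = scatter, bead = bead, unlabeled_n = unlabeled_n,
              condition = condition, published = published, seed = seed)
  class(cfg) <- "scenario_config"
  validate_scenario_config(cfg)
}

validate_scenario_config <- function(cfg) {
  rd <- cfg$receptor_distribution
  fam <- rd$family %||% "lognormal"
  if (fam == "lognormal") {
    if (!is_scalar_number(rd$median) || rd$median <= 0) {
      stop_validation("invalid scenario config: receptor_distribution$median must be > 0")
    }
    if (!is_scalar_number(rd$cv) || rd$cv <= 0) {
      stop_validation("invalid scenario config: receptor_distribution$cv must be > 0")
    }
  } else if (fam == "lognormal_mixture") {
    comps <- rd$components
    if (is.null(comps) || length(comps) < 2) {
      stop_validation("invalid scenario config: mixture needs >= 2 components")
    }
    w <- vapply(comps, function(co) co$weight %||% NA_real_, numeric(1))
    if (anyNA(w) || any(w <= 0) || abs(sum(w) - 1) > 1e-8) {
      stop_validation("invalid scenario config: mixture weights must be positive and sum to 1")
    }
  } else {
    stop_validation("unsupported receptor distribution family: ", fam)
  }
  if (!is_scalar_number(cfg$n_cells) || cfg$n_cells <= 0) {
    stop_validation("invalid scenario config: n_cells must be > 0")
  }
  if (!is_scalar_number(cfg$n_replicates) || cfg$n_replicates < 1) {
    stop_validation("invalid scenario config: n_replicates must be >= 1")
  }
  if (!is_scalar_number(cfg$instrument$gain) || cfg$instrument$gain <= 0) {
    stop_validation("invalid scenario config: instrument$gain must be > 0")
  }
  if (cfg$instrument$noise_cv < 0 || cfg$instrument$autofluor_gm < 0) {
    stop_validation("invalid scenario config: instrument noise/autofluorescence must be >= 0")
  }
  fr <- unlist(cfg$populations[c("contaminant_fraction", "debris_fraction",
                                 "doublet_fraction")])
  if (any(fr < 0) || any(fr >= 1) || sum(fr) >= 1) {
    stop_validation("invalid scenario config: population fractions must lie in [0, 1) and sum below 1")
  }
  cfg
}

#' Load a pipeline or scenario configuration from YAML
#'
#' A flat YAML document is interpreted as a [scenario_config()] when it
#' contains a `receptor_distribution` field and as a [pipeline_config()]
#' otherwise. Absent fields take the documented defaults (k = 3, 500-receptor
#' bins, alpha = 0.05, the standard four bead levels).
#'
#' @param path Path to a YAML file.
#' @return A `pipeline_config` or `scenario_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  doc <- yaml::read_yaml(path)
  if (!is.null(doc$receptor_distribution)) {
    return(scenario_from_document(doc))
  }
  args <- doc[intersect(names(doc), names(formals(pipeline_config)))]
  do.call(pipeline_config, args)
}

# build a scenario_config from a parsed YAML document; a distribution given as
# observed (post-exclusion) statistics is deconvolved to population parameters
scenario_from_document <- function(doc) {
  rd <- doc$receptor_distribution
  if (!is.null(rd$observed)) {
    obs <- rd$observed
    pop <- calibrate_receptor_lognormal(median = obs$median,
                                        cv = obs$cv_percent / 100,
                                        k = obs$exclusion_k %||% 3)
    rd <- list(family = "lognormal", median = pop$median, cv = pop$cv,
               observed = obs)
  }
  scenario_config(
    name = doc$name %||% "scenario",
    receptor_distribution = rd,
    n_cells = doc$n_cells %||% 10000,
    n_replicates = doc$n_replicates %||% 6,
    instrument = doc$instrument %||% list(),
    populations = doc$populations %||% list(),
    fl1 = doc$fl1 %||% list(),
    scatter = doc$scatter %||% list(),
    bead = doc$bead %||% list(),
    unlabeled_n = doc$unlabeled_n %||% 5000,
    condition = doc$condition %||% list(),
    published = doc$published %||% list(),
    seed = doc$seed
  )
}
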