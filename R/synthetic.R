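#' Draw per-cell receptor counts
#'
#' Samples true receptor counts from a scenario's receptor distribution.
#' For the `lognormal` family the parameters are solved so that the
#' *population* median and coefficient of variation equal the configured
#' values: `meanlog = log(median)`, `sdlog^2 = log(1 + cv^2)`. The
#' `lognormal_mixture` family draws from weighted log-normal components
#' given by their medians and `sdlog`s.
#'
#' @param dist A receptor distribution list (see [scenario_config()]) or a
#'   `scenario_config`, whose `receptor_distribution` is used.
#' @param n Number of cells to draw.
#' @param seed Optional seed (set once; pass `NULL` inside a seeded run).
#' @return Numeric vector of `n` non-negative receptor counts.
#' @examples
#' r <- draw_receptor_counts(list(family = "lognormal", median = 1800, cv = 1.1),
#'                           1000, seed = 1)
#' @export
draw_receptor_counts <- function(dist, n, seed = NULL) {
  if (inherits(dist, "scenario_config")) dist <- dist$receptor_distribution
  if (!is.null(seed)) set.seed(seed)
  if (n == 0) return(numeric(0))
  fam <- dist$family %||% "lognormal"
  if (fam == "lognormal") {
    sdlog <- sqrt(log(1 + dist$cv^2))
    return(stats::rlnorm(n, meanlog = log(dist$median), sdlog = sdlog))
  }
  if (fam == "lognormal_mixture") {
    comps <- dist$components
    w <- vapply(comps, function(co) co$weight, numeric(1))
    idx <- sample.int(length(comps), n, replace = TRUE, prob = w)
    meanlog <- vapply(comps, function(co) log(co$median), numeric(1))
    sdlog <- vapply(comps, function(co) {
      co$sdlog %||% sqrt(log(1 + co$cv^2))
    }, numeric(1))
    return(stats::rlnorm(n, meanlog = meanlog[idx], sdlog = sdlog[idx]))
  }
  stop("unsupported receptor distribution family: ", fam, call. = FALSE)
}

# geometric-mean-preserving multiplicative log-normal noise (E[log eps] = 0)
draw_gm_noise <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  stats::rlnorm(n, meanlog = 0, sdlog = sqrt(log(1 + cv^2)))
}

draw_autofluor <- function(n, gm, cv) {
  if (gm <= 0) return(numeric(n))
  gm * draw_gm_noise(n, cv)
}

draw_scatter <- function(n, cl) {
  cbind(fsc = pmax(0, stats::rnorm(n, cl$fsc_mean, cl$fsc_sd)),
        ssc = pmax(0, stats::rnorm(n, cl$ssc_mean, cl$ssc_sd)))
}

#' Simulate a cell event table
#'
#' Forward model for one cytometry acquisition. Target cells carry receptor
#' count R drawn from the scenario distribution; when `labeled`, the PE
#' channel response is `fl2 = gain * R * eps + A` with `eps` multiplicative
#' geometric-mean-preserving log-normal instrument noise and `A` an additive
#' autofluorescence draw (antibody labeling is saturating with one PE
#' fluorophore per antibody, so bound PE equals surface receptors). Unlabeled
#' cells show autofluorescence only. CD34-negative contaminants carry no
#' target receptors; debris forms a low-scatter cluster; doublets are sums of
#' two independent singlet target events in every channel. Ground-truth
#' columns `true_receptors` and `population_label` are always populated.
#'
#' @param cfg A [scenario_config()].
#' @param labeled Was the sample stained with the PE antibody (and FITC)?
#' @param seed Optional seed.
#' @param n_events Number of events to draw (defaults to `cfg$n_cells` for
#'   labeled samples and `cfg$unlabeled_n` otherwise).
#' @return An `event_table` with ground truth.
#' @export
generate_cell_events <- function(cfg, labeled = TRUE, seed = NULL,
                                 n_events = NULL) {
  stopifnot(inherits(cfg, "scenario_config"))
  if (!is.null(seed)) set.seed(seed)
  n <- n_events %||% (if (labeled) cfg$n_cells else cfg$unlabeled_n)
  ins <- cfg$instrument
  pops <- cfg$populations
  f_target <- 1 - pops$contaminant_fraction - pops$debris_fraction -
    pops$doublet_fraction
  counts <- as.vector(stats::rmultinom(1, n, c(
    target = f_target, contaminant = pops$contaminant_fraction,
    debris = pops$debris_fraction, doublet = pops$doublet_fraction)))
  n_t <- counts[1]; n_c <- counts[2]; n_d <- counts[3]; n_db <- counts[4]

  fl1_draw <- function(m, gm) gm * draw_gm_noise(m, cfg$fl1$cv)
  cell_fl2 <- function(R, m) {
    A <- draw_autofluor(m, ins$autofluor_gm, ins$autofluor_cv)
    if (labeled) ins$gain * R * draw_gm_noise(m, ins$noise_cv) + A else A
  }

  make_singlet <- function(m, cluster, with_receptors) {
    R <- if (with_receptors) draw_receptor_counts(cfg, m) else numeric(m)
    sc <- draw_scatter(m, cluster)
    fl1 <- if (labeled && with_receptors) {
      fl1_draw(m, cfg$fl1$positive_gm)   # CD34+ endothelial cells
    } else {
      fl1_draw(m, cfg$fl1$negative_gm)
    }
    list(fsc = sc[, "fsc"], ssc = sc[, "ssc"], fl1 = fl1,
         fl2 = cell_fl2(R, m), R = R)
  }

  tgt <- make_singlet(n_t, cfg$scatter$target, TRUE)
  ctm <- make_singlet(n_c, cfg$scatter$contaminant, FALSE)

  deb_sc <- draw_scatter(n_d, cfg$scatter$debris)
  deb <- list(fsc = deb_sc[, "fsc"], ssc = deb_sc[, "ssc"],
              fl1 = fl1_draw(n_d, cfg$fl1$negative_gm * 0.5),
              fl2 = draw_autofluor(n_d, ins$autofluor_gm * 0.3,
                                   ins$autofluor_cv),
              R = rep(NA_real_, n_d))

  a <- make_singlet(n_db, cfg$scatter$target, TRUE)
  b <- make_singlet(n_db, cfg$scatter$target, TRUE)
  dbl <- list(fsc = a$fsc + b$fsc, ssc = a$ssc + b$ssc,
              fl1 = a$fl1 + b$fl1, fl2 = a$fl2 + b$fl2, R = a$R + b$R)

  tab <- event_table(
    fsc = c(tgt$fsc, ctm$fsc, deb$fsc, dbl$fsc),
    ssc = c(tgt$ssc, ctm$ssc, deb$ssc, dbl$ssc),
    fl1 = c(tgt$fl1, ctm$fl1, deb$fl1, dbl$fl1),
    fl2 = c(tgt$fl2, ctm$fl2, deb$fl2, dbl$fl2),
    true_receptors = c(tgt$R, rep(0, n_c), deb$R, dbl$R),
    population_label = rep(c("target", "contaminant", "debris", "doublet"),
                           times = c(n_t, n_c, n_d, n_db)),
    metadata = list(sample_id = paste0(cfg$name, if (labeled) "_labeled" else "_unlabeled"),
                    condition = paste(unlist(cfg$condition), collapse = "/"),
                    labeled = labeled)
  )
  subset_events(tab, sample.int(nrow(tab)))  # shuffle acquisition order
}

#' Simulate a PE-bead acquisition
#'
#' Generates `n_per_level` events per bead level with
#' `fl2 = gain * PE_level * eps`, where `eps` is geometric-mean-preserving
#' log-normal bead noise, so the per-level FL2 geometric mean is an unbiased
#' estimate of `gain * PE_level`. Beads form their own scatter cluster,
#' distinct from cells. The generating level index is recorded in
#' `population_label` as `bead_level_<k>`.
#'
#' @param cfg A [scenario_config()].
#' @param seed Optional seed.
#' @return An `event_table` of bead events.
#' @export
generate_bead_events <- function(cfg, seed = NULL) {
  stopifnot(inherits(cfg, "scenario_config"))
  if (!is.null(seed)) set.seed(seed)
  levels <- cfg$bead$levels
  m <- cfg$bead$n_per_level
  n <- m * length(levels)
  level_idx <- rep(seq_along(levels), each = m)
  fl2 <- cfg$instrument$gain * levels[level_idx] *
    draw_gm_noise(n, cfg$bead$noise_cv)
  sc <- draw_scatter(n, cfg$scatter$bead)
  tab <- event_table(
    fsc = sc[, "fsc"], ssc = sc[, "ssc"],
    fl1 = 30 * draw_gm_noise(n, 0.3), fl2 = fl2,
    true_receptors = levels[level_idx],
    population_label = paste0("bead_level_", level_idx),
    metadata = list(sample_id = paste0(cfg$name, "_beads"), labeled = FALSE)
  )
  subset_events(tab, sample.int(nrow(tab)))
}

# closed-form summary statistics of a k-SD single-pass-truncated log-normal:
# for LN(0, sdlog), cut at population mean +/- k*SD, return the retained
# fraction and the retained CV and median factor (median_post / median_pop)
truncated_lognormal_stats <- function(sdlog, k = 3) {
  s2 <- sdlog^2
  M1 <- exp(s2 / 2)
  cv <- sqrt(exp(s2) - 1)
  SD <- M1 * cv
  lo <- M1 - k * SD
  hi <- M1 + k * SD
  p_lo <- if (lo <= 0) 0 else stats::plnorm(lo, 0, sdlog)
  p_hi <- stats::plnorm(hi, 0, sdlog)
  keep <- p_hi - p_lo
  z1 <- function(cut) if (cut <= 0) -Inf else (log(cut) - s2) / sdlog
  z2 <- function(cut) if (cut <= 0) -Inf else (log(cut) - 2 * s2) / sdlog
  m1 <- M1 * (stats::pnorm(z1(hi)) - stats::pnorm(z1(lo))) / keep
  m2 <- exp(2 * s2) * (stats::pnorm(z2(hi)) - stats::pnorm(z2(lo))) / keep
  list(keep = keep,
       cv_post = sqrt(m2 - m1^2) / m1,
       median_factor = exp(sdlog * stats::qnorm(p_lo + keep / 2)))
}

#' Deconvolve published post-exclusion statistics to population parameters
#'
#' Pooled cell-by-cell statistics are conventionally reported *after*
#' excluding values beyond k standard deviations from the mean. Re-applying
#' that exclusion to a log-normal population whose parameters are set to the
#' reported median and CV shrinks the measured CV substantially (the cut
#' removes the heavy upper tail that generated the reported CV in the first
#' place). This function inverts the single-pass k-SD truncation map in
#' closed form: it returns the population median and CV of the log-normal
#' whose *post-exclusion* median and CV equal the supplied values, so a
#' simulated sample reproduces the published statistics when analysed with
#' the published procedure.
#'
#' @param median Reported (post-exclusion) median, receptors/cell.
#' @param cv Reported (post-exclusion) coefficient of variation, fraction.
#' @param k Exclusion multiplier used by the reporting analysis (default 3).
#' @return List with `median`, `cv` (population values), `sdlog`, and
#'   `keep_fraction` (expected retained fraction under exclusion).
#' @examples
#' pop <- calibrate_receptor_lognormal(median = 1800, cv = 1.1)
#' pop$cv  # population CV needed to observe CV 1.1 after 3-SD exclusion
#' @export
calibrate_receptor_lognormal <- function(median, cv, k = 3) {
  stopifnot(median > 0, cv > 0, k > 0)
  f <- function(s) truncated_lognormal_stats(s, k)$cv_post - cv
  sdlog <- stats::uniroot(f, c(1e-4, 6), tol = 1e-10)$root
  st <- truncated_lognormal_stats(sdlog, k)
  pop_median <- median / st$median_factor
  list(median = pop_median, cv = sqrt(exp(sdlog^2) - 1), sdlog = sdlog,
       keep_fraction = st$keep)
}

#' Packaged simulation scenarios
#'
#' `list_scenarios()` names the scenario files shipped with the package (one
#' per published condition plus a raw-suspension scenario); `scenario()`
#' loads one by name into a [scenario_config()], deconvolving observed
#' statistics into population parameters where the file specifies them (see
#' [calibrate_receptor_lognormal()]).
#'
#' @param name Scenario name as returned by `list_scenarios()`.
#' @return `scenario()`: a `scenario_config`; `list_scenarios()`: a character
#'   vector.
#' @examples
#' list_scenarios()
#' cfg <- scenario("c57bl6_gastrocnemius_vegfr1")
#' @export
scenario <- function(name) {
  dir <- system.file("extdata", "scenarios", package = "receptorcensus")
  path <- file.path(dir, paste0(name, ".yaml"))
  if (!file.exists(path)) {
    stop("unknown scenario '", name, "'; see list_scenarios()", call. = FALSE)
  }
  load_config(path)
}

#' @rdname scenario
#' @export
list_scenarios <- function() {
  dir <- system.file("extdata", "scenarios", package = "receptorcensus")
  sort(sub("\\.yaml$", "", list.files(dir, pattern = "\\.yaml$")))
}
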