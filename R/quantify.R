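#' Endogenous PE background of unlabeled cells
#'
#' The FL2 geometric mean of the (gated) unlabeled sample, converted through
#' the bead calibration to PE-equivalent molecules/cell. This is the
#' autofluorescence background subtracted from labeled-cell receptor
#' numbers. If no event has positive FL2 (a noiseless simulation with zero
#' autofluorescence), the background is 0.
#'
#' @param unlabeled Unlabeled `event_table` (non-empty).
#' @param curve A `calibration_curve`.
#' @return Background in PE molecules/cell (scalar >= 0).
#' @export
background_pe <- function(unlabeled, curve) {
  validate_event_table(unlabeled)
  if (nrow(unlabeled) == 0) {
    stop("cannot estimate background from an empty unlabeled table", call. = FALSE)
  }
  if (all(unlabeled$fl2 <= 0)) return(0)
  gm <- geometric_mean(unlabeled$fl2)
  as.numeric(fluorescence_to_pe(as.numeric(gm), curve))
}

#' Per-cell receptor sample
#'
#' Container for the background-subtracted receptor numbers of one
#' biological replicate. Values are non-negative reals (1 PE molecule == 1
#' bound antibody == 1 surface receptor).
#'
#' @param per_cell Numeric vector of receptors/cell, all `>= 0`.
#' @param condition Optional condition label(s).
#' @param replicate_id Optional replicate identifier.
#' @param background_pe PE background subtracted per cell (`>= 0`).
#' @param n_excluded Events excluded before conversion (non-positive FL2).
#' @param n_clamped Events clamped to 0 after subtraction.
#' @return An object of class `receptor_sample`.
#' @export
receptor_sample <- function(per_cell, condition = NULL, replicate_id = NULL,
                            background_pe = 0, n_excluded = 0L,
                            n_clamped = 0L) {
  per_cell <- as.numeric(per_cell)
  if (any(per_cell < 0, na.rm = TRUE)) {
    stop_validation("receptor sample values must be >= 0")
  }
  if (!is_scalar_number(background_pe) || background_pe < 0) {
    stop_validation("background_pe must be a scalar >= 0")
  }
  structure(list(per_cell = per_cell, condition = condition,
                 replicate_id = replicate_id, background_pe = background_pe,
                 n_excluded = n_excluded, n_clamped = n_clamped),
            class = "receptor_sample")
}

#' Convert gated labeled-cell events to receptors per cell
#'
#' Applies the bead calibration to each event's FL2 intensity and subtracts
#' the scalar PE background per cell: `r = max(0, PE(fl2) - background)`.
#' Negative differences are clamped to 0 (receptor counts are physical);
#' clamped and excluded (non-positive FL2) event counts are reported on the
#' returned sample.
#'
#' @param cells Gated, labeled `event_table`.
#' @param curve A `calibration_curve`.
#' @param background PE background (from [background_pe()]).
#' @param subtract Set `FALSE` to skip background subtraction.
#' @return A [receptor_sample()].
#' @export
receptors_per_cell <- function(cells, curve, background = 0, subtract = TRUE) {
  validate_event_table(cells)
  if (nrow(cells) == 0) {
    warning("empty input: returning an empty receptor sample", call. = FALSE)
    return(receptor_sample(numeric(0), background_pe = background,
                           condition = event_metadata(cells)$condition))
  }
  pe <- fluorescence_to_pe(cells$fl2, curve)
  n_excluded <- attr(pe, "n_excluded")
  pe <- pe[!is.na(pe)]
  vals <- if (subtract) pe - background else pe
  n_clamped <- sum(vals < 0)
  md <- event_metadata(cells)
  receptor_sample(pmax(0, vals),
                  condition = md$condition, replicate_id = md$sample_id,
                  background_pe = if (subtract) background else 0,
                  n_excluded = n_excluded, n_clamped = n_clamped)
}

replicate_estimate <- function(sample, location = c("geometric", "arithmetic")) {
  location <- match.arg(location)
  v <- sample$per_cell
  if (length(v) == 0) return(NA_real_)
  if (location == "arithmetic") return(mean(v))
  as.numeric(geometric_mean(v))
}

#' Replicate-level (ensemble) summary
#'
#' Summarises per-replicate receptor samples the way ensemble results are
#' reported: one location estimate per biological replicate, then mean +/-
#' SEM across replicates, with `SEM = SD(replicate estimates) / sqrt(n)`.
#' The default replicate location statistic is the geometric mean of the
#' background-subtracted per-cell values — the cytometry convention for
#' log-normally distributed signals; `location = "arithmetic"` uses the
#' plain mean. The result is invariant to replicate order.
#'
#' @param samples List of [receptor_sample()]s (one per replicate), or a
#'   single sample.
#' @param location `"geometric"` (default) or `"arithmetic"`.
#' @return Object of class `ensemble_result`: list with `n`, `mean`, `sem`,
#'   `replicate_estimates`, `location`.
#' @export
ensemble_summary <- function(samples, location = c("geometric", "arithmetic")) {
  location <- match.arg(location)
  if (inherits(samples, "receptor_sample")) samples <- list(samples)
  if (length(samples) < 1) stop("need at least one replicate", call. = FALSE)
  est <- vapply(samples, replicate_estimate, numeric(1), location = location)
  n <- length(est)
  sem <- if (n > 1) stats::sd(est) / sqrt(n) else NA_real_
  structure(list(n = n, mean = mean(est), sem = sem,
                 replicate_estimates = est, location = location),
            class = "ensemble_result")
}

#' @export
print.ensemble_result <- function(x, ...) {
  cat(sprintf("Ensemble summary (%s location): n = %d, mean = %.1f +/- %.1f (SEM) receptors/cell\n",
              x$location, x$n, x$mean, x$sem))
  invisible(x)
}

#' Compile condition means into a pooled estimate
#'
#' Replicate-count-weighted average of condition means, as used to compile
#' an overall receptors/cell figure from per-condition ensemble results.
#' Rounding to the nearest 100 happens only at the report layer.
#'
#' @param results List of `ensemble_result`s, or a numeric vector of
#'   condition means (then `n` must be given).
#' @param n Replicate counts (weights) when `results` is numeric.
#' @return The n-weighted mean (full precision).
#' @examples
#' compile_conditions(c(2600, 3700, 2000, 3200), n = c(6, 6, 11, 10))
#' @export
compile_conditions <- function(results, n = NULL) {
  if (is.list(results) && all(vapply(results, inherits, logical(1),
                                     "ensemble_result"))) {
    means <- vapply(results, function(r) r$mean, numeric(1))
    n <- vapply(results, function(r) r$n, numeric(1))
  } else {
    means <- as.numeric(results)
    if (is.null(n)) stop("replicate counts 'n' required", call. = FALSE)
  }
  if (length(means) < 1) stop("need at least one condition", call. = FALSE)
  stats::weighted.mean(means, w = n)
}

#' Sub-cellular compartment estimate
#'
#' Extends a measured surface-receptor number to whole-cell compartments
#' given the fraction of total receptor residing on the surface (from
#' trafficking studies): `total = surface / surface_fraction`,
#' `intracellular = total - surface`, and optionally
#' `recycled = recycled_fraction * intracellular` for the constitutively
#' recycling pool. The print method applies the conventional report
#' rounding (intracellular to the nearest 1,000, recycled to the nearest
#' 100); stored values are full precision.
#'
#' @param surface Measured surface receptors/cell (`>= 0`).
#' @param surface_fraction Fraction of total receptor on the surface, in
#'   (0, 1].
#' @param recycled_fraction Optional fraction of the intracellular pool that
#'   constitutively recycles, in `[0, 1]`.
#' @return Object of class `compartment_estimate`.
#' @examples
#' compartment_estimate(2800, surface_fraction = 0.2)   # ~11,000 intracellular
#' @export
compartment_estimate <- function(surface, surface_fraction,
                                 recycled_fraction = NULL) {
  if (!is_scalar_number(surface) || surface < 0) {
    stop_validation("surface must be a scalar >= 0")
  }
  if (!is_scalar_number(surface_fraction) || surface_fraction <= 0 ||
      surface_fraction > 1) {
    stop_validation("surface_fraction must lie in (0, 1]")
  }
  total <- surface / surface_fraction
  intracellular <- total - surface
  recycled <- if (!is.null(recycled_fraction)) {
    if (!is_scalar_number(recycled_fraction) || recycled_fraction < 0 ||
        recycled_fraction > 1) {
      stop_validation("recycled_fraction must lie in [0, 1]")
    }
    recycled_fraction * intracellular
  } else {
    NA_real_
  }
  structure(list(surface = surface, surface_fraction = surface_fraction,
                 total = total, intracellular = intracellular,
                 recycled = recycled,
                 recycled_fraction_of_intracellular = recycled_fraction %||% NA_real_),
            class = "compartment_estimate")
}

#' @export
print.compartment_estimate <- function(x, ...) {
  cat(sprintf("surface: %s receptors/cell (%.0f%% of total)\n",
              format(round_to(x$surface, 100), big.mark = ","),
              100 * x$surface_fraction))
  cat(sprintf("total: %s   intracellular: ~%s receptors/cell\n",
              format(round_to(x$total, 100), big.mark = ","),
              format(round_to(x$intracellular, 1000), big.mark = ",")))
  if (!is.na(x$recycled)) {
    cat(sprintf("constitutively recycled: ~%s receptors/cell\n",
                format(round_to(x$recycled, 100), big.mark = ",")))
  }
  invisible(x)
}
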