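#' Geometric mean of fluorescence intensities
#'
#' `exp(mean(log(v)))` over the strictly positive values; non-positive values
#' are excluded (not offset-shifted, which would distort the log-domain fit)
#' and their count is reported in the `"n_excluded"` attribute.
#'
#' @param values Numeric vector of intensities (a.u.).
#' @return The geometric mean, with attribute `n_excluded`.
#' @examples
#' geometric_mean(c(2, 8, 32))        # 8
#' geometric_mean(c(0, 10, 1000))     # 100, one value dropped
#' @export
geometric_mean <- function(values) {
  values <- values[!is.na(values)]
  pos <- values[values > 0]
  if (length(pos) == 0) {
    stop("geometric mean undefined: no strictly positive values", call. = FALSE)
  }
  structure(exp(mean(log(pos))), n_excluded = length(values) - length(pos))
}

#' Fit the PE-bead calibration curve
#'
#' Ordinary least squares of log10(per-level FL2 geometric mean) on
#' log10(PE molecules/bead): `y = m x + b`, where x is log10(PE
#' molecules/cell) and y is log10(FL2). The fitted slope `m` and intercept
#' `b` invert fluorescence to absolute PE counts; `r_squared` is the fit
#' diagnostic. The fit is invariant to the ordering of the levels. A
#' non-positive slope is flagged with a warning (`monotone = FALSE`), since
#' the instrument response must increase with PE load.
#'
#' @param bead_geomeans Per-level FL2 geometric means: either named by level
#'   or in the same order as `levels`.
#' @param levels A [bead_level_set()].
#' @return An object of class `calibration_curve`: list with `m`, `b`,
#'   `r_squared`, `monotone`, and `points` (the log-log pairs used).
#' @examples
#' curve <- fit_calibration(c(515, 5956, 26653, 69045), bead_level_set())
#' curve$m  # 1: identity response
#' @export
fit_calibration <- function(bead_geomeans, levels = bead_level_set()) {
  levels <- bead_level_set(levels)
  gm <- as.numeric(bead_geomeans)
  if (!is.null(names(bead_geomeans))) {
    gm <- as.numeric(bead_geomeans[as.character(levels)])
  }
  if (length(gm) != length(levels)) {
    stop("calibration error: need one geometric mean per bead level", call. = FALSE)
  }
  usable <- is.finite(gm) & gm > 0
  if (sum(usable) < 2) {
    stop("calibration error: fewer than 2 usable bead points", call. = FALSE)
  }
  x <- log10(as.numeric(levels)[usable])
  y <- log10(gm[usable])
  fit <- stats::lm(y ~ x)
  m <- unname(stats::coef(fit)[2])
  b <- unname(stats::coef(fit)[1])
  # a noiseless response fits exactly; summary.lm warns about that, but a
  # perfect calibration is a legitimate (simulated) input
  r2 <- if (stats::var(y) == 0) 1 else suppressWarnings(summary(fit)$r.squared)
  monotone <- m > 0
  if (!monotone) {
    warning("calibration slope is not positive; response should increase with PE load",
            call. = FALSE)
  }
  structure(list(m = m, b = b, r_squared = r2, monotone = monotone,
                 points = tibble::tibble(log10_pe = x, log10_fl2 = y)),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("PE bead calibration: log10(FL2) = %.4f * log10(PE) + %.4f  (r^2 = %.4f, %d points)\n",
              x$m, x$b, x$r_squared, nrow(x$points)))
  invisible(x)
}

#' Convert FL2 fluorescence to PE molecules
#'
#' Inverts the calibration curve: `PE = 10^((log10(fl2) - b) / m)`. The
#' conversion is monotone increasing in `fl2` and extrapolates outside the
#' bead range by construction (cell signals below the lowest bead level are
#' common). Non-positive intensities are undefined in the log domain and map
#' to `NA`; their count is reported in the `"n_excluded"` attribute.
#'
#' @param fl2 Numeric vector of FL2 intensities (a.u.).
#' @param curve A [fit_calibration()] result.
#' @return Numeric vector of PE molecule counts (`NA` where `fl2 <= 0`),
#'   with attribute `n_excluded`.
#' @export
fluorescence_to_pe <- function(fl2, curve) {
  stopifnot(inherits(curve, "calibration_curve"))
  out <- rep(NA_real_, length(fl2))
  pos <- !is.na(fl2) & fl2 > 0
  out[pos] <- 10^((log10(fl2[pos]) - curve$b) / curve$m)
  structure(out, n_excluded = sum(!pos))
}

#' Calibrate directly from a bead acquisition
#'
#' Convenience wrapper for one imaging session: assigns bead events to
#' levels ([identify_bead_levels()]), takes per-level FL2 geometric means,
#' and fits the log-log regression ([fit_calibration()]).
#'
#' @param beads Bead `event_table` (already scatter-gated if needed).
#' @param levels A [bead_level_set()].
#' @return A `calibration_curve`; per-level geometric means and event counts
#'   are attached as attributes `geomeans` and `counts`.
#' @export
calibrate_from_beads <- function(beads, levels = bead_level_set()) {
  by_level <- identify_bead_levels(beads, levels)
  gms <- vapply(by_level, function(tab) as.numeric(geometric_mean(tab$fl2)),
                numeric(1))
  curve <- fit_calibration(gms, levels)
  attr(curve, "geomeans") <- gms
  attr(curve, "counts") <- attr(by_level, "counts")
  curve
}
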