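#' Build a condition summary table
#'
#' Collects scenario results into one table with the conventional two-level
#' layout: ensemble columns (replicate count, mean +/- SEM) and cell-by-cell
#' columns (pooled cell count, median, CV%, skewness, kurtosis). Report
#' rounding is applied here and only here: means and medians to the nearest
#' 100 receptors/cell, SEM, skewness and kurtosis to two significant
#' digits, CV to the nearest percent. Optionally appends one n-weighted compiled row
#' per receptor. Identical inputs yield an identical table.
#'
#' @param results List of `scenario_result`s (see [run_scenario()]).
#' @param compiled Append compiled (n-weighted) rows per receptor label?
#' @return A tibble.
#' @export
build_report <- function(results, compiled = FALSE) {
  if (inherits(results, "scenario_result")) results <- list(results)
  if (length(results) < 1) stop("need at least one scenario result", call. = FALSE)
  rows <- lapply(results, function(r) {
    tibble::tibble(
      sample = r$name,
      receptor = r$condition$receptor %||% NA_character_,
      n = r$ensemble$n,
      mean = round_to(r$ensemble$mean, 100),
      sem = signif(r$ensemble$sem, 2),
      n_cells = r$cells$n_cells,
      median = round_to(r$cells$median, 100),
      cv_percent = round(r$cells$cv_percent),
      skewness = signif(r$cells$skewness, 2),
      kurtosis = signif(r$cells$kurtosis, 2)
    )
  })
  out <- do.call(rbind, rows)
  if (compiled) {
    for (rec in unique(out$receptor[!is.na(out$receptor)])) {
      sel <- which(out$receptor == rec & out$sample != "compiled")
      sub <- results[sel]
      cm <- compile_conditions(lapply(sub, function(r) r$ensemble))
      out <- rbind(out, tibble::tibble(
        sample = "compiled", receptor = rec,
        n = sum(vapply(sub, function(r) r$ensemble$n, numeric(1))),
        mean = round_to(cm, 100), sem = NA_real_,
        n_cells = sum(vapply(sub, function(r) r$cells$n_cells, numeric(1))),
        median = NA_real_, cv_percent = NA_real_,
        skewness = NA_real_, kurtosis = NA_real_))
    }
  }
  out
}

#' Write a report table to a tab-separated file
#'
#' @param report A tibble (e.g. from [build_report()], or a
#'   `distribution_summary` histogram).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  utils::write.table(as.data.frame(report), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Plot helpers
#'
#' `plot_calibration()` draws the bead calibration points and fitted log-log
#' regression line; `plot_distribution()` draws the fixed-width cell-by-cell
#' receptor histogram. Both require ggplot2.
#'
#' @param curve A `calibration_curve`.
#' @param summary A `distribution_summary`.
#' @param title Optional plot title.
#' @return A ggplot object.
#' @export
plot_calibration <- function(curve, title = "PE bead calibration") {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
  ggplot2::ggplot(curve$points,
                  ggplot2::aes(x = log10_pe, y = log10_fl2)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_abline(slope = curve$m, intercept = curve$b,
                         linetype = "dashed") +
    ggplot2::labs(x = "log10(PE molecules/bead)",
                  y = "log10(FL2 geometric mean)",
                  title = title,
                  subtitle = sprintf("y = %.3f x + %.3f (r² = %.4f)",
                                     curve$m, curve$b, curve$r_squared)) +
    ggplot2::theme_minimal()
}

#' @rdname plot_calibration
#' @export
plot_distribution <- function(summary, title = "Receptors per cell") {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
  ggplot2::ggplot(summary$histogram,
                  ggplot2::aes(x = bin_lo, y = count)) +
    ggplot2::geom_col(width = summary$histogram$bin_hi[1] -
                        summary$histogram$bin_lo[1],
                      just = 0, fill = "grey40") +
    ggplot2::labs(x = "receptors/cell", y = "cells", title = title) +
    ggplot2::theme_minimal()
}
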