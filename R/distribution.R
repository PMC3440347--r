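#' Pool replicate samples and exclude outliers
#'
#' Pools per-cell receptor values across replicates and applies the
#' single-pass k-SD exclusion used for cell-by-cell analysis: the pooled
#' mean and SD are computed once, and values with `|v - mean| > k * SD` are
#' dropped. The exclusion is deliberately non-iterative; re-running it on
#' its own output can exclude further values, which is logged, not hidden.
#'
#' @param samples List of [receptor_sample()]s or numeric vectors (or one
#'   numeric vector).
#' @param k SD multiplier (`> 0`, default 3).
#' @return Numeric vector of retained values, with attributes `n_total`,
#'   `n_excluded`, `pooled_mean`, `pooled_sd`.
#' @export
pool_and_exclude <- function(samples, k = 3) {
  if (!is_scalar_number(k) || k <= 0) stop_validation("k must be > 0")
  if (is.numeric(samples)) samples <- list(samples)
  pooled <- unlist(lapply(samples, function(s) {
    if (inherits(s, "receptor_sample")) s$per_cell else as.numeric(s)
  }), use.names = FALSE)
  n <- length(pooled)
  if (n < 2) stop("pooled sample needs at least 2 values", call. = FALSE)
  m <- mean(pooled)
  s <- stats::sd(pooled)
  keep <- abs(pooled - m) <= k * s
  structure(pooled[keep], n_total = n, n_excluded = sum(!keep),
            pooled_mean = m, pooled_sd = s)
}

# plain central-moment estimators (no small-sample correction) and their
# Fisher-corrected counterparts
moment_skewness <- function(x, corrected = FALSE) {
  n <- length(x)
  if (n < 2 || (corrected && n < 3)) return(NA_real_)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) return(NA_real_)
  g1 <- mean((x - m)^3) / m2^1.5
  if (!corrected) return(g1)
  g1 * sqrt(n * (n - 1)) / (n - 2)
}

moment_kurtosis <- function(x, excess = TRUE, corrected = FALSE) {
  n <- length(x)
  if (n < 2 || (corrected && n < 4)) return(NA_real_)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) return(NA_real_)
  g2 <- mean((x - m)^4) / m2^2 - 3
  out <- if (corrected) {
    ((n + 1) * g2 + 6) * (n - 1) / ((n - 2) * (n - 3))
  } else {
    g2
  }
  if (excess) out else out + 3
}

#' Cell-by-cell distribution summary
#'
#' Characterises a pooled per-cell receptor distribution: sample median,
#' coefficient of variation (100 * SD / mean), skewness and excess kurtosis
#' (plain moment estimators; a normal distribution scores 0 on both), and a
#' histogram with half-open bins `[lo, hi)` of fixed width starting at 0.
#' Positive skewness reflects the decreasing frequency of cells with very
#' high receptor numbers; positive excess kurtosis reflects tails heavier
#' (and a peak sharper) than a Gaussian.
#'
#' @param values Numeric vector of receptors/cell (e.g. from
#'   [pool_and_exclude()]; its exclusion count is carried through).
#' @param bin_width Histogram bin width, receptors/cell (default 500).
#' @param excess Report excess kurtosis (default) or the raw fourth
#'   standardized moment.
#' @param corrected Use small-sample corrected estimators (default `FALSE`).
#' @return Object of class `distribution_summary`: `n_cells`, `median`,
#'   `cv_percent`, `skewness`, `kurtosis`, `kurtosis_convention`,
#'   `histogram` (tibble `bin_lo`, `bin_hi`, `count`), `n_excluded`.
#' @export
summarize_distribution <- function(values, bin_width = 500, excess = TRUE,
                                   corrected = FALSE) {
  if (!is_scalar_number(bin_width) || bin_width <= 0) {
    stop_validation("bin_width must be > 0")
  }
  n_excluded <- attr(values, "n_excluded") %||% 0L
  x <- as.numeric(values)
  n <- length(x)
  if (n < 2) stop("need at least 2 values to summarise a distribution", call. = FALSE)
  m <- mean(x)
  cv <- if (m == 0) {
    warning("CV undefined: sample mean is zero", call. = FALSE)
    NA_real_
  } else {
    100 * stats::sd(x) / m
  }
  top <- max(x, 0)
  breaks <- seq(0, (floor(top / bin_width) + 1) * bin_width, by = bin_width)
  counts <- vapply(seq_len(length(breaks) - 1), function(i) {
    sum(x >= breaks[i] & x < breaks[i + 1])
  }, integer(1))
  structure(list(
    n_cells = n,
    median = stats::median(x),
    cv_percent = cv,
    skewness = moment_skewness(x, corrected),
    kurtosis = moment_kurtosis(x, excess, corrected),
    kurtosis_convention = if (excess) "excess" else "raw",
    histogram = tibble::tibble(bin_lo = breaks[-length(breaks)],
                               bin_hi = breaks[-1], count = counts),
    n_excluded = n_excluded
  ), class = "distribution_summary")
}

#' @export
print.distribution_summary <- function(x, ...) {
  cat(sprintf("Cell-by-cell summary: n = %d (%d excluded)\n", x$n_cells,
              x$n_excluded))
  cat(sprintf("  median = %.0f receptors/cell, CV = %.0f%%, skewness = %.2f, %s kurtosis = %.2f\n",
              x$median, x$cv_percent, x$skewness, x$kurtosis_convention,
              x$kurtosis))
  invisible(x)
}

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' Compares two pooled per-cell receptor distributions with the two-sided
#' two-sample K-S test on the raw per-cell values (not the binned
#' histograms, which discard information): D is the supremum distance
#' between the empirical CDFs and p comes from the asymptotic K-S
#' distribution at effective sample size `n_a * n_b / (n_a + n_b)`. Receptor
#' values clamped at zero can produce ties; the asymptotic p-value is then
#' conservative, which is accepted.
#'
#' @param a,b Numeric vectors (each `n >= 2`) or [receptor_sample()]s.
#' @return List with `D`, `p` and `n_effective`.
#' @export
ks_two_sample <- function(a, b) {
  if (inherits(a, "receptor_sample")) a <- a$per_cell
  if (inherits(b, "receptor_sample")) b <- b$per_cell
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2 || length(b) < 2) {
    stop("both samples need at least 2 values", call. = FALSE)
  }
  ht <- suppressWarnings(stats::ks.test(a, b, exact = FALSE))
  na <- as.numeric(length(a))
  nb <- as.numeric(length(b))
  list(D = unname(ht$statistic), p = ht$p.value,
       n_effective = na * nb / (na + nb))
}
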