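#' Scatter gates
#'
#' A scatter gate selects events by their position in linear
#' (forward scatter, side scatter) space. `scatter_gate()` builds a
#' rectangular gate from channel ranges; `polygon_gate()` builds a gate from
#' the vertices of a simple polygon. Both must enclose positive area.
#'
#' @param fsc,ssc For `scatter_gate()`: length-2 numeric ranges
#'   `c(lo, hi)`. For `polygon_gate()`: numeric vectors of vertex
#'   coordinates (>= 3 vertices, in order around the polygon).
#' @return An object of class `scatter_gate`.
#' @examples
#' g <- scatter_gate(fsc = c(30000, 70000), ssc = c(10000, 50000))
#' @export
scatter_gate <- function(fsc, ssc) {
  stopifnot(length(fsc) == 2, length(ssc) == 2)
  if (!all(is.finite(c(fsc, ssc))) || diff(fsc) <= 0 || diff(ssc) <= 0) {
    stop_validation("degenerate scatter gate: ranges must have positive extent")
  }
  structure(list(type = "rectangle", fsc = as.numeric(fsc),
                 ssc = as.numeric(ssc)),
            class = "scatter_gate")
}

#' @rdname scatter_gate
#' @export
polygon_gate <- function(fsc, ssc) {
  stopifnot(length(fsc) == length(ssc), length(fsc) >= 3)
  area <- abs(sum(fsc * c(ssc[-1], ssc[1]) - c(fsc[-1], fsc[1]) * ssc)) / 2
  if (!is.finite(area) || area <= 0) {
    stop_validation("degenerate polygon gate: vertices enclose no area")
  }
  structure(list(type = "polygon", fsc = as.numeric(fsc),
                 ssc = as.numeric(ssc)),
            class = "scatter_gate")
}

gate_contains <- function(gate, fsc, ssc) {
  if (gate$type == "rectangle") {
    return(fsc >= gate$fsc[1] & fsc <= gate$fsc[2] &
           ssc >= gate$ssc[1] & ssc <= gate$ssc[2])
  }
  # even-odd ray casting; boundary points count as inside
  px <- gate$fsc; py <- gate$ssc
  n <- length(px)
  inside <- rep(FALSE, length(fsc))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((py[i] > ssc) != (py[j] > ssc)) &
      (fsc < (px[j] - px[i]) * (ssc - py[i]) / (py[j] - py[i]) + px[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Fit a singlet scatter gate automatically
#'
#' Locates the densest cluster in (fsc, ssc) by iterated median/MAD trimming
#' (events beyond 3.5 robust SDs of the running center are discarded at each
#' iteration) and returns a rectangular gate at center +/- `n_sigma` robust
#' SDs per axis. With a dominant singlet population this converges onto the
#' singlet cluster and excludes debris and doublet clusters; it is
#' deterministic and needs no starting gate.
#'
#' @param tab An `event_table`.
#' @param n_sigma Half-width of the fitted box in robust SDs (default 3).
#' @param iterations Trimming iterations (default 3).
#' @return A rectangular [scatter_gate()].
#' @export
fit_scatter_gate <- function(tab, n_sigma = 3, iterations = 3) {
  validate_event_table(tab)
  if (nrow(tab) < 10) stop("too few events to fit a scatter gate", call. = FALSE)
  fsc <- tab$fsc; ssc <- tab$ssc
  keep <- rep(TRUE, length(fsc))
  for (i in seq_len(iterations)) {
    cf <- stats::median(fsc[keep]); cs <- stats::median(ssc[keep])
    sf <- stats::mad(fsc[keep]); ss <- stats::mad(ssc[keep])
    if (sf == 0 || ss == 0) break
    keep <- abs(fsc - cf) < 3.5 * sf & abs(ssc - cs) < 3.5 * ss
  }
  cf <- stats::median(fsc[keep]); cs <- stats::median(ssc[keep])
  sf <- max(stats::mad(fsc[keep]), 1e-8 + 0.001 * max(abs(cf), 1))
  ss <- max(stats::mad(ssc[keep]), 1e-8 + 0.001 * max(abs(cs), 1))
  scatter_gate(fsc = c(cf - n_sigma * sf, cf + n_sigma * sf),
               ssc = c(cs - n_sigma * ss, cs + n_sigma * ss))
}

#' Select singlet events with a scatter gate
#'
#' Pure filter on linear (fsc, ssc): returns the subset of events inside the
#' gate region, preserving order, intensities and metadata. The numbers of
#' events in and out are attached as the `"gating"` attribute.
#'
#' @param tab An `event_table`.
#' @param gate A [scatter_gate()] (or [polygon_gate()]).
#' @return The gated `event_table`.
#' @export
gate_singlets <- function(tab, gate) {
  validate_event_table(tab)
  if (!inherits(gate, "scatter_gate")) {
    stop_validation("'gate' must be a scatter_gate")
  }
  keep <- gate_contains(gate, tab$fsc, tab$ssc)
  out <- subset_events(tab, keep)
  attr(out, "gating") <- list(stage = "scatter", n_in = nrow(tab),
                              n_out = nrow(out))
  out
}

#' FL1 positivity threshold
#'
#' Rule for selecting CD34-FITC-positive (endothelial) events on the FL1
#' channel: either a fixed intensity threshold or a quantile of an unlabeled
#' reference sample (default the 99.9th percentile, anchoring specificity at
#' 0.1% on unlabeled cells).
#'
#' @param threshold Fixed FL1 threshold in a.u. (`> 0`) when `rule = "fixed"`.
#' @param rule `"fixed"` or `"quantile_of_unlabeled"`.
#' @param quantile Reference quantile in (0, 1) for the quantile rule.
#' @return An object of class `fl1_threshold`.
#' @export
fl1_threshold <- function(threshold = NULL,
                          rule = c("quantile_of_unlabeled", "fixed"),
                          quantile = 0.999) {
  rule <- match.arg(rule)
  if (rule == "fixed") {
    if (!is_scalar_number(threshold) || threshold < 0) {
      stop_validation("fixed FL1 threshold must be a non-negative number")
    }
  } else {
    if (!is_scalar_number(quantile) || quantile <= 0 || quantile >= 1) {
      stop_validation("FL1 reference quantile must be in (0, 1)")
    }
  }
  structure(list(rule = rule, threshold = threshold, quantile = quantile),
            class = "fl1_threshold")
}

#' Gate FL1(CD34-FITC)-positive events
#'
#' Keeps events with `fl1` strictly above the resolved threshold. With the
#' quantile rule the threshold is resolved from the unlabeled reference
#' table's FL1 distribution. The resolved threshold is attached to the result
#' as attribute `"fl1_threshold"`.
#'
#' @param tab An `event_table` (labeled sample).
#' @param thr An [fl1_threshold()].
#' @param unlabeled_reference Unlabeled `event_table`; required (non-empty)
#'   for the quantile rule.
#' @return The gated `event_table`.
#' @export
gate_fl1_positive <- function(tab, thr = fl1_threshold(),
                              unlabeled_reference = NULL) {
  validate_event_table(tab)
  if (!inherits(thr, "fl1_threshold")) {
    stop_validation("'thr' must be an fl1_threshold")
  }
  if (thr$rule == "fixed") {
    cut <- thr$threshold
  } else {
    if (is.null(unlabeled_reference) || nrow(unlabeled_reference) == 0) {
      stop("quantile_of_unlabeled rule requires a non-empty unlabeled reference table",
           call. = FALSE)
    }
    cut <- stats::quantile(unlabeled_reference$fl1, probs = thr$quantile,
                           names = FALSE, type = 7)
  }
  out <- subset_events(tab, tab$fl1 > cut)
  attr(out, "gating") <- list(stage = "fl1", n_in = nrow(tab),
                              n_out = nrow(out))
  attr(out, "fl1_threshold") <- cut
  out
}

#' Assign bead events to their PE levels
#'
#' Clusters bead events on log10(fl2) with 1-D k-means (k = number of
#' levels, centers initialised at evenly spaced quantiles) and matches
#' clusters to levels by rank, so the assignment is monotone in fl2 — the
#' algorithmic counterpart of reading subpopulations off the bead histogram.
#' Clusters whose separation is below `min_separation` summed within-cluster
#' SDs are rejected as unresolvable.
#'
#' @param beads Bead `event_table` (event count >= number of levels).
#' @param levels A [bead_level_set()].
#' @param min_separation Required gap between adjacent cluster centers, in
#'   units of the two clusters' summed within-cluster SD (default 2).
#' @return Named list (one `event_table` per level, names = PE level); the
#'   per-level event counts are attached as attribute `"counts"`.
#' @export
identify_bead_levels <- function(beads, levels = bead_level_set(),
                                 min_separation = 2) {
  validate_event_table(beads)
  levels <- bead_level_set(levels)
  k <- length(levels)
  pos <- beads$fl2 > 0
  if (sum(pos) < k) {
    stop("calibration input error: fewer usable bead events (", sum(pos),
         ") than bead levels (", k, ")", call. = FALSE)
  }
  lf <- log10(beads$fl2[pos])
  init <- stats::quantile(lf, probs = (2 * seq_len(k) - 1) / (2 * k),
                          names = FALSE)
  if (length(unique(init)) < k) {
    stop("calibration input error: bead subpopulations are not resolvable",
         call. = FALSE)
  }
  km <- suppressWarnings(stats::kmeans(lf, centers = matrix(init, ncol = 1),
                                       iter.max = 50))
  ord <- order(km$centers[, 1])
  rank_of_cluster <- match(seq_len(k), ord)
  centers <- km$centers[ord, 1]
  sds <- vapply(seq_len(k), function(j) {
    v <- lf[km$cluster == ord[j]]
    if (length(v) > 1) stats::sd(v) else 0
  }, numeric(1))
  gaps <- diff(centers)
  req <- min_separation * (sds[-k] + sds[-1])
  if (any(gaps <= req)) {
    stop("calibration input error: bead subpopulations overlap (cluster separation below threshold)",
         call. = FALSE)
  }
  assignment <- rank_of_cluster[km$cluster]
  idx_pos <- which(pos)
  out <- lapply(seq_len(k), function(j) {
    subset_events(beads, idx_pos[assignment == j])
  })
  names(out) <- as.character(levels)
  attr(out, "counts") <- vapply(out, nrow, integer(1))
  attr(out, "n_dropped_nonpositive") <- sum(!pos)
  out
}
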