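#' One-way ANOVA with Tukey HSD pairwise comparison
#'
#' Tests for differences in replicate-level means across groups: a one-way
#' ANOVA F-test followed by Tukey's honest significant difference, which
#' adjusts pairwise p-values via the studentized-range distribution. The
#' comparison operates on replicate means (one value per biological
#' replicate), not pooled single cells; pooled-cell distributions are
#' compared with [ks_two_sample()].
#'
#' @param groups Named list mapping group label to a numeric vector of
#'   replicate means (each group `n >= 2`; at least 2 groups).
#' @param alpha Significance level for the `significant` flag.
#' @return Object of class `comparison_result`: list with `groups`,
#'   `anova_p`, `pairwise` (tibble: `pair`, `mean_difference`, `adjusted_p`,
#'   `significant`), `alpha`.
#' @examples
#' anova_tukey(list(a = c(1, 2, 3), b = c(11, 12, 13)))
#' @export
anova_tukey <- function(groups, alpha = 0.05) {
  if (!is.list(groups) || length(groups) < 2) {
    stop_validation("need at least 2 groups")
  }
  if (is.null(names(groups)) || any(names(groups) == "")) {
    stop_validation("groups must be named")
  }
  sizes <- vapply(groups, length, integer(1))
  if (any(sizes < 2)) {
    stop_validation("every group needs at least 2 replicate values (offending: ",
                    paste(names(groups)[sizes < 2], collapse = ", "), ")")
  }
  df <- data.frame(
    value = unlist(groups, use.names = FALSE),
    group = factor(rep(names(groups), times = sizes), levels = names(groups))
  )
  fit <- stats::aov(value ~ group, data = df)
  anova_p <- summary(fit)[[1]][["Pr(>F)"]][1]
  tk <- stats::TukeyHSD(fit)$group
  pairwise <- tibble::tibble(
    pair = rownames(tk),
    mean_difference = unname(tk[, "diff"]),
    adjusted_p = unname(tk[, "p adj"]),
    significant = unname(tk[, "p adj"]) < alpha
  )
  structure(list(groups = names(groups), anova_p = anova_p,
                 pairwise = pairwise, alpha = alpha),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("One-way ANOVA across %d groups: p = %.4g\n",
              length(x$groups), x$anova_p))
  cat(sprintf("Tukey HSD pairwise comparisons (alpha = %.3g):\n", x$alpha))
  print(as.data.frame(x$pairwise), row.names = FALSE)
  invisible(x)
}
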