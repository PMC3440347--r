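# shared fixtures and independent oracles, built in code at test time

# ideal-instrument scenario: no noise, no autofluorescence, pure target cells
noiseless_scenario <- function(median = 2000, cv = 1, n_cells = 500,
                               n_replicates = 2) {
  scenario_config(
    name = "noiseless",
    receptor_distribution = list(family = "lognormal", median = median, cv = cv),
    n_cells = n_cells, n_replicates = n_replicates, unlabeled_n = 200,
    instrument = list(gain = 1, noise_cv = 0, autofluor_gm = 0, autofluor_cv = 0),
    populations = list(contaminant_fraction = 0, debris_fraction = 0,
                       doublet_fraction = 0),
    bead = list(n_per_level = 50, noise_cv = 0)
  )
}

wide_open_pipeline <- function(...) {
  pipeline_config(scatter_gate = scatter_gate(fsc = c(0, 1e9), ssc = c(0, 1e9)),
                  fl1_rule = "fixed", fl1_threshold = 0, ...)
}

# brute-force single-pass k-SD filter, element by element
brute_force_exclude <- function(x, k = 3) {
  m <- mean(x)
  s <- sd(x)
  kept <- c()
  for (v in x) if (abs(v - m) <= k * s) kept <- c(kept, v)
  kept
}

# closed-form OLS on (x, y) via raw sums, independent of lm()
ols_oracle <- function(x, y) {
  n <- length(x)
  sxy <- sum(x * y) - sum(x) * sum(y) / n
  sxx <- sum(x^2) - sum(x)^2 / n
  m <- sxy / sxx
  b <- mean(y) - m * mean(x)
  ss_res <- sum((y - (m * x + b))^2)
  ss_tot <- sum((y - mean(y))^2)
  list(m = m, b = b, r_squared = 1 - ss_res / ss_tot)
}

# two-sided permutation test for a difference in group means
permutation_p <- function(a, b, n_perm = 2000) {
  obs <- abs(mean(a) - mean(b))
  pooled <- c(a, b)
  na <- length(a)
  hits <- 0
  for (i in seq_len(n_perm)) {
    idx <- sample.int(length(pooled), na)
    d <- abs(mean(pooled[idx]) - mean(pooled[-idx]))
    if (d >= obs - 1e-12) hits <- hits + 1
  }
  (hits + 1) / (n_perm + 1)
}

# minimal FCS 3.0 writer (list mode, 32-bit floats, little endian) used to
# exercise the binary reader without storing binary fixtures
write_minimal_fcs <- function(path, mat, ch_names = colnames(mat)) {
  n_par <- ncol(mat)
  n_tot <- nrow(mat)
  d <- "/"
  kw <- c("$MODE", "L", "$DATATYPE", "F", "$BYTEORD", "1,2,3,4",
          "$PAR", n_par, "$TOT", n_tot)
  for (i in seq_len(n_par)) {
    kw <- c(kw, sprintf("$P%dB", i), "32", sprintf("$P%dN", i), ch_names[i])
  }
  text <- paste0(d, paste(kw, collapse = d), d)
  text_start <- 58
  text_end <- text_start + nchar(text) - 1
  data_start <- text_end + 1
  data_end <- data_start + 4 * n_par * n_tot - 1
  header <- sprintf("FCS3.0    %8d%8d%8d%8d%8d%8d",
                    text_start, text_end, data_start, data_end, 0, 0)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(header, con, eos = NULL)
  writeChar(text, con, eos = NULL)
  writeBin(as.vector(t(mat)), con, size = 4, endian = "little")
  invisible(path)
}

random_events <- function(n, seed = 1) {
  set.seed(seed)
  event_table(fsc = runif(n, 1, 1e5), ssc = runif(n, 1, 1e5),
              fl1 = rlnorm(n, 5, 1), fl2 = rlnorm(n, 6, 1),
              metadata = list(sample_id = "rand", labeled = TRUE))
}
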