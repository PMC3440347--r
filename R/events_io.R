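#' Per-event cytometry intensity table
#'
#' An `event_table` is a tibble with one row per cytometry event and linear
#' (non-log-amplified) channel intensities in arbitrary units: `fsc` (forward
#' scatter), `ssc` (side scatter), `fl1` (FITC channel, used qualitatively for
#' CD34 gating) and `fl2` (PE channel, used quantitatively). Synthetic tables
#' additionally carry ground-truth columns `true_receptors` (the receptor
#' count each event was generated from) and `population_label` (one of
#' `"target"`, `"contaminant"`, `"debris"`, `"doublet"` or `"bead_level_<k>"`).
#' Sample-level metadata (`sample_id`, `condition`, `replicate`, `labeled`)
#' travels in the `"metadata"` attribute and survives writing/reading.
#'
#' @param fsc,ssc,fl1,fl2 Numeric vectors of equal length; finite, `>= 0`.
#' @param true_receptors Optional numeric vector of ground-truth receptor
#'   counts (`NA` where undefined, e.g. debris).
#' @param population_label Optional character vector of ground-truth labels.
#' @param metadata Named list of sample-level metadata.
#' @return A tibble of class `event_table`.
#' @examples
#' event_table(fsc = c(1, 2), ssc = c(1, 2), fl1 = c(0, 5), fl2 = c(10, 20))
#' @export
event_table <- function(fsc, ssc, fl1, fl2,
                        true_receptors = NULL, population_label = NULL,
                        metadata = list()) {
  tab <- tibble::tibble(fsc = as.numeric(fsc), ssc = as.numeric(ssc),
                        fl1 = as.numeric(fl1), fl2 = as.numeric(fl2))
  if (!is.null(true_receptors)) tab$true_receptors <- as.numeric(true_receptors)
  if (!is.null(population_label)) tab$population_label <- as.character(population_label)
  attr(tab, "metadata") <- metadata
  class(tab) <- c("event_table", class(tab))
  validate_event_table(tab)
}

#' Validate an event table
#'
#' Checks the `event_table` invariants: all four channel columns present,
#' all intensities finite and non-negative.
#'
#' @param tab An `event_table` (or plain data frame with the channel columns).
#' @return `tab`, invisibly unchanged, or an error.
#' @export
validate_event_table <- function(tab) {
  required <- c("fsc", "ssc", "fl1", "fl2")
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0) {
    stop_validation("event table is missing channel column(s): ",
                    paste(missing, collapse = ", "))
  }
  for (ch in required) {
    v <- tab[[ch]]
    if (!is.numeric(v)) {
      stop_validation("channel '", ch, "' is not numeric")
    }
    if (anyNA(v) || any(!is.finite(v))) {
      stop_validation("channel '", ch, "' contains non-finite values")
    }
    if (any(v < 0)) {
      stop_validation("channel '", ch, "' contains negative intensities")
    }
  }
  tab
}

event_metadata <- function(tab) attr(tab, "metadata") %||% list()

# keep event_table class and metadata across subsetting done inside the package
subset_events <- function(tab, keep) {
  out <- tab[keep, , drop = FALSE]
  attr(out, "metadata") <- attr(tab, "metadata")
  if (!inherits(out, "event_table")) class(out) <- c("event_table", class(out))
  out
}

#' Write an event table to a delimited text file
#'
#' The canonical on-disk format is tab-separated text with a one-line column
#' header; sample metadata is stored in `#key\tvalue` comment lines before the
#' header. Channel values round-trip to at least 15 significant digits.
#'
#' @param tab An `event_table`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [read_event_table()]
#' @export
write_event_table <- function(tab, path) {
  validate_event_table(tab)
  con <- tryCatch(file(path, open = "wt"),
                  error = function(e) stop("cannot open '", path, "' for writing: ",
                                           conditionMessage(e), call. = FALSE))
  on.exit(close(con), add = TRUE)
  md <- event_metadata(tab)
  for (key in names(md)) {
    val <- md[[key]]
    if (!is.null(val) && length(val) == 1L && !is.na(val)) {
      writeLines(sprintf("#%s\t%s", key, format(val, digits = 15)), con)
    }
  }
  utils::write.table(as.data.frame(tab), con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read an event table
#'
#' Reads either the canonical tab-separated event file (see
#' [write_event_table()]) or, with `dialect = "fcs"`, a binary FCS 3.0/3.1
#' list-mode file whose channels are mapped onto `fsc`, `ssc`, `fl1`, `fl2`.
#'
#' @param path Input file path.
#' @param dialect `"tabular"` (default) or `"fcs"`.
#' @return An `event_table`; row order of the file is preserved.
#' @export
read_event_table <- function(path, dialect = c("tabular", "fcs")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (dialect == "fcs") return(read_fcs(path))
  lines <- readLines(path, warn = FALSE)
  meta_lines <- grep("^#", lines, value = TRUE)
  md <- list()
  for (ml in meta_lines) {
    parts <- strsplit(sub("^#", "", ml), "\t", fixed = TRUE)[[1]]
    if (length(parts) == 2) {
      val <- parts[2]
      num <- suppressWarnings(as.numeric(val))
      if (val %in% c("TRUE", "FALSE")) val <- as.logical(val)
      else if (!is.na(num)) val <- num
      md[[parts[1]]] <- val
    }
  }
  body <- lines[!grepl("^#", lines)]
  if (length(body) == 0) stop("file '", path, "' has no header line", call. = FALSE)
  df <- utils::read.table(text = body, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  required <- c("fsc", "ssc", "fl1", "fl2")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("event file is missing channel column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  event_table(df$fsc, df$ssc, df$fl1, df$fl2,
              true_receptors = df[["true_receptors"]],
              population_label = df[["population_label"]],
              metadata = md)
}

#' PE-bead standard levels
#'
#' The set of known PE molecules per bead for the calibration standard. The
#' default is the four-level Quantibrite-type standard: low 515, medium-low
#' 5,956, medium-high 26,653 and high 69,045 PE molecules/bead.
#'
#' @param levels Strictly increasing positive numeric vector, length >= 2
#'   (the log-log regression needs at least two points).
#' @return Numeric vector of class `bead_level_set`.
#' @export
bead_level_set <- function(levels = c(515, 5956, 26653, 69045)) {
  levels <- as.numeric(levels)
  if (length(levels) < 2) {
    stop_validation("bead level set needs at least 2 levels")
  }
  if (any(!is.finite(levels)) || any(levels <= 0)) {
    stop_validation("bead levels must be positive and finite")
  }
  if (any(diff(levels) <= 0)) {
    stop_validation("bead levels must be strictly increasing")
  }
  structure(levels, class = "bead_level_set")
}
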