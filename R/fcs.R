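#' Read an FCS 3.0/3.1 list-mode file into an event table
#'
#' Minimal read-only adapter for binary FCS 3.0/3.1 files: parses the TEXT
#' segment, reads the DATA segment for `$DATATYPE` F (float), D (double) or I
#' (unsigned integer, 8/16/32/64-bit) in list mode, and maps channel short
#' names (`$PnN`) onto the four canonical channels. The default mapping
#' recognises names containing `FSC`, `SSC`, `FL1`/`FITC` and `FL2`/`PE`
#' (height variants such as `FSC-H` included). Compensation, analysis
#' segments and multiple data sets are out of scope.
#'
#' @param path Path to an FCS file.
#' @param channel_map Optional named character vector mapping canonical names
#'   (`fsc`, `ssc`, `fl1`, `fl2`) to exact `$PnN` channel names.
#' @return An `event_table`; acquisition order is preserved.
#' @export
read_fcs <- function(path, channel_map = NULL) {
  con <- file(path, open = "rb")
  on.exit(close(con), add = TRUE)

  header <- readChar(con, 58, useBytes = TRUE)
  version <- trimws(substr(header, 1, 6))
  if (!version %in% c("FCS3.0", "FCS3.1")) {
    stop("unsupported FCS version: '", version, "'", call. = FALSE)
  }
  off <- function(i) {
    as.numeric(trimws(substr(header, 11 + (i - 1) * 8, 18 + (i - 1) * 8)))
  }
  text_start <- off(1); text_end <- off(2)
  data_start <- off(3); data_end <- off(4)

  seek(con, text_start)
  raw_text <- readChar(con, text_end - text_start + 1, useBytes = TRUE)
  delim <- substr(raw_text, 1, 1)
  parts <- strsplit(substring(raw_text, 2), delim, fixed = TRUE)[[1]]
  if (length(parts) %% 2 == 1) parts <- parts[-length(parts)]
  keys <- toupper(trimws(parts[seq(1, length(parts), by = 2)]))
  vals <- trimws(parts[seq(2, length(parts), by = 2)])
  kw <- stats::setNames(as.list(vals), keys)

  if (!is.null(kw$`$MODE`) && toupper(kw$`$MODE`) != "L") {
    stop("only list-mode ($MODE L) FCS data is supported", call. = FALSE)
  }
  n_par <- as.integer(kw$`$PAR`)
  n_tot <- as.integer(kw$`$TOT`)
  dtype <- toupper(kw$`$DATATYPE`)
  byte_ord <- kw$`$BYTEORD` %||% "1,2,3,4"
  endian <- if (startsWith(byte_ord, "1")) "little" else "big"
  if (data_start == 0 && !is.null(kw$`$BEGINDATA`)) {
    data_start <- as.numeric(kw$`$BEGINDATA`)
    data_end <- as.numeric(kw$`$ENDDATA`)
  }

  bits <- vapply(seq_len(n_par),
                 function(i) as.integer(kw[[sprintf("$P%dB", i)]]), integer(1))
  ch_names <- vapply(seq_len(n_par),
                     function(i) kw[[sprintf("$P%dN", i)]] %||% sprintf("P%d", i),
                     character(1))

  seek(con, data_start)
  n_values <- n_par * n_tot
  if (dtype == "F") {
    if (any(bits != 32)) stop("$DATATYPE F requires 32-bit parameters", call. = FALSE)
    values <- readBin(con, "double", n = n_values, size = 4, endian = endian)
  } else if (dtype == "D") {
    values <- readBin(con, "double", n = n_values, size = 8, endian = endian)
  } else if (dtype == "I") {
    if (length(unique(bits)) != 1) {
      stop("mixed $PnB widths for integer data are not supported", call. = FALSE)
    }
    size <- bits[1] / 8
    if (!size %in% c(1, 2, 4, 8)) stop("unsupported $PnB: ", bits[1], call. = FALSE)
    values <- readBin(con, "integer", n = n_values, size = size,
                      signed = FALSE, endian = endian)
  } else {
    stop("unsupported $DATATYPE: ", dtype, call. = FALSE)
  }
  if (length(values) < n_values) stop("truncated FCS data segment", call. = FALSE)
  mat <- matrix(values, nrow = n_tot, ncol = n_par, byrow = TRUE)
  colnames(mat) <- ch_names

  map <- channel_map %||% guess_channel_map(ch_names)
  missing <- setdiff(c("fsc", "ssc", "fl1", "fl2"), names(map))
  if (length(missing) > 0) {
    stop("cannot map FCS channels (", paste(ch_names, collapse = ", "),
         ") onto: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  event_table(fsc = mat[, map[["fsc"]]], ssc = mat[, map[["ssc"]]],
              fl1 = mat[, map[["fl1"]]], fl2 = mat[, map[["fl2"]]],
              metadata = list(source = basename(path), fcs_version = version))
}

guess_channel_map <- function(ch_names) {
  up <- toupper(ch_names)
  pick <- function(patterns) {
    for (p in patterns) {
      hit <- grep(p, up)
      if (length(hit) > 0) return(ch_names[hit[1]])
    }
    NULL
  }
  map <- list(fsc = pick(c("^FSC", "FORWARD")),
              ssc = pick(c("^SSC", "SIDE")),
              fl1 = pick(c("^FL1", "FITC")),
              fl2 = pick(c("^FL2", "\\bPE\\b", "^PE")))
  unlist(map[!vapply(map, is.null, logical(1))])
}
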