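`%||%` <- function(x, y) if (is.null(x)) y else x

stop_validation <- function(..., call. = FALSE) {
  stop(..., call. = call.)
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

# report-layer rounding: receptor means to the nearest 100, compartment
# totals to the nearest 1000, recycled pools to the nearest 100
round_to <- function(x, nearest) {
  round(x / nearest) * nearest
}
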