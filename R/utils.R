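# Internal helpers: classed error conditions and small assertions.

abort_sl <- function(msg, class, call. = FALSE) {
  stop(structure(
    class = c(class, "spectroleaf_error", "error", "condition"),
    list(message = msg, call = NULL)
  ))
}

# error classes used across the package:
#   sl_io_error         missing/mis-sized files, unwritable paths
#   sl_format_error     malformed headers / tables
#   sl_parameter_error  bad user-supplied knobs (even window, h too large...)
#   sl_precondition     violated operation preconditions (empty mask, n<3...)
#   sl_degenerate       degenerate numeric input (flat spectrum, var(y)=0)
#   sl_contract_error   mismatched shapes/wavelengths between arguments
#   sl_numeric_error    numerically singular systems

is_count <- function(x, min = 1L) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x >= min && x == as.integer(x)
}

is_number <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# nearest grid index for a target wavelength (1-based)
nearest_band <- function(wavelengths_nm, target_nm) {
  which.min(abs(wavelengths_nm - target_nm))
}

# indices of local maxima of a non-negative curve; plateau members and edge
# bands count when they are >= every existing neighbour
local_maxima <- function(s) {
  n <- length(s)
  if (n == 1L) return(1L)
  left <- c(TRUE, s[-1L] >= s[-n])
  right <- c(s[-n] >= s[-1L], TRUE)
  which(left & right)
}
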