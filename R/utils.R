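#' Round half away from zero
#'
#' Printed prevalence tables round halves up (77.25 -> 77.3), whereas base R's
#' `round()` rounds to even. Used only at the reporting layer; intermediate
#' computation keeps full precision.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# percentage of k out of n, reported to one decimal (half-up)
pct <- function(k, n, digits = 1) {
  if (n == 0) return(0)
  round_half_up(100 * k / n, digits)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ <- function(...) stop(..., call. = FALSE)

assert_cols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop_(what, " is missing required column(s): ",
          paste(missing, collapse = ", "))
  }
  invisible(df)
}
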