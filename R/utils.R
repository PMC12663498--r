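#' Round half away from zero
#'
#' Rounding used for report tables: exact halves round away from zero
#' (`round_half_up(0.5) == 1`, `round_half_up(-0.5) == -1`), unlike base R's
#' round-half-to-even.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5) / s
}

#' @keywords internal
#' @noRd
as_pct <- function(p) round_half_up(100 * p)

# reverse cumulative sum: out[i] = sum(x[i:n])
revcumsum <- function(x) {
  if (length(x) == 0L) return(numeric(0))
  rev(cumsum(rev(x)))
}

stop_named <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
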