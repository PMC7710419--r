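#' Frequency band definitions
#'
#' Conventional clinical band edges consistent with a 1-45 Hz analysis
#' band: delta 1-4, theta 4-8, alpha 8-13, beta 13-30, low gamma 30-45 Hz.
#' Bands are half-open `[low, high)`, non-overlapping, and partition the
#' 1-45 Hz range.
#'
#' @param name Band name; one of `"delta"`, `"theta"`, `"alpha"`, `"beta"`,
#'   `"low_gamma"`.
#' @param low,high Band edges in Hz for a custom band.
#' @return `band_definition(...)`: a list with `name`, `low`, `high` of class
#'   `band_definition`. `default_bands()`: named list of the five defaults.
#' @export
band_definition <- function(name, low, high) {
  if (!(is.numeric(low) && is.numeric(high) && low > 0 && high > low)) {
    stop("band edges must satisfy 0 < low < high")
  }
  structure(list(name = name, low = low, high = high),
            class = "band_definition")
}

#' @rdname band_definition
#' @export
default_bands <- function() {
  list(
    delta     = band_definition("delta", 1, 4),
    theta     = band_definition("theta", 4, 8),
    alpha     = band_definition("alpha", 8, 13),
    beta      = band_definition("beta", 13, 30),
    low_gamma = band_definition("low_gamma", 30, 45)
  )
}

check_bands <- function(bands) {
  lows <- vapply(bands, `[[`, numeric(1), "low")
  highs <- vapply(bands, `[[`, numeric(1), "high")
  o <- order(lows)
  if (any(highs[o][-length(bands)] > lows[o][-1] + 1e-9)) {
    stop("bands must be non-overlapping")
  }
  invisible(bands)
}
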