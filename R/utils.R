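#' Round half away from zero
#'
#' Commercial rounding at a fixed number of decimals. Base \code{round()}
#' rounds half to even ("banker's rounding"); the percentage tables produced
#' by this package instead round halves away from zero, so that e.g.
#' \code{roundHalfAway(0.25, 1) == 0.3}.
#'
#' @param x numeric vector.
#' @param digits number of decimal places (default 1).
#' @return numeric vector, rounded.
#' @export
#' @examples
#' roundHalfAway(c(0.25, -0.25, 2.349), 1)
roundHalfAway <- function(x, digits = 1L) {
  m <- 10^digits
  # add a one-ulp nudge so values that are exact halves in decimal but sit
  # just below .5 in binary (e.g. 100*161/374) still round up
  sign(x) * floor(abs(x) * m + 0.5 + 1e-9) / m
}

#' Zone percentage with the package's rounding convention
#'
#' The percentage printed in every zone distribution table:
#' \code{100 * count / size}, rounded half away from zero to one decimal.
#' Returns \code{NA} where \code{size} is zero.
#'
#' @param count number of annotated nodes in the zone.
#' @param size zone size (number of nodes in the zone).
#' @return numeric vector of percentages on the 0--100 scale.
#' @export
#' @examples
#' zonePercent(161, 374)   # 43.0
#' zonePercent(1002, 4610) # 21.7
zonePercent <- function(count, size) {
  out <- rep(NA_real_, length(count))
  ok <- size > 0
  out[ok] <- roundHalfAway(100 * count[ok] / size[ok], 1L)
  out
}

# internal: consistent progress/cleaning messages
.logmsg <- function(...) message("[PINzones] ", ...)
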