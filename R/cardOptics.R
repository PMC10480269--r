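#' Reflectance of the card at a position
#'
#' Piecewise-constant 1D reflectance field along the travel axis:
#' `reflectanceBlack` inside any dark bar, `reflectanceWhite` elsewhere on
#' the card, and 0 beyond the card edges. Positions are mm from the card
#' midpoint.
#'
#' @param card a \linkS4class{StripedCard}
#' @param position numeric vector of positions, mm
#' @return reflectance fraction(s) in `[0, 1]`
#' @export
reflectanceProfile <- function(card, position) {
  stopifnot(is(card, "StripedCard"))
  r <- ifelse(abs(position) <= card@cardExtent / 2,
              card@reflectanceWhite, 0)
  for (ctr in barCenters(card)) {
    inBar <- abs(position - ctr) <= card@barWidth / 2 &
      abs(position) <= card@cardExtent / 2
    r[inBar] <- card@reflectanceBlack
  }
  r
}

# breakpoints of the piecewise-constant field (mm), sorted
fieldBreaks <- function(card) {
  ctr <- barCenters(card)
  sort(unique(c(-card@cardExtent / 2, card@cardExtent / 2,
                ctr - card@barWidth / 2, ctr + card@barWidth / 2)))
}

# Fraction of the spot kernel lying left of u (mm from spot centre).
# tophat disc: chord-weighted CDF; gaussian: diameter read as FWHM.
spotKernelCdf <- function(u, spot) {
  if (spot@profile == "tophat") {
    r <- spot@diameter / 2
    u <- pmin(pmax(u, -r), r)
    (u * sqrt(pmax(r^2 - u^2, 0)) + r^2 * asin(u / r)) / (pi * r^2) + 0.5
  } else {
    sigma <- spot@diameter / (2 * sqrt(2 * log(2)))
    stats::pnorm(u, mean = 0, sd = sigma)
  }
}

#' Reflected fraction of the laser spot
#'
#' Kernel-weighted average of the card reflectance over the spot footprint.
#' The circular spot reduces to a 1D kernel along the travel axis (chord
#' weighted for the uniform disc; the stripes span the card width, so the
#' transverse dimension integrates out). The spot centre sits at
#' `geometryFactor * displacement` (displacement in cm, converted to mm).
#' Off-card parts of the footprint contribute zero, so the result is bounded
#' by `reflectanceBlack * (on-card fraction)` and `reflectanceWhite` and is
#' continuous in displacement.
#'
#' @param card a \linkS4class{StripedCard}
#' @param spot a \linkS4class{LaserSpot}
#' @param displacement platform displacement(s), cm
#' @return reflected fraction(s) in `[0, 1]`
#' @examples
#' # spot fully on white card
#' reflectedFraction(StripedCard(barCenterOffset = -20), LaserSpot(), 0)
#' @export
reflectedFraction <- function(card, spot, displacement) {
  stopifnot(is(card, "StripedCard"), is(spot, "LaserSpot"))
  if (any(!is.finite(displacement)))
    stop("displacement must be finite")
  brk <- fieldBreaks(card)
  # reflectance of each interval (-Inf,b1], [b1,b2], ..., [bk,Inf)
  mids <- c(brk[1] - 1, (brk[-1] + brk[-length(brk)]) / 2,
            brk[length(brk)] + 1)
  vals <- reflectanceProfile(card, mids)
  vapply(displacement, function(d) {
    x0 <- 10 * spot@geometryFactor * d
    w <- diff(c(0, spotKernelCdf(brk - x0, spot), 1))
    sum(w * vals)
  }, numeric(1))
}

#' Default card placement for a motion
#'
#' Builds the striped card the simulator uses for a given motion: a single
#' dark bar centred at the lower turning point of the spot travel
#' (`-geometryFactor * displacement / 2`, in mm). The spot then dwells on the
#' bar once per cycle, near zero velocity, producing one smooth reflectance
#' dip per period whose DFT fundamental is the platform frequency `f`. (A bar
#' at mid-travel is crossed twice per cycle at even spacing and would alias
#' the fundamental to `2f`; a bar between mid-travel and the turning point
#' yields two narrow dips per cycle whose harmonics can dominate the
#' fundamental.)
#'
#' @param spec a \linkS4class{MotionSpec}
#' @param spot a \linkS4class{LaserSpot} (for `geometryFactor`)
#' @param ... further arguments passed to [StripedCard()]
#' @return a \linkS4class{StripedCard}
#' @export
defaultCardFor <- function(spec, spot = LaserSpot(), ...) {
  travel <- 10 * spot@geometryFactor * spec@displacement  # mm, peak-to-peak
  StripedCard(barCenterOffset = -travel / 2, ...)
}
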