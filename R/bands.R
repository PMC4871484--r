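#' Spectral band of a photocycle state
#'
#' A chromophore absorption band parameterized as a (possibly skewed) Gaussian
#' in wavelength: a band center, a full width at half maximum, and a peak molar
#' extinction coefficient. The skew parameter makes the red and blue half-widths
#' unequal, which is the simplest account of the asymmetry of retinal-protein
#' absorption bands.
#'
#' @param center band maximum in nm; must be positive.
#' @param width full width at half maximum in nm; must be positive.
#' @param peak_extinction molar extinction coefficient at the band maximum,
#'   in M^-1 cm^-1; must be non-negative.
#' @param skew dimensionless asymmetry in (-1, 1); the half-width on the red
#'   side is scaled by (1 + skew) and on the blue side by (1 - skew). Default 0
#'   (symmetric Gaussian).
#' @return an object of class `spectral_band`.
#' @examples
#' gs <- spectral_band(524, 100, 50000)
#' extinction_at(gs, c(480, 524, 560))
#' @export
spectral_band <- function(center, width, peak_extinction, skew = 0) {
  stopifnot(is.numeric(center), length(center) == 1L,
            is.numeric(width), length(width) == 1L,
            is.numeric(peak_extinction), length(peak_extinction) == 1L,
            is.numeric(skew), length(skew) == 1L)
  if (center <= 0) stop("band center must be > 0 nm")
  if (width <= 0) stop("band width (FWHM) must be > 0 nm")
  if (peak_extinction < 0) stop("peak extinction must be >= 0")
  if (abs(skew) >= 1) stop("skew must lie in (-1, 1)")
  structure(list(center = center, width = width,
                 peak_extinction = peak_extinction, skew = skew),
            class = "spectral_band")
}

#' Evaluate a spectral band
#'
#' @param band a [spectral_band()].
#' @param wavelengths numeric vector of wavelengths in nm.
#' @return molar extinction (M^-1 cm^-1) at each wavelength.
#' @export
extinction_at <- function(band, wavelengths) {
  stopifnot(inherits(band, "spectral_band"), is.numeric(wavelengths))
  d <- wavelengths - band$center
  w <- ifelse(d >= 0, band$width * (1 + band$skew), band$width * (1 - band$skew))
  band$peak_extinction * exp(-4 * log(2) * (d / w)^2)
}

#' @export
print.spectral_band <- function(x, ...) {
  cat(sprintf("spectral band: center %.1f nm, FWHM %.1f nm, peak %.0f M^-1 cm^-1, skew %.2f\n",
              x$center, x$width, x$peak_extinction, x$skew))
  invisible(x)
}
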