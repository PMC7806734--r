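#' LED emission spectrum from peak wavelength(s) and FWHM
#'
#' Models each emission band as a Gaussian with `sigma = FWHM / 2.355`
#' (2*sqrt(2*log 2)), evaluated on a 1-nm grid over 300-800 nm and normalized
#' to unit integral. Single-band LEDs take one component; a
#' phosphor-converted white LED takes two (a blue diode band plus a broad
#' phosphor band) with relative power weights summing to 1. The maze's four
#' sources are red 628/17 nm, green 517/31 nm, blue 452/22 nm and white
#' 441/19 + 533/104 nm (peak/FWHM); the white band weights are not part of
#' the published characterization, so the blue-diode fraction defaults to 0.3
#' and is configurable.
#'
#' @param peak_nm Numeric vector (1 or 2) of peak wavelengths in nm, within
#'   300-800.
#' @param fwhm_nm Full widths at half maximum in nm (> 0), same length.
#' @param weights Relative power fractions (same length, summing to 1).
#' @param step_nm Grid resolution in nm (default 1).
#' @return Object of class `led_spectrum`: `lambda` (nm grid), `power`
#'   (relative spectral power, unit trapezoid integral), `peak_nm`,
#'   `fwhm_nm`, `weights`.
#' @examples
#' red <- led_spectrum(628, 17)
#' @export
led_spectrum <- function(peak_nm, fwhm_nm, weights = NULL, step_nm = 1) {
  stopifnot(length(peak_nm) %in% 1:2, length(fwhm_nm) == length(peak_nm),
            all(peak_nm >= 300), all(peak_nm <= 800), all(fwhm_nm > 0))
  if (is.null(weights)) weights <- rep(1 / length(peak_nm), length(peak_nm))
  stopifnot(length(weights) == length(peak_nm), all(weights > 0))
  if (abs(sum(weights) - 1) > 1e-9) stop("component weights must sum to 1")
  lambda <- seq(300, 800, by = step_nm)
  sigma <- fwhm_nm / (2 * sqrt(2 * log(2)))
  power <- rep(0, length(lambda))
  for (i in seq_along(peak_nm)) {
    power <- power + weights[i] * stats::dnorm(lambda, peak_nm[i], sigma[i])
  }
  power <- power / trapz(lambda, power)
  structure(
    list(lambda = lambda, power = power, peak_nm = peak_nm,
         fwhm_nm = fwhm_nm, weights = weights),
    class = "led_spectrum"
  )
}

#' Idealized monochromatic spectrum
#'
#' A single-wavelength source, represented exactly (conversions use the
#' closed forms at `lambda_nm` rather than a narrow numerical band). Useful
#' for checking the conversions against definitions, e.g. 683 lux of 555-nm
#' light is 1 W/m2 by the definition of the candela.
#'
#' @param lambda_nm Wavelength in nm.
#' @return Object of classes `mono_spectrum` and `led_spectrum`.
#' @export
monochromatic_spectrum <- function(lambda_nm) {
  stopifnot(length(lambda_nm) == 1L, lambda_nm >= 300, lambda_nm <= 800)
  structure(
    list(lambda = lambda_nm, power = NULL, peak_nm = lambda_nm,
         fwhm_nm = 0, weights = 1),
    class = c("mono_spectrum", "led_spectrum")
  )
}

#' The four maze LED spectra
#'
#' @param white_blue_weight Power fraction of the white LED's blue-diode band
#'   (default 0.3; the phosphor band carries the rest).
#' @return Named list of `led_spectrum` objects for arms `B`, `G`, `R`, `W`.
#' @export
vis4m_led_set <- function(white_blue_weight = 0.3) {
  stopifnot(white_blue_weight > 0, white_blue_weight < 1)
  list(
    B = led_spectrum(452, 22),
    G = led_spectrum(517, 31),
    R = led_spectrum(628, 17),
    W = led_spectrum(c(441, 533), c(19, 104),
                     weights = c(white_blue_weight, 1 - white_blue_weight))
  )
}

is_monochromatic <- function(spectrum) inherits(spectrum, "mono_spectrum")
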