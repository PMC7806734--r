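# CIE 1924 photopic luminous-efficiency function V(lambda), 380-780 nm at
# 5-nm steps (standard published values, peak 1.0000 at 555 nm). The working
# 1-nm grid is obtained by natural-spline interpolation; V is taken as zero
# outside the tabulated range.
.cie_v_nm <- seq(380, 780, by = 5)
.cie_v_val <- c(
  0.0000390, 0.0000640, 0.0001200, 0.0002170, 0.0003960, 0.0006400,
  0.0012100, 0.0021800, 0.0040000, 0.0073000, 0.0116000, 0.0168400,
  0.0230000, 0.0298000, 0.0380000, 0.0480000, 0.0600000, 0.0739000,
  0.0909800, 0.1126000, 0.1390200, 0.1693000, 0.2080200, 0.2586000,
  0.3230000, 0.4073000, 0.5030000, 0.6082000, 0.7100000, 0.7932000,
  0.8620000, 0.9148500, 0.9540000, 0.9803000, 0.9949500, 1.0000000,
  0.9950000, 0.9786000, 0.9520000, 0.9154000, 0.8700000, 0.8163000,
  0.7570000, 0.6949000, 0.6310000, 0.5668000, 0.5030000, 0.4412000,
  0.3810000, 0.3210000, 0.2650000, 0.2170000, 0.1750000, 0.1382000,
  0.1070000, 0.0816000, 0.0610000, 0.0445800, 0.0320000, 0.0232000,
  0.0170000, 0.0119200, 0.0082100, 0.0057200, 0.0041000, 0.0029300,
  0.0020900, 0.0014800, 0.0010500, 0.0007400, 0.0005200, 0.0003600,
  0.0002500, 0.0001700, 0.0001200, 0.0000850, 0.0000600, 0.0000400,
  0.0000300, 0.0000200, 0.0000150
)

#' CIE photopic luminous-efficiency function V(lambda)
#'
#' Standard 1924 2-degree photopic curve, peak-normalized to 1 at 555 nm,
#' used to convert between photometric (lux) and radiometric (W) quantities.
#' Interpolated from the embedded 5-nm table; zero outside 380-780 nm.
#'
#' @param lambda_nm Wavelength(s) in nm.
#' @return V values in `[0, 1]`.
#' @examples
#' cie_photopic_luminosity(555)  # 1
#' @export
cie_photopic_luminosity <- function(lambda_nm) {
  v <- stats::spline(.cie_v_nm, .cie_v_val, xout = lambda_nm,
                     method = "natural")$y
  v[lambda_nm < 380 | lambda_nm > 780] <- 0
  pmin(pmax(v, 0), 1)
}

#' Mouse lens spectral transmission (synthetic logistic model)
#'
#' The mouse lens, unlike the adult human lens, transmits a substantial
#' fraction of near-UV light, which is what allows the 360-nm S-opsin to be
#' driven by environmental light. No tabulated transmission curve ships with
#' this package; instead a documented logistic model is used: transmission
#' rises sigmoidally with wavelength, with half-transmission at
#' `lambda50_nm` (default 340 nm) and slope `scale_nm` (default 15 nm),
#' saturating at 1 for long wavelengths. This synthetic stand-in preserves
#' the qualitative shape (high visible transmission, partial UV
#' transmission) and can be disabled (`model = "none"` returns 1
#' everywhere).
#'
#' @param lambda_nm Wavelength(s) in nm.
#' @param model `"logistic"` (default) or `"none"`.
#' @param lambda50_nm,scale_nm Logistic location and scale in nm.
#' @return Transmission values in `[0, 1]`.
#' @export
mouse_lens_transmission <- function(lambda_nm, model = c("logistic", "none"),
                                    lambda50_nm = 340, scale_nm = 15) {
  model <- match.arg(model)
  if (model == "none") return(rep(1, length(lambda_nm)))
  stats::plogis((lambda_nm - lambda50_nm) / scale_nm)
}
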