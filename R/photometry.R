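# Planck constant [J s] and speed of light [m/s]
.h_planck <- 6.62607015e-34
.c_light <- 2.99792458e8
.km_lm_per_w <- 683   # maximum luminous efficacy at 555 nm

#' Exposure-value conversions of the incident-light meter
#'
#' The arm intensities are measured with an incident light meter in
#' exposure-value mode at ISO 100 and converted with `lux = 2.5 * 2^EV` and
#' `cd/m2 = 2^(EV - 3)`; the two formulas imply a fixed illuminance/luminance
#' ratio of 20 for this meter setup. Inverses are provided for configs that
#' specify lux or cd/m2 directly.
#'
#' @param ev Exposure value(s) at ISO 100.
#' @param lux Illuminance(s) in lux (> 0 for the inverse).
#' @param cd_m2 Luminance(s) in cd/m2 (> 0 for the inverse).
#' @return Numeric vector: lux, EV or cd/m2 respectively.
#' @examples
#' ev_to_illuminance(0)   # 2.5 lux
#' ev_to_luminance(3)     # 1 cd/m2
#' @name ev_conversions
NULL

#' @rdname ev_conversions
#' @export
ev_to_illuminance <- function(ev) 2.5 * 2^ev

#' @rdname ev_conversions
#' @export
illuminance_to_ev <- function(lux) {
  stopifnot(all(lux > 0))
  log2(lux / 2.5)
}

#' @rdname ev_conversions
#' @export
ev_to_luminance <- function(ev) 2^(ev - 3)

#' @rdname ev_conversions
#' @export
luminance_to_ev <- function(cd_m2) {
  stopifnot(all(cd_m2 > 0))
  log2(cd_m2) + 3
}

spectrum_photopic_overlap <- function(spectrum) {
  if (is_monochromatic(spectrum)) {
    cie_photopic_luminosity(spectrum$lambda)
  } else {
    trapz(spectrum$lambda,
          spectrum$power * cie_photopic_luminosity(spectrum$lambda))
  }
}

#' Convert illuminance to irradiance for a given source spectrum
#'
#' Illuminance weights power by the human photopic luminous-efficiency
#' function V(lambda); recovering the radiometric power therefore requires
#' the source's relative spectral power distribution S (unit integral):
#' `E_e [W/m2] = lux / (683 * integral(S * V))`, reported in uW/cm2
#' (1 W/m2 = 100 uW/cm2). For a monochromatic source the integral collapses
#' to `V(lambda)`, so 683 lux at 555 nm is exactly 100 uW/cm2 (definition of
#' the candela).
#'
#' @param lux Illuminance in lux (>= 0).
#' @param spectrum An [led_spectrum()] or [monochromatic_spectrum()].
#' @return Irradiance in uW/cm2.
#' @export
illuminance_to_irradiance <- function(lux, spectrum) {
  stopifnot(all(lux >= 0), inherits(spectrum, "led_spectrum"))
  overlap <- spectrum_photopic_overlap(spectrum)
  if (overlap <= 0) stop("non-visible spectrum: zero photopic overlap")
  (lux / (.km_lm_per_w * overlap)) * 100
}

#' Convert irradiance to log10 photon flux
#'
#' Spectral photon flux is spectral power divided by the photon energy
#' `h * c / lambda`; the total is `integral(E_e * S(lambda) * lambda / (h c))`
#' with S the unit-integral relative spectral power distribution, returned as
#' log10 photons/cm2/s.
#'
#' @param irradiance_uw_cm2 Irradiance in uW/cm2 (> 0).
#' @param spectrum An [led_spectrum()] or [monochromatic_spectrum()].
#' @return log10 photons/cm2/s.
#' @examples
#' irradiance_to_log_photon_flux(1, monochromatic_spectrum(500))  # ~12.40
#' @export
irradiance_to_log_photon_flux <- function(irradiance_uw_cm2, spectrum) {
  if (!all(irradiance_uw_cm2 > 0)) stop("irradiance must be positive")
  stopifnot(inherits(spectrum, "led_spectrum"))
  e_w_cm2 <- irradiance_uw_cm2 * 1e-6
  if (is_monochromatic(spectrum)) {
    flux <- e_w_cm2 * (spectrum$lambda * 1e-9) / (.h_planck * .c_light)
  } else {
    per_nm <- spectrum$power * (spectrum$lambda * 1e-9) /
      (.h_planck * .c_light)
    flux <- e_w_cm2 * trapz(spectrum$lambda, per_nm)
  }
  log10(flux)
}

#' Visual-pigment spectral-sensitivity template
#'
#' A1-chromophore visual-pigment absorbance template (alpha band plus the
#' short-wavelength beta band) parameterized solely by the wavelength of peak
#' sensitivity, following the widely used rhodopsin-template
#' parameterization; the curve is numerically peak-normalized to 1. Mouse
#' photopigments: S-opsin 360 nm, M-opsin 508 nm, rod 498 nm, melanopsin
#' 480 nm (see [mouse_opsins()]).
#'
#' @param lambda_max_nm Peak wavelength in nm, within 330-600.
#' @param name Optional pigment name carried in the result.
#' @return Object of class `opsin_template`: `name`, `lambda_max_nm`, and
#'   `sensitivity(lambda_nm)`, a function returning values in `[0, 1]`.
#' @examples
#' s <- pigment_sensitivity(360, "S-opsin")
#' s$sensitivity(360)   # 1
#' @export
pigment_sensitivity <- function(lambda_max_nm, name = NULL) {
  if (lambda_max_nm < 330 || lambda_max_nm > 600) {
    stop("lambda_max_nm outside template validity range [330, 600]")
  }
  lm <- lambda_max_nm
  raw <- function(lambda_nm) {
    x <- lm / lambda_nm
    a <- 0.8795 + 0.0459 * exp(-(lm - 300)^2 / 11940)
    alpha <- 1 / (exp(69.7 * (a - x)) + exp(28 * (0.922 - x)) +
                    exp(-14.9 * (1.104 - x)) + 0.674)
    lmb <- 189 + 0.315 * lm
    bb <- -40.5 + 0.195 * lm
    beta <- 0.26 * exp(-((lambda_nm - lmb) / bb)^2)
    alpha + beta
  }
  peak <- raw(lm)   # normalize at lambda_max; beta band can nudge the true
                    # maximum a fraction of a percent above, capped below
  structure(
    list(name = name %||% sprintf("pigment_%gnm", lm), lambda_max_nm = lm,
         sensitivity = function(lambda_nm) pmin(raw(lambda_nm) / peak, 1)),
    class = "opsin_template"
  )
}

#' The four mouse photopigment templates
#'
#' @return Named list of [pigment_sensitivity()] templates: `S` (360 nm),
#'   `M` (508 nm), `rod` (498 nm), `melanopsin` (480 nm).
#' @export
mouse_opsins <- function() {
  list(
    S = pigment_sensitivity(360, "S-opsin"),
    M = pigment_sensitivity(508, "M-opsin"),
    rod = pigment_sensitivity(498, "rod"),
    melanopsin = pigment_sensitivity(480, "melanopsin")
  )
}

#' Opsin-effective log10 photon flux of a stimulus
#'
#' Weights the spectral photon flux of the stimulus by the pigment's spectral
#' sensitivity and (optionally) the mouse lens transmission before
#' integrating: the result summarizes how strongly the stimulus drives a
#' given photopigment, in log10 effective photons/cm2/s. It is always less
#' than or equal to the total photon flux, since both weights are at most 1.
#'
#' @param spectrum An [led_spectrum()] or [monochromatic_spectrum()].
#' @param irradiance_uw_cm2 Irradiance in uW/cm2 (> 0).
#' @param opsin An `opsin_template` from [pigment_sensitivity()].
#' @param lens_correction Apply [mouse_lens_transmission()] (default TRUE).
#' @return log10 effective photons/cm2/s; `-Inf` with a warning when the
#'   spectrum and pigment do not overlap at all.
#' @export
effective_log_photon_flux <- function(spectrum, irradiance_uw_cm2, opsin,
                                      lens_correction = TRUE) {
  if (!all(irradiance_uw_cm2 > 0)) stop("irradiance must be positive")
  stopifnot(inherits(spectrum, "led_spectrum"),
            inherits(opsin, "opsin_template"))
  lens <- function(l) {
    if (lens_correction) mouse_lens_transmission(l) else rep(1, length(l))
  }
  e_w_cm2 <- irradiance_uw_cm2 * 1e-6
  if (is_monochromatic(spectrum)) {
    l <- spectrum$lambda
    flux <- e_w_cm2 * (l * 1e-9) / (.h_planck * .c_light) *
      opsin$sensitivity(l) * lens(l)
  } else {
    l <- spectrum$lambda
    per_nm <- spectrum$power * (l * 1e-9) / (.h_planck * .c_light) *
      opsin$sensitivity(l) * lens(l)
    flux <- e_w_cm2 * trapz(l, per_nm)
  }
  if (flux <= 0) {
    warning("zero spectral overlap between stimulus and pigment")
    return(-Inf)
  }
  log10(flux)
}

#' Classify a luminance into rod/cone operating regimes
#'
#' Mesopic and photopic vision occur in the luminance ranges 0.001-3 cd/m2
#' and above 10 cd/m2 respectively; below 0.001 cd/m2 is scotopic, and the
#' unnamed overlap (3, 10] cd/m2 is labelled `"transition"`. The mesopic
#' interval is closed at 3.
#'
#' @param luminance_cd_m2 Luminance(s) in cd/m2 (>= 0).
#' @return Character vector over
#'   `{"scotopic", "mesopic", "transition", "photopic"}`.
#' @export
classify_light_regime <- function(luminance_cd_m2) {
  if (any(luminance_cd_m2 < 0)) stop("luminance must be non-negative")
  cut_lab <- function(l) {
    if (l < 0.001) "scotopic"
    else if (l <= 3) "mesopic"
    else if (l <= 10) "transition"
    else "photopic"
  }
  vapply(luminance_cd_m2, cut_lab, character(1))
}

#' Luminance ratio of an object against its background
#'
#' In contrast mode the stimulus strength of each grayscale object is
#' summarized by its luminance ratio against the black maze walls (e.g. the
#' measured ratios 1.06 black, 6.00 grey, 6.56 clear, 9.69 white).
#'
#' @param object_luminance,background_luminance Luminances in the same units;
#'   background must be positive.
#' @return `object_luminance / background_luminance`.
#' @export
luminance_ratio <- function(object_luminance, background_luminance) {
  if (any(background_luminance <= 0)) stop("background luminance must be positive")
  object_luminance / background_luminance
}

#' Fully characterized per-arm light condition
#'
#' Derives the complete photometric and radiometric description of one
#' illumination condition from per-arm exposure values or illuminances plus
#' the arm LED spectra: EV, lux, cd/m2, irradiance, log10 photon flux,
#' per-opsin effective log10 flux, and the luminance regime. Unlit arms (0
#' lux, as in the no-color condition) report `-Inf` fluxes.
#'
#' @param name Condition label (`"NC"`, `"L"`, `"M"`, `"H"`, `"RH"`, `"E"`,
#'   or free text).
#' @param arms Named list (one entry per arm label) of lists with either
#'   `ev` or `lux` (or `cd_m2`).
#' @param spectra Named list of `led_spectrum` per arm (default
#'   [vis4m_led_set()]).
#' @param opsins Named list of templates (default [mouse_opsins()]).
#' @param lens_correction Passed to [effective_log_photon_flux()].
#' @return Object of class `light_condition` wrapping a per-arm tibble.
#' @export
light_condition <- function(name, arms, spectra = vis4m_led_set(),
                            opsins = mouse_opsins(), lens_correction = TRUE) {
  stopifnot(is.list(arms), length(arms) >= 1L, !is.null(names(arms)))
  missing_spec <- setdiff(names(arms), names(spectra))
  if (length(missing_spec) > 0L) {
    stop("no spectrum for arm(s): ", paste(missing_spec, collapse = ", "))
  }
  rows <- lapply(names(arms), function(arm) {
    a <- arms[[arm]]
    if (!is.null(a$ev)) {
      ev <- a$ev
      lux <- ev_to_illuminance(ev)
    } else if (!is.null(a$lux)) {
      if (a$lux < 0) stop("negative illuminance for arm ", arm)
      lux <- a$lux
      ev <- if (lux > 0) illuminance_to_ev(lux) else -Inf
    } else if (!is.null(a$cd_m2)) {
      if (a$cd_m2 < 0) stop("negative luminance for arm ", arm)
      ev <- if (a$cd_m2 > 0) luminance_to_ev(a$cd_m2) else -Inf
      lux <- if (is.finite(ev)) ev_to_illuminance(ev) else 0
    } else {
      stop("arm ", arm, " must declare ev, lux or cd_m2")
    }
    cd <- if (is.finite(ev)) ev_to_luminance(ev) else 0
    sp <- spectra[[arm]]
    if (lux > 0) {
      irr <- illuminance_to_irradiance(lux, sp)
      logflux <- irradiance_to_log_photon_flux(irr, sp)
      eff <- vapply(opsins, function(op) {
        effective_log_photon_flux(sp, irr, op, lens_correction)
      }, numeric(1))
    } else {
      irr <- 0
      logflux <- -Inf
      eff <- stats::setNames(rep(-Inf, length(opsins)), names(opsins))
    }
    c(list(arm = arm, ev = ev, illuminance_lux = lux, luminance_cd_m2 = cd,
           irradiance_uw_cm2 = irr, log_photon_flux = logflux,
           regime = classify_light_regime(cd)),
      stats::setNames(as.list(eff), paste0("eff_log_flux_", names(opsins))))
  })
  tab <- tibble::as_tibble(do.call(rbind, lapply(rows, as.data.frame)))
  structure(list(name = name, table = tab), class = "light_condition")
}

#' @export
print.light_condition <- function(x, ...) {
  cat(sprintf("<light_condition> %s\n", x$name))
  print(x$table)
  invisible(x)
}
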