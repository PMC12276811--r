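# Photon-flux arithmetic for LED stimulus calibration. Stimuli of
# different wavelengths are equated on photon flux (isoquantal), not
# radiant power, because photoreceptor catch counts photons.

PLANCK_H <- 6.62607015e-34   # J s
LIGHT_C <- 2.99792458e8      # m / s

#' Read a two-column spectrum file
#'
#' Plain-text spectrometer export: wavelength (nm) and spectral irradiance
#' (W cm^-2 nm^-1), whitespace- or comma-delimited, `#` comments allowed.
#'
#' @param path File path.
#' @return A tibble `wavelength`, `irradiance`, ascending in wavelength.
#' @export
read_spectrum <- function(path) {
  raw <- utils::read.table(path, header = FALSE, comment.char = "#",
                           sep = "", col.names = c("wavelength", "irradiance"))
  sp <- as_tibble(raw) %>% arrange(.data$wavelength)
  validate_spectrum(sp)
  sp
}

validate_spectrum <- function(spectrum) {
  if (any(diff(spectrum$wavelength) <= 0)) {
    abort("spectrum wavelength grid must be strictly ascending")
  }
  if (any(spectrum$irradiance < 0)) abort("spectral irradiance must be >= 0")
  invisible(spectrum)
}

#' Photon flux of a spectrum over a band
#'
#' Converts spectral irradiance to photon flux by the trapezoidal integral
#' of `E(lambda) * lambda / (h c)` over the band: each photon at
#' wavelength lambda carries energy `h c / lambda`.
#'
#' @param spectrum Tibble with `wavelength` (nm, ascending) and
#'   `irradiance` (W cm^-2 nm^-1).
#' @param band Length-2 numeric, integration band in nm; defaults to the
#'   full grid extent. Must lie within the grid.
#' @return Photon flux in photons cm^-2 s^-1.
#' @examples
#' sp <- tibble::tibble(wavelength = 499:501, irradiance = c(0, 1, 0))
#' photon_flux(sp)
#' @export
photon_flux <- function(spectrum, band = range(spectrum$wavelength)) {
  validate_spectrum(spectrum)
  g <- range(spectrum$wavelength)
  if (band[1] < g[1] - 1e-9 || band[2] > g[2] + 1e-9) {
    abort(sprintf("band [%g, %g] nm lies outside the spectrum grid [%g, %g] nm",
                  band[1], band[2], g[1], g[2]))
  }
  wl <- spectrum$wavelength
  irr <- spectrum$irradiance
  # clip the grid to the band, interpolating the edge points
  inside <- wl >= band[1] & wl <= band[2]
  wl_c <- wl[inside]; irr_c <- irr[inside]
  for (edge in band) {
    if (!any(abs(wl_c - edge) < 1e-12)) {
      e_irr <- approx(wl, irr, xout = edge)$y
      wl_c <- c(wl_c, edge); irr_c <- c(irr_c, e_irr)
    }
  }
  o <- order(wl_c)
  wl_c <- wl_c[o]; irr_c <- irr_c[o]
  if (length(wl_c) < 2) return(0)
  # lambda in nm -> m; result: W cm^-2 nm^-1 * nm / J = photons cm^-2 s^-1
  integrand <- irr_c * (wl_c * 1e-9) / (PLANCK_H * LIGHT_C)
  pracma::trapz(wl_c, integrand)
}

#' Scale factor bringing a channel to an isoquantal target
#'
#' LED output is controlled by PWM duty cycle, assumed proportional to
#' irradiance, so a single multiplicative scale tunes a channel to the
#' target photon flux (default ~3.5e11 photons cm^-2 s^-1, the isoquantal
#' level used for all monochromatic stimuli at relative intensity 1.0).
#'
#' @param spectrum Channel spectrum at the current drive level.
#' @param target_flux Target photon flux, photons cm^-2 s^-1.
#' @param band Integration band (nm); defaults to the grid extent.
#' @return Scalar scale factor; `photon_flux(scale * E) == target_flux`.
#' @export
solve_isoquantal_scale <- function(spectrum, target_flux = 3.5e11,
                                   band = range(spectrum$wavelength)) {
  flux <- photon_flux(spectrum, band)
  if (flux <= 0) abort("spectrum has zero photon flux in the band; cannot scale")
  target_flux / flux
}

#' Rescale a spectrum
#'
#' @param spectrum Spectrum tibble.
#' @param scale Multiplicative factor applied to the irradiance.
#' @return The scaled spectrum.
#' @export
scale_spectrum <- function(spectrum, scale) {
  mutate(spectrum, irradiance = .data$irradiance * scale)
}
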