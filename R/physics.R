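# Electron-optical constants and derivations shared across the package.
#
# CODATA-2018 values:
#   h  = 6.62607015e-34  J s    (exact)
#   m0 = 9.1093837015e-31 kg
#   e  = 1.602176634e-19  C     (exact)
#   c  = 299792458        m/s   (exact)
.codata <- list(
  h  = 6.62607015e-34,
  m0 = 9.1093837015e-31,
  e  = 1.602176634e-19,
  c  = 299792458
)

#' Relativistic electron wavelength
#'
#' Wavelength of an electron accelerated through a potential `voltage`,
#' using the relativistic de Broglie relation
#' \deqn{\lambda = h / \sqrt{2 m_0 e V (1 + eV / (2 m_0 c^2))}.}
#' At 200 kV this gives 0.02508 Angstrom, the standard value for a
#' 200 keV transmission electron microscope.
#'
#' @param voltage Accelerating voltage in kV (the microscopist's convention).
#' @return Wavelength in Angstrom.
#' @examples
#' electron_wavelength(200)  # 0.02508 A
#' @export
electron_wavelength <- function(voltage) {
  if (!is.numeric(voltage) || any(!is.finite(voltage)) || any(voltage <= 0))
    stop("`voltage` must be a positive accelerating voltage in kV")
  V <- voltage * 1e3
  with(.codata, {
    lambda_m <- h / sqrt(2 * m0 * e * V * (1 + e * V / (2 * m0 * c^2)))
    lambda_m * 1e10
  })
}

#' Resolution at a detector radius
#'
#' Converts a radial distance on the detector into a Bragg resolution
#' using the exact scattering-angle relation
#' \eqn{d = \lambda / (2 \sin(\theta))} with
#' \eqn{2\theta = \arctan(r / L)}. At electron wavelengths the scattering
#' angles are small, so \eqn{d \approx L \lambda / r} holds to within a
#' percent for \eqn{r/L < 0.05}.
#'
#' @param radius Radial distance from the beam centre on the detector, mm.
#' @param camera_length Effective camera length, mm.
#' @param wavelength Electron wavelength, Angstrom.
#' @return Resolution d in Angstrom; `Inf` at radius 0 (zero scattering angle).
#' @export
resolution_at_radius <- function(radius, camera_length, wavelength) {
  if (any(radius < 0)) stop("`radius` must be non-negative")
  if (camera_length <= 0) stop("`camera_length` must be positive")
  if (wavelength <= 0) stop("`wavelength` must be positive")
  theta <- 0.5 * atan(radius / camera_length)
  d <- wavelength / (2 * sin(theta))
  d[radius == 0] <- Inf
  d
}

#' Beam and geometry parameters
#'
#' Bundle of the electron-optical parameters a cRED data set carries:
#' accelerating voltage, the wavelength it implies, effective camera
#' length and detector pixel pitch (55 um for the regular Timepix pixel).
#'
#' @param voltage Accelerating voltage, kV.
#' @param camera_length Effective camera length, mm.
#' @param pixel_pitch Pixel pitch, um.
#' @return A `beam_parameters` list with fields `voltage`, `wavelength`
#'   (Angstrom), `camera_length` and `pixel_pitch`.
#' @export
beam_parameters <- function(voltage = 200, camera_length = 250,
                            pixel_pitch = 55) {
  if (pixel_pitch <= 0) stop("`pixel_pitch` must be positive")
  structure(
    list(
      voltage = voltage,
      wavelength = electron_wavelength(voltage),
      camera_length = camera_length,
      pixel_pitch = pixel_pitch
    ),
    class = "beam_parameters"
  )
}

#' @export
print.beam_parameters <- function(x, ...) {
  cat(sprintf(
    "Beam parameters: %g kV (lambda = %.5g A), camera length %g mm, pixel %g um\n",
    x$voltage, x$wavelength, x$camera_length, x$pixel_pitch))
  invisible(x)
}
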