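#' First zero of the zeroth-order Bessel function
#'
#' The transverse core radius of a Bessel beam is set by the first zero of
#' J0, commonly quoted as 2.405. The full-precision value 2.404826 is used
#' internally; the two differ by less than 0.01%.
#'
#' @keywords internal
J0_FIRST_ZERO <- 2.404826

#' Optical setup: wavelength, medium and wavenumber
#'
#' Bundles the illumination wavelength and the refractive index of the space
#' the beam propagates in. The angular wavenumber `k = 2*pi*medium_index /
#' wavelength` is derived at construction and carried along; it is never set
#' independently of the wavelength.
#'
#' All lengths are SI metres. The beam-shaping space just after the spatial
#' light modulator is air, so `medium_index` defaults to 1.
#'
#' @param wavelength Vacuum wavelength in metres (default 488 nm).
#' @param medium_index Refractive index of the propagation medium (>= 1).
#'
#' @return An object of class `optical_setup` with fields `wavelength`,
#'   `medium_index` and `k` (rad/m).
#' @examples
#' setup <- optical_setup(488e-9)
#' setup$k
#' @export
optical_setup <- function(wavelength = 488e-9, medium_index = 1) {
  if (!is.numeric(wavelength) || length(wavelength) != 1L || wavelength <= 0) {
    rlang::abort("`wavelength` must be a single positive length in metres.",
                 class = "ssbeam_error_domain")
  }
  if (!is.numeric(medium_index) || length(medium_index) != 1L || medium_index < 1) {
    rlang::abort("`medium_index` must be a single number >= 1.",
                 class = "ssbeam_error_domain")
  }
  structure(
    list(
      wavelength = wavelength,
      medium_index = medium_index,
      k = 2 * pi * medium_index / wavelength
    ),
    class = "optical_setup"
  )
}

#' @export
print.optical_setup <- function(x, ...) {
  cat(sprintf(
    "<optical_setup> lambda = %.1f nm, n = %.3f, k = %.4g rad/m\n",
    x$wavelength * 1e9, x$medium_index, x$k
  ))
  invisible(x)
}

#' Single Bessel-beam component of a superposition
#'
#' A zeroth-order Bessel beam is characterised by its amplitude weight `A`
#' and its radial wavevector `kr`; the longitudinal wavevector follows
#' exactly from the free-space dispersion relation `kz = sqrt(k^2 - kr^2)`.
#'
#' @param amplitude Dimensionless field amplitude weight in \[0, 1\].
#' @param kr Radial wavevector in rad/m, `0 < kr < k`.
#' @param setup An [optical_setup()].
#'
#' @return An object of class `bessel_component` with fields `amplitude`,
#'   `kr` and `kz`.
#' @export
bessel_component <- function(amplitude, kr, setup = optical_setup()) {
  stopifnot(inherits(setup, "optical_setup"))
  if (!is.numeric(amplitude) || length(amplitude) != 1L ||
      amplitude < 0 || amplitude > 1) {
    rlang::abort("`amplitude` must be a single number in [0, 1].",
                 class = "ssbeam_error_domain")
  }
  if (!is.numeric(kr) || length(kr) != 1L || kr <= 0) {
    rlang::abort("`kr` must be a single positive radial wavevector (rad/m).",
                 class = "ssbeam_error_domain")
  }
  structure(
    list(
      amplitude = amplitude,
      kr = kr,
      kz = axial_wavevector(kr, setup),
      setup = setup
    ),
    class = "bessel_component"
  )
}

#' Two-component Bessel superposition parameter set
#'
#' The sidelobe-suppressed Bessel beam (SSBB) is the coherent superposition
#' of two zeroth-order Bessel beams,
#' `SP(r, z) = A1 J0(kr1 r) exp(i kz1 z) + A2 J0(kr2 r) exp(i kz2 z)`.
#' This constructor validates the amplitude constraint `A1 + A2 = 1`, orders
#' the components so that `kr1 < kr2`, and derives the composite core radius
#' (see [ssbb_core_radius()]) and the axial beat period (see
#' [beat_period()]).
#'
#' @param A1,A2 Amplitude weights; must sum to 1 within `1e-9`.
#' @param kr1,kr2 Radial wavevectors in rad/m; reordered so `kr1 < kr2`.
#' @param setup An [optical_setup()].
#'
#' @return An object of class `superposition_spec` with fields
#'   `component_1`, `component_2`, `core_radius` (m), `period` (m) and
#'   `setup`.
#' @examples
#' spec <- superposition_spec(0.525, 2.95e4, 0.475, 5.17e4)
#' spec$core_radius * 1e6  # ~60 um
#' spec$period * 1e3       # ~89.8 mm
#' @export
superposition_spec <- function(A1, kr1, A2, kr2, setup = optical_setup()) {
  if (abs(A1 + A2 - 1) > 1e-9) {
    rlang::abort("Amplitudes must satisfy A1 + A2 = 1 (within 1e-9).",
                 class = "ssbeam_error_constraint")
  }
  if (kr1 > kr2) {  # ordering convention: component 1 carries the smaller kr
    tmp <- list(A1, kr1); A1 <- A2; kr1 <- kr2; A2 <- tmp[[1]]; kr2 <- tmp[[2]]
  }
  structure(
    list(
      component_1 = bessel_component(A1, kr1, setup),
      component_2 = bessel_component(A2, kr2, setup),
      core_radius = ssbb_core_radius(A1, kr1, A2, kr2),
      period = beat_period(kr1, kr2, setup),
      setup = setup
    ),
    class = "superposition_spec"
  )
}

#' @export
print.superposition_spec <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<superposition_spec>\n",
      "  A1 = %.4f, kr1 = %.4g rad/m (kz1 = %.8g rad/m)\n",
      "  A2 = %.4f, kr2 = %.4g rad/m (kz2 = %.8g rad/m)\n",
      "  core radius = %.2f um, beat period = %.2f mm\n"
    ),
    x$component_1$amplitude, x$component_1$kr, x$component_1$kz,
    x$component_2$amplitude, x$component_2$kr, x$component_2$kz,
    x$core_radius * 1e6, x$period * 1e3
  ))
  invisible(x)
}
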