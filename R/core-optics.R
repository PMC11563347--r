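#' Longitudinal wavevector of a Bessel beam
#'
#' Free-space dispersion: `kz = sqrt(k^2 - kr^2)`. Radial wavevectors at or
#' beyond `k` correspond to evanescent waves and are rejected.
#'
#' @param kr Radial wavevector(s), rad/m, `0 <= kr < k`.
#' @param setup An [optical_setup()].
#' @return `kz` in rad/m, same length as `kr`; strictly decreasing in `kr`.
#' @examples
#' setup <- optical_setup(488e-9)
#' axial_wavevector(0, setup) == setup$k
#' @export
axial_wavevector <- function(kr, setup = optical_setup()) {
  stopifnot(inherits(setup, "optical_setup"))
  if (any(kr < 0)) {
    rlang::abort("`kr` must be nonnegative.", class = "ssbeam_error_domain")
  }
  if (any(kr >= setup$k)) {
    rlang::abort(
      "`kr` >= k: the component is evanescent and carries no propagating field.",
      class = "ssbeam_error_evanescent"
    )
  }
  sqrt(setup$k^2 - kr^2)
}

#' Axial beat period of a two-Bessel superposition
#'
#' Two superposed Bessel beams with different longitudinal wavevectors drift
#' in and out of phase along the propagation axis; their relative phase
#' realigns with period `P = 2*pi / |kz1 - kz2|`. The period sets the axial
#' window over which the sidelobe suppression of the composite beam is
#' maintained.
#'
#' @param kr1,kr2 Radial wavevectors in rad/m (order irrelevant).
#' @param setup An [optical_setup()].
#' @return Period `P` in metres.
#' @examples
#' beat_period(2.95e4, 5.17e4) * 1e3  # ~89.8 mm at 488 nm
#' @export
beat_period <- function(kr1, kr2, setup = optical_setup()) {
  if (kr1 == kr2) {
    rlang::abort(
      "`kr1` == `kr2`: the beat period is undefined for identical components.",
      class = "ssbeam_error_degenerate"
    )
  }
  kz1 <- axial_wavevector(kr1, setup)
  kz2 <- axial_wavevector(kr2, setup)
  2 * pi / abs(kz1 - kz2)
}

#' Core radius of a single Bessel beam
#'
#' The central lobe of `J0(kr * r)` extends to its first zero, giving a core
#' radius `r0 = 2.405 / kr` (2.404826 held internally).
#'
#' @param kr Radial wavevector(s), rad/m, positive.
#' @return Core radius in metres.
#' @export
bb_core_radius <- function(kr) {
  if (any(kr <= 0)) {
    rlang::abort("`kr` must be positive.", class = "ssbeam_error_domain")
  }
  J0_FIRST_ZERO / kr
}

#' Approximate core radius of a two-Bessel superposition
#'
#' For the sidelobe-suppressed composite beam the core radius is well
#' approximated by replacing the single radial wavevector with the
#' amplitude-weighted mean: `r0 = 2.405 / (A1 kr1 + A2 kr2)`. With `A2 = 0`
#' this reduces to [bb_core_radius()].
#'
#' @param A1,A2 Amplitude weights; must sum to 1 within `1e-6`.
#' @param kr1,kr2 Radial wavevectors, rad/m, positive.
#' @return Core radius in metres.
#' @examples
#' ssbb_core_radius(0.525, 2.95e4, 0.475, 5.17e4) * 1e6  # ~60 um
#' @export
ssbb_core_radius <- function(A1, kr1, A2, kr2) {
  if (A1 < 0 || A2 < 0) {
    rlang::abort("Amplitudes must be nonnegative.", class = "ssbeam_error_domain")
  }
  if (abs(A1 + A2 - 1) > 1e-6) {
    rlang::abort("Amplitudes must satisfy A1 + A2 = 1 (within 1e-6).",
                 class = "ssbeam_error_constraint")
  }
  if (kr1 <= 0 || kr2 <= 0) {
    rlang::abort("Radial wavevectors must be positive.",
                 class = "ssbeam_error_domain")
  }
  J0_FIRST_ZERO / (A1 * kr1 + A2 * kr2)
}

#' Complex field of the two-Bessel superposition
#'
#' Evaluates `SP(r, z) = A1 J0(kr1 r) exp(i kz1 z) + A2 J0(kr2 r) exp(i kz2 z)`.
#' If both `r` and `z` have length > 1 the field is returned on the outer
#' grid as a complex matrix with `length(r)` rows and `length(z)` columns;
#' otherwise the shorter argument is recycled and a vector is returned.
#'
#' @param spec A [superposition_spec()].
#' @param r Radial coordinate(s), metres, `>= 0`.
#' @param z Axial coordinate(s), metres.
#' @return Complex amplitude(s); intensity is `Mod(.)^2`.
#' @examples
#' spec <- superposition_spec(0.525, 2.95e4, 0.475, 5.17e4)
#' Mod(superposition_field(spec, 0, 0))^2  # central peak, intensity 1
#' @export
superposition_field <- function(spec, r, z = 0) {
  stopifnot(inherits(spec, "superposition_spec"))
  if (any(r < 0)) {
    rlang::abort("`r` must be nonnegative.", class = "ssbeam_error_domain")
  }
  c1 <- spec$component_1
  c2 <- spec$component_2
  J1 <- besselJ(c1$kr * r, 0)
  J2 <- besselJ(c2$kr * r, 0)
  ph1 <- exp(1i * c1$kz * z)
  ph2 <- exp(1i * c2$kz * z)
  if (length(r) > 1L && length(z) > 1L) {
    outer(c1$amplitude * J1, ph1) + outer(c2$amplitude * J2, ph2)
  } else {
    c1$amplitude * J1 * ph1 + c2$amplitude * J2 * ph2
  }
}

#' Radial intensity profile container
#'
#' A tibble subclass holding a transverse line profile: ascending radii
#' (starting at 0 by convention for beam profiles) and nonnegative
#' intensities.
#'
#' @param radii Radial coordinates in metres, strictly increasing.
#' @param values Intensities (arbitrary units, `>= 0`).
#' @return A tibble of class `radial_profile` with columns `radius`, `value`.
#' @export
radial_profile <- function(radii, values) {
  if (length(radii) != length(values)) {
    rlang::abort("`radii` and `values` must have equal length.",
                 class = "ssbeam_error_shape")
  }
  if (any(diff(radii) <= 0)) {
    rlang::abort("`radii` must be strictly increasing.",
                 class = "ssbeam_error_shape")
  }
  if (any(values < 0)) {
    rlang::abort("`values` must be nonnegative.", class = "ssbeam_error_domain")
  }
  tibble::new_tibble(
    tibble::tibble(radius = as.numeric(radii), value = as.numeric(values)),
    class = "radial_profile"
  )
}

#' Radial intensity profile of a superposition at one plane
#'
#' Convenience wrapper: samples `|SP(r, z)|^2` on a uniform radial grid.
#'
#' @param spec A [superposition_spec()].
#' @param z Axial plane, metres (default 0).
#' @param r_max Outer radius, metres; defaults to `10 * core_radius`.
#' @param n Number of radial samples (default 5000).
#' @return A [radial_profile()].
#' @export
superposition_profile <- function(spec, z = 0, r_max = 10 * spec$core_radius,
                                  n = 5000L) {
  r <- seq(0, r_max, length.out = n)
  radial_profile(r, Mod(superposition_field(spec, r, z))^2)
}

#' Sidelobe table of a radial intensity profile
#'
#' Formalises the "sidelobe fraction" measurement: local maxima beyond the
#' first minimum after the central peak, each normalised to the central-peak
#' intensity and sorted by radius. Detection scans the discrete derivative
#' for sign changes; ripples below `floor` (relative to the peak) are
#' ignored. A monotonically decreasing profile yields an empty table.
#'
#' @param profile A [radial_profile()] (or data frame with columns `radius`
#'   and `value`) whose global maximum lies at or near `r = 0`.
#' @param floor Relative-height floor below which maxima are discarded
#'   (default `1e-4`).
#' @return A tibble with columns `radius` (m) and `relative_intensity`.
#' @examples
#' r <- seq(0, 10 * bb_core_radius(4e4), length.out = 4000)
#' p <- radial_profile(r, besselJ(4e4 * r, 0)^2)
#' sidelobe_table(p)  # first entries ~0.162, ~0.090
#' @export
sidelobe_table <- function(profile, floor = 1e-4) {
  stopifnot(is.data.frame(profile), all(c("radius", "value") %in% names(profile)))
  v <- profile$value
  r <- profile$radius
  ipk <- which.max(v)
  # the central peak must sit at (or adjacent to) the innermost samples
  if (r[ipk] > r[1] + 0.05 * (r[length(r)] - r[1])) {
    rlang::abort("Profile has no central peak at small radius.",
                 class = "ssbeam_error_shape")
  }
  peak <- v[ipk]
  d <- diff(v)
  # first local minimum after the central peak
  imin <- which(d[-1] > 0 & d[-length(d)] <= 0) + 1L
  imin <- imin[imin > ipk]
  if (length(imin) == 0L) {
    return(tibble::tibble(radius = numeric(), relative_intensity = numeric()))
  }
  start <- imin[1]
  # local maxima beyond that minimum
  imax <- which(d[-1] < 0 & d[-length(d)] >= 0) + 1L
  imax <- imax[imax > start]
  rel <- v[imax] / peak
  keep <- rel >= floor
  tibble::tibble(radius = r[imax][keep], relative_intensity = rel[keep])
}
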