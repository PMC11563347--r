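#' Light-sheet thickness profile along the detection axis
#'
#' A tibble subclass holding the sheet profile `S(z)` (detection axis `z`),
#' normalised to a maximum of 1 on construction.
#'
#' @param z Detection-axis coordinates, metres, strictly increasing.
#' @param intensity Nonnegative intensities.
#' @param provenance `"analytic"` or `"projected-from-volume"`.
#' @return A tibble of class `sheet_profile` with columns `z`, `intensity`.
#' @export
sheet_profile <- function(z, intensity, provenance = "analytic") {
  if (any(diff(z) <= 0)) {
    rlang::abort("`z` must be strictly increasing.", class = "ssbeam_error_shape")
  }
  if (any(intensity < 0)) {
    rlang::abort("`intensity` must be nonnegative.", class = "ssbeam_error_domain")
  }
  out <- tibble::new_tibble(
    tibble::tibble(z = as.numeric(z), intensity = intensity / max(intensity)),
    class = "sheet_profile"
  )
  attr(out, "provenance") <- provenance
  out
}

#' Scanned-sheet profile from a transverse beam cross-section
#'
#' Scanning the beam along `y` with a galvanometer produces a time-averaged
#' sheet whose thickness profile is the line integral of the transverse
#' intensity along the scan direction: `S(z) = integral I(y, z) dy` over the
#' scan window. Projection raises the *relative* sidelobes compared with the
#' pointwise beam profile, which is why a Bessel-beam sheet is worse than
#' its own line profile suggests.
#'
#' @param intensity Matrix `I[y, z]` (rows = scan coordinate `y`, cols =
#'   detection coordinate `z`), nonnegative.
#' @param y,z Coordinate vectors for the rows and columns, metres.
#' @param y_window Length-2 scan window in metres (default: full `y` range).
#' @return A [sheet_profile()] with provenance `"projected-from-volume"`.
#' @export
scanned_sheet_profile <- function(intensity, y, z,
                                  y_window = range(y)) {
  if (nrow(intensity) != length(y) || ncol(intensity) != length(z)) {
    rlang::abort("`intensity` must be y-by-z.", class = "ssbeam_error_shape")
  }
  if (any(intensity < 0)) {
    rlang::abort("`intensity` must be nonnegative.", class = "ssbeam_error_domain")
  }
  if (y_window[1] < min(y) - 1e-12 || y_window[2] > max(y) + 1e-12) {
    rlang::abort("`y_window` exceeds the sampled grid.",
                 class = "ssbeam_error_domain")
  }
  keep <- y >= y_window[1] & y <= y_window[2]
  S <- colSums(intensity[keep, , drop = FALSE])
  sheet_profile(z, S, provenance = "projected-from-volume")
}

#' Analytic scanned-sheet profile of a beam at one propagation plane
#'
#' Builds the transverse intensity `|SP(sqrt(y^2 + z^2), z_prop)|^2` on a
#' (y, z) grid and projects it along the scan axis.
#'
#' @param spec A [superposition_spec()] (possibly telescope-scaled to the
#'   sample plane), or a single radial wavevector (rad/m) for a plain
#'   Bessel beam.
#' @param z_prop Propagation plane, metres (default 0; ignored for a plain
#'   Bessel beam, whose transverse profile is z-invariant).
#' @param half_window Half-width of both the scan window and the detection
#'   axis, metres; default `10 * core_radius`.
#' @param n Samples per axis (default 1001).
#' @return A [sheet_profile()].
#' @export
beam_sheet_profile <- function(spec, z_prop = 0,
                               half_window = NULL,
                               n = 1001L) {
  if (is.numeric(spec)) {
    kr <- spec
    half_window <- half_window %||% (10 * bb_core_radius(kr))
    y <- seq(-half_window, half_window, length.out = n)
    rho <- sqrt(outer(y^2, y^2, `+`))
    return(scanned_sheet_profile(besselJ(kr * rho, 0)^2, y, y))
  }
  stopifnot(inherits(spec, "superposition_spec"))
  half_window <- half_window %||% (10 * spec$core_radius)
  y <- seq(-half_window, half_window, length.out = n)
  z <- y
  rho <- sqrt(outer(y^2, z^2, `+`))
  c1 <- spec$component_1
  c2 <- spec$component_2
  u <- c1$amplitude * besselJ(c1$kr * rho, 0) * exp(1i * c1$kz * z_prop) +
    c2$amplitude * besselJ(c2$kr * rho, 0) * exp(1i * c2$kz * z_prop)
  scanned_sheet_profile(Mod(u)^2, y, z)
}

#' Central-lobe thickness of a light-sheet
#'
#' Full width at half maximum of the central lobe only, measured between
#' the innermost half-max crossings around the peak (sidelobe shoulders are
#' deliberately excluded). Invariant to intensity rescaling.
#'
#' @param profile A [sheet_profile()] (or data frame with `z`, `intensity`).
#' @return Thickness in metres.
#' @export
sheet_thickness <- function(profile) {
  stopifnot(is.data.frame(profile), all(c("z", "intensity") %in% names(profile)))
  width_at_level(profile$z, profile$intensity, level = 0.5,
                 crossing = "innermost")
}

#' Depth of focus of a Gaussian light-sheet of given thickness
#'
#' For a Gaussian sheet whose thickness (central-lobe FWHM-equivalent
#' waist measure) is `w0`, the usable axial extent is twice the Rayleigh
#' range with `w0` as the waist: `DOF = 2 * pi * w0^2 / lambda` (vacuum
#' wavelength). [gaussian_sheet_thickness()] is the exact inverse.
#'
#' @param w0 Sheet thickness, metres.
#' @param setup An [optical_setup()].
#' @return DOF in metres.
#' @examples
#' gaussian_sheet_dof(4.8e-6) * 1e6   # ~296 um at 488 nm
#' gaussian_sheet_thickness(540e-6) * 1e6  # ~6.5 um
#' @export
gaussian_sheet_dof <- function(w0, setup = optical_setup()) {
  if (any(w0 <= 0)) {
    rlang::abort("`w0` must be positive.", class = "ssbeam_error_domain")
  }
  2 * pi * w0^2 / setup$wavelength
}

#' @rdname gaussian_sheet_dof
#' @param dof Depth of focus, metres.
#' @export
gaussian_sheet_thickness <- function(dof, setup = optical_setup()) {
  if (any(dof <= 0)) {
    rlang::abort("`dof` must be positive.", class = "ssbeam_error_domain")
  }
  sqrt(dof * setup$wavelength / (2 * pi))
}

#' Detection-side axial response model
#'
#' The detection objective contributes its own axial blur to the system
#' PSF. In the absence of a measured response it is modelled as a
#' normalised Gaussian with FWHM `2 * lambda_em * n / NA^2` (a standard
#' axial-extent estimate for a widefield objective).
#'
#' @param numerical_aperture Detection NA, `0 < NA < medium_index`.
#' @param wavelength_em Emission wavelength, metres (default 520 nm).
#' @param medium_index Immersion index (default 1.33, water).
#' @return An object of class `detection_model` with the derived
#'   `axial_fwhm` field.
#' @examples
#' detection_model(0.367)$axial_fwhm * 1e6  # ~10.3 um
#' @export
detection_model <- function(numerical_aperture = 0.367,
                            wavelength_em = 520e-9,
                            medium_index = 1.33) {
  if (numerical_aperture <= 0 || numerical_aperture >= medium_index) {
    rlang::abort("Need 0 < NA < medium_index.", class = "ssbeam_error_domain")
  }
  structure(
    list(
      numerical_aperture = numerical_aperture,
      wavelength_em = wavelength_em,
      medium_index = medium_index,
      axial_profile_kind = "gaussian",
      axial_fwhm = 2 * wavelength_em * medium_index / numerical_aperture^2,
      lateral_fwhm = 0.61 * wavelength_em / numerical_aperture
    ),
    class = "detection_model"
  )
}

#' Axial response of the detection objective
#'
#' Normalised Gaussian in `|z|` with the model's axial FWHM.
#'
#' @param model A [detection_model()].
#' @param z Detection-axis coordinate(s), metres.
#' @return Response in \[0, 1\], equal to 1 at `z = 0`, symmetric in `z`.
#' @export
detection_axial_profile <- function(model, z) {
  stopifnot(inherits(model, "detection_model"))
  sigma <- model$axial_fwhm / (2 * sqrt(2 * log(2)))
  exp(-z^2 / (2 * sigma^2))
}

#' System axial PSF: sheet times detection response
#'
#' The axial response of the light-sheet microscope is the pointwise
#' product of the illumination sheet profile and the detection axial
#' profile (both normalised), renormalised to peak 1. Widths are reported
#' under two conventions: FWHM of the central lobe (innermost half-max
#' crossings) and the 1/e^2 full width using the *outermost* crossings of
#' the 0.1353 level, which is the convention that registers sidelobe
#' shoulders.
#'
#' @param sheet A [sheet_profile()].
#' @param det A [detection_model()].
#' @return An object of class `system_psf`: tibble columns `z`, `response`,
#'   plus `widths` in the attributes (see [glance.system_psf()]).
#' @export
system_axial_psf <- function(sheet, det) {
  stopifnot(is.data.frame(sheet), inherits(det, "detection_model"))
  resp <- sheet$intensity / max(sheet$intensity) *
    detection_axial_profile(det, sheet$z)
  resp <- resp / max(resp)
  out <- tibble::new_tibble(
    tibble::tibble(z = sheet$z, response = resp),
    class = "system_psf"
  )
  attr(out, "widths") <- c(
    fwhm = width_at_level(sheet$z, resp, 0.5, "innermost"),
    width_1e2 = width_at_level(sheet$z, resp, exp(-2), "outermost")
  )
  attr(out, "detection") <- det
  out
}

#' One-row width summary of a system PSF
#'
#' @param x A `system_psf`.
#' @param ... Unused.
#' @return Tibble with `fwhm` and `width_1e2` (metres).
#' @method glance system_psf
#' @export
glance.system_psf <- function(x, ...) {
  w <- attr(x, "widths")
  tibble::tibble(fwhm = unname(w["fwhm"]), width_1e2 = unname(w["width_1e2"]))
}

#' One-dimensional Richardson-Lucy deconvolution
#'
#' The standard multiplicative update for nonnegative profiles under a
#' known PSF: `est <- est * (K' %*% (obs / (K %*% est)))` with `K` the
#' (circular) convolution by the unit-sum PSF and `K'` its adjoint.
#' Convolutions are evaluated by FFT with circular boundary conditions, so
#' total flux is conserved exactly at every iteration and nonnegativity is
#' preserved. Profiles should decay towards the window edges.
#'
#' @param observed Nonnegative numeric vector.
#' @param psf Nonnegative numeric vector, same length or shorter (it is
#'   zero-padded and centred); normalised internally to unit sum.
#' @param iterations Number of multiplicative updates (default 10).
#' @return Deconvolved profile, same length as `observed`.
#' @export
richardson_lucy_1d <- function(observed, psf, iterations = 10L) {
  if (any(observed < 0) || any(psf < 0)) {
    rlang::abort("Inputs must be nonnegative.", class = "ssbeam_error_domain")
  }
  if (sum(psf) <= 0) {
    rlang::abort("PSF must have positive total weight.",
                 class = "ssbeam_error_domain")
  }
  n <- length(observed)
  if (length(psf) > n) {
    rlang::abort("PSF longer than the observed profile.",
                 class = "ssbeam_error_shape")
  }
  # centre the psf in a length-n circular kernel
  kern <- numeric(n)
  ipk <- which.max(psf)
  idx <- ((seq_along(psf) - ipk) %% n) + 1L
  kern[idx] <- kern[idx] + psf
  kern <- kern / sum(kern)
  K <- stats::fft(kern)
  conv <- function(v, Kf) Re(stats::fft(stats::fft(v) * Kf, inverse = TRUE)) / n
  Kc <- Conj(K)  # adjoint = correlation
  est <- rep(mean(observed), n)
  eps <- .Machine$double.eps
  for (i in seq_len(iterations)) {
    blur <- conv(est, K)
    ratio <- observed / pmax(blur, eps)
    est <- est * pmax(conv(ratio, Kc), 0)
  }
  est
}
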