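#' Complex transverse field at one propagation plane
#'
#' @param grid A [mask_grid()] describing the sampling.
#' @param amplitude Complex matrix (rows = y, cols = x).
#' @param z Axial coordinate of the plane, metres.
#' @param setup The [optical_setup()] the field propagates in.
#' @return An object of class `field_slice`.
#' @export
field_slice <- function(grid, amplitude, z = 0, setup = optical_setup()) {
  stopifnot(inherits(grid, "mask_grid"))
  if (nrow(amplitude) != grid$n_y || ncol(amplitude) != grid$n_x) {
    rlang::abort("`amplitude` dimensions must match the grid.",
                 class = "ssbeam_error_shape")
  }
  if (any(!is.finite(Mod(amplitude)))) {
    rlang::abort("`amplitude` must be finite.", class = "ssbeam_error_domain")
  }
  structure(list(grid = grid, amplitude = amplitude, z = z, setup = setup),
            class = "field_slice")
}

#' Total optical power carried by a field slice
#'
#' Discrete surrogate of `integral |u|^2 dA`: `sum(|u|^2) * pitch^2`.
#'
#' @param field A [field_slice()].
#' @return Power in arbitrary units * m^2.
#' @export
field_power <- function(field) {
  stopifnot(inherits(field, "field_slice"))
  sum(Mod(field$amplitude)^2) * field$grid$pitch^2
}

# FFT spatial angular frequencies for n samples at the given pitch (rad/m)
fft_kaxis <- function(n, pitch) {
  f <- c(seq(0, floor((n - 1) / 2)), seq(-floor(n / 2), -1)) / (n * pitch)
  2 * pi * f
}

#' Gaussian-apodized source field behind a phase mask
#'
#' Models the illumination arriving at the spatial light modulator as a
#' collimated Gaussian beam, `u(x, y) = exp(-rho^2 / waist^2) * exp(i *
#' phase)`. The finite Gaussian waist is what limits the depth of focus of
#' the generated Bessel beam.
#'
#' @param grid A [mask_grid()].
#' @param waist 1/e field radius in metres; the window must span at least 4
#'   waists.
#' @param mask Optional `phase_mask` on the same grid (default: flat phase).
#' @param setup An [optical_setup()].
#' @return A [field_slice()] at `z = 0`.
#' @export
gaussian_apodized_source <- function(grid, waist, mask = NULL,
                                     setup = optical_setup()) {
  stopifnot(inherits(grid, "mask_grid"))
  window <- min(grid$n_x, grid$n_y) * grid$pitch
  if (4 * waist > window) {
    rlang::abort(
      sprintf("Waist %.3g m too large for the %.3g m window (need >= 4 waists).",
              waist, window),
      class = "ssbeam_error_domain"
    )
  }
  rho <- grid_rho(grid)
  u <- exp(-rho^2 / waist^2)
  if (!is.null(mask)) {
    stopifnot(inherits(mask, "phase_mask"))
    if (mask$grid$n_x != grid$n_x || mask$grid$n_y != grid$n_y) {
      rlang::abort("Mask grid does not match.", class = "ssbeam_error_shape")
    }
    u <- u * exp(1i * mask$phase)
  }
  field_slice(grid, u, z = 0, setup = setup)
}

#' Sample the two-Bessel superposition on a grid as a field slice
#'
#' Evaluates the analytic superposition field on the full 2-D grid at one
#' plane; useful as the initial condition for numerical propagation and as
#' the analytic reference it is compared against.
#'
#' @param spec A [superposition_spec()].
#' @param grid A [mask_grid()].
#' @param z Plane, metres.
#' @return A [field_slice()].
#' @export
superposition_slice <- function(spec, grid, z = 0) {
  rho <- grid_rho(grid)
  c1 <- spec$component_1
  c2 <- spec$component_2
  u <- c1$amplitude * besselJ(c1$kr * rho, 0) * exp(1i * c1$kz * z) +
    c2$amplitude * besselJ(c2$kr * rho, 0) * exp(1i * c2$kz * z)
  field_slice(grid, u, z = z, setup = spec$setup)
}

#' Band-limited angular-spectrum propagation
#'
#' Propagates a scalar field by `dz` with the exact free-space transfer
#' function `H = exp(i * dz * sqrt(k^2 - kx^2 - ky^2))` applied in the
#' Fourier domain. Evanescent components (`kx^2 + ky^2 > k^2`) are zeroed;
#' the standard anti-aliasing band limit
#' `|kx| <= k / sqrt(1 + (2 dz / Lx)^2)` (and likewise in y) removes plane
#' waves whose fringes would alias across the periodic window for the
#' requested distance. Within the retained band the transfer is unitary, so
#' power is conserved there and never increases overall;
#' `propagate(dz)` followed by `propagate(-dz)` restores the band-limited
#' field.
#'
#' @param field A [field_slice()].
#' @param dz Signed propagation distance, metres.
#' @param band_limit Apply the anti-aliasing limit (default `TRUE`).
#' @return A [field_slice()] at `z + dz`.
#' @export
angular_spectrum_propagate <- function(field, dz, band_limit = TRUE) {
  stopifnot(inherits(field, "field_slice"))
  g <- field$grid
  k <- field$setup$k
  kx <- fft_kaxis(g$n_x, g$pitch)
  ky <- fft_kaxis(g$n_y, g$pitch)
  kx2 <- matrix(kx^2, g$n_y, g$n_x, byrow = TRUE)
  ky2 <- matrix(ky^2, g$n_y, g$n_x)
  kt2 <- kx2 + ky2
  prop <- kt2 < k^2
  kzm <- sqrt(pmax(k^2 - kt2, 0))
  H <- matrix(0i, g$n_y, g$n_x)
  H[prop] <- exp(1i * dz * kzm[prop])
  if (band_limit && dz != 0) {
    Lx <- g$n_x * g$pitch
    Ly <- g$n_y * g$pitch
    kx_lim <- k / sqrt(1 + (2 * dz / Lx)^2)
    ky_lim <- k / sqrt(1 + (2 * dz / Ly)^2)
    keep <- (kx2 <= kx_lim^2) & (ky2 <= ky_lim^2)
    if (!any(keep)) {
      rlang::abort(
        "Band limit removes the whole spectrum; enlarge the window or shorten dz.",
        class = "ssbeam_error_aliasing"
      )
    }
    H[!keep] <- 0i
  }
  U <- stats::fft(field$amplitude)
  u2 <- stats::fft(U * H, inverse = TRUE) / length(U)
  field_slice(g, u2, z = field$z + dz, setup = field$setup)
}

#' Stacked intensity over a set of propagation planes
#'
#' Repeatedly applies [angular_spectrum_propagate()] and records `|u|^2`,
#' returning an `intensity_volume`: a 3-D array indexed `[z, y, x]` with the
#' plane coordinates attached.
#'
#' @param field Starting [field_slice()].
#' @param z_planes Strictly increasing axial coordinates (metres), absolute
#'   (relative to the field's own plane).
#' @param band_limit Passed to the propagator.
#' @return An object of class `intensity_volume` with fields `z_planes`,
#'   `intensity` (array `[z, y, x]`) and `grid`.
#' @export
propagate_volume <- function(field, z_planes, band_limit = TRUE) {
  stopifnot(inherits(field, "field_slice"))
  if (any(diff(z_planes) <= 0)) {
    rlang::abort("`z_planes` must be strictly increasing.",
                 class = "ssbeam_error_shape")
  }
  g <- field$grid
  out <- array(0, dim = c(length(z_planes), g$n_y, g$n_x))
  cur <- field
  for (i in seq_along(z_planes)) {
    cur <- angular_spectrum_propagate(cur, z_planes[i] - cur$z, band_limit)
    out[i, , ] <- Mod(cur$amplitude)^2
  }
  structure(list(z_planes = z_planes, intensity = out, grid = g),
            class = "intensity_volume")
}

#' On-axis intensity of an intensity volume
#'
#' @param volume An `intensity_volume`.
#' @return A tibble with columns `z` and `intensity` (centre-pixel value).
#' @export
on_axis_profile <- function(volume) {
  stopifnot(inherits(volume, "intensity_volume"))
  iy <- floor(volume$grid$n_y / 2) + 1L
  ix <- floor(volume$grid$n_x / 2) + 1L
  tibble::tibble(z = volume$z_planes, intensity = volume$intensity[, iy, ix])
}

#' Depth of focus of an axial intensity profile
#'
#' The length of the connected axial interval, containing the global
#' maximum, over which the on-axis intensity stays at or above 50% of its
#' maximum. Edges are located by linear interpolation; if the profile is
#' still above threshold at the end of the evaluated range, the range edge
#' is used. The definition is recorded on the result as an attribute. The
#' measure is invariant under intensity rescaling.
#'
#' @param x An `intensity_volume`, or a data frame with columns `z` and
#'   `intensity`.
#' @param ... Passed between methods.
#' @return DOF in metres, with attribute `definition = "on_axis_half_max"`.
#' @export
measure_dof <- function(x, ...) UseMethod("measure_dof")

#' @export
measure_dof.intensity_volume <- function(x, ...) {
  measure_dof(on_axis_profile(x), ...)
}

#' @export
measure_dof.data.frame <- function(x, ...) {
  stopifnot(all(c("z", "intensity") %in% names(x)))
  z <- x$z
  v <- x$intensity / max(x$intensity)
  ipk <- which.max(v)
  thr <- 0.5
  if (all(v >= thr)) {
    out <- diff(range(z))
    attr(out, "definition") <- "on_axis_half_max"
    return(out)
  }
  # walk left from the peak
  left <- z[1]
  for (i in seq(ipk, 2L)) {
    if (v[i - 1L] < thr) {
      left <- z[i - 1L] + (z[i] - z[i - 1L]) * (thr - v[i - 1L]) / (v[i] - v[i - 1L])
      break
    }
    if (i == 2L) left <- z[1]
  }
  right <- z[length(z)]
  for (i in seq(ipk, length(z) - 1L)) {
    if (v[i + 1L] < thr) {
      right <- z[i] + (z[i + 1L] - z[i]) * (v[i] - thr) / (v[i] - v[i + 1L])
      break
    }
    if (i == length(z) - 1L) right <- z[length(z)]
  }
  out <- right - left
  attr(out, "definition") <- "on_axis_half_max"
  out
}

#' Afocal telescope scaling
#'
#' An aberration-free telescope of transverse magnification `M` scales
#' transverse lengths by `M`, radial wavevectors by `1/M`, and longitudinal
#' lengths by `M^2` (paraxially). Applied analytically to superposition
#' specs (the scaled `kr` values are re-fed through the exact dispersion
#' relation), to grids (pitch scaling) and to plain lengths.
#'
#' @param x A [superposition_spec()], [mask_grid()], or numeric length(s).
#' @param M Transverse magnification, > 0.
#' @param kind For numeric input: `"transverse"` (x M), `"longitudinal"`
#'   (x M^2) or `"kr"` (/ M).
#' @return Object of the same kind, scaled.
#' @export
telescope_scale <- function(x, M, kind = c("transverse", "longitudinal", "kr")) {
  if (M <= 0) {
    rlang::abort("`M` must be positive.", class = "ssbeam_error_domain")
  }
  UseMethod("telescope_scale")
}

#' @export
telescope_scale.superposition_spec <- function(x, M, ...) {
  superposition_spec(
    x$component_1$amplitude, x$component_1$kr / M,
    x$component_2$amplitude, x$component_2$kr / M,
    x$setup
  )
}

#' @export
telescope_scale.mask_grid <- function(x, M, ...) {
  mask_grid(x$n_x, x$n_y, x$pitch * M)
}

#' @export
telescope_scale.numeric <- function(x, M,
                                    kind = c("transverse", "longitudinal", "kr")) {
  kind <- match.arg(kind)
  switch(kind,
         transverse = x * M,
         longitudinal = x * M^2,
         kr = x / M)
}

#' Write an intensity volume as a multi-page 32-bit float TIFF
#'
#' One page per axial plane, plus a JSON sidecar with the plane coordinates
#' and pixel pitch.
#'
#' @param volume An `intensity_volume`.
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "intensity_volume"))
  pages <- lapply(seq_along(volume$z_planes), function(i) {
    m <- volume$intensity[i, , ]
    m / max(m, 1e-300)
  })
  scale <- vapply(seq_along(volume$z_planes),
                  function(i) max(volume$intensity[i, , ], 1e-300), numeric(1))
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  jsonlite::write_json(
    list(z_planes = volume$z_planes, pitch = volume$grid$pitch,
         page_scale = scale),
    paste0(path, ".json"), digits = NA
  )
  invisible(path)
}
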