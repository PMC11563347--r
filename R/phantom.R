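#' Specification of a synthetic scattering bead phantom
#'
#' Describes an agarose-like block containing a low concentration of
#' fluorescent microspheres and a high concentration of non-fluorescent
#' scatterers. Scattering is treated phenomenologically: the excitation
#' sheet attenuates along the beam axis as `exp(-x / scattering_length)`
#' (Beer-Lambert) and a diffuse haze proportional to the scattered fraction
#' `1 - exp(-x / scattering_length)` is added to the background. Noise is
#' Poisson on the expected photon signal followed by additive Gaussian read
#' noise; everything is seeded.
#'
#' Defaults emulate the imaging-depth comparison conditions: a 480 x 60 x
#' 60 um block (beam along x) at 1 um voxel pitch, 1 um beads, a
#' scattering length of 300 um and a background floor calibrated so the
#' expected bead SNR falls from roughly 2.9 near the surface to roughly
#' 1.4 at 430 um depth.
#'
#' @param volume_size Length-3 numeric (x, y, z extents), metres.
#' @param voxel_pitch Isotropic voxel pitch, metres (default 1 um).
#' @param fluorescent_density Fluorescent beads per cubic metre.
#' @param scatterer_density Non-fluorescent scatterers per cubic metre
#'   (carried in the ground truth; their optical effect is the
#'   `scattering_length`).
#' @param bead_diameter Bead diameter, metres (default 1 um).
#' @param scattering_length Beer-Lambert attenuation length, metres.
#' @param haze_coefficient Haze amplitude relative to the unattenuated bead
#'   peak signal (default 0.19).
#' @param baseline Depth-independent background floor (camera offset plus
#'   matrix autofluorescence) relative to the unattenuated bead peak
#'   (default 0.42).
#' @param gaussian_read_sd Additive read-noise standard deviation, in
#'   intensity units relative to unit bead peak (default 0.01).
#' @param poisson_scale Expected photon count for a unit-intensity voxel
#'   (default 200); larger means less shot noise.
#' @param seed Integer seed.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(volume_size = c(480e-6, 60e-6, 60e-6),
                         voxel_pitch = 1e-6,
                         fluorescent_density = 2e13,
                         scatterer_density = 2e15,
                         bead_diameter = 1e-6,
                         scattering_length = 300e-6,
                         haze_coefficient = 0.19,
                         baseline = 0.42,
                         gaussian_read_sd = 0.01,
                         poisson_scale = 200,
                         seed = 1L) {
  if (any(volume_size <= 0) || voxel_pitch <= 0) {
    rlang::abort("Volume size and voxel pitch must be positive.",
                 class = "ssbeam_error_domain")
  }
  if (fluorescent_density < 0 || scatterer_density < 0) {
    rlang::abort("Densities must be nonnegative.", class = "ssbeam_error_domain")
  }
  if (scattering_length <= 0) {
    rlang::abort("`scattering_length` must be positive.",
                 class = "ssbeam_error_domain")
  }
  structure(
    list(volume_size = volume_size, voxel_pitch = voxel_pitch,
         fluorescent_density = fluorescent_density,
         scatterer_density = scatterer_density,
         bead_diameter = bead_diameter,
         scattering_length = scattering_length,
         haze_coefficient = haze_coefficient,
         baseline = baseline,
         gaussian_read_sd = gaussian_read_sd,
         poisson_scale = poisson_scale,
         seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

with_preserved_rng <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

#' Draw bead positions for a phantom
#'
#' Bead counts are Poisson with mean `density * volume`; positions are
#' uniform over the block. Bit-reproducible for a fixed spec seed.
#'
#' @param spec A [phantom_spec()].
#' @return A tibble with columns `x`, `y`, `z` (metres) and `kind`
#'   (`"fluorescent"` or `"scatterer"`).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  vol <- prod(spec$volume_size)
  with_preserved_rng(spec$seed, {
    n_f <- stats::rpois(1L, spec$fluorescent_density * vol)
    n_s <- stats::rpois(1L, spec$scatterer_density * vol)
    draw <- function(n, kind) {
      tibble::tibble(
        x = stats::runif(n, 0, spec$volume_size[1]),
        y = stats::runif(n, 0, spec$volume_size[2]),
        z = stats::runif(n, 0, spec$volume_size[3]),
        kind = rep(kind, n)
      )
    }
    dplyr::bind_rows(draw(n_f, "fluorescent"), draw(n_s, "scatterer"))
  })
}

#' Render a simulated image stack of a bead phantom
#'
#' Forward model for a light-sheet acquisition of the phantom, beam along
#' `x`, detection along `z`:
#' the expected intensity at voxel `(x, y, z)` is the sum over fluorescent
#' beads of `exp(-x_b / ls)` (excitation attenuation) times a lateral
#' Gaussian blob (bead diameter convolved with the detection lateral PSF)
#' times the system axial response `sheet x detection` evaluated at
#' `z - z_b`, plus a depth-growing haze `haze * (1 - exp(-x / ls))`.
#' Poisson shot noise and Gaussian read noise are then applied, seeded from
#' the spec. Ground-truth bead coordinates are attached losslessly.
#'
#' @param beads Tibble from [generate_phantom()] (scatterers are ignored
#'   for rendering).
#' @param sheet A [sheet_profile()] at the sample plane.
#' @param det A [detection_model()].
#' @param spec The [phantom_spec()].
#' @param noise Apply the noise model (default `TRUE`).
#' @return An object of class `simulated_stack`: `intensity` array
#'   `[x, y, z]`, `pitch`, `beads` (fluorescent ground truth), `spec`.
#' @export
image_phantom <- function(beads, sheet, det, spec, noise = TRUE) {
  stopifnot(is.data.frame(beads), inherits(det, "detection_model"),
            inherits(spec, "phantom_spec"))
  p <- spec$voxel_pitch
  nx <- max(1L, round(spec$volume_size[1] / p))
  ny <- max(1L, round(spec$volume_size[2] / p))
  nz <- max(1L, round(spec$volume_size[3] / p))
  xs <- (seq_len(nx) - 0.5) * p
  ys <- (seq_len(ny) - 0.5) * p
  zs <- (seq_len(nz) - 0.5) * p
  fl <- beads[beads$kind == "fluorescent", , drop = FALSE]
  # lateral blob: bead size convolved with detection lateral PSF (Gaussians)
  fwhm_lat <- sqrt(spec$bead_diameter^2 + det$lateral_fwhm^2)
  sig_lat <- fwhm_lat / (2 * sqrt(2 * log(2)))
  # axial: system response (sheet x detection), interpolated; bead size added
  ax_resp <- sheet$intensity / max(sheet$intensity) *
    detection_axial_profile(det, sheet$z)
  ax_fun <- stats::approxfun(sheet$z, ax_resp / max(ax_resp), yleft = 0,
                             yright = 0)
  expected <- array(0, dim = c(nx, ny, nz))
  ls <- spec$scattering_length
  for (b in seq_len(nrow(fl))) {
    amp <- exp(-fl$x[b] / ls)
    gx <- exp(-(xs - fl$x[b])^2 / (2 * sig_lat^2))
    gy <- exp(-(ys - fl$y[b])^2 / (2 * sig_lat^2))
    # axially the bead (1 um) is much narrower than the system response
    # (several um), so the axial blob is the system response itself,
    # evaluated at the sub-voxel bead position
    gz <- ax_fun(zs - fl$z[b])
    contrib <- outer(gx, gy) %o% gz
    expected <- expected + amp * contrib
  }
  haze <- spec$baseline + spec$haze_coefficient * (1 - exp(-xs / ls))
  expected <- expected + array(rep(haze, times = ny * nz), dim = c(nx, ny, nz))
  out <- if (noise) {
    with_preserved_rng(spec$seed + 1L, {
      counts <- stats::rpois(length(expected),
                             lambda = as.vector(expected) * spec$poisson_scale)
      img <- counts / spec$poisson_scale +
        stats::rnorm(length(expected), 0, spec$gaussian_read_sd)
      array(pmax(img, 0), dim = dim(expected))
    })
  } else {
    expected
  }
  structure(
    list(intensity = out, pitch = p, beads = fl, spec = spec,
         axes = list(x = xs, y = ys, z = zs)),
    class = "simulated_stack"
  )
}

#' @export
print.simulated_stack <- function(x, ...) {
  d <- dim(x$intensity)
  cat(sprintf("<simulated_stack> %d x %d x %d voxels, pitch %.2g m, %d beads\n",
              d[1], d[2], d[3], x$pitch, nrow(x$beads)))
  invisible(x)
}

#' Per-bead peak SNR as a function of imaging depth
#'
#' For each ground-truth fluorescent bead, takes the intensity maximum in a
#' small neighbourhood around the bead and divides by the mean background
#' (voxels in the same depth slab, away from every bead). Used to quantify
#' how scattering degrades the recorded signal with depth.
#'
#' @param stack A [image_phantom()] result.
#' @param neighborhood Half-size of the peak-search cube, voxels (default 3).
#' @param exclusion Radius around beads excluded from background, metres
#'   (default 8 um).
#' @return A tibble with columns `depth` (m) and `snr`, one row per bead,
#'   sorted by depth.
#' @export
snr_vs_depth <- function(stack, neighborhood = 3L, exclusion = 8e-6) {
  stopifnot(inherits(stack, "simulated_stack"))
  d <- dim(stack$intensity)
  xs <- stack$axes$x; ys <- stack$axes$y; zs <- stack$axes$z
  beads <- stack$beads
  purrr::map_dfr(seq_len(nrow(beads)), function(b) {
    ix <- which.min(abs(xs - beads$x[b]))
    iy <- which.min(abs(ys - beads$y[b]))
    iz <- which.min(abs(zs - beads$z[b]))
    rng <- function(i, n) max(1L, i - neighborhood):min(n, i + neighborhood)
    peak <- max(stack$intensity[rng(ix, d[1]), rng(iy, d[2]), rng(iz, d[3])])
    # background: same depth slab, excluding all bead neighbourhoods
    slab <- stack$intensity[rng(ix, d[1]), , , drop = FALSE]
    mask <- array(TRUE, dim = dim(slab))
    for (bb in seq_len(nrow(beads))) {
      if (abs(beads$x[bb] - beads$x[b]) > 3 * exclusion) next
      jy <- which(abs(ys - beads$y[bb]) < exclusion)
      jz <- which(abs(zs - beads$z[bb]) < exclusion)
      if (length(jy) && length(jz)) mask[, jy, jz] <- FALSE
    }
    bg <- slab[mask]
    tibble::tibble(depth = beads$x[b],
                   snr = if (length(bg)) max(peak, 0) / mean(bg) else NA_real_)
  }) |> dplyr::arrange(.data$depth)
}

#' Write a simulated stack as a multi-page 32-bit float TIFF
#'
#' One page per `x` plane, plus the ground-truth bead table as CSV and the
#' spec echo as JSON beside it.
#'
#' @param stack A `simulated_stack`.
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "simulated_stack"))
  mx <- max(stack$intensity, 1e-300)
  pages <- lapply(seq_len(dim(stack$intensity)[1]),
                  function(i) stack$intensity[i, , ] / mx)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  utils::write.csv(
    dplyr::mutate(stack$beads, dplyr::across(c("x", "y", "z"), ~ .x * 1e6)),
    paste0(path, ".beads.csv"), row.names = FALSE
  )
  jsonlite::write_json(
    c(unclass(stack$spec), list(intensity_scale = mx)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
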