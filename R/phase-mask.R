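#' Pixel grid of a phase mask or field
#'
#' Physical pixel geometry of the spatial light modulator (or of any sampled
#' transverse plane): pixel counts and pitch, origin at the grid centre.
#' Coordinates follow the FFT-friendly convention `x = (i - 1 - floor(n/2)) *
#' pitch`, so the pixel at index `floor(n/2) + 1` sits exactly at the origin
#' for both even and odd counts.
#'
#' @param n_x,n_y Pixel counts (default `n_y = n_x`).
#' @param pitch Pixel pitch in metres.
#' @return An object of class `mask_grid`.
#' @export
mask_grid <- function(n_x, n_y = n_x, pitch) {
  if (pitch <= 0) {
    rlang::abort("`pitch` must be positive.", class = "ssbeam_error_domain")
  }
  structure(
    list(n_x = as.integer(n_x), n_y = as.integer(n_y), pitch = pitch),
    class = "mask_grid"
  )
}

#' Centred physical coordinates of a grid axis
#' @keywords internal
grid_axis <- function(n, pitch) {
  (seq_len(n) - 1L - floor(n / 2)) * pitch
}

#' Radial coordinate matrix of a grid (rows = y, cols = x)
#' @keywords internal
grid_rho <- function(grid) {
  x <- grid_axis(grid$n_x, grid$pitch)
  y <- grid_axis(grid$n_y, grid$pitch)
  sqrt(outer(y^2, x^2, `+`))
}

#' Radial wavevector produced by an axicon phase of given opening angle
#'
#' An axicon phase with opening angle `alpha` deflects rays onto a cone,
#' giving a Bessel beam with `kr = k * sin(alpha / 2)`. The half-angle
#' convention is the one under which the printed (angle, wavevector, core
#' radius) triples of the reference design are mutually consistent, e.g.
#' 0.46 degrees maps to 5.17e4 rad/m at 488 nm.
#'
#' @param opening_angle Opening angle in degrees, in (0, 90).
#' @param setup An [optical_setup()].
#' @return `kr` in rad/m.
#' @examples
#' axicon_kr(0.46)  # ~5.17e4 rad/m
#' @export
axicon_kr <- function(opening_angle, setup = optical_setup()) {
  if (any(opening_angle <= 0) || any(opening_angle >= 90)) {
    rlang::abort("`opening_angle` must lie in (0, 90) degrees.",
                 class = "ssbeam_error_domain")
  }
  setup$k * sin(opening_angle / 2 * pi / 180)
}

#' Conical (axicon) phase mask
#'
#' Synthesises the wrapped axicon phase `phi(x, y) = (-kr * rho) mod 2*pi`
#' with `rho = sqrt(x^2 + y^2)`. The radial phase ramp must satisfy the
#' Nyquist condition `kr * pitch < pi` or the sawtooth rings alias.
#'
#' @param grid A [mask_grid()].
#' @param kr Radial wavevector in rad/m (`kr = 0` gives a flat mask).
#' @return An object of class `phase_mask`: fields `grid` and `phase`
#'   (matrix of radians in `[0, 2*pi)`, rows = y, cols = x).
#' @export
axicon_phase <- function(grid, kr) {
  stopifnot(inherits(grid, "mask_grid"))
  if (kr < 0) {
    rlang::abort("`kr` must be nonnegative.", class = "ssbeam_error_domain")
  }
  if (kr * grid$pitch >= pi) {
    rlang::abort(
      sprintf(
        "Axicon ramp aliases: kr * pitch = %.3f >= pi. Reduce the pitch below %.3g m.",
        kr * grid$pitch, pi / kr
      ),
      class = "ssbeam_error_aliasing"
    )
  }
  phase <- (-kr * grid_rho(grid)) %% (2 * pi)
  new_phase_mask(grid, phase)
}

new_phase_mask <- function(grid, phase, meta = list()) {
  structure(list(grid = grid, phase = phase, meta = meta),
            class = "phase_mask")
}

#' @export
print.phase_mask <- function(x, ...) {
  cat(sprintf("<phase_mask> %d x %d px, pitch %.3g m\n",
              x$grid$n_x, x$grid$n_y, x$grid$pitch))
  invisible(x)
}

#' Randomly multiplex two phase masks
#'
#' Combines two phase functions into a single element by assigning each
#' pixel, independently, the value of `mask_a` with probability `weight_a`
#' and of `mask_b` otherwise. Under coherent illumination the far field is
#' approximately the weighted sum of the two single-mask far fields (each
#' axicon contributing its ring at its own `kr`) on top of a speckle
#' background. Deterministic for a fixed `seed`; the seed is recorded in the
#' mask metadata and no global random state is left modified.
#'
#' @param mask_a,mask_b [axicon_phase()] masks on identical grids.
#' @param weight_a Pixel-assignment probability for `mask_a`, in \[0, 1\].
#'   Taken equal to the amplitude weight of the corresponding beam.
#' @param seed Integer seed for the pixel assignment.
#' @return A `phase_mask` whose pixels are drawn from the two inputs.
#' @export
random_multiplex <- function(mask_a, mask_b, weight_a, seed) {
  stopifnot(inherits(mask_a, "phase_mask"), inherits(mask_b, "phase_mask"))
  ga <- mask_a$grid; gb <- mask_b$grid
  if (ga$n_x != gb$n_x || ga$n_y != gb$n_y || ga$pitch != gb$pitch) {
    rlang::abort("Masks must share an identical grid.",
                 class = "ssbeam_error_shape")
  }
  if (weight_a < 0 || weight_a > 1) {
    rlang::abort("`weight_a` must lie in [0, 1].", class = "ssbeam_error_domain")
  }
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
  take_a <- matrix(stats::runif(ga$n_y * ga$n_x) < weight_a, ga$n_y, ga$n_x)
  phase <- ifelse(take_a, mask_a$phase, mask_b$phase)
  new_phase_mask(ga, phase, meta = list(seed = as.integer(seed),
                                        weight_a = weight_a))
}

#' Export a phase mask as a calibrated grayscale image
#'
#' Quantises the wrapped phase to `gray_levels` levels with the linear
#' lookup `g = round(phase / (2*pi) * gray_levels) mod gray_levels` and
#' writes a lossless grayscale image (8-bit PNG for up to 256 levels,
#' 16-bit grayscale TIFF otherwise) plus a JSON metadata sidecar
#' (`<path>.json`) recording the grid pitch, calibration and any
#' multiplexing seed. Re-importing with [read_mask()] reproduces the phase
#' within one gray level (`2*pi / gray_levels` radians).
#'
#' @param mask A `phase_mask`.
#' @param path Output image path (extension `.png` or `.tif`/`.tiff`
#'   according to `gray_levels`).
#' @param gray_levels Number of quantisation levels (default 256; between 2
#'   and 65536).
#' @return `path`, invisibly.
#' @export
export_mask <- function(mask, path, gray_levels = 256L) {
  stopifnot(inherits(mask, "phase_mask"))
  gray_levels <- as.integer(gray_levels)
  if (gray_levels < 2L || gray_levels > 65536L) {
    rlang::abort("`gray_levels` must lie in [2, 65536].",
                 class = "ssbeam_error_domain")
  }
  depth <- if (gray_levels <= 256L) 8L else 16L
  maxval <- 2^depth - 1
  g <- round(mask$phase / (2 * pi) * gray_levels) %% gray_levels
  img <- g / maxval  # writers map [0,1] onto the integer code range
  if (depth == 8L) {
    png::writePNG(img, target = path)
  } else {
    tiff::writeTIFF(img, path, bits.per.sample = 16L)
  }
  meta <- list(
    n_x = mask$grid$n_x, n_y = mask$grid$n_y, pitch = mask$grid$pitch,
    gray_levels = gray_levels, bit_depth = depth,
    calibration = "phase = gray_level / gray_levels * 2*pi",
    seed = mask$meta$seed, weight_a = mask$meta$weight_a
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Import a phase mask written by [export_mask()]
#'
#' @param path Image path (the `<path>.json` sidecar must sit beside it).
#' @return A `phase_mask`.
#' @export
read_mask <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  img <- if (meta$bit_depth == 8L) png::readPNG(path) else tiff::readTIFF(path)
  g <- round(img * (2^meta$bit_depth - 1))
  phase <- g / meta$gray_levels * 2 * pi
  grid <- mask_grid(meta$n_x, meta$n_y, meta$pitch)
  new_phase_mask(grid, phase,
                 meta = list(seed = meta$seed, weight_a = meta$weight_a))
}
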