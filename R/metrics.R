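#' Width of a profile at a relative intensity level
#'
#' Normalises the profile to its maximum and returns the span between two
#' level crossings located by linear interpolation. With `crossing =
#' "innermost"` the crossings immediately bracketing the global peak are
#' used (the central-lobe convention for FWHM); with `"outermost"` the
#' first and last crossings anywhere are used, so sidelobe shoulders above
#' the level extend the width (the convention used for 1/e^2 widths of
#' sidelobed PSFs). The result is invariant to intensity rescaling and to
#' shifts of the coordinate.
#'
#' @param coords Strictly monotone coordinate vector (metres), or a
#'   two-column data frame (coordinates, values) in which case the
#'   remaining arguments shift left by one.
#' @param values Intensity values, same length.
#' @param level Relative level in (0, 1), default 0.5.
#' @param crossing `"innermost"` or `"outermost"`.
#' @return Width in coordinate units.
#' @examples
#' z <- seq(-10, 10, by = 0.01)
#' width_at_level(z, exp(-z^2 / 2), exp(-2), "outermost")  # 4 sigma = 4
#' @export
width_at_level <- function(coords, values = NULL, level = 0.5,
                           crossing = c("innermost", "outermost")) {
  if (is.data.frame(coords)) {  # two-column profile: shift arguments left
    if (!is.null(values)) {
      if (is.character(level)) crossing <- level
      level <- values
    }
    values <- coords[[2L]]
    coords <- coords[[1L]]
  }
  crossing <- match.arg(crossing)
  if (level <= 0 || level >= 1) {
    rlang::abort("`level` must lie strictly between 0 and 1.",
                 class = "ssbeam_error_domain")
  }
  if (any(diff(coords) <= 0)) {
    if (all(diff(coords) < 0)) {  # accept descending coordinates
      coords <- rev(coords); values <- rev(values)
    } else {
      rlang::abort("`coords` must be strictly monotone.",
                   class = "ssbeam_error_shape")
    }
  }
  v <- values / max(values)
  above <- v >= level
  if (!any(!above) || !any(above)) {
    rlang::abort("Profile never crosses the requested level.",
                 class = "ssbeam_error_shape")
  }
  cross_at <- function(i) {  # crossing between samples i and i+1
    coords[i] + (coords[i + 1L] - coords[i]) * (level - v[i]) / (v[i + 1L] - v[i])
  }
  ipk <- which.max(v)
  if (crossing == "innermost") {
    i_left <- NULL
    for (i in seq(ipk - 1L, 1L)) {
      if (ipk == 1L) break
      if (v[i] < level) { i_left <- i; break }
    }
    i_right <- NULL
    for (i in seq(ipk, length(v) - 1L)) {
      if (v[i + 1L] < level) { i_right <- i; break }
    }
    if (is.null(i_left) || is.null(i_right)) {
      rlang::abort("Profile never crosses the level on both sides of the peak.",
                   class = "ssbeam_error_shape")
    }
    cross_at(i_right) - cross_at(i_left)
  } else {
    ups <- which(!above[-length(above)] & above[-1L])
    downs <- which(above[-length(above)] & !above[-1L])
    if (length(ups) == 0L || length(downs) == 0L) {
      rlang::abort("Profile never crosses the level on both sides.",
                   class = "ssbeam_error_shape")
    }
    cross_at(downs[length(downs)]) - cross_at(ups[1L])
  }
}

#' Signal-to-noise ratio: peak signal over mean background
#'
#' `SNR = max(signal) / mean(background)`: the ratio of the intensity
#' maximum to the mean background level.
#'
#' @param signal Numeric vector/array of signal-region intensities.
#' @param background Numeric vector/array of background intensities
#'   (non-empty).
#' @return Dimensionless SNR.
#' @export
snr <- function(signal, background) {
  if (length(background) == 0L) {
    rlang::abort("Background region is empty.", class = "ssbeam_error_domain")
  }
  max(signal) / mean(background)
}

#' Rectangular region of interest
#'
#' @param center Length-2 integer-ish (row, col) centre in pixels.
#' @param width,height Box size in pixels (default 30 x 30).
#' @return An object of class `roi_box`.
#' @export
roi_box <- function(center, width = 30L, height = width) {
  structure(list(center = as.numeric(center),
                 width = as.integer(width), height = as.integer(height)),
            class = "roi_box")
}

roi_indices <- function(box, dims) {
  r0 <- round(box$center[1] - (box$height - 1) / 2)
  c0 <- round(box$center[2] - (box$width - 1) / 2)
  rows <- r0:(r0 + box$height - 1L)
  cols <- c0:(c0 + box$width - 1L)
  if (min(rows) < 1L || min(cols) < 1L || max(rows) > dims[1] || max(cols) > dims[2]) {
    rlang::abort("ROI box extends beyond the image.", class = "ssbeam_error_domain")
  }
  list(rows = rows, cols = cols)
}

#' Contrast-to-noise ratio between two image boxes
#'
#' `CNR = (mean_s - mean_b) / sqrt(var_s + var_b)`: the mean-intensity
#' contrast between a signal box and a background box, normalised by the
#' pooled pixel noise. Antisymmetric under swapping the boxes; the sign is
#' preserved.
#'
#' @param image Numeric matrix (rows, cols).
#' @param signal_box,background_box [roi_box()]es, disjoint, inside the
#'   image.
#' @return Dimensionless CNR.
#' @export
cnr <- function(image, signal_box, background_box) {
  stopifnot(is.matrix(image),
            inherits(signal_box, "roi_box"), inherits(background_box, "roi_box"))
  si <- roi_indices(signal_box, dim(image))
  bi <- roi_indices(background_box, dim(image))
  if (length(intersect(si$rows, bi$rows)) > 0L &&
      length(intersect(si$cols, bi$cols)) > 0L) {
    rlang::abort("Signal and background boxes overlap.",
                 class = "ssbeam_error_domain")
  }
  s <- image[si$rows, si$cols]
  b <- image[bi$rows, bi$cols]
  (mean(s) - mean(b)) / sqrt(stats::var(as.vector(s)) + stats::var(as.vector(b)))
}

#' Oblique stage-scan geometry
#'
#' In an open-top light-sheet system the imaging plane is tilted (default
#' 45 degrees) with respect to the stage travel, so a raw stack indexed by
#' (plane `l`, row `m`, column `n`) is sheared in physical space:
#' `x' = n * pixel_size + l * shear`, `y' = m * pixel_size`,
#' `z' = l * step * sin(tilt)`. The shear per plane is `step * cos(tilt)`;
#' with `literal_shear = TRUE` the variant `pixel_size * sin(tilt)` is
#' used instead (the two coincide when `step == pixel_size` at 45 degrees).
#'
#' @param pixel_size Camera pixel size at the sample, metres.
#' @param step Stage translation per plane, metres.
#' @param tilt_deg Tilt between imaging plane and stage travel (default 45).
#' @param literal_shear Use `pixel_size * sin(tilt)` as the per-plane shear.
#' @return An object of class `scan_geometry`.
#' @export
scan_geometry <- function(pixel_size, step = pixel_size, tilt_deg = 45,
                          literal_shear = FALSE) {
  if (pixel_size <= 0 || step <= 0) {
    rlang::abort("`pixel_size` and `step` must be positive.",
                 class = "ssbeam_error_domain")
  }
  tilt <- tilt_deg * pi / 180
  shear <- if (literal_shear) pixel_size * sin(tilt) else step * cos(tilt)
  structure(
    list(pixel_size = pixel_size, step = step, tilt_deg = tilt_deg,
         shear_per_plane = shear, dz_per_plane = step * sin(tilt),
         literal_shear = literal_shear),
    class = "scan_geometry"
  )
}

#' Physical coordinates of a scan-stack voxel
#'
#' @param l,m,n 0-based plane, row and column indices.
#' @param geom A [scan_geometry()].
#' @return A tibble with columns `xp`, `yp`, `zp` (metres).
#' @export
scan_to_physical <- function(l, m, n, geom) {
  stopifnot(inherits(geom, "scan_geometry"))
  tibble::tibble(
    xp = n * geom$pixel_size + l * geom$shear_per_plane,
    yp = m * geom$pixel_size,
    zp = l * geom$dz_per_plane
  )
}

#' Forward-shear a physical-space volume into scan coordinates
#'
#' Samples a physical-coordinate intensity function at the voxel positions
#' of a tilted stage scan; the synthetic inverse of [affine_unshear()],
#' used for round-trip validation.
#'
#' @param f Function of (xp, yp, zp) metres returning intensity.
#' @param n_planes,n_rows,n_cols Stack dimensions (l, m, n).
#' @param geom A [scan_geometry()].
#' @return Array `[l, m, n]` (0-based indices map per [scan_to_physical()]).
#' @export
forward_shear <- function(f, n_planes, n_rows, n_cols, geom) {
  out <- array(0, dim = c(n_planes, n_rows, n_cols))
  for (l in seq_len(n_planes) - 1L) {
    xp <- (seq_len(n_cols) - 1L) * geom$pixel_size + l * geom$shear_per_plane
    yp <- (seq_len(n_rows) - 1L) * geom$pixel_size
    zp <- l * geom$dz_per_plane
    out[l + 1L, , ] <- outer(yp, xp, function(y, x) f(x, y, zp))
  }
  out
}

#' Resample a tilted stage-scan stack onto orthogonal physical axes
#'
#' Inverts the shear of [scan_geometry()]: each output voxel at physical
#' `(x', y', z')` is looked up at plane `l = z' / dz_per_plane`, column
#' `n = (x' - l * shear) / pixel_size`, row `m = y' / pixel_size`, with
#' bilinear interpolation in `(l, n)` (the `y'` axis maps one-to-one and is
#' untouched). Voxels that fall outside the acquired stack are `NA`.
#'
#' @param stack Array `[l, m, n]`.
#' @param geom A [scan_geometry()].
#' @param z_spacing Output z' spacing (default `dz_per_plane`).
#' @return A list of class `physical_volume`: `intensity` array
#'   `[z', y', x']`, plus the axis spacings.
#' @export
affine_unshear <- function(stack, geom, z_spacing = geom$dz_per_plane) {
  stopifnot(inherits(geom, "scan_geometry"), length(dim(stack)) == 3L)
  d <- dim(stack)
  n_planes <- d[1]; n_rows <- d[2]; n_cols <- d[3]
  x_max <- (n_cols - 1L) * geom$pixel_size +
    (n_planes - 1L) * geom$shear_per_plane
  z_max <- (n_planes - 1L) * geom$dz_per_plane
  xs <- seq(0, x_max, by = geom$pixel_size)
  zs <- seq(0, z_max, by = z_spacing)
  out <- array(NA_real_, dim = c(length(zs), n_rows, length(xs)))
  for (iz in seq_along(zs)) {
    lf <- zs[iz] / geom$dz_per_plane
    l0 <- floor(lf); wl <- lf - l0
    if (l0 > n_planes - 1L || l0 < 0) next
    l1 <- min(l0 + 1L, n_planes - 1L)
    for (ix in seq_along(xs)) {
      interp_plane <- function(l, w) {
        if (w == 0 && l > n_planes - 1L) return(rep(NA_real_, n_rows))
        nf <- (xs[ix] - l * geom$shear_per_plane) / geom$pixel_size
        n0 <- floor(nf); wn <- nf - n0
        if (n0 < 0 || n0 > n_cols - 1L) return(rep(NA_real_, n_rows))
        n1 <- min(n0 + 1L, n_cols - 1L)
        (1 - wn) * stack[l + 1L, , n0 + 1L] + wn * stack[l + 1L, , n1 + 1L]
      }
      p0 <- interp_plane(l0, 1 - wl)
      p1 <- if (wl > 0) interp_plane(l1, wl) else p0
      out[iz, , ix] <- (1 - wl) * p0 + wl * p1
    }
  }
  structure(
    list(intensity = out,
         x_spacing = geom$pixel_size, y_spacing = geom$pixel_size,
         z_spacing = z_spacing),
    class = "physical_volume"
  )
}
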