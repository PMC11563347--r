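test_that("width_at_level matches closed-form shapes", {
  # unit triangle of base B: half-max width B/2
  x <- seq(-1, 1, by = 0.001)
  tri <- pmax(1 - abs(x), 0)
  expect_equal(width_at_level(x, tri, 0.5, "innermost"), 1, tolerance = 1e-6)
  # Gaussian at 1/e^2: 4 sigma
  sigma <- 2.5
  z <- seq(-20, 20, by = 0.01)
  gau <- exp(-z^2 / (2 * sigma^2))
  expect_equal(width_at_level(z, gau, exp(-2), "outermost"), 4 * sigma,
               tolerance = 1e-4)
  # invariance to rescaling and coordinate shift
  expect_equal(width_at_level(z + 3, 7 * gau, 0.5, "innermost"),
               width_at_level(z, gau, 0.5, "innermost"))
  # data-frame interface with shifted arguments
  expect_equal(width_at_level(data.frame(z = z, v = gau), exp(-2), "outermost"),
               4 * sigma, tolerance = 1e-4)
  expect_error(width_at_level(z, gau + 2, 0.5), class = "ssbeam_error_shape")
})

test_that("innermost and outermost conventions differ exactly on shoulders", {
  z <- seq(-15, 15, by = 0.01)
  core <- exp(-z^2 / (2 * 1.5^2))
  shoulders <- 0.2 * (exp(-(z - 7)^2 / (2 * 0.8^2)) + exp(-(z + 7)^2 / (2 * 0.8^2)))
  prof <- core + shoulders
  w_in <- width_at_level(z, prof, 0.5, "innermost")
  w_out <- width_at_level(z, prof, exp(-2), "outermost")
  # innermost@0.5 sees only the core; outermost@0.1353 includes the bumps
  expect_lt(w_in, 4)
  expect_gt(w_out, 14)
})

test_that("snr is the peak-to-mean-background ratio", {
  expect_equal(snr(rep(3, 10), rep(3, 50)), 1)
  expect_equal(snr(c(2, 10, 1), rep(2, 100)), 5)
  expect_error(snr(1:3, numeric(0)), class = "ssbeam_error_domain")
})

test_that("cnr matches its closed form on synthetic Gaussian fields", {
  set.seed(4)
  img <- matrix(stats::rnorm(300 * 300, 5, 1), 300, 300)
  img[16:135, 16:135] <- stats::rnorm(120 * 120, 10, 1)
  sbox <- roi_box(c(75, 75), 120)
  bbox <- roi_box(c(225, 225), 120)
  v <- cnr(img, sbox, bbox)
  expect_equal(v, 5 / sqrt(2), tolerance = 0.02)
  expect_equal(cnr(img, bbox, sbox), -v)       # antisymmetry
  expect_equal(cnr(img, roi_box(c(225, 75), 120), bbox), 0, tolerance = 0.1)
  expect_error(cnr(img, sbox, roi_box(c(80, 80), 120)),
               class = "ssbeam_error_domain")
  expect_error(cnr(img, sbox, roi_box(c(295, 295), 30)),
               class = "ssbeam_error_domain")
})

test_that("SSBB phantom yields higher CNR than BB phantom on the same seed", {
  det <- detection_model()
  spec <- telescope_scale(ref_spec(), 4.8 / 60)
  sheet_ss <- beam_sheet_profile(spec, n = 1201L)
  sheet_bb <- beam_sheet_profile(2.404826 / spec$core_radius,
                                 half_window = 10 * spec$core_radius,
                                 n = 1201L)
  # in-plane labelled structure larger than the signal box, plus a sparse
  # lattice of out-of-plane beads whose light leaks into the imaged plane
  # through the sheet's axial sidelobes and roughens the background
  inplane <- expand.grid(x = seq(27.5e-6, 46.5e-6, by = 1e-6),
                         y = seq(5.5e-6, 24.5e-6, by = 1e-6))
  lattice <- expand.grid(x = seq(2.5e-6, 56.5e-6, by = 6e-6),
                         y = seq(3.5e-6, 27.5e-6, by = 6e-6))
  offsets <- rep(c(-12e-6, -8e-6, -5e-6, 5e-6, 8e-6, 12e-6),
                 length.out = nrow(lattice))
  beads <- dplyr::bind_rows(
    tibble::tibble(x = inplane$x, y = inplane$y, z = 25.5e-6,
                   kind = "fluorescent"),
    tibble::tibble(x = lattice$x, y = lattice$y, z = 25.5e-6 + offsets,
                   kind = "fluorescent")
  )
  cnr_for <- function(sheet) {
    pspec <- phantom_spec(volume_size = c(60e-6, 30e-6, 50e-6),
                          fluorescent_density = 0, poisson_scale = 5000,
                          seed = 17L)
    st <- image_phantom(beads, sheet, det, pspec)
    cnr(st$intensity[, , 26], roi_box(c(37, 15), 14), roi_box(c(10, 15), 14))
  }
  expect_gt(cnr_for(sheet_ss), cnr_for(sheet_bb))
})

test_that("scan geometry maps indices to physical coordinates as specified", {
  geom <- scan_geometry(pixel_size = 0.5e-6, step = 0.5e-6)
  # single plane l = 0: pure pixel-size scaling, no shear
  p0 <- scan_to_physical(0, 0:3, 0:3, geom)
  expect_equal(p0$xp, (0:3) * 0.5e-6)
  expect_equal(p0$yp, (0:3) * 0.5e-6)
  expect_true(all(p0$zp == 0))
  # successive planes shift x' by exactly one shear step
  pa <- scan_to_physical(1, 0, 0, geom)
  pb <- scan_to_physical(2, 0, 0, geom)
  expect_equal(pb$xp - pa$xp, geom$shear_per_plane)
  expect_equal(geom$shear_per_plane, 0.5e-6 * cos(pi / 4))
  # the literal-formula variant coincides when step == pixel size at 45 deg
  lit <- scan_geometry(0.5e-6, 0.5e-6, literal_shear = TRUE)
  expect_equal(lit$shear_per_plane, geom$shear_per_plane)
})

test_that("forward shear then unshear recovers bead positions within a voxel", {
  geom <- scan_geometry(pixel_size = 0.5e-6, step = 0.5e-6)
  beads <- list(c(10e-6, 5e-6, 4e-6), c(6.5e-6, 2.5e-6, 7e-6))
  f <- function(x, y, z) {
    v <- 0
    for (b in beads) {
      v <- v + exp(-((x - b[1])^2 + (y - b[2])^2 + (z - b[3])^2) / (2 * (0.8e-6)^2))
    }
    v
  }
  stack <- forward_shear(f, n_planes = 30, n_rows = 24, n_cols = 48, geom)
  vol <- affine_unshear(stack, geom)
  for (b in beads) {
    iz <- round(b[3] / vol$z_spacing) + 1L
    iy <- round(b[2] / vol$y_spacing) + 1L
    ix <- round(b[1] / vol$x_spacing) + 1L
    # the recovered maximum in a small neighbourhood sits within one voxel
    nb <- vol$intensity[
      max(1, iz - 3):min(dim(vol$intensity)[1], iz + 3),
      max(1, iy - 3):min(dim(vol$intensity)[2], iy + 3),
      max(1, ix - 3):min(dim(vol$intensity)[3], ix + 3)
    ]
    peak <- which(nb == max(nb, na.rm = TRUE), arr.ind = TRUE)[1, ]
    expect_lte(max(abs(peak - 4)), 1)
  }
})
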