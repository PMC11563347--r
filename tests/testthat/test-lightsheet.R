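test_that("projection along the scan axis behaves like a line integral", {
  y <- seq(-10, 10, length.out = 201) * 1e-6
  z <- seq(-8, 8, length.out = 161) * 1e-6
  # separable intensity: the projection must be proportional to g(z)
  fy <- exp(-y^2 / (2e-6)^2)
  gz <- exp(-z^2 / (3e-6)^2)
  S <- scanned_sheet_profile(outer(fy, gz), y, z)
  expect_equal(S$intensity, gz / max(gz), tolerance = 1e-12)
  # window guard
  expect_error(scanned_sheet_profile(outer(fy, gz), y, z, y_window = c(-1, 1)),
               class = "ssbeam_error_domain")
})

test_that("projection raises relative sidelobes for both beam families", {
  M <- 4.8 / 60
  spec <- telescope_scale(ref_spec(), M)
  kr_bb <- 2.404826 / spec$core_radius
  lobe_ratio <- function(z, I) {
    tab <- sidelobe_table(radial_profile(z[z >= 0], I[z >= 0]))
    tab$relative_intensity[1]
  }
  # pointwise (beam) versus projected (sheet) first sidelobe, plain Bessel
  sh_bb <- beam_sheet_profile(kr_bb, n = 1201L)
  point_bb <- lobe_ratio(sh_bb$z, besselJ(kr_bb * abs(sh_bb$z), 0)^2)
  sheet_bb <- lobe_ratio(sh_bb$z, sh_bb$intensity)
  expect_gt(sheet_bb, point_bb)   # 16.2% pointwise grows substantially
  expect_gt(sheet_bb, 0.3)
  # SSBB sheet keeps its first lobe well below the BB sheet's
  sh_ss <- beam_sheet_profile(spec, n = 1201L)
  sheet_ss <- lobe_ratio(sh_ss$z, sh_ss$intensity)
  expect_lt(sheet_ss, sheet_bb / 2)
})

test_that("sheet thickness matches closed forms and the sample-plane design", {
  z <- seq(-30, 30, length.out = 2401) * 1e-6
  sigma <- 4e-6
  g <- sheet_profile(z, exp(-z^2 / (2 * sigma^2)))
  expect_equal(sheet_thickness(g), 2 * sqrt(2 * log(2)) * sigma,
               tolerance = 1e-5)
  expect_equal(sheet_thickness(sheet_profile(z, 5 * exp(-z^2 / (2 * sigma^2)) / 5)),
               sheet_thickness(g))
  # the 60 um design telescoped to a 4.8 um core gives a ~4.8 um sheet
  spec <- telescope_scale(ref_spec(), 4.8 / 60)
  th <- sheet_thickness(beam_sheet_profile(spec, n = 2001L))
  expect_equal(th, 4.8e-6, tolerance = 0.1)
})

test_that("Gaussian sheet DOF reproduces the matched-thickness table", {
  expect_equal(gaussian_sheet_dof(4.8e-6) * 1e6, 296, tolerance = 5e-3)
  expect_equal(gaussian_sheet_thickness(540e-6) * 1e6, 6.5, tolerance = 5e-3)
  # exact round trip and quadratic scaling
  for (w in c(2e-6, 4.8e-6, 9e-6)) {
    expect_equal(gaussian_sheet_thickness(gaussian_sheet_dof(w)), w)
    expect_equal(gaussian_sheet_dof(2 * w), 4 * gaussian_sheet_dof(w))
  }
})

test_that("detection axial model has the expected width and symmetry", {
  det <- detection_model(0.367, 520e-9, 1.33)
  expect_equal(det$axial_fwhm, 10.27e-6, tolerance = 1e-3)
  expect_equal(detection_axial_profile(det, 0), 1)
  z <- seq(0, 20e-6, length.out = 50)
  expect_equal(detection_axial_profile(det, z), detection_axial_profile(det, -z))
  expect_equal(detection_axial_profile(det, det$axial_fwhm / 2), 0.5)
  expect_error(detection_model(1.4, medium_index = 1.33),
               class = "ssbeam_error_domain")
})

test_that("system PSF shows the documented BB/SSBB width ordering", {
  M <- 4.8 / 60
  spec <- telescope_scale(ref_spec(), M)
  det <- detection_model()
  sh_ss <- beam_sheet_profile(spec, n = 1601L)
  sh_bb <- beam_sheet_profile(2.404826 / spec$core_radius,
                              half_window = 10 * spec$core_radius, n = 1601L)
  psf_ss <- system_axial_psf(sh_ss, det)
  psf_bb <- system_axial_psf(sh_bb, det)
  w_ss <- glance(psf_ss)
  w_bb <- glance(psf_bb)
  # 1/e^2 width strictly smaller for the SSBB; FWHMs within ~25%
  expect_lt(w_ss$width_1e2, w_bb$width_1e2)
  expect_lt(abs(w_ss$fwhm - w_bb$fwhm) / w_bb$fwhm, 0.25)
  # BB keeps its first-ring shoulder (|z| ~ 7 um) above the 1/e^2 level,
  # the SSBB does not; the width ratio shows the same ordering against the
  # shoulder-free Gaussian reference 4 sigma / FWHM = 1.70
  at7 <- function(psf) stats::approx(psf$z, psf$response, xout = 7e-6)$y
  expect_gt(at7(psf_bb), exp(-2))
  expect_lt(at7(psf_ss), exp(-2))
  expect_gt(w_bb$width_1e2 / w_bb$fwhm, w_ss$width_1e2 / w_ss$fwhm)
  expect_gt(w_ss$width_1e2 / w_ss$fwhm, 4 / (2 * sqrt(2 * log(2))))
  # a uniform sheet hands back the detection profile under the product model
  z <- seq(-20, 20, length.out = 801) * 1e-6
  flat_sheet <- sheet_profile(z, rep(1, length(z)))
  psf_d <- system_axial_psf(flat_sheet, det)
  expect_equal(psf_d$response, detection_axial_profile(det, z), tolerance = 1e-12)
})

test_that("Richardson-Lucy conserves flux, sharpens, and respects a delta PSF", {
  z <- seq_len(301)
  truth <- ifelse(z == 151, 1, 0)
  sigma <- 8
  psf <- exp(-(z - 151)^2 / (2 * sigma^2))
  psf <- psf / sum(psf)
  observed <- Re(stats::fft(stats::fft(truth) *
                              stats::fft(psf[c(151:301, 1:150)]), inverse = TRUE)) / 301
  observed <- pmax(observed, 0)
  dec <- richardson_lucy_1d(observed, psf, iterations = 10L)
  expect_true(all(dec >= 0))
  expect_equal(sum(dec), sum(observed), tolerance = 1e-6)
  w_obs <- width_at_level(z, observed, 0.5, "innermost")
  w_dec <- width_at_level(z, dec, 0.5, "innermost")
  expect_lt(w_dec, w_obs)
  # delta PSF: identity at any iteration count
  delta <- ifelse(z == 151, 1, 0)
  expect_equal(richardson_lucy_1d(observed, delta, 7L), observed,
               tolerance = 1e-10)
  expect_error(richardson_lucy_1d(observed, 0 * delta),
               class = "ssbeam_error_domain")
})

test_that("ten RL iterations sharpen the BB PSF and suppress its shoulder", {
  M <- 4.8 / 60
  spec <- telescope_scale(ref_spec(), M)
  det <- detection_model()
  psf_bb <- system_axial_psf(
    beam_sheet_profile(2.404826 / spec$core_radius,
                       half_window = 10 * spec$core_radius, n = 1601L), det)
  dec <- richardson_lucy_1d(psf_bb$response, psf_bb$response, 10L)
  dec <- dec / max(dec)
  dfun <- stats::approxfun(psf_bb$z, dec)
  pfun <- stats::approxfun(psf_bb$z, psf_bb$response)
  # the 7 um first-ring shoulder drops from above 1/e^2 to well below it,
  # and the central lobe narrows
  expect_gt(pfun(7e-6), exp(-2))
  expect_lt(dfun(7e-6), pfun(7e-6))
  expect_lt(dfun(7e-6), exp(-2))
  expect_lt(width_at_level(psf_bb$z, dec, 0.5, "innermost"),
            width_at_level(psf_bb$z, psf_bb$response, 0.5, "innermost"))
})
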