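test_that("plane wave propagates with a pure phase advance", {
  g <- mask_grid(64, pitch = 10e-6)
  setup <- ref_setup()
  u0 <- matrix(1 + 0i, 64, 64)
  f <- field_slice(g, u0, setup = setup)
  dz <- 1e-3
  f2 <- angular_spectrum_propagate(f, dz)
  expect_equal(f2$amplitude, u0 * exp(1i * setup$k * dz), tolerance = 1e-12)
  expect_equal(f2$z, dz)
})

test_that("propagation is unitary in the band and reversible", {
  g <- mask_grid(256, pitch = 4e-3 / 256)
  spec <- ref_spec()
  f0 <- superposition_slice(spec, g)
  f1 <- angular_spectrum_propagate(f0, 10e-3)
  expect_equal(field_power(f1) / field_power(f0), 1, tolerance = 1e-10)
  back <- angular_spectrum_propagate(f1, -10e-3)
  expect_lt(
    max(Mod(back$amplitude - f0$amplitude)) / max(Mod(f0$amplitude)),
    1e-8
  )
})

test_that("numeric propagation of the superposition matches the analytic field", {
  g <- mask_grid(1024, pitch = 8e-3 / 1024)
  spec <- ref_spec()
  zt <- spec$period / 3
  num <- angular_spectrum_propagate(superposition_slice(spec, g), zt)
  ana <- superposition_slice(spec, g, z = zt)
  rho <- sqrt(outer(
    ((seq_len(1024) - 1 - 512) * g$pitch)^2,
    ((seq_len(1024) - 1 - 512) * g$pitch)^2, `+`
  ))
  sel <- rho <= 10 * spec$core_radius
  In <- Mod(num$amplitude)^2
  Ia <- Mod(ana$amplitude)^2
  rms <- sqrt(mean((In[sel] - Ia[sel])^2)) / max(Ia[sel])
  expect_lt(rms, 0.02)
})

test_that("Bessel core is propagation-invariant within its geometric range", {
  g <- mask_grid(512, pitch = 4e-3 / 512)
  kr <- 4.045e4
  spec1 <- superposition_spec(1 - 1e-9, kr, 1e-9, kr * 1.3, ref_setup())
  f0 <- superposition_slice(spec1, g)
  f1 <- angular_spectrum_propagate(f0, 50e-3)
  ic <- floor(512 / 2) + 1L
  measure_core <- function(f) {
    I <- Mod(f$amplitude[ic, ic:512])^2
    r <- (seq_len(513 - ic) - 1) * g$pitch
    i <- which(I < I[1] / 2)[1]  # half-max radius of the core, interpolated
    r[i - 1] + (r[i] - r[i - 1]) * (I[i - 1] - I[1] / 2) / (I[i - 1] - I[i])
  }
  expect_equal(measure_core(f1), measure_core(f0), tolerance = 0.02)
})

test_that("sidelobe suppression survives propagation to P/6", {
  g <- mask_grid(1024, pitch = 8e-3 / 1024)
  spec <- ref_spec()
  f <- angular_spectrum_propagate(superposition_slice(spec, g), spec$period / 6)
  ic <- floor(1024 / 2) + 1L
  I <- Mod(f$amplitude[ic, ic:1024])^2
  r <- (seq_len(1025 - ic) - 1) * g$pitch
  keep <- r <= 10 * spec$core_radius
  tab <- sidelobe_table(radial_profile(r[keep], I[keep]))
  expect_lte(max(tab$relative_intensity[1:2]), 0.07)
})

test_that("Gaussian-axicon source reproduces the closed-form depth of focus", {
  # On-axis intensity of a Gaussian-illuminated axicon follows
  # I(z) ~ z * exp(-2 z^2 tan(a/2)^2 / w^2); its half-max support is
  # 0.803 * w / tan(a/2) (roots of u e^(-2u^2) = e^(-1/2)/4).
  g <- mask_grid(512, pitch = 8e-3 / 512)
  kr <- axicon_kr(0.36)
  waist <- 0.55e-3
  src <- gaussian_apodized_source(g, waist, axicon_phase(g, kr))
  vol <- propagate_volume(src, seq(5e-3, 280e-3, by = 5e-3))
  dof <- measure_dof(vol)
  tan_half <- tan(0.18 * pi / 180)
  expect_equal(as.numeric(dof), 0.803 * waist / tan_half, tolerance = 0.05)
  expect_equal(attr(dof, "definition"), "on_axis_half_max")
  # doubling the waist doubles the depth of focus (geometric scaling)
  g2 <- mask_grid(512, pitch = 16e-3 / 512)
  src2 <- gaussian_apodized_source(g2, 2 * waist, axicon_phase(g2, kr))
  vol2 <- propagate_volume(src2, seq(10e-3, 560e-3, by = 10e-3))
  expect_equal(as.numeric(measure_dof(vol2)) / as.numeric(dof), 2,
               tolerance = 0.08)
  # waist too large for the window is refused
  expect_error(gaussian_apodized_source(g, 3e-3), class = "ssbeam_error_domain")
})

test_that("measure_dof matches boxcar and Lorentzian oracles", {
  z <- seq(0, 100, by = 0.25)
  boxcar <- as.numeric(z >= 20 & z <= 60) + 1e-9
  expect_equal(as.numeric(measure_dof(tibble::tibble(z = z, intensity = boxcar))),
               40, tolerance = 0.01)
  # Gaussian-focus axial profile 1 / (1 + (z/zR)^2): half max at z = +-zR
  zR <- 7
  zz <- seq(-50, 50, by = 0.05)
  lor <- 1 / (1 + (zz / zR)^2)
  expect_equal(as.numeric(measure_dof(tibble::tibble(z = zz, intensity = lor))),
               2 * zR, tolerance = 1e-3)
  # invariant under intensity rescaling
  expect_equal(
    as.numeric(measure_dof(tibble::tibble(z = zz, intensity = 37 * lor))),
    as.numeric(measure_dof(tibble::tibble(z = zz, intensity = lor)))
  )
})

test_that("telescope scaling acts on lengths, wavevectors and specs", {
  spec <- ref_spec()
  expect_equal(telescope_scale(spec, 1)$core_radius, spec$core_radius)
  M <- 4.8 / 60
  sc <- telescope_scale(spec, M)
  expect_equal(sc$core_radius, spec$core_radius * M, tolerance = 1e-12)
  expect_equal(sc$component_2$kr, spec$component_2$kr / M)
  # longitudinal lengths scale by M^2 up to the paraxial correction
  # (kr/k)^2/4 ~ 0.2% at this magnification
  expect_equal(sc$period, spec$period * M^2, tolerance = 5e-3)
  # sample-plane landmarks: scaled beat period ~0.57 mm, near the quoted
  # ~0.54 mm sheet DOF; scaled BB half-max DOF ~1.1 mm vs quoted ~1.4 mm
  expect_equal(sc$period * 1e3, 0.574, tolerance = 5e-3)
  expect_equal(telescope_scale(175e-3, M, kind = "longitudinal") * 1e3, 1.12,
               tolerance = 1e-2)
  expect_equal(telescope_scale(60e-6, M, kind = "transverse"), 4.8e-6)
  expect_equal(telescope_scale(5.17e4, M, kind = "kr"), 5.17e4 / M)
  expect_equal(telescope_scale(mask_grid(64, pitch = 1e-5), 0.5)$pitch, 5e-6)
})
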