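# ssbeam

Design and simulation of **sidelobe-suppressed Bessel beams (SSBB)** for
one-photon light-sheet fluorescence microscopy.

Bessel beams make excellent light-sheets — a narrow core that survives a
long propagation range — but their concentric sidelobes (16.2% and 9.0% of
the core intensity for the first two rings of J0²) excite out-of-plane
fluorescence and destroy contrast in one-photon imaging. An SSBB is the
coherent superposition of two Bessel beams,

    SP(r, z) = A1 J0(kr1 r) exp(i kz1 z) + A2 J0(kr2 r) exp(i kz2 z),
    kzi = sqrt(k^2 − kri^2),

with amplitudes and radial wavevectors chosen so the two ring systems
cancel over a radial band while the cores add. The cancellation recurs
along the axis with beat period `P = 2π/|kz1 − kz2|`, which takes the role
of the depth of focus.

The package covers the full workflow, for microscopists and optical
engineers who want to design, verify, and evaluate such beams without
touching hardware:

* **Closed-form optics** — wavevectors, core radii (`r0 = 2.405/kr`, and
  `2.405/(A1·kr1 + A2·kr2)` for the composite), beat periods, field
  evaluation, sidelobe tables.
* **Constrained design** — `solve_design()` minimizes the band-integrated
  intensity `∫∫ |SP(r,z)|² dr dz` over `[r0, 10 r0] × [0, P/3]` with
  `A1 + A2 = 1`, a fixed core radius and a fixed ratio `kr1/kr2`, reduced
  to a deterministic 1-D search over `A1`.
* **Phase masks** — axicon phases (`kr = k sin(α/2)`), seeded random
  multiplexing of two axicons into one SLM element, calibrated PNG/TIFF
  export with JSON sidecars.
* **Diffraction verification** — band-limited angular-spectrum propagation
  (unitary in band, reversible), depth-of-focus measurement, telescope
  scaling to the sample plane.
* **Light-sheet & PSF** — scanned-sheet profiles, sheet thickness,
  Gaussian-sheet DOF (`2π w0²/λ`), detection-axial model, system axial
  PSF with FWHM/1-e² widths, 1-D Richardson–Lucy deconvolution.
* **Synthetic phantoms & metrics** — seeded scattering bead phantoms
  (Beer–Lambert attenuation + haze + Poisson/read noise), SNR-vs-depth,
  CNR box protocol, and the 45° stage-scan affine unshear.

## Worked example

```r
library(ssbeam)

# the reference 488 nm design: 60 um core, two beams at ratio 0.57
spec <- superposition_spec(0.525, 2.95e4, 0.475, 5.17e4)
spec
#> <superposition_spec>
#>   A1 = 0.5250, kr1 = 2.95e+04 rad/m (kz1 = 12875346 rad/m)
#>   A2 = 0.4750, kr2 = 5.17e+04 rad/m (kz2 = 12875276 rad/m)
#>   core radius = 60.05 um, beat period = 89.75 mm

head(sidelobe_table(superposition_profile(spec)), 3)
#> # A tibble: 3 × 2
#>      radius relative_intensity
#>       <dbl>              <dbl>
#> 1 0.0000911             0.0394
#> 2 0.000178              0.0130
#> 3 0.000251              0.0593
```

The first two sidelobes carry 3.9% and 1.3% of the core intensity —
compared with 16.2% and 9.0% for a plain Bessel beam of the same core
radius — and the suppression window `P/3` is about 30 mm. Scaling to the
sample plane and folding in the detection objective:

```r
det <- detection_model()                      # NA 0.367, 520 nm, water
sample_spec <- telescope_scale(spec, 4.8/60)  # 60 um core -> 4.8 um
glance(system_axial_psf(beam_sheet_profile(sample_spec), det))
#> # A tibble: 1 × 2
#>         fwhm  width_1e2
#>        <dbl>      <dbl>
#> 1 0.00000448 0.00000918
```

The SSBB system PSF is 4.5 µm at half max and 9.2 µm at 1/e²; the matching
Bessel-beam sheet gives 5.2 µm and 14.3 µm — nearly the same resolution,
but a much smaller sidelobe skirt. A Gaussian sheet of the same 4.8 µm
thickness would hold focus for only `gaussian_sheet_dof(4.8e-6)` ≈ 297 µm,
and would need to thicken to 6.5 µm to match the SSBB's axial range.

Each result type has `autoplot()`; design fits have `tidy()`/`glance()`;
`run_pipeline()` executes design → masks → PSF → phantom → metrics from a
YAML config, and `inst/cli/ssbeam.R` wraps the same functions for shell
use.

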