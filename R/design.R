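#' Constrained SSBB design problem
#'
#' Describes the sidelobe-suppression design search: at a fixed target core
#' radius and radial-wavevector ratio `rho = kr1/kr2`, the amplitude split
#' `A1` is the single free parameter (see [solve_design()]). The objective
#' integrates the composite intensity over a radial band (in units of the
#' core radius) and an axial band (as fractions of the beat period).
#'
#' @param setup An [optical_setup()].
#' @param target_core_radius Desired composite core radius, metres
#'   (default 60 um).
#' @param wavevector_ratio Fixed ratio `kr1/kr2` in (0, 1) (default 0.57).
#' @param radial_band Length-2 numeric, band in units of the core radius
#'   (default `c(1, 10)`); the lower edge must be `>= 1` so the central lobe
#'   is excluded.
#' @param z_band Length-2 numeric, band as fractions of the beat period in
#'   `[0, 1]` (default `c(0, 1/3)`).
#' @param n_r,n_z Quadrature resolution (defaults 2000 x 200).
#' @return An object of class `design_problem`.
#' @export
design_problem <- function(setup = optical_setup(),
                           target_core_radius = 60e-6,
                           wavevector_ratio = 0.57,
                           radial_band = c(1, 10),
                           z_band = c(0, 1 / 3),
                           n_r = 2000L, n_z = 200L) {
  stopifnot(inherits(setup, "optical_setup"))
  if (wavevector_ratio <= 0 || wavevector_ratio >= 1) {
    rlang::abort("`wavevector_ratio` must lie strictly between 0 and 1.",
                 class = "ssbeam_error_domain")
  }
  if (radial_band[1] < 1 || radial_band[2] <= radial_band[1]) {
    rlang::abort("`radial_band` must be increasing with lower edge >= 1 (in r0 units).",
                 class = "ssbeam_error_domain")
  }
  if (z_band[1] < 0 || z_band[2] > 1 || z_band[2] < z_band[1]) {
    rlang::abort("`z_band` must lie within [0, 1] (fractions of the period).",
                 class = "ssbeam_error_domain")
  }
  structure(
    list(
      setup = setup,
      target_core_radius = target_core_radius,
      wavevector_ratio = wavevector_ratio,
      radial_band = radial_band,
      z_band = z_band,
      n_r = as.integer(n_r),
      n_z = as.integer(n_z)
    ),
    class = "design_problem"
  )
}

#' Candidate superposition for a given amplitude split
#'
#' Applies the two design constraints in closed form: `A2 = 1 - A1` and the
#' core-radius relation `r0 = 2.405 / (A1 kr1 + A2 kr2)` with `kr1 = rho *
#' kr2`, which yields `kr2 = 2.405 / (r0 (A1 rho + 1 - A1))`. Every
#' candidate therefore satisfies both constraints exactly by construction.
#'
#' @param problem A [design_problem()].
#' @param A1 Amplitude of the low-`kr` component, in (0, 1).
#' @return A [superposition_spec()].
#' @export
candidate_spec <- function(problem, A1) {
  stopifnot(inherits(problem, "design_problem"))
  rho <- problem$wavevector_ratio
  r0 <- problem$target_core_radius
  kr2 <- J0_FIRST_ZERO / (r0 * (A1 * rho + (1 - A1)))
  kr1 <- rho * kr2
  superposition_spec(A1, kr1, 1 - A1, kr2, problem$setup)
}

# trapezoidal weights on a uniform grid
trapezoid_weights <- function(x) {
  n <- length(x)
  if (n == 1L) return(1)
  w <- rep(x[2] - x[1], n)
  w[c(1L, n)] <- w[1L] / 2
  w
}

#' Sidelobe-suppression objective
#'
#' Numerical quadrature of the composite intensity over the design bands:
#' `integral |SP(r, z)|^2 dr dz` for `r` in `[r_lo * r0, r_hi * r0]` and `z`
#' in `[z_lo * P, z_hi * P]`. The radial measure is `dr` as the objective is
#' written; an energy-weighted `r dr` variant is available via `weight`.
#' Trapezoidal quadrature on uniform grids; the separable structure of
#' `|SP|^2` (two Bessel factors and one axial cosine) is exploited so the
#' cost is linear in `n_r + n_z`.
#'
#' A degenerate axial band (`z_lo == z_hi`) is interpreted as the
#' single-plane radial line integral at that plane (unit axial weight)
#' rather than a measure-zero integral.
#'
#' @param spec A [superposition_spec()].
#' @param problem A [design_problem()].
#' @param weight Radial measure, `"dr"` (default) or `"rdr"`.
#' @param normalize If `TRUE`, divide by the band area so the value is a
#'   band-averaged intensity; the default `FALSE` returns the raw integral.
#' @return Nonnegative scalar.
#' @export
suppression_objective <- function(spec, problem, weight = c("dr", "rdr"),
                                  normalize = FALSE) {
  stopifnot(inherits(spec, "superposition_spec"),
            inherits(problem, "design_problem"))
  weight <- match.arg(weight)
  r0 <- spec$core_radius
  P <- spec$period
  kr2 <- spec$component_2$kr
  r_lo <- problem$radial_band[1] * r0
  r_hi <- problem$radial_band[2] * r0
  # require >= 10 samples per Bessel lobe (lobe spacing ~ pi/kr2)
  lobes <- (r_hi - r_lo) * kr2 / pi
  if (problem$n_r < 10 * lobes) {
    rlang::abort(
      sprintf(
        "Quadrature too coarse: %d radial points for ~%.0f lobes; use n_r >= %d.",
        problem$n_r, lobes, ceiling(10 * lobes)
      ),
      class = "ssbeam_error_resolution"
    )
  }
  rr <- seq(r_lo, r_hi, length.out = problem$n_r)
  wr <- trapezoid_weights(rr)
  if (weight == "rdr") wr <- wr * rr
  c1 <- spec$component_1
  c2 <- spec$component_2
  J1 <- besselJ(c1$kr * rr, 0)
  J2 <- besselJ(c2$kr * rr, 0)
  I11 <- sum(J1^2 * wr)
  I22 <- sum(J2^2 * wr)
  I12 <- sum(J1 * J2 * wr)
  dkz <- c1$kz - c2$kz
  z_lo <- problem$z_band[1] * P
  z_hi <- problem$z_band[2] * P
  if (z_lo == z_hi) {           # degenerate band: single-plane line integral
    Z <- 1
    C <- cos(dkz * z_lo)
    area <- r_hi - r_lo
  } else {
    zz <- seq(z_lo, z_hi, length.out = problem$n_z)
    wz <- trapezoid_weights(zz)
    Z <- sum(wz)
    C <- sum(cos(dkz * zz) * wz)
    area <- (r_hi - r_lo) * (z_hi - z_lo)
  }
  A1 <- c1$amplitude
  A2 <- c2$amplitude
  v <- A1^2 * I11 * Z + A2^2 * I22 * Z + 2 * A1 * A2 * I12 * C
  if (normalize) v / area else v
}

#' Solve the constrained sidelobe-suppression design
#'
#' The four-parameter search `(A1, A2, kr1, kr2)` collapses to one dimension
#' once the constraints are enforced (see [candidate_spec()]). The solver
#' evaluates [suppression_objective()] on a 50-point coarse grid over
#' `A1` in `[0.05, 0.95]`, checks unimodality of the sampled trace, then
#' refines by golden-section search ([stats::optimize()]) in the bracketing
#' interval. Fully deterministic.
#'
#' @param problem A [design_problem()].
#' @param weight Radial quadrature measure passed to
#'   [suppression_objective()].
#' @param coarse_n Coarse-grid size (default 50).
#' @param tol Convergence tolerance on `A1` (default 1e-5).
#' @return An object of class `ssbb_design`: fields `spec` (the optimal
#'   [superposition_spec()]), `A1`, `objective_value` (band-averaged),
#'   `trace` (tibble of all evaluations), `problem`.
#' @examples
#' \donttest{
#' fit <- solve_design(design_problem())
#' glance(fit)
#' }
#' @export
solve_design <- function(problem, weight = c("dr", "rdr"),
                         coarse_n = 50L, tol = 1e-5) {
  stopifnot(inherits(problem, "design_problem"))
  weight <- match.arg(weight)
  f <- function(a1) {
    suppression_objective(candidate_spec(problem, a1), problem, weight = weight)
  }
  grid <- seq(0.05, 0.95, length.out = coarse_n)
  vals <- vapply(grid, f, numeric(1))
  imin <- which.min(vals)
  # unimodality of the sampled trace: the sign of the discrete slope should
  # change exactly once
  slope_sign <- sign(diff(vals))
  changes <- sum(diff(slope_sign[slope_sign != 0]) != 0)
  unimodal <- changes <= 1
  if (!unimodal) {
    rlang::warn("Objective trace is not unimodal; returning the global grid minimum refined locally.")
  }
  lo <- grid[max(1L, imin - 1L)]
  hi <- grid[min(length(grid), imin + 1L)]
  opt <- stats::optimize(f, c(lo, hi), tol = tol)
  spec <- candidate_spec(problem, opt$minimum)
  trace <- tibble::tibble(A1 = c(grid, opt$minimum),
                          objective = c(vals, opt$objective),
                          stage = c(rep("coarse", length(grid)), "refined"))
  structure(
    list(
      spec = spec,
      A1 = opt$minimum,
      objective_value = suppression_objective(spec, problem, weight = weight,
                                              normalize = TRUE),
      trace = trace,
      problem = problem,
      weight = weight
    ),
    class = "ssbb_design"
  )
}

#' @export
print.ssbb_design <- function(x, ...) {
  cat(sprintf(
    "<ssbb_design> A1 = %.4f, A2 = %.4f\n  kr1 = %.4g, kr2 = %.4g rad/m\n  core radius = %.2f um, period = %.2f mm\n  band-averaged objective = %.4g\n",
    x$spec$component_1$amplitude, x$spec$component_2$amplitude,
    x$spec$component_1$kr, x$spec$component_2$kr,
    x$spec$core_radius * 1e6, x$spec$period * 1e3, x$objective_value
  ))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an SSBB design fit
#'
#' @param x An `ssbb_design` object.
#' @param ... Unused.
#' @return One row per parameter: `term`, `estimate`, `unit`.
#' @method tidy ssbb_design
#' @export
tidy.ssbb_design <- function(x, ...) {
  tibble::tibble(
    term = c("A1", "A2", "kr1", "kr2", "core_radius", "period"),
    estimate = c(
      x$spec$component_1$amplitude, x$spec$component_2$amplitude,
      x$spec$component_1$kr, x$spec$component_2$kr,
      x$spec$core_radius, x$spec$period
    ),
    unit = c("", "", "rad/m", "rad/m", "m", "m")
  )
}

#' One-row summary of an SSBB design fit
#'
#' @param x An `ssbb_design` object.
#' @param ... Unused.
#' @return A one-row tibble with the optimum, objective value and the
#'   number of objective evaluations.
#' @method glance ssbb_design
#' @export
glance.ssbb_design <- function(x, ...) {
  tibble::tibble(
    A1 = x$A1,
    objective = x$objective_value,
    core_radius = x$spec$core_radius,
    period = x$spec$period,
    n_eval = nrow(x$trace)
  )
}

#' Axial length over which sidelobes stay suppressed
#'
#' The largest `z*` such that for every plane `z` in `[0, z*]` the maximum
#' sidelobe of `|SP(., z)|^2` within the radial band stays at or below
#' `threshold` (relative to the global central-peak intensity over the
#' evaluated range, which for `A1 + A2 = 1` is the `z = 0` on-axis value).
#' Evaluated on a uniform grid of at least 100 planes per period, out to
#' `z_max` (default half a period).
#'
#' `n_lobes` restricts the check to the first `n` sidelobes (counted
#' outward from the core); the default `Inf` checks every lobe in the band.
#'
#' @param spec A [superposition_spec()].
#' @param threshold Relative intensity in (0, 1\].
#' @param radial_band Band in core-radius units (default `c(1, 10)`).
#' @param n_lobes Number of innermost sidelobes inspected (default `Inf`).
#' @param z_max Upper end of the evaluated range, metres (default `P/2`).
#' @param n_z Number of axial planes (default 100 per period, min 100).
#' @param n_r Radial samples (default 4000).
#' @return `z*` in metres; 0 (with a warning) if the threshold is already
#'   exceeded at `z = 0`.
#' @export
suppression_length <- function(spec, threshold,
                               radial_band = c(1, 10), n_lobes = Inf,
                               z_max = spec$period / 2,
                               n_z = max(100L, ceiling(100 * z_max / spec$period)),
                               n_r = 4000L) {
  stopifnot(inherits(spec, "superposition_spec"))
  if (threshold <= 0 || threshold > 1) {
    rlang::abort("`threshold` must lie in (0, 1].", class = "ssbeam_error_domain")
  }
  r0 <- spec$core_radius
  rr <- seq(radial_band[1] * r0, radial_band[2] * r0, length.out = n_r)
  c1 <- spec$component_1
  c2 <- spec$component_2
  J1 <- besselJ(c1$kr * rr, 0)
  J2 <- besselJ(c2$kr * rr, 0)
  dkz <- c1$kz - c2$kz
  peak <- Mod(superposition_field(spec, 0, 0))^2
  zz <- seq(0, z_max, length.out = n_z)
  worst <- vapply(zz, function(z) {
    I <- c1$amplitude^2 * J1^2 + c2$amplitude^2 * J2^2 +
      2 * c1$amplitude * c2$amplitude * J1 * J2 * cos(dkz * z)
    d <- diff(I)
    pk <- which(d[-1] < 0 & d[-length(d)] >= 0) + 1L
    cand <- I[pk]
    if (is.finite(n_lobes)) cand <- utils::head(cand, n_lobes)
    if (length(cand) == 0L) return(0)
    max(cand) / peak
  }, numeric(1))
  bad <- which(worst > threshold)
  if (length(bad) == 0L) return(z_max)
  if (bad[1] == 1L) {
    rlang::warn("Sidelobe threshold exceeded already at z = 0; suppression length is 0.")
    return(0)
  }
  zz[bad[1] - 1L]
}
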