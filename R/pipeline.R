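#' Load and validate a run configuration
#'
#' Reads a YAML configuration with sections mirroring the pipeline stages
#' (`design`, `mask`, `propagation`, `sheet`, `phantom`, `metrics`) plus a
#' global `seed` and `outdir`. Unknown top-level keys are rejected. Numeric
#' keys may carry a unit suffix (`_nm`, `_um`, `_mm`, `_deg`) and are
#' converted to SI on load (`wavelength_nm: 488` becomes
#' `wavelength: 488e-9`); angles stay in degrees with the suffix stripped.
#'
#' @param path YAML file path.
#' @return A named list of class `run_config` (resolved, SI units).
#' @export
load_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- c("design", "mask", "propagation", "sheet", "phantom", "metrics",
             "seed", "outdir")
  extra <- setdiff(names(raw), known)
  if (length(extra)) {
    rlang::abort(paste0("Unknown config keys: ", paste(extra, collapse = ", ")),
                 class = "ssbeam_error_config")
  }
  convert <- function(x) {
    if (!is.list(x)) return(x)
    out <- list()
    for (nm in names(x)) {
      v <- x[[nm]]
      if (is.list(v)) { out[[nm]] <- convert(v); next }
      if (grepl("_nm$", nm) && is.numeric(v)) {
        out[[sub("_nm$", "", nm)]] <- v * 1e-9
      } else if (grepl("_um$", nm) && is.numeric(v)) {
        out[[sub("_um$", "", nm)]] <- v * 1e-6
      } else if (grepl("_mm$", nm) && is.numeric(v)) {
        out[[sub("_mm$", "", nm)]] <- v * 1e-3
      } else if (grepl("_deg$", nm) && is.numeric(v)) {
        out[[sub("_deg$", "", nm)]] <- v
      } else {
        out[[nm]] <- v
      }
    }
    out
  }
  structure(convert(raw), class = "run_config")
}

#' Write a resolved run configuration
#'
#' @param config A `run_config`.
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the design-to-metrics pipeline
#'
#' Executes the stages in order -- design optimization, phase-mask
#' synthesis (single axicon and randomly multiplexed pair), analytic sheet
#' profiles and system PSF at the sample plane, and (optionally) a bead
#' phantom with SNR-versus-depth metrics -- writing every artifact under
#' `outdir` together with the resolved configuration. Deterministic stages
#' are bit-reproducible; stochastic stages (multiplexing, phantom) are
#' reproducible under the global seed.
#'
#' @param config A `run_config` (see [load_run_config()]) or a plain named
#'   list with the same structure; all fields optional.
#' @param outdir Output directory (default from config, else tempdir).
#' @return Invisibly, a named list with the key results (`design`, mask
#'   paths, `psf_bb`, `psf_ssbb`, `snr` tibble if a phantom was run).
#' @export
run_pipeline <- function(config = list(), outdir = NULL) {
  cfg <- unclass(config)
  outdir <- outdir %||% cfg$outdir %||% file.path(tempdir(), "ssbeam-run")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  seed <- cfg$seed %||% 1L
  setup <- optical_setup(
    wavelength = cfg$design$wavelength %||% 488e-9,
    medium_index = cfg$design$medium_index %||% 1
  )

  # -- design ---------------------------------------------------------------
  problem <- design_problem(
    setup = setup,
    target_core_radius = cfg$design$target_core_radius %||% 60e-6,
    wavevector_ratio = cfg$design$wavevector_ratio %||% 0.57,
    radial_band = cfg$design$radial_band %||% c(1, 10),
    z_band = cfg$design$z_band %||% c(0, 1 / 3),
    n_r = cfg$design$n_r %||% 2000L,
    n_z = cfg$design$n_z %||% 200L
  )
  fit <- solve_design(problem)
  jsonlite::write_json(
    list(
      A1 = fit$spec$component_1$amplitude,
      A2 = fit$spec$component_2$amplitude,
      kr1 = fit$spec$component_1$kr, kr2 = fit$spec$component_2$kr,
      core_radius_m = fit$spec$core_radius,
      core_radius_um = fit$spec$core_radius * 1e6,
      period_m = fit$spec$period, period_mm = fit$spec$period * 1e3,
      objective = fit$objective_value
    ),
    file.path(outdir, "design.json"), auto_unbox = TRUE, digits = NA
  )
  utils::write.csv(fit$trace, file.path(outdir, "design_trace.csv"),
                   row.names = FALSE)

  # -- masks ----------------------------------------------------------------
  grid <- mask_grid(cfg$mask$n %||% 512L, pitch = cfg$mask$pitch %||% 12.5e-6)
  spec_use <- if (isTRUE(cfg$design$use_fit)) {
    fit$spec
  } else {
    superposition_spec(cfg$design$A1 %||% 0.525, cfg$design$kr1 %||% 2.95e4,
                       1 - (cfg$design$A1 %||% 0.525),
                       cfg$design$kr2 %||% 5.17e4, setup)
  }
  kr_bb <- J0_FIRST_ZERO / spec_use$core_radius
  mask_bb <- axicon_phase(grid, kr_bb)
  mask_a <- axicon_phase(grid, spec_use$component_1$kr)
  mask_b <- axicon_phase(grid, spec_use$component_2$kr)
  mask_ssbb <- random_multiplex(mask_a, mask_b,
                                spec_use$component_1$amplitude, seed = seed)
  export_mask(mask_bb, file.path(outdir, "mask_bb.png"))
  export_mask(mask_ssbb, file.path(outdir, "mask_ssbb.png"))

  # -- sheet profiles and system PSF at the sample plane --------------------
  M <- cfg$sheet$magnification %||% 0.08
  spec_sample <- telescope_scale(spec_use, M)
  det <- detection_model(
    numerical_aperture = cfg$sheet$numerical_aperture %||% 0.367,
    wavelength_em = cfg$sheet$wavelength_em %||% 520e-9,
    medium_index = cfg$sheet$medium_index %||% 1.33
  )
  sheet_ssbb <- beam_sheet_profile(spec_sample)
  sheet_bb <- beam_sheet_profile(kr_bb / M,
                                 half_window = 10 * spec_sample$core_radius)
  psf_ssbb <- system_axial_psf(sheet_ssbb, det)
  psf_bb <- system_axial_psf(sheet_bb, det)
  psf_report <- dplyr::bind_rows(
    dplyr::mutate(glance(psf_bb), beam = "BB"),
    dplyr::mutate(glance(psf_ssbb), beam = "SSBB")
  )
  utils::write.csv(psf_report, file.path(outdir, "psf_widths.csv"),
                   row.names = FALSE)

  # -- phantom (optional) ---------------------------------------------------
  snr_tbl <- NULL
  if (isTRUE(cfg$phantom$enabled %||% FALSE)) {
    pspec <- phantom_spec(seed = seed)
    beads <- generate_phantom(pspec)
    stack <- image_phantom(beads, sheet_ssbb, det, pspec)
    write_stack(stack, file.path(outdir, "phantom_ssbb.tif"))
    snr_tbl <- snr_vs_depth(stack)
    utils::write.csv(snr_tbl, file.path(outdir, "snr_vs_depth.csv"),
                     row.names = FALSE)
  }

  write_run_config(structure(cfg, class = "run_config"),
                   file.path(outdir, "config_resolved.yaml"))
  invisible(list(design = fit, outdir = outdir,
                 masks = c(bb = file.path(outdir, "mask_bb.png"),
                           ssbb = file.path(outdir, "mask_ssbb.png")),
                 psf_bb = psf_bb, psf_ssbb = psf_ssbb,
                 psf_widths = psf_report, snr = snr_tbl))
}
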