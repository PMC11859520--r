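#' Parameters of a synthetic lake absorption spectrum
#'
#' The lake presets and user-defined waters are generated as a pure-water
#' baseline plus a CDOM-like exponential decay referenced to 400 nm plus two
#' Gaussian chlorophyll-a pigment peaks at 440 and 675 nm. When
#' `anchor_mu_a_800` is set, the non-water components are rescaled by a
#' common factor so the total absorption at 800 nm equals the anchor exactly.
#'
#' @param cdom_amplitude CDOM absorption at 400 nm, m^-1, >= 0.
#' @param cdom_slope CDOM exponential slope, nm^-1, > 0.
#' @param pigment_peak_amplitudes peak amplitudes (m^-1) at 440 and 675 nm.
#' @param pigment_peak_widths Gaussian sigma (nm) of the two peaks.
#' @param anchor_mu_a_800 optional total absorption at 800 nm to pin, m^-1.
#' @return a `lake_spectrum_params` object.
#' @export
lake_spectrum_params <- function(cdom_amplitude, cdom_slope,
                                 pigment_peak_amplitudes = c(0, 0),
                                 pigment_peak_widths = c(30, 15),
                                 anchor_mu_a_800 = NULL) {
  stopifnot(length(pigment_peak_amplitudes) == 2L,
            length(pigment_peak_widths) == 2L)
  if (cdom_amplitude < 0 || any(pigment_peak_amplitudes < 0))
    stop("amplitudes must be >= 0")
  if (cdom_slope <= 0) stop("cdom_slope must be > 0")
  if (any(pigment_peak_widths <= 0)) stop("pigment_peak_widths must be > 0")
  structure(list(cdom_amplitude = cdom_amplitude, cdom_slope = cdom_slope,
                 pigment_peak_amplitudes = pigment_peak_amplitudes,
                 pigment_peak_widths = pigment_peak_widths,
                 anchor_mu_a_800 = anchor_mu_a_800),
            class = "lake_spectrum_params")
}

# non-water component (CDOM + pigment peaks), before any anchor rescale
.lake_nonwater <- function(params, wavelength_nm) {
  cdom <- params$cdom_amplitude *
    exp(-params$cdom_slope * (wavelength_nm - 400))
  peaks <- params$pigment_peak_amplitudes[1] *
    exp(-0.5 * ((wavelength_nm - 440) / params$pigment_peak_widths[1])^2) +
    params$pigment_peak_amplitudes[2] *
    exp(-0.5 * ((wavelength_nm - 675) / params$pigment_peak_widths[2])^2)
  cdom + peaks
}

#' Synthetic lake absorption spectrum
#'
#' Total absorption = pure-water baseline + CDOM exponential + pigment peaks,
#' with the non-water part rescaled to hit `anchor_mu_a_800` exactly when the
#' anchor is set. The 750 nm absorption shoulder always comes from the
#' pure-water table, never from the synthetic components.
#'
#' @param params a [lake_spectrum_params()].
#' @param wavelength_nm wavelength grid, nm.
#' @return absorption coefficients, m^-1.
#' @export
synth_lake_absorption <- function(params, wavelength_nm) {
  stopifnot(inherits(params, "lake_spectrum_params"))
  wl <- as.numeric(wavelength_nm)
  water <- iop_at(pure_water_iop(sort(unique(c(wl, 800)))), wl)$mu_a
  nonwater <- .lake_nonwater(params, wl)
  if (!is.null(params$anchor_mu_a_800)) {
    water800 <- iop_at(pure_water_iop(c(750, 800)), 800)$mu_a
    excess <- params$anchor_mu_a_800 - water800
    if (excess < 0)
      stop(sprintf("anchor %g m^-1 at 800 nm is below the pure-water absorption %g m^-1",
                   params$anchor_mu_a_800, water800))
    nonwater800 <- .lake_nonwater(params, 800)
    if (nonwater800 <= 0 && excess > 0)
      stop("cannot anchor: non-water absorption vanishes at 800 nm")
    scale <- if (excess == 0) 0 else excess / nonwater800
    nonwater <- scale * nonwater
  }
  water + nonwater
}

#' Synthetic woody-debris absorption spectrum
#'
#' A smooth exponential decline over 400-800 nm, mu_a(lambda) =
#' level * 350 * exp(-(lambda - 400)/400) m^-1 (3.5 cm^-1 at 400 nm,
#' 1.3 cm^-1 at 800 nm at the default level), in the range published for
#' degraded hardwood: strongly absorbing relative to water everywhere in the
#' band while leaving the fixed 35 cm^-1 reduced scattering dominant, which
#' is what makes submerged debris a bright target in clear water.
#'
#' @param wavelength_nm wavelength grid, nm.
#' @param level positive scale factor (spectrum is exactly linear in it).
#' @return absorption coefficients, m^-1.
#' @export
synth_wood_absorption <- function(wavelength_nm, level = 1) {
  if (!is.finite(level) || level <= 0) stop("level must be > 0")
  level * 350 * exp(-(as.numeric(wavelength_nm) - 400) / 400)
}

#' Small test scenes with matching sweep settings
#'
#' Ready-made scenes for unit tests and quick experiments: `tiny` is a
#' 1 x 1 x 1 m box at 0.05 m voxels with one cylinder at 0.4 m depth;
#' `small` is a 5 x 5 x 8 m box at 0.05 m voxels with three cylinders at
#' 2, 5 and 7.5 m.
#'
#' @param size_class `"tiny"` or `"small"`.
#' @param water water preset name for the scene medium.
#' @param C chlorophyll concentration, mg m^-3.
#' @param wavelength_nm wavelength grid carried by the scene's media.
#' @return a list with elements `scene` (a [voxel_scene()]) and `sweep`
#'   (a [sweep_spec()] sized for quick runs).
#' @export
fixture_scene <- function(size_class = c("tiny", "small"), water = "pure",
                          C = 1, wavelength_nm = seq(400, 800, 50)) {
  size_class <- match.arg(size_class)
  if (size_class == "tiny") {
    extent <- c(1, 1, 1)
    cyls <- list(cylinder_spec(0.5, 0.4, 0.2, 1L))
  } else {
    extent <- c(5, 5, 8)
    cyls <- list(cylinder_spec(1.25, 2.0, 0.2, 1L),
                 cylinder_spec(2.50, 5.0, 0.2, 2L),
                 cylinder_spec(3.75, 7.5, 0.2, 3L))
  }
  wood <- wood_iop(wavelength_nm)
  media <- c(list("0" = lake_water_iop(water, C, wavelength_nm)),
             stats::setNames(rep(list(wood), length(cyls)),
                             vapply(cyls, function(s) as.character(s$medium_label), "")))
  scene <- build_lake_scene(extent = extent, voxel_size = 0.05,
                            cylinders = cyls, media = media)
  sweep <- sweep_spec(wavelengths = c(450, 550, 800), water = water,
                      C_values = C, n_photons = 2e4, base_seed = 1)
  list(scene = scene, sweep = sweep)
}
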