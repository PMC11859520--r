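#' Inherent optical property spectrum of one medium
#'
#' Bundles the wavelength-resolved absorption coefficient, scattering
#' coefficient, scattering anisotropy and refractive index of a single medium.
#' All coefficients are stored in SI units (m^-1); use [coef_to_per_m()] when
#' constructing from cm^-1 sources.
#'
#' @param wavelength_nm strictly increasing wavelengths in nanometers.
#' @param mu_a absorption coefficients, m^-1, one per wavelength.
#' @param mu_s scattering coefficients, m^-1, one per wavelength.
#' @param g scattering anisotropy (mean cosine of the single-scattering
#'   deflection angle); a scalar or one value per wavelength, in \[-1, 1\].
#' @param refractive_index real refractive index, >= 1.
#' @return an object of class `iop_spectrum`.
#' @seealso [pure_water_iop()], [lake_water_iop()], [wood_iop()], [iop_at()]
#' @export
iop_spectrum <- function(wavelength_nm, mu_a, mu_s, g, refractive_index = 1.33) {
  wavelength_nm <- as.numeric(wavelength_nm)
  mu_a <- as.numeric(mu_a)
  mu_s <- as.numeric(mu_s)
  g <- as.numeric(g)
  n <- length(wavelength_nm)
  if (n < 1) stop("iop_spectrum needs at least one wavelength")
  if (any(!is.finite(wavelength_nm)) || any(diff(wavelength_nm) <= 0))
    stop("wavelengths must be finite and strictly increasing")
  if (length(mu_a) != n || length(mu_s) != n)
    stop("mu_a and mu_s must have one value per wavelength")
  if (!(length(g) %in% c(1L, n)))
    stop("g must be a scalar or one value per wavelength")
  if (any(!is.finite(mu_a)) || any(mu_a < 0)) stop("mu_a must be finite and >= 0")
  if (any(!is.finite(mu_s)) || any(mu_s < 0)) stop("mu_s must be finite and >= 0")
  if (any(!is.finite(g)) || any(g < -1) || any(g > 1)) stop("g must lie in [-1, 1]")
  if (!is.finite(refractive_index) || refractive_index < 1)
    stop("refractive_index must be >= 1")
  structure(
    list(wavelength_nm = wavelength_nm, mu_a = mu_a, mu_s = mu_s,
         g = g, refractive_index = refractive_index),
    class = "iop_spectrum")
}

#' @export
print.iop_spectrum <- function(x, ...) {
  rng <- range(x$wavelength_nm)
  cat(sprintf("<iop_spectrum> %g-%g nm (%d points), n = %g\n",
              rng[1], rng[2], length(x$wavelength_nm), x$refractive_index))
  cat(sprintf("  mu_a: %.4g-%.4g m^-1, mu_s: %.4g-%.4g m^-1, g: %s\n",
              min(x$mu_a), max(x$mu_a), min(x$mu_s), max(x$mu_s),
              if (length(x$g) == 1L) format(x$g) else
                sprintf("%.3g-%.3g", min(x$g), max(x$g))))
  invisible(x)
}

#' Interpolate an IOP spectrum at requested wavelengths
#'
#' Linear interpolation of mu_a, mu_s and (if per-wavelength) g. Requesting a
#' wavelength outside the spectrum's range is an error naming the offending
#' value, never an extrapolation.
#'
#' @param iop an [iop_spectrum()].
#' @param wavelength_nm wavelengths to evaluate at.
#' @return a list with elements `wavelength_nm`, `mu_a`, `mu_s`, `g`,
#'   `refractive_index`.
#' @export
iop_at <- function(iop, wavelength_nm) {
  stopifnot(inherits(iop, "iop_spectrum"))
  wl <- as.numeric(wavelength_nm)
  rng <- range(iop$wavelength_nm)
  bad <- wl < rng[1] | wl > rng[2]
  if (any(bad))
    stop(sprintf("wavelength %g nm outside the spectrum range [%g, %g] nm",
                 wl[which(bad)[1]], rng[1], rng[2]))
  interp1 <- function(y) {
    if (length(iop$wavelength_nm) == 1L) rep(y, length(wl))
    else approx(iop$wavelength_nm, y, xout = wl)$y
  }
  g <- if (length(iop$g) == 1L) rep(iop$g, length(wl)) else interp1(iop$g)
  list(wavelength_nm = wl, mu_a = interp1(iop$mu_a), mu_s = interp1(iop$mu_s),
       g = g, refractive_index = iop$refractive_index)
}

# cached bundled pure-water table
.pw_env <- new.env(parent = emptyenv())

pure_water_table <- function() {
  if (is.null(.pw_env$tab)) {
    path <- system.file("extdata", "pure_water_hale_querry_1973.tsv",
                        package = "borealmc", mustWork = TRUE)
    .pw_env$tab <- read.table(path, header = TRUE, comment.char = "#")
  }
  .pw_env$tab
}

#' Pure-water inherent optical properties
#'
#' Absorption from the bundled table derived from the Hale & Querry (1973)
#' imaginary refractive index of water (mu_a = 4 pi k / lambda), scattering
#' from the molecular (density-fluctuation) law 0.0037 (450/lambda)^4.32 m^-1,
#' both linearly interpolated onto the requested grid. Water absorption rises
#' steeply into the near infrared, with a local shoulder near 750 nm that
#' shapes the contrast dips seen in lake imagery. The anisotropy is set to the
#' lake-water value 0.924 so that this spectrum is exactly the zero-chlorophyll
#' limit of [lake_water_iop()]; the tiny molecular mu_s makes the choice of g
#' physically inconsequential.
#'
#' @param wavelength_nm requested wavelengths, within the table's 300-1000 nm.
#' @return an [iop_spectrum()] with refractive index 1.33.
#' @examples
#' pure_water_iop(800)$mu_a  # ~1.96 m^-1
#' @export
pure_water_iop <- function(wavelength_nm) {
  tab <- pure_water_table()
  wl <- sort(unique(as.numeric(wavelength_nm)))
  bad <- wl < min(tab$wavelength_nm) | wl > max(tab$wavelength_nm)
  if (any(bad))
    stop(sprintf("wavelength %g nm outside the bundled pure-water table range [%g, %g] nm",
                 wl[which(bad)[1]], min(tab$wavelength_nm), max(tab$wavelength_nm)))
  iop_spectrum(
    wavelength_nm = wl,
    mu_a = approx(tab$wavelength_nm, tab$mu_a_m, xout = wl)$y,
    mu_s = approx(tab$wavelength_nm, tab$mu_s_m, xout = wl)$y,
    g = 0.924, refractive_index = 1.33)
}

#' Chlorophyll scattering coefficient of lake water
#'
#' Total scattering of lake water as the pure-water molecular term plus a
#' chlorophyll-particle term that scales as the 0.62 power of concentration
#' and falls off inversely with wavelength relative to 550 nm:
#' mu_s(lambda, C) = mu_s_PW(lambda) + (550/lambda) * 0.30 * C^0.62, in m^-1.
#' At C = 0 this returns the pure-water scattering exactly.
#'
#' @param wavelength_nm wavelength(s) in nm, > 0.
#' @param C chlorophyll concentration in mg m^-3, >= 0 (scalar).
#' @param mu_s_pw optional pure-water scattering coefficient(s) in m^-1; by
#'   default interpolated from the bundled table.
#' @return scattering coefficient(s) in m^-1.
#' @examples
#' chlorophyll_scattering(550, 10) - chlorophyll_scattering(550, 0) # 0.30 * 10^0.62
#' @export
chlorophyll_scattering <- function(wavelength_nm, C, mu_s_pw = NULL) {
  if (any(wavelength_nm <= 0)) stop("wavelength must be positive")
  if (length(C) != 1L || !is.finite(C) || C < 0)
    stop("chlorophyll concentration C must be a single value >= 0")
  if (is.null(mu_s_pw))
    mu_s_pw <- iop_at(pure_water_iop(sort(unique(wavelength_nm))),
                      wavelength_nm)$mu_s
  mu_s_pw + (550 / wavelength_nm) * 0.30 * C^0.62
}

# documented constants behind the four boreal-lake presets; non-water
# absorption is rescaled at run time so mu_a(800 nm) hits the anchor exactly.
.lake_presets <- list(
  LAN = list(cdom_amplitude = 2,  cdom_slope = 0.004,
             pigment_peak_amplitudes = c(0.1, 0.05),
             anchor_mu_a_800 = 2.8,
             description = "lake Antu Sinijarv: low phytoplankton"),
  LPA = list(cdom_amplitude = 5,  cdom_slope = 0.005,
             pigment_peak_amplitudes = c(0.5, 0.25),
             anchor_mu_a_800 = 3.1,
             description = "lake Paijanne: intermediate-low phytoplankton"),
  LVO = list(cdom_amplitude = 12, cdom_slope = 0.006,
             pigment_peak_amplitudes = c(1.2, 0.6),
             anchor_mu_a_800 = 3.4,
             description = "lake Vortsjarv: intermediate-high phytoplankton"),
  LVA = list(cdom_amplitude = 25, cdom_slope = 0.007,
             pigment_peak_amplitudes = c(2.0, 1.0),
             anchor_mu_a_800 = 3.8,
             description = "lake Valkekotinen: high phytoplankton"))

#' Built-in water presets
#'
#' Named absorption presets for the simulated waters: `pure` (bundled
#' pure-water table) and four boreal-lake stand-ins `LAN`, `LPA`, `LVO`,
#' `LVA` ordered by increasing phytoplankton level. Lake presets are
#' synthetic spectra (pure-water baseline + CDOM exponential + pigment
#' peaks, see [synth_lake_absorption()]) pinned so that the LAN and LVA
#' absorption at 800 nm equals the published anchors 2.8 and 3.8 m^-1
#' (0.028 and 0.038 cm^-1) exactly; the LPA/LVO anchors 3.1 and 3.4 m^-1
#' are interpolated stand-ins.
#'
#' @param name one of `"pure"`, `"LAN"`, `"LPA"`, `"LVO"`, `"LVA"`.
#' @return a `water_preset` object: name, description and (for lakes) the
#'   [lake_spectrum_params()] driving the synthetic generator.
#' @export
water_preset <- function(name) {
  valid <- c("pure", names(.lake_presets))
  if (!is.character(name) || length(name) != 1L || !(name %in% valid))
    stop(sprintf("unknown water preset %s; valid presets: %s",
                 deparse(substitute(name)), paste(valid, collapse = ", ")))
  if (name == "pure") {
    params <- NULL
    descr <- "pure water (no phytoplankton), bundled Hale & Querry table"
  } else {
    p <- .lake_presets[[name]]
    params <- lake_spectrum_params(
      cdom_amplitude = p$cdom_amplitude, cdom_slope = p$cdom_slope,
      pigment_peak_amplitudes = p$pigment_peak_amplitudes,
      anchor_mu_a_800 = p$anchor_mu_a_800)
    descr <- p$description
  }
  structure(list(name = name, params = params, description = descr),
            class = "water_preset")
}

#' @export
print.water_preset <- function(x, ...) {
  cat(sprintf("<water_preset> %s: %s\n", x$name, x$description))
  invisible(x)
}

#' Lake-water inherent optical properties
#'
#' Combines a water preset's absorption spectrum with chlorophyll scattering
#' at concentration `C` ([chlorophyll_scattering()]) and the forward-peaked
#' lake-water anisotropy g = 0.924.
#'
#' @param preset a preset name or [water_preset()] object.
#' @param C chlorophyll concentration, mg m^-3.
#' @param wavelength_nm wavelength grid, nm.
#' @return an [iop_spectrum()].
#' @examples
#' iop_at(lake_water_iop("LAN", C = 10, seq(400, 800, 50)), 800)$mu_a  # 2.8
#' @export
lake_water_iop <- function(preset, C, wavelength_nm) {
  if (is.character(preset)) preset <- water_preset(preset)
  stopifnot(inherits(preset, "water_preset"))
  wl <- sort(unique(as.numeric(wavelength_nm)))
  if (preset$name == "pure") {
    pw <- pure_water_iop(wl)
    mu_a <- pw$mu_a
  } else {
    mu_a <- synth_lake_absorption(preset$params, wl)
  }
  mu_s_pw <- iop_at(pure_water_iop(wl), wl)$mu_s
  mu_s <- chlorophyll_scattering(wl, C, mu_s_pw = mu_s_pw)
  iop_spectrum(wl, mu_a, mu_s, g = 0.924, refractive_index = 1.33)
}

#' Henyey-Greenstein phase function over the deflection cosine
#'
#' p(cos theta) = (1/2) (1 - g^2) / (1 + g^2 - 2 g cos theta)^(3/2),
#' normalized so its integral over cos theta in \[-1, 1\] is 1. g = 0 gives
#' the isotropic density 1/2; the mean cosine of the density equals g.
#'
#' @param cos_theta deflection cosine(s) in \[-1, 1\].
#' @param g asymmetry parameter, |g| < 1.
#' @return density values.
#' @export
hg_phase_density <- function(cos_theta, g) {
  if (!is.finite(g) || abs(g) >= 1) stop("|g| must be < 1")
  if (any(abs(cos_theta) > 1)) stop("|cos_theta| must be <= 1")
  0.5 * (1 - g^2) / (1 + g^2 - 2 * g * cos_theta)^1.5
}

#' Draw Henyey-Greenstein deflection samples
#'
#' Samples the deflection cosine by the closed-form inverse transform of the
#' Henyey-Greenstein CDF, cos theta = (1 + g^2 - ((1-g^2)/(1-g+2gu))^2)/(2g)
#' (and 2u - 1 in the isotropic limit), with an independent uniform azimuth
#' on \[0, 2 pi).
#'
#' @param n number of samples (ignored when `u` is supplied).
#' @param g asymmetry parameter, |g| < 1.
#' @param u optional uniform deviates in \[0, 1) driving the deflection
#'   cosine, for deterministic use.
#' @param azimuth_u optional uniform deviates driving the azimuth.
#' @return a data.frame with columns `cos_theta` and `azimuth`.
#' @examples
#' hg_sample(1, 0, u = 0.5)$cos_theta  # exactly 0
#' @export
hg_sample <- function(n, g, u = NULL, azimuth_u = NULL) {
  if (!is.finite(g) || abs(g) >= 1) stop("|g| must be < 1")
  if (is.null(u)) u <- runif(n) else n <- length(u)
  if (is.null(azimuth_u)) azimuth_u <- runif(n)
  if (abs(g) < 1e-12) {
    ct <- 2 * u - 1
  } else {
    tmp <- (1 - g^2) / (1 - g + 2 * g * u)
    ct <- (1 + g^2 - tmp^2) / (2 * g)
  }
  data.frame(cos_theta = pmin(1, pmax(-1, ct)),
             azimuth = 2 * pi * azimuth_u)
}

#' Anisotropy factor of a phase density
#'
#' Quadrature of cos theta * p(cos theta) over \[-1, 1\]. The density must be
#' normalized: an integral deviating from 1 by more than `tol` is rejected.
#'
#' @param p a function of the deflection cosine returning density values.
#' @param tol normalization tolerance (default 1e-6).
#' @return the mean deflection cosine g.
#' @export
anisotropy_from_phase <- function(p, tol = 1e-6) {
  norm <- integrate(p, -1, 1, rel.tol = 1e-10, abs.tol = 1e-12)$value
  if (abs(norm - 1) > tol)
    stop(sprintf("phase density is not normalized: integral = %.8g", norm))
  integrate(function(x) x * p(x), -1, 1, rel.tol = 1e-10, abs.tol = 1e-12)$value
}

#' Reduced scattering coefficient
#'
#' mu_s' = mu_s (1 - g), the isotropic-equivalent scattering rate used to
#' describe photon diffusion after many forward-peaked scattering events.
#'
#' @param mu_s scattering coefficient, m^-1, >= 0.
#' @param g anisotropy in \[-1, 1\].
#' @return mu_s' in m^-1.
#' @export
reduced_scattering <- function(mu_s, g) {
  if (any(mu_s < 0)) stop("mu_s must be >= 0")
  if (any(abs(g) > 1)) stop("|g| must be <= 1")
  mu_s * (1 - g)
}

#' Woody-debris (degraded chestnut) inherent optical properties
#'
#' The debris reduced scattering coefficient is fixed at 3500 m^-1 (35 cm^-1)
#' across 400-800 nm, realized as mu_s = mu_s' / (1 - g_wood) with the
#' similarity relation; absorption comes from a user spectrum table when
#' given, otherwise from the bundled synthetic chestnut-like spectrum
#' ([synth_wood_absorption()]), which decreases with wavelength.
#'
#' @param wavelength_nm wavelength grid, nm.
#' @param mu_a_table optional absorption source: a path to a spectrum table
#'   file ([read_spectrum_table()]) or a data.frame with columns
#'   `wavelength_nm` and `value` plus a `units` attribute (default m^-1).
#' @param g_wood anisotropy assigned to wood scattering (default 0.9).
#' @param level scale factor for the default absorption spectrum.
#' @return an [iop_spectrum()] with refractive index 1.33 (matched to water,
#'   since waterlogged debris has no strong index step).
#' @export
wood_iop <- function(wavelength_nm, mu_a_table = NULL, g_wood = 0.9, level = 1) {
  wl <- sort(unique(as.numeric(wavelength_nm)))
  if (!is.finite(g_wood) || abs(g_wood) >= 1) stop("|g_wood| must be < 1")
  mu_s_prime <- 3500  # m^-1, flat over 400-800 nm
  mu_s <- mu_s_prime / (1 - g_wood)
  if (is.null(mu_a_table)) {
    mu_a <- synth_wood_absorption(wl, level = level)
  } else {
    tab <- if (is.character(mu_a_table)) read_spectrum_table(mu_a_table) else mu_a_table
    units <- attr(tab, "units")
    val <- coef_to_per_m(tab$value, if (is.null(units)) "m^-1" else units)
    if (nrow(tab) == 1L) {
      mu_a <- rep(val, length(wl))
    } else {
      rng <- range(tab$wavelength_nm)
      bad <- wl < rng[1] | wl > rng[2]
      if (any(bad))
        stop(sprintf("wavelength %g nm outside the supplied wood absorption table range [%g, %g] nm",
                     wl[which(bad)[1]], rng[1], rng[2]))
      mu_a <- approx(tab$wavelength_nm, val, xout = wl)$y
    }
  }
  iop_spectrum(wl, mu_a, rep(mu_s, length(wl)), g = g_wood,
               refractive_index = 1.33)
}
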