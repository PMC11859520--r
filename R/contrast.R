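#' Reflectance image
#'
#' Wraps a surface reflectance grid (escaped-upward weight per surface pixel)
#' with its pixel pitch and provenance. Accepts a `sim_result` or a bare
#' matrix.
#'
#' @param x a `sim_result` from [run_transport()] or a numeric matrix.
#' @param pixel_size pixel pitch in m (taken from the result when omitted).
#' @param normalized whether `values` are max-normalized.
#' @param wavelength_nm,seed optional provenance (filled from a result).
#' @return a `reflectance_image`: list with `values`, `pixel_size`,
#'   `normalized`, `wavelength_nm`, `seed`.
#' @export
reflectance_image <- function(x, pixel_size = NULL, normalized = FALSE,
                              wavelength_nm = NA_real_, seed = NA_integer_) {
  if (inherits(x, "sim_result")) {
    values <- x$reflectance
    pixel_size <- x$pixel_size
    wavelength_nm <- x$wavelength_nm
    seed <- x$seed
  } else {
    values <- as.matrix(x)
    if (is.null(pixel_size)) stop("pixel_size is required for a bare matrix")
  }
  if (any(values < 0)) stop("reflectance values must be >= 0")
  if (normalized && nrow(values) && max(values) != 1)
    stop("normalized images must have maximum 1")
  structure(list(values = values, pixel_size = pixel_size,
                 normalized = normalized, wavelength_nm = wavelength_nm,
                 seed = seed),
            class = "reflectance_image")
}

#' Max-normalize a reflectance image
#'
#' Divides by the image maximum (as displayed spectral images are) and sets
#' the `normalized` flag. Contrast is a ratio of intensities, so
#' normalization never changes any contrast value.
#'
#' @param image a [reflectance_image()].
#' @return the normalized image.
#' @export
normalize_image <- function(image) {
  stopifnot(inherits(image, "reflectance_image"))
  m <- max(image$values)
  if (m <= 0) stop("cannot normalize an all-zero image")
  image$values <- image$values / m
  image$normalized <- TRUE
  image
}

#' Intensity profile across the X dimension
#'
#' Per-X mean intensity over a central band of Y rows (default the central
#' 50% of Y), the cross-debris profile that contrast is read from.
#'
#' @param image a [reflectance_image()].
#' @param band_frac fraction of the Y extent averaged over, centered.
#' @return a data.frame with columns `x_m` (pixel centers) and `intensity`.
#' @export
intensity_profile <- function(image, band_frac = 0.5) {
  stopifnot(inherits(image, "reflectance_image"))
  v <- image$values
  if (!nrow(v) || !ncol(v)) stop("empty image")
  stopifnot(band_frac > 0, band_frac <= 1)
  ny <- ncol(v)
  nband <- max(1L, round(band_frac * ny))
  j0 <- floor((ny - nband) / 2) + 1L
  band <- j0:(j0 + nband - 1L)
  data.frame(x_m = (seq_len(nrow(v)) - 0.5) * image$pixel_size,
             intensity = rowMeans(v[, band, drop = FALSE]))
}

#' Michelson-type image contrast
#'
#' contrast = (I_W - I_b) / (I_W + I_b), where I_W is the reflected intensity
#' at the debris location and I_b the background intensity. Signed: negative
#' when the target is darker than the background.
#'
#' @param I_W target intensity (>= 0).
#' @param I_b background intensity (>= 0).
#' @return contrast in \[-1, 1\].
#' @export
contrast <- function(I_W, I_b) {
  s <- I_W + I_b
  if (any(s <= 0)) stop("undefined contrast: I_W + I_b must be > 0")
  (I_W - I_b) / s
}

#' Measure woody-debris contrast in a reflectance image
#'
#' Reads the X intensity profile, averages it over a window of physical width
#' `window_m` (0.20 m by default, the cylinder diameter, equal to 20 pixels
#' at the reference 1 cm pitch; at other pitches the window is rounded to an
#' odd pixel count centered on the debris) to get I_W, averages the
#' background windows to get I_b, and reports the signed contrast, its
#' absolute value, and the spread (standard deviation of per-pixel contrasts
#' inside the target window, the quantity shown as error bars) plus the
#' standard error of the window mean.
#'
#' @param image a [reflectance_image()].
#' @param targets data.frame with columns `x_m` and `depth_m` (one row per
#'   debris cylinder), e.g. the `cylinders` attribute of a built scene.
#' @param background_windows list of `c(lo, hi)` X intervals in m; by default
#'   0.5 m-wide windows at the midpoints between adjacent targets and at the
#'   outer margins.
#' @param window_m physical width of the target window, m.
#' @param band_frac Y band fraction passed to [intensity_profile()].
#' @return a data.frame with one row per target: `debris_x_m`,
#'   `debris_depth_m`, `I_W`, `I_b`, `contrast`, `abs_contrast`, `spread`,
#'   `standard_error`, `n_px_target`.
#' @export
measure_debris_contrast <- function(image, targets, background_windows = NULL,
                                    window_m = 0.2, band_frac = 0.5) {
  stopifnot(inherits(image, "reflectance_image"))
  targets <- as.data.frame(targets)
  if (!all(c("x_m", "depth_m") %in% names(targets)))
    stop("targets needs columns x_m and depth_m")
  prof <- intensity_profile(image, band_frac = band_frac)
  px <- image$pixel_size
  nx <- nrow(prof)
  Lx <- nx * px

  window_px <- function(xc) {
    npix <- round(window_m / px)
    if (npix %% 2 == 0) npix <- npix + 1L
    ic <- which.min(abs(prof$x_m - xc))
    half <- (npix - 1L) / 2L
    lo <- ic - half; hi <- ic + half
    if (lo < 1L || hi > nx)
      stop(sprintf("target window at x = %g m extends outside the image", xc))
    lo:hi
  }
  twin <- lapply(targets$x_m, window_px)

  if (is.null(background_windows)) {
    xs <- sort(targets$x_m)
    mids <- c(xs[1] / 2,
              if (length(xs) > 1) (xs[-length(xs)] + xs[-1]) / 2,
              (xs[length(xs)] + Lx) / 2)
    background_windows <- lapply(mids, function(m)
      c(max(0, m - 0.25), min(Lx, m + 0.25)))
  }
  bpix <- unique(unlist(lapply(background_windows, function(wn) {
    if (wn[1] < 0 || wn[2] > Lx || wn[1] >= wn[2])
      stop(sprintf("background window [%g, %g] m is outside the image", wn[1], wn[2]))
    which(prof$x_m >= wn[1] & prof$x_m <= wn[2])
  })))
  if (!length(bpix)) stop("background windows cover no pixels")
  if (length(intersect(bpix, unlist(twin))))
    stop("background windows overlap a target window")
  I_b <- mean(prof$intensity[bpix])

  out <- lapply(seq_len(nrow(targets)), function(i) {
    vals <- prof$intensity[twin[[i]]]
    I_W <- mean(vals)
    per_px <- contrast(vals, I_b)
    data.frame(debris_x_m = targets$x_m[i], debris_depth_m = targets$depth_m[i],
               I_W = I_W, I_b = I_b,
               contrast = contrast(I_W, I_b),
               abs_contrast = abs(contrast(I_W, I_b)),
               spread = if (length(vals) > 1) sd(per_px) else 0,
               standard_error = if (length(vals) > 1)
                 sd(per_px) / sqrt(length(vals)) else 0,
               n_px_target = length(vals))
  })
  do.call(rbind, out)
}
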