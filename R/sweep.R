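#' Wavelength / chlorophyll sweep specification
#'
#' @param wavelengths wavelength grid, nm (default 400-800 in 50 nm steps).
#' @param water water preset name.
#' @param C_values chlorophyll concentrations to sweep, mg m^-3.
#' @param scene_profile one of the [lake_scene_profile()] profiles.
#' @param n_photons photons per transport run.
#' @param base_seed base seed; each (wavelength, C) cell derives its own seed
#'   with a stable hash so adding a wavelength never perturbs other cells.
#' @param voxel_size scene voxel edge, m.
#' @param wood_level scale of the default wood absorption spectrum.
#' @param surface_model,lateral_boundary passed to [transport_config()].
#' @return a `sweep_spec` object.
#' @export
sweep_spec <- function(wavelengths = seq(400, 800, 50), water = "pure",
                       C_values = c(0.1, 1, 10),
                       scene_profile = "figure-depths",
                       n_photons = 1e6, base_seed = 1L, voxel_size = 0.05,
                       wood_level = 1, surface_model = "fresnel",
                       lateral_boundary = "escape") {
  stopifnot(length(wavelengths) >= 1, all(C_values >= 0))
  water_preset(water)  # validate name early
  structure(list(wavelengths = sort(unique(as.numeric(wavelengths))),
                 water = water, C_values = as.numeric(C_values),
                 scene_profile = scene_profile, n_photons = n_photons,
                 base_seed = as.integer(base_seed), voxel_size = voxel_size,
                 wood_level = wood_level, surface_model = surface_model,
                 lateral_boundary = lateral_boundary),
            class = "sweep_spec")
}

#' Stable per-cell seed
#'
#' Derives a deterministic seed for one (wavelength, C) sweep cell from the
#' base seed and a polynomial string hash, so cell results are independent
#' of execution order and of which other cells exist.
#'
#' @param base_seed integer base seed.
#' @param wavelength_nm,C cell coordinates.
#' @return a non-negative integer seed below 2^31.
#' @export
cell_seed <- function(base_seed, wavelength_nm, C) {
  key <- sprintf("%.9g|%.9g", wavelength_nm, C)
  h <- 0
  for (code in utf8ToInt(key)) h <- (h * 31 + code) %% 2147483647
  bitwXor(as.integer(base_seed), as.integer(h)) %% 2147483647L
}

#' Run a wavelength x chlorophyll contrast sweep
#'
#' One transport run per (wavelength, C) cell with a cell-local seed; debris
#' contrast is measured for every cylinder of the scene profile. The result
#' is the complete contrast surface over (wavelength, C, depth), the
#' quantitative equivalent of the study's contrast spectra.
#'
#' @param spec a [sweep_spec()].
#' @return a `contrast_table` data.frame: one row per (wavelength, C,
#'   cylinder) with columns `wavelength_nm`, `water`, `C_mg_m3`,
#'   `debris_x_m`, `debris_depth_m`, `I_W`, `I_b`, `contrast`,
#'   `abs_contrast`, `spread`, `standard_error`, `n_photons`, `seed`.
#' @export
run_sweep <- function(spec) {
  stopifnot(inherits(spec, "sweep_spec"))
  rows <- list()
  for (C in spec$C_values) {
    scene <- lake_scene_profile(spec$scene_profile,
                                voxel_size = spec$voxel_size,
                                water = spec$water, C = C,
                                wavelength_nm = spec$wavelengths,
                                wood_level = spec$wood_level)
    targets <- attr(scene, "cylinders")
    for (wl in spec$wavelengths) {
      seed <- cell_seed(spec$base_seed, wl, C)
      res <- run_transport(
        scene, source_spec(wl),
        transport_config(n_photons = spec$n_photons, seed = seed,
                         surface_model = spec$surface_model,
                         lateral_boundary = spec$lateral_boundary))
      cm <- measure_debris_contrast(reflectance_image(res), targets)
      cm$wavelength_nm <- wl
      cm$water <- spec$water
      cm$C_mg_m3 <- C
      cm$n_photons <- spec$n_photons
      cm$seed <- seed
      rows[[length(rows) + 1L]] <- cm
    }
  }
  out <- do.call(rbind, rows)
  out <- out[, c("wavelength_nm", "water", "C_mg_m3", "debris_x_m",
                 "debris_depth_m", "I_W", "I_b", "contrast", "abs_contrast",
                 "spread", "standard_error", "n_photons", "seed")]
  rownames(out) <- NULL
  class(out) <- c("contrast_table", "data.frame")
  out
}

#' Maximum visible depth per wavelength
#'
#' For each wavelength, the largest simulated depth whose contrast magnitude
#' reaches the cut-off (10% by default, the conventional visibility limit in
#' digital imaging).
#'
#' @param table a `contrast_table` from [run_sweep()] (a single water and C).
#' @param cutoff contrast cut-off fraction.
#' @param use_abs compare `abs_contrast` (default) rather than signed
#'   contrast against the cut-off.
#' @return a data.frame with `wavelength_nm`, `max_depth_m` (NA when no
#'   depth qualifies) and `all_visible` (TRUE when even the deepest
#'   simulated cylinder qualifies, i.e. the true limit is >= the deepest
#'   simulated depth).
#' @export
max_visible_depth <- function(table, cutoff = 0.10, use_abs = TRUE) {
  stopifnot(is.data.frame(table), nrow(table) > 0)
  val <- if (use_abs) table$abs_contrast else table$contrast
  split_tab <- split(data.frame(depth = table$debris_depth_m, val = val),
                     table$wavelength_nm)
  out <- lapply(names(split_tab), function(wl) {
    s <- split_tab[[wl]]
    ok <- s$depth[s$val >= cutoff]
    data.frame(wavelength_nm = as.numeric(wl),
               max_depth_m = if (length(ok)) max(ok) else NA_real_,
               all_visible = length(ok) == length(s$depth))
  })
  out <- do.call(rbind, out)
  out[order(out$wavelength_nm), ]
}

#' Recommend imaging wavelengths from a contrast table
#'
#' Recommended bands are the wavelengths achieving the maximal visible depth
#' at the cut-off (contiguous grid points merged into intervals). Avoid
#' bands are contiguous wavelengths where the shallowest-depth contrast dips
#' below the running median by more than `dip_factor`, which captures the
#' water-absorption dips near 600-650 and 750 nm.
#'
#' @param table a `contrast_table` spanning at least 3 wavelengths, for a
#'   single water and chlorophyll concentration.
#' @param cutoff contrast cut-off fraction.
#' @param dip_factor a wavelength is flagged when its shallow contrast is
#'   below running_median / dip_factor.
#' @return a `wavelength_recommendation`: list with `water`, `C_mg_m3`,
#'   `depths` (the [max_visible_depth()] table), `recommended_bands` and
#'   `avoid_bands` (two-column matrices of nm intervals), and `text`.
#' @export
recommend_wavelengths <- function(table, cutoff = 0.10, dip_factor = 1.5) {
  stopifnot(is.data.frame(table))
  if (length(unique(table$wavelength_nm)) < 3)
    stop("recommendation needs a table spanning at least 3 wavelengths")
  if (length(unique(table$water)) > 1 || length(unique(table$C_mg_m3)) > 1)
    stop("filter the table to a single water and chlorophyll concentration first")
  depths <- max_visible_depth(table, cutoff = cutoff)
  wl <- depths$wavelength_nm
  step <- if (length(wl) > 1) min(diff(wl)) else 0

  merge_bands <- function(sel) {
    if (!any(sel)) return(matrix(numeric(), ncol = 2,
                                 dimnames = list(NULL, c("from_nm", "to_nm"))))
    idx <- which(sel)
    breaks <- c(0, which(diff(idx) > 1), length(idx))
    bands <- t(vapply(seq_len(length(breaks) - 1), function(k) {
      grp <- idx[(breaks[k] + 1):breaks[k + 1]]
      c(wl[min(grp)], wl[max(grp)])
    }, numeric(2)))
    dimnames(bands) <- list(NULL, c("from_nm", "to_nm"))
    bands
  }

  depth_val <- ifelse(is.na(depths$max_depth_m), -Inf, depths$max_depth_m)
  recommended <- merge_bands(depth_val == max(depth_val) & is.finite(max(depth_val)))

  shallow <- min(table$debris_depth_m)
  sh <- table[table$debris_depth_m == shallow, ]
  sh <- sh[order(sh$wavelength_nm), ]
  med <- runmed(sh$abs_contrast, k = min(5L, length(sh$abs_contrast) -
                                           (1 - length(sh$abs_contrast) %% 2)))
  dip <- sh$abs_contrast < med / dip_factor
  # never advise avoiding a recommended wavelength
  in_rec <- rep(FALSE, length(wl))
  if (nrow(recommended))
    for (k in seq_len(nrow(recommended)))
      in_rec <- in_rec | (wl >= recommended[k, 1] & wl <= recommended[k, 2])
  avoid <- merge_bands(dip & !in_rec)

  fmt <- function(b) if (!nrow(b)) "none" else
    paste(sprintf("%g-%g nm", b[, 1], b[, 2]), collapse = ", ")
  text <- sprintf(paste0(
    "Water %s at C = %g mg/m^3: best visible depth %s m at the %.0f%% cut-off. ",
    "Recommended band(s): %s. Avoid band(s): %s (shallow-depth contrast dips ",
    "more than %.2gx below the running median, driven by water absorption)."),
    unique(table$water), unique(table$C_mg_m3),
    if (is.finite(max(depth_val))) format(max(depth_val)) else "none",
    100 * cutoff, fmt(recommended), fmt(avoid), dip_factor)

  structure(list(water = unique(table$water), C_mg_m3 = unique(table$C_mg_m3),
                 cutoff = cutoff, depths = depths,
                 recommended_bands = recommended, avoid_bands = avoid,
                 text = text),
            class = "wavelength_recommendation")
}

#' @export
print.wavelength_recommendation <- function(x, ...) {
  cat(strwrap(x$text, width = 78), sep = "\n")
  invisible(x)
}
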