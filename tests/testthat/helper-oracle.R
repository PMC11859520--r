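# Independent scalar Monte Carlo oracle: diffuse reflectance of a
# semi-infinite homogeneous medium in planar geometry with a matched surface.
# Deliberately shares no code with the package kernel: plain R, vectorized
# over photons, no voxel grid, base-R RNG.
oracle_planar_reflectance <- function(mu_a, mu_s, g = 0, n_photons = 2e4,
                                      seed = 1, w_min = 1e-7) {
  set.seed(seed)
  mt <- mu_a + mu_s
  albedo <- mu_s / mt
  z <- rep(0, n_photons)
  uz <- rep(1, n_photons)
  w <- rep(1, n_photons)
  alive <- rep(TRUE, n_photons)
  refl <- 0
  for (step in 1:5000) {
    if (!any(alive)) break
    n <- sum(alive)
    s <- -log(runif(n)) / mt
    z[alive] <- z[alive] + s * uz[alive]
    esc <- alive & z < 0
    refl <- refl + sum(w[esc])
    alive[esc] <- FALSE
    if (!any(alive)) break
    w[alive] <- w[alive] * albedo
    dead <- alive & w < w_min
    alive[dead] <- FALSE
    n <- sum(alive)
    if (n == 0) break
    if (abs(g) < 1e-12) {
      uz[alive] <- runif(n, -1, 1)
    } else {
      u <- runif(n)
      tmp <- (1 - g^2) / (1 - g + 2 * g * u)
      ct <- (1 + g^2 - tmp^2) / (2 * g)
      st <- sqrt(pmax(0, 1 - ct^2))
      phi <- runif(n, 0, 2 * pi)
      old <- uz[alive]
      sold <- sqrt(pmax(0, 1 - old^2))
      uz[alive] <- ifelse(sold < 1e-6, ct * sign(old),
                          -st * cos(phi) * sold + old * ct)
    }
  }
  refl / n_photons
}

# Closed-form Henyey-Greenstein CDF over the deflection cosine
hg_cdf <- function(x, g) {
  if (abs(g) < 1e-12) return((x + 1) / 2)
  (1 - g^2) / (2 * g) * (1 / sqrt(1 + g^2 - 2 * g * x) - 1 / (1 + g))
}

# water-only rectangular test scene with a single constant-IOP medium
flat_scene <- function(mu_a, mu_s, g, extent = c(1, 1, 2), voxel_size = 0.05) {
  med <- list("0" = iop_spectrum(c(400, 800), rep(mu_a, 2), rep(mu_s, 2), g = g))
  build_lake_scene(extent = extent, voxel_size = voxel_size,
                   cylinders = list(), media = med)
}

ledger_gap <- function(res) {
  led <- res$ledger
  abs(led[["launched"]] - sum(led[names(led) != "launched"])) / led[["launched"]]
}
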