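test_that("a pure absorber follows the Beer-Lambert depth law", {
  sc <- flat_scene(mu_a = 1, mu_s = 0, g = 0)
  res <- run_transport(sc, source_spec(550, profile = "uniform"),
                       transport_config(n_photons = 2e5, seed = 7,
                                        surface_model = "matched",
                                        tally_fluence = TRUE))
  # all weight deposits in water; fraction reaching z = 1 m is exp(-1)
  dep <- apply(res$fluence, 3, sum)
  nz1 <- sum((seq_along(dep) - 1) * sc$voxel_size < 1)  # layers above 1 m
  frac <- (sum(dep[-(1:nz1)]) + res$ledger[["escaped_bottom"]]) /
    res$ledger[["launched"]]
  se <- sqrt(exp(-1) * (1 - exp(-1)) / 2e5)
  expect_lt(abs(frac - exp(-1)), 3 * se)
  # log-deposition slope recovers -mu_a within 5%
  prof <- fluence_depth_profile(res)
  keep <- prof$depth_m < 1.5
  fit <- lm(log(prof$deposited[keep]) ~ prof$depth_m[keep])
  expect_lt(abs(coef(fit)[2] + 1) / 1, 0.05)
})

test_that("the weight ledger balances exactly on every kind of scene", {
  runs <- list(
    run_transport(flat_scene(1, 10, 0.9), source_spec(550),
                  transport_config(n_photons = 2e4, seed = 1)),
    run_transport(flat_scene(0.05, 2, 0.924), source_spec(550),
                  transport_config(n_photons = 2e4, seed = 2,
                                   lateral_boundary = "mirror")),
    run_transport(fixture_scene("tiny", water = "LAN", C = 10)$scene,
                  source_spec(800),
                  transport_config(n_photons = 2e4, seed = 3)))
  for (res in runs) {
    expect_lt(ledger_gap(res), 1e-6)
    expect_true(all(res$ledger[names(res$ledger) != "roulette_killed"] >= 0))
  }
})

test_that("a scattering-only slab conserves weight without absorption", {
  sc <- flat_scene(mu_a = 0, mu_s = 5, g = 0.5, extent = c(1, 1, 0.5))
  res <- run_transport(sc, source_spec(550, profile = "uniform"),
                       transport_config(n_photons = 5e4, seed = 11,
                                        surface_model = "matched"))
  led <- res$ledger
  expect_equal(led[["absorbed_water"]] + led[["absorbed_debris"]], 0)
  escaped <- led[["reflected_surface"]] + led[["escaped_bottom"]] +
    led[["escaped_sides"]] + led[["roulette_killed"]]
  expect_equal(escaped, led[["launched"]], tolerance = 1e-9)
})

test_that("normal-incidence Fresnel entry reflects the closed-form fraction", {
  sc <- flat_scene(1, 1, 0.5)
  res <- run_transport(sc, source_spec(550, profile = "uniform"),
                       transport_config(n_photons = 1e4, seed = 5,
                                        surface_model = "fresnel"))
  r_specular <- ((1 - 1.33) / (1 + 1.33))^2
  expect_equal(res$ledger[["specular"]] / res$ledger[["launched"]],
               r_specular, tolerance = 1e-9)
})

test_that("identical seeds give bit-identical results", {
  fs <- fixture_scene("tiny", water = "LAN", C = 10)
  cfg <- transport_config(n_photons = 1e4, seed = 123, tally_fluence = TRUE)
  r1 <- run_transport(fs$scene, source_spec(550), cfg)
  r2 <- run_transport(fs$scene, source_spec(550), cfg)
  expect_identical(r1$reflectance, r2$reflectance)
  expect_identical(r1$ledger, r2$ledger)
  expect_identical(r1$fluence, r2$fluence)
  r3 <- run_transport(fs$scene, source_spec(550),
                      transport_config(n_photons = 1e4, seed = 124))
  expect_false(identical(r1$ledger, r3$ledger))
})

test_that("diffuse reflectance matches an independent planar Monte Carlo", {
  # mu_a = 0.1 cm^-1, mu_s' = 1 cm^-1 (isotropic), matched semi-infinite
  mu_a <- 10; mu_s <- 100
  want <- oracle_planar_reflectance(mu_a, mu_s, g = 0, n_photons = 3e4, seed = 2)
  sc <- flat_scene(mu_a, mu_s, g = 0, extent = c(0.6, 0.6, 0.4),
                   voxel_size = 0.02)
  res <- run_transport(sc, source_spec(550, profile = "uniform"),
                       transport_config(n_photons = 1e5, seed = 9,
                                        surface_model = "matched",
                                        lateral_boundary = "mirror"))
  got <- res$ledger[["reflected_surface"]] / res$ledger[["launched"]]
  expect_lt(abs(got - want) / want, 0.05)
})

test_that("Russian roulette leaves the mean reflectance unbiased", {
  sc <- flat_scene(mu_a = 2, mu_s = 20, g = 0.5, extent = c(0.5, 0.5, 0.5))
  refl_frac <- function(threshold, seed) {
    res <- run_transport(sc, source_spec(550, profile = "uniform"),
                         transport_config(n_photons = 5e3, seed = seed,
                                          roulette_threshold = threshold,
                                          surface_model = "matched"))
    res$ledger[["reflected_surface"]] / res$ledger[["launched"]]
  }
  with_rr <- vapply(1:20, function(s) refl_frac(1e-2, s), 0)
  without <- vapply(1:20, function(s) refl_frac(0, 100 + s), 0)
  se <- sqrt(var(with_rr) / 20 + var(without) / 20)
  expect_lt(abs(mean(with_rr) - mean(without)), 3 * se)
})

test_that("ledger totals are stable under grid refinement", {
  refl_frac <- function(voxel, seed) {
    sc <- flat_scene(mu_a = 1, mu_s = 10, g = 0.9, extent = c(1, 1, 1),
                     voxel_size = voxel)
    res <- run_transport(sc, source_spec(550, profile = "uniform"),
                         transport_config(n_photons = 2e4, seed = seed))
    res$ledger[["reflected_surface"]] / res$ledger[["launched"]]
  }
  coarse <- vapply(1:5, function(s) refl_frac(0.05, s), 0)
  fine <- vapply(1:5, function(s) refl_frac(0.02, 50 + s), 0)
  se <- sqrt(var(coarse) / 5 + var(fine) / 5)
  expect_lt(abs(mean(coarse) - mean(fine)), 3 * se)
})

test_that("degenerate configurations are rejected", {
  expect_error(run_transport(flat_scene(0, 0, 0), source_spec(550),
                             transport_config(n_photons = 10, seed = 1)),
               "vacuum")
  expect_error(source_spec(550, direction = c(0, 0, -1)), "downward")
  expect_error(transport_config(n_photons = 0), "n_photons")
  expect_error(transport_config(roulette_survival = 0), "roulette_survival")
  res <- run_transport(flat_scene(1, 1, 0), source_spec(550),
                       transport_config(n_photons = 100, seed = 1))
  expect_error(fluence_depth_profile(res), "tally_fluence")
})

test_that("a scatter-guard termination still balances the ledger", {
  sc <- flat_scene(mu_a = 0.001, mu_s = 50, g = 0, extent = c(0.5, 0.5, 0.5))
  res <- run_transport(sc, source_spec(550, profile = "uniform"),
                       transport_config(n_photons = 2e3, seed = 4,
                                        max_scatter_events = 10,
                                        surface_model = "matched"))
  expect_gt(res$ledger[["roulette_killed"]], 0)
  expect_lt(ledger_gap(res), 1e-6)
})
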