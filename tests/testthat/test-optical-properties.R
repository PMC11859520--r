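test_that("pure-water table lookup interpolates and respects knots", {
  # value at a table knot is the knot value (interpolation identity)
  iop <- pure_water_iop(800)
  expect_equal(iop$mu_a, 1.9635, tolerance = 1e-6)
  expect_equal(iop$refractive_index, 1.33)
  # absorption rises from blue to NIR
  both <- pure_water_iop(c(400, 800))
  expect_lt(both$mu_a[1], both$mu_a[2])
  # 750 nm water shoulder exceeds the 800 nm value
  sh <- pure_water_iop(c(750, 800))
  expect_gt(sh$mu_a[1], sh$mu_a[2])
  # midpoint between knots is the linear interpolant
  knots <- pure_water_iop(c(775, 800))
  mid <- pure_water_iop(787.5)
  expect_equal(mid$mu_a, mean(knots$mu_a), tolerance = 1e-12)
  expect_error(pure_water_iop(1200), "1200")
})

test_that("chlorophyll scattering follows the 550 nm power law", {
  mu_pw_550 <- pure_water_iop(550)$mu_s
  expect_identical(chlorophyll_scattering(550, 0), mu_pw_550)
  expect_equal(chlorophyll_scattering(550, 1) - mu_pw_550, 0.30,
               tolerance = 1e-12)
  expect_equal(chlorophyll_scattering(550, 10) - mu_pw_550, 0.30 * 10^0.62,
               tolerance = 1e-12)  # 1.250608...
  # strictly increasing in C, strictly decreasing in lambda (fixed mu_s_PW)
  Cs <- c(0.1, 0.5, 1, 5, 10)
  vals_C <- vapply(Cs, function(C)
    chlorophyll_scattering(550, C, mu_s_pw = 0), 0)
  expect_true(all(diff(vals_C) > 0))
  wls <- seq(400, 800, 50)
  vals_wl <- chlorophyll_scattering(wls, 5, mu_s_pw = 0)
  expect_true(all(diff(vals_wl) < 0))
  expect_error(chlorophyll_scattering(550, -1), "C")
})

test_that("lake presets hit the printed 800 nm anchors after unit conversion", {
  wl <- seq(400, 800, 50)
  lan <- iop_at(lake_water_iop("LAN", C = 10, wl), 800)
  lva <- iop_at(lake_water_iop("LVA", C = 0.1, wl), 800)
  expect_equal(lan$mu_a, coef_to_per_m(0.028, "cm^-1"), tolerance = 1e-9)
  expect_equal(lva$mu_a, coef_to_per_m(0.038, "cm^-1"), tolerance = 1e-9)
  expect_equal(lan$g, 0.924)
  # pure preset at C = 0 is exactly the bundled pure-water spectrum
  expect_equal(lake_water_iop("pure", C = 0, wl),
               pure_water_iop(wl), tolerance = 1e-12)
  expect_error(water_preset("LXX"), "pure, LAN, LPA, LVO, LVA")
})

test_that("Henyey-Greenstein density is normalized with mean cosine g", {
  expect_equal(hg_phase_density(c(-0.3, 0, 0.9), 0), rep(0.5, 3))
  for (g in c(-0.9, 0, 0.5, 0.924)) {
    p <- function(x) hg_phase_density(x, g)
    norm <- integrate(p, -1, 1, rel.tol = 1e-12)$value
    expect_equal(norm, 1, tolerance = 1e-8)
  }
  expect_equal(anisotropy_from_phase(function(x) hg_phase_density(x, 0.924)),
               0.924, tolerance = 1e-6)
  expect_equal(anisotropy_from_phase(function(x) hg_phase_density(x, -0.5)),
               -0.5, tolerance = 1e-6)
  expect_equal(anisotropy_from_phase(function(x) rep(0.5, length(x))), 0,
               tolerance = 1e-8)
  expect_error(anisotropy_from_phase(function(x) rep(1, length(x))),
               "not normalized")
  expect_error(hg_phase_density(0.5, 1.0), "g")
})

test_that("Henyey-Greenstein sampler matches its density and moments", {
  expect_equal(hg_sample(1, 0, u = 0.5)$cos_theta, 0)
  # median of the g = 0.924 distribution via the closed-form inverse
  med <- hg_sample(1, 0.924, u = 0.5)$cos_theta
  expect_equal(hg_cdf(med, 0.924), 0.5, tolerance = 1e-12)
  set.seed(42)
  n <- 1e6
  for (g in c(0, 0.5, 0.924)) {
    s <- hg_sample(n, g)
    se <- sd(s$cos_theta) / sqrt(n)
    expect_lt(abs(mean(s$cos_theta) - g), 3 * se)
    expect_true(all(s$azimuth >= 0 & s$azimuth < 2 * pi))
  }
  # distributional agreement with the closed-form CDF at g = 0.5
  s <- hg_sample(n, 0.5)$cos_theta
  grid <- seq(-0.99, 0.99, length.out = 41)
  emp <- ecdf(s)(grid)
  expect_lt(max(abs(emp - hg_cdf(grid, 0.5))), 0.005)
})

test_that("reduced scattering and unit conversions are exact", {
  expect_equal(reduced_scattering(10, 0), 10)
  expect_equal(reduced_scattering(10, 1), 0)
  expect_equal(reduced_scattering(46.05, 0.924), 3.4998, tolerance = 1e-12)
  x <- c(0.028, 0.038, 35, 1.234567890123)
  expect_equal(coef_to_per_cm(coef_to_per_m(x, "cm^-1")), x,
               tolerance = 1e-12)
})

test_that("wood optics keep the fixed 35 cm^-1 reduced scattering", {
  wl <- seq(400, 800, 50)
  wood <- wood_iop(wl)
  expect_equal(reduced_scattering(wood$mu_s, 0.9), rep(3500, length(wl)))
  # default absorption decreases from 400 to 800 nm
  expect_true(all(diff(wood$mu_a) < 0))
  expect_gt(wood$mu_a[1], wood$mu_a[length(wl)])
  # a user-supplied constant absorption passes through unchanged
  tab <- data.frame(wavelength_nm = 600, value = 100)
  attr(tab, "units") <- "m^-1"
  expect_equal(wood_iop(wl, mu_a_table = tab)$mu_a, rep(100, length(wl)))
  # cm^-1 user table converts
  tab2 <- data.frame(wavelength_nm = c(400, 800), value = c(2, 1))
  attr(tab2, "units") <- "cm^-1"
  expect_equal(wood_iop(c(400, 800), mu_a_table = tab2)$mu_a, c(200, 100))
  expect_error(wood_iop(c(300, 800), mu_a_table = tab2), "300")
})

test_that("iop_spectrum validates its invariants", {
  expect_error(iop_spectrum(c(500, 400), c(1, 1), c(1, 1), 0.9),
               "strictly increasing")
  expect_error(iop_spectrum(c(400, 500), c(-1, 1), c(1, 1), 0.9), "mu_a")
  expect_error(iop_spectrum(c(400, 500), c(1, 1), c(1, 1), 1.5), "g")
  expect_error(iop_spectrum(400, 1, 1, 0.9, refractive_index = 0.9),
               "refractive_index")
  expect_error(iop_at(pure_water_iop(c(400, 500)), 600), "600")
})

test_that("spectrum tables round-trip through the text format", {
  df <- data.frame(wavelength_nm = c(400, 550, 800),
                   value = c(3.5, 2.1, 1.3))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_spectrum_table(df, path, units = "cm^-1", comment = "wood absorption")
  back <- read_spectrum_table(path)
  expect_equal(back$wavelength_nm, df$wavelength_nm)
  expect_equal(back$value, df$value)
  expect_identical(attr(back, "units"), "cm^-1")
  # missing units header is rejected
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("400 1", "500 2"), bad)
  expect_error(read_spectrum_table(bad), "units")
})
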