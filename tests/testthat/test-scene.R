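water_med <- function() list("0" = iop_spectrum(c(400, 800), c(1, 1), c(1, 1), 0.9))
wood_med <- function(lab = 1L) {
  m <- water_med()
  m[[as.character(lab)]] <- iop_spectrum(c(400, 800), c(10, 10), c(100, 100), 0.9)
  m
}

test_that("an empty cylinder list gives a water-only scene", {
  sc <- build_lake_scene(extent = c(1, 1, 1), voxel_size = 0.05,
                         cylinders = list(), media = water_med())
  expect_true(all(sc$labels == 0L))
  expect_identical(dim(sc$labels), c(20L, 20L, 20L))
  expect_identical(nrow(attr(sc, "cylinders")), 0L)
})

test_that("the published 1 cm voxel grid has the printed shape", {
  sc <- build_lake_scene(extent = c(5, 15, 3), voxel_size = 0.01,
                         cylinders = list(), media = water_med())
  expect_identical(dim(sc$labels), c(500L, 1500L, 300L))
  rm(sc); gc(verbose = FALSE)
})

test_that("rasterized cylinder volume matches the analytic volume", {
  # full-length 0.20 m cylinder across a 15 m axis at 1 cm voxels
  cyl <- cylinder_spec(0.5, 0.5, 0.2, 1L)
  sc <- build_lake_scene(extent = c(1, 15, 1), voxel_size = 0.01,
                         cylinders = list(cyl), media = wood_med())
  count <- sum(sc$labels == 1L)
  analytic <- pi * 0.1^2 * 15 / 0.01^3
  expect_lt(abs(count - analytic) / analytic, 0.02)
  # cross-section count close to pi r^2 in voxel units
  cross <- count / dim(sc$labels)[2]
  expect_lte(abs(cross - pi * 10^2), 8)
  rm(sc); gc(verbose = FALSE)
})

test_that("rasterization error shrinks as the voxels shrink", {
  analytic <- pi * 0.1^2 * 0.4
  err <- vapply(c(0.04, 0.02, 0.01), function(d) {
    sc <- build_lake_scene(extent = c(1, 0.4, 1), voxel_size = d,
                           cylinders = list(cylinder_spec(0.5, 0.5, 0.2, 1L)),
                           media = wood_med())
    abs(sum(sc$labels == 1L) * d^3 - analytic) / analytic
  }, 0)
  expect_true(all(diff(err) < 0))
})

test_that("rasterization is center-inclusion with shift equivariance", {
  # sub-voxel cylinder centered on a voxel center labels exactly one column
  sc <- build_lake_scene(extent = c(1, 0.2, 1), voxel_size = 0.05,
                         cylinders = list(cylinder_spec(0.125, 0.125, 0.04, 1L)),
                         media = wood_med())
  expect_identical(sum(sc$labels == 1L), as.integer(dim(sc$labels)[2]))
  # translating by one voxel pitch translates the labeled set by one index
  sc2 <- build_lake_scene(extent = c(2, 0.2, 2), voxel_size = 0.05,
                          cylinders = list(cylinder_spec(0.6, 1.0, 0.3, 1L)),
                          media = wood_med())
  sc3 <- build_lake_scene(extent = c(2, 0.2, 2), voxel_size = 0.05,
                          cylinders = list(cylinder_spec(0.65, 1.0, 0.3, 1L)),
                          media = wood_med())
  idx2 <- which(sc2$labels == 1L, arr.ind = TRUE)
  idx3 <- which(sc3$labels == 1L, arr.ind = TRUE)
  idx2[, 1] <- idx2[, 1] + 1L
  expect_identical(idx2[order(idx2[, 1], idx2[, 2], idx2[, 3]), ],
                   idx3[order(idx3[, 1], idx3[, 2], idx3[, 3]), ])
})

test_that("overlapping cylinders resolve to the later label", {
  m <- wood_med()
  m[["2"]] <- m[["1"]]
  sc <- build_lake_scene(extent = c(2, 0.2, 2), voxel_size = 0.05,
                         cylinders = list(cylinder_spec(1, 1, 0.4, 1L),
                                          cylinder_spec(1, 1, 0.4, 2L)),
                         media = m)
  expect_identical(sum(sc$labels == 1L), 0L)
  expect_gt(sum(sc$labels == 2L), 0L)
})

test_that("invalid geometry and media are rejected with context", {
  expect_error(build_lake_scene(extent = c(1, 1, 1), voxel_size = 0.05,
                                cylinders = list(cylinder_spec(0.95, 0.5, 0.2, 1L)),
                                media = wood_med()),
               "cylinder 1")
  expect_error(cylinder_spec(0.5, 0.05, 0.2), "surface")
  expect_error(build_lake_scene(extent = c(1, 1, 1), voxel_size = 0.03,
                                cylinders = list(), media = water_med()),
               "divisible")
  # a label present in the grid but absent from media is caught
  labels <- array(0L, dim = c(10, 10, 10))
  labels[5, 5, 5] <- 3L
  expect_error(voxel_scene(c(0.5, 0.5, 0.5), 0.05, labels, water_med()),
               "media")
})

test_that("scene serialization round-trips labels bit-exactly", {
  fs <- fixture_scene("tiny")
  path <- withr::local_tempfile(fileext = ".scene")
  write_scene(fs$scene, path)
  back <- read_scene(path)
  expect_identical(back$labels, fs$scene$labels)
  expect_equal(back$extent, fs$scene$extent)
  expect_equal(back$voxel_size, fs$scene$voxel_size)
  expect_equal(back$media[["0"]]$mu_a, fs$scene$media[["0"]]$mu_a)
  expect_equal(back$media[["1"]]$mu_s, fs$scene$media[["1"]]$mu_s)
})

test_that("study profiles have the documented geometry", {
  wl <- c(550, 800)
  fig <- lake_scene_profile("figure-depths", wavelength_nm = wl)
  expect_equal(attr(fig, "cylinders")$depth_m, c(0.25, 0.50, 0.75))
  expect_equal(attr(fig, "cylinders")$x_m, c(2.5, 7.0, 12.5))
  expect_equal(fig$extent, c(15, 5, 3))
  pap <- lake_scene_profile("paper-depths", wavelength_nm = wl)
  expect_equal(attr(pap, "cylinders")$depth_m, c(2.5, 5.0, 7.5))
  expect_equal(pap$extent, c(15, 5, 8))
  expect_identical(sort(unique(as.vector(fig$labels))), 0:3)
})
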