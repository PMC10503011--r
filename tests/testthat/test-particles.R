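# Program A: local-maxima detection, zone partition, zone densities.

test_that("local-maxima detection handles plateaus and degenerate images", {
  fp <- matrix(TRUE, 16, 16)
  const <- frame_stack(matrix(7, 16, 16))
  expect_identical(detect_local_maxima(const, list(footprint = fp),
                                       min_intensity = 0)$n_total, 0L)

  f <- matrix(0, 16, 16); f[5, 9] <- 100
  ps <- detect_local_maxima(frame_stack(f), list(footprint = fp),
                            min_intensity = 50)
  expect_identical(ps$n_total, 1L)
  expect_identical(ps$particles$y, 5L)
  expect_identical(ps$particles$x, 9L)
  expect_identical(ps$particles$intensity, 100)

  # a 2x2 equal-valued plateau yields one particle at the rounded centroid
  # (mean 6.5 -> 6: ties toward the top-left)
  f2 <- matrix(0, 16, 16); f2[6:7, 6:7] <- 9
  ps2 <- detect_local_maxima(frame_stack(f2), list(footprint = fp),
                             min_intensity = 1)
  expect_identical(ps2$n_total, 1L)
  expect_identical(c(ps2$particles$y, ps2$particles$x), c(6L, 6L))

  # below-threshold maxima are ignored
  expect_identical(detect_local_maxima(frame_stack(f2),
                                       list(footprint = fp),
                                       min_intensity = 10)$n_total, 0L)
})

test_that("raising the detection threshold never increases the count", {
  set.seed(7)
  f <- matrix(runif(48 * 48, 0, 100), 48, 48)
  fp <- disk_mask(20, c(48, 48))
  counts <- vapply(seq(0, 100, by = 10), function(thr)
    detect_local_maxima(frame_stack(f), list(footprint = fp),
                        min_intensity = thr)$n_total, 0L)
  expect_true(all(diff(counts) <= 0))
})

test_that("well-separated planted puncta are recovered almost perfectly", {
  noise_sd <- 5
  kern_peak <- max(gaussian_spot_kernel(40 / 27.5))
  amp <- 10 * noise_sd / kern_peak     # spot peak at 10x the noise s.d.
  for (s in 1:5) {
    b <- make_bouton_geometry(1, c(12, 12), 0.15, seed = s)[[1]]
    pts <- plant_puncta_n(b, 50, min_spacing_px = 8, amplitude = amp,
                          seed = s + 50)
    truth <- scene_truth(list(b), list(pts))
    sc <- render_scene(truth, psf_sigma_nm = 40, background_level = 10,
                       noise = list(gaussian_sd = noise_sd),
                       channels = "vesicle", seed = s + 100)
    ps <- detect_local_maxima(sc, truth_mask(b))
    mm <- match_particles(ps, pts)
    expect_gte(mm$n_matched, 48)
    expect_lte(mm$n_false_positive, 1)
  }
})

test_that("zone partition is exact and follows the physical band depth", {
  calib <- calibration_preset("sted")
  for (s in 1:10) {
    b <- random_mask(s)
    z <- partition_zones(truth_mask(b), band_nm = 200, calib)
    fp <- b$footprint
    expect_identical(sum(z$peripheral) + sum(z$central), sum(fp))
    expect_false(any(z$peripheral & z$central))
    expect_true(all((z$peripheral | z$central) == fp))
    expect_equal(z$peripheral_area_um2 + z$central_area_um2,
                 b$area_um2, tolerance = 1e-12)
    dm <- EBImage::distmap(fp * 1) * calib$pixel_size_xy
    expect_true(all(dm[z$peripheral] <= 200))
    expect_true(all(dm[z$central] > 200))
  }
  # a disk thinner than the band is all peripheral
  thin <- list(footprint = disk_mask(150 / 27.5))
  zt <- partition_zones(thin, 200, calib)
  expect_identical(sum(zt$central), 0L)
  # band -> infinity: peripheral = footprint
  b <- random_mask(3)
  zinf <- partition_zones(truth_mask(b), band_nm = 1e9, calib)
  expect_identical(zinf$peripheral, b$footprint)
})

test_that("zone densities are count/area with flagged undefined zones", {
  b <- make_bouton_geometry(1, c(8, 8), 0, seed = 2)[[1]]
  z <- partition_zones(truth_mask(b))
  peri_px <- which(z$peripheral, arr.ind = TRUE)
  cent_px <- which(z$central, arr.ind = TRUE)
  pts <- data.frame(y = c(peri_px[1:10, 1], cent_px[1:4, 1]),
                    x = c(peri_px[1:10, 2], cent_px[1:4, 2]),
                    amplitude = 1)
  zd <- zone_density(particles_from_truth(pts), z)
  expect_equal(zd$peripheral_density, 10 / z$peripheral_area_um2)
  expect_equal(zd$central_density, 4 / z$central_area_um2)
  expect_identical(zd$n_peripheral + zd$n_central, 14L)

  empty <- particles_from_truth(data.frame(y = integer(), x = integer(),
                                           amplitude = numeric()))
  zd0 <- zone_density(empty, z)
  expect_identical(zd0$peripheral_density, 0)
  expect_identical(zd0$central_density, 0)

  thin <- partition_zones(list(footprint = disk_mask(150 / 27.5)))
  zdt <- zone_density(empty, thin)
  expect_false(zdt$central_defined)
  expect_true(is.na(zdt$central_density))
})

test_that("uniformly planted fields show no peripheral/central bias", {
  diffs <- sapply(1:40, function(s) {
    b <- make_bouton_geometry(1, c(6, 10), seed = s + 300)[[1]]
    pl <- plant_puncta(b, 1.5, 1.5, seed = s + 600)
    zd <- zone_density(particles_from_truth(pl$puncta), pl$zones)
    zd$peripheral_density - zd$central_density
  })
  se <- sd(diffs) / sqrt(length(diffs))
  expect_lt(abs(mean(diffs)), 3 * se + 1e-9)
})
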