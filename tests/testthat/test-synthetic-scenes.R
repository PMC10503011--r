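# The scene generator: geometry, planting, rendering, truth bookkeeping.

test_that("bouton geometry respects area targets, connectivity and spacing", {
  expect_length(make_bouton_geometry(0), 0)

  one <- make_bouton_geometry(1, c(3, 3), shape_irregularity = 0, seed = 3)
  expect_length(one, 1)
  expect_lt(abs(one[[1]]$area_um2 - 3) / 3, 0.05)

  geom <- make_bouton_geometry(6, c(2.5, 12), seed = 5)
  areas <- vapply(geom, `[[`, 0, "area_um2")
  expect_true(all(areas > 2.5 * 0.95 & areas < 12 * 1.05))
  for (b in geom) {
    lab <- EBImage::bwlabel(b$footprint * 1)
    expect_equal(max(lab), 1)           # single connected component
    bb <- which(b$footprint, arr.ind = TRUE)
    expect_true(min(bb) > 1)            # border-clear
  }
  # pairwise gap >= 2 px: dilating one bouton by 2 never touches another
  for (i in 1:5) for (j in (i + 1):6) {
    grown <- EBImage::dilate(geom[[i]]$footprint * 1, EBImage::makeBrush(5, "box"))
    expect_false(any((grown > 0.5) & geom[[j]]$footprint))
  }

  expect_identical(make_bouton_geometry(3, seed = 9),
                   make_bouton_geometry(3, seed = 9))
  expect_error(make_bouton_geometry(2, c(11, 12), canvas = c(60, 60)),
               "placement error")
})

test_that("puncta planting follows zone geometry and records realized truth", {
  b <- make_bouton_geometry(1, c(8, 8), seed = 2)[[1]]
  none <- plant_puncta(b, 0, 0, seed = 1)
  expect_identical(nrow(none$puncta), 0L)

  peri_only <- plant_puncta(b, 3, 0, seed = 4)
  zp <- peri_only$zones
  expect_true(all(zp$peripheral[cbind(peri_only$puncta$y,
                                      peri_only$puncta$x)]))
  expect_identical(peri_only$realized$n_central, 0L)
  expect_identical(peri_only$realized$n_peripheral, nrow(peri_only$puncta))

  expect_identical(plant_puncta(b, 2, 1, seed = 6)$puncta,
                   plant_puncta(b, 2, 1, seed = 6)$puncta)
  # pairwise spacing >= 2 px among kept puncta
  p <- plant_puncta(b, 4, 4, seed = 8)$puncta
  if (nrow(p) > 1) {
    d2 <- as.matrix(dist(p[, c("y", "x")]))^2
    expect_gte(min(d2[upper.tri(d2)]), 4)
  }
  expect_error(plant_puncta(b, 5e3, 0, seed = 1), "saturation")
})

test_that("rendering conserves planted intensity and honours limit cases", {
  b <- make_bouton_geometry(1, c(4, 4), seed = 7)
  empty_truth <- scene_truth(b, list(data.frame(z = integer(), y = integer(),
                                                x = integer(),
                                                amplitude = numeric())))
  sc0 <- render_scene(empty_truth, background_level = 0,
                      noise = list(gaussian_sd = 0), quantize_bits = NULL,
                      channels = "vesicle")
  expect_true(all(sc0$channels$vesicle$voxels == 0))

  ctr <- round(b[[1]]$center)
  one <- scene_truth(b, list(data.frame(z = 1L, y = ctr[1], x = ctr[2],
                                        amplitude = 123.5)))
  sc1 <- render_scene(one, psf_sigma_nm = 0, background_level = 0,
                      noise = list(gaussian_sd = 0), quantize_bits = NULL,
                      channels = "vesicle")
  v <- sc1$channels$vesicle$voxels
  expect_identical(sum(v > 0), 1L)
  expect_identical(v[ctr[1], ctr[2], 1], 123.5)

  pts <- plant_puncta(b[[1]], 1.5, 1.5, seed = 5)$puncta
  truth <- scene_truth(b, list(pts))
  sc <- render_scene(truth, background_level = 0,
                     noise = list(gaussian_sd = 0), quantize_bits = NULL,
                     channels = "vesicle")
  expect_equal(sum(sc$channels$vesicle$voxels), sum(pts$amplitude),
               tolerance = 1e-9)

  sc_a <- render_scene(truth, seed = 42)
  sc_b <- render_scene(truth, seed = 42)
  expect_identical(sc_a$channels$vesicle$voxels, sc_b$channels$vesicle$voxels)
  expect_identical(sc_a$channels$membrane$voxels,
                   sc_b$channels$membrane$voxels)
})

test_that("FM pairs plant the stated unload fraction in the noiseless limit", {
  p0 <- make_fm_pair(0, noise = list(gaussian_sd = 0), seed = 3)
  expect_identical(p0$load$channels$dye_load$voxels,
                   p0$unload$channels$dye_unload$voxels)
  p1 <- make_fm_pair(1, noise = list(gaussian_sd = 0), seed = 3)
  fp <- Reduce(`|`, lapply(p1$truth$boutons, `[[`, "footprint"))
  un <- p1$unload$channels$dye_unload$voxels[, , 1]
  expect_true(all(un[fp] == p1$truth$extra$remote_bk))
})

test_that("coloc scenes place the requested overlap structure", {
  full <- make_coloc_scene(1, seed = 9)
  csp <- full$truth$puncta[[1]]
  rab <- full$truth$extra$rab
  key <- paste(csp$y, csp$x)
  expect_true(all(paste(rab$y, rab$x) %in% key))
  expect_identical(full$truth$overlap_fraction, 1)

  none <- make_coloc_scene(0, seed = 9)
  csp <- none$truth$puncta[[1]]; rab <- none$truth$extra$rab
  d2min <- min(outer(rab$y, csp$y, `-`)^2 + outer(rab$x, csp$x, `-`)^2)
  expect_gte(d2min, 36)   # min_sep_px = 6 enforced
  expect_identical(none$truth$overlap_fraction, 0)
})

test_that("scene truths serialize losslessly to YAML", {
  sc <- make_puncta_scene(n_boutons = 2, peripheral_density = 2,
                          central_density = 1, area_range_um2 = c(3, 6),
                          seed = 13)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_truth(sc$truth, path)
  back <- read_truth(path)
  expect_identical(back$boutons[[1]]$footprint, sc$truth$boutons[[1]]$footprint)
  expect_identical(back$boutons[[2]]$footprint, sc$truth$boutons[[2]]$footprint)
  expect_equal(back$puncta[[1]]$y, sc$truth$puncta[[1]]$y)
  expect_equal(back$puncta[[2]]$amplitude, sc$truth$puncta[[2]]$amplitude)
  expect_equal(back$calibration, sc$truth$calibration)
})
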