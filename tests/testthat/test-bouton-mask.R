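# Segmentation from the membrane rim, size filtering, BIC size model.

test_that("degenerate membrane images segment to an empty list with a warning", {
  zeros <- frame_stack(matrix(0, 64, 64), role = "membrane")
  expect_warning(res <- segment_boutons(zeros), "constant")
  expect_length(res, 0)
})

test_that("segmentation recovers generator footprints (Jaccard >= 0.9)", {
  sc <- make_puncta_scene(n_boutons = 3, peripheral_density = 1,
                          central_density = 1, seed = 21)
  masks <- segment_boutons(sc$scene)
  expect_length(masks, 3)
  m <- match_boutons(masks, sc$truth$boutons)
  expect_true(all(!is.na(m$mask_label)))
  expect_true(all(m$jaccard >= 0.9))
  # labels follow raster order of centroids
  cy <- vapply(masks, function(x) round(x$centroid[1]), 0)
  cx <- vapply(masks, function(x) round(x$centroid[2]), 0)
  expect_identical(order(cy, cx), seq_along(masks))
})

test_that("a noise-free rim of a 3 um^2 bouton segments to within 10% area", {
  geom <- make_bouton_geometry(1, c(3, 3), shape_irregularity = 0, seed = 4)
  truth <- scene_truth(geom)
  sc <- render_scene(truth, noise = list(gaussian_sd = 0), background_level = 0,
                     channels = "membrane", seed = 1)
  masks <- segment_boutons(sc)
  expect_length(masks, 1)
  expect_lt(abs(masks[[1]]$area_um2 - 3) / 3, 0.10)
  expect_gte(jaccard(masks[[1]]$footprint, geom[[1]]$footprint), 0.9)
})

test_that("the size filter uses inclusive bounds and partitions exhaustively", {
  fake <- lapply(c(1.0, 2.5, 7.0, 12.0, 15.0),
                 function(a) list(area_um2 = a))
  flt <- filter_by_area(fake)
  expect_identical(vapply(flt$kept, `[[`, 0, "area_um2"), c(2.5, 7.0, 12.0))
  expect_identical(vapply(flt$rejected, `[[`, 0, "area_um2"), c(1.0, 15.0))
  expect_identical(length(flt$kept) + length(flt$rejected), length(fake))

  empty <- filter_by_area(list())
  expect_length(empty$kept, 0)
  expect_length(empty$rejected, 0)
})

test_that("center slice picks the maximum-area section, ties to the middle", {
  one <- frame_stack(matrix(0, 32, 32), role = "membrane")
  expect_identical(center_slice(one, list(footprint = matrix(TRUE, 32, 32))),
                   1L)

  # widest membrane extent planted on slice 4 of 7
  geom <- make_bouton_geometry(1, c(8, 8), shape_irregularity = 0, seed = 6)
  truth <- scene_truth(geom)
  sc <- render_scene(truth, nz = 7, center_z = 4, z_shrink_px = 3,
                     noise = list(gaussian_sd = 0), channels = "membrane",
                     seed = 1)
  masks <- segment_boutons(sc)
  expect_identical(center_slice(sc, masks[[1]]), 4L)

  # perfectly uniform across 5 slices: middle slice (index 3 of 1..5)
  disk <- disk_mask(10, c(32, 32))
  rim <- disk & !disk_mask(8, c(32, 32))
  vol <- array(rep(rim * 1000, 5), c(32, 32, 5))
  st <- calibrated_stack(vol, 27.5, 0.1145, "membrane")
  expect_identical(center_slice(st, list(footprint = disk), threshold = 500),
                   3L)
})

test_that("BIC model selection distinguishes one- and two-component samples", {
  expect_error(fit_size_model(1:5), "insufficient")

  set.seed(101)
  x1 <- rnorm(500, 6, 1.5)
  f1 <- fit_size_model(x1, max_components = 3)
  expect_identical(f1$selected_k, 1L)
  expect_length(f1$bic_values, 3)
  # likelihood never decreases with k (within EM tolerance)
  lls <- vapply(f1$candidates, function(c) c$loglik, 0)
  expect_true(all(diff(lls) > -1e-6))
  # BIC decreases with log-likelihood at fixed k by construction
  expect_equal(f1$bic_values,
               -2 * lls + (3 * (1:3) - 1) * log(500), tolerance = 1e-12)

  x2 <- c(rnorm(250, 4, 0.8), rnorm(250, 10, 0.8))
  f2 <- fit_size_model(x2, max_components = 3)
  expect_identical(f2$selected_k, 2L)
  # type-Ib interval covers the dominant component
  expect_true(f2$type_ib_range[1] < 10 && f2$type_ib_range[2] > 4)

  expect_identical(fit_size_model(x1, seed = 5)$bic_values,
                   fit_size_model(x1, seed = 5)$bic_values)
})
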