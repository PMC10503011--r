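# Background estimation, mean bouton intensity, normalization, FM1-43.

test_that("background estimation reduces to the constant on flat images", {
  frame <- matrix(7, 96, 96)
  masks <- list(list(footprint = disk_mask(15, c(96, 96)), label = 1L))
  expect_equal(estimate_background(frame, masks, "remote"), 7)
  expect_equal(estimate_background(frame, masks, "local"), 7)
  expect_equal(estimate_background(frame, masks, "combined"), 7)

  all_mask <- list(list(footprint = matrix(TRUE, 96, 96)))
  expect_error(estimate_background(frame, all_mask), "no background")
})

test_that("background recovery on a generated scene with a local gradient", {
  sc <- make_fm_pair(0.5, local_bk = 70, remote_bk = 40,
                     noise = list(gaussian_sd = 3), seed = 21)
  masks <- truth_masks(sc$truth$boutons)
  remote <- estimate_background(sc$load$channels$dye_load, masks, "remote")
  local <- estimate_background(sc$load$channels$dye_load, masks, "local")
  expect_lt(abs(remote - 40), 2)
  expect_true(all(abs(local - 70) < 2))
  comb <- estimate_background(sc$load$channels$dye_load, masks, "combined")
  expect_true(all(abs(comb - 55) < 2))
})

test_that("the 5-slice mean rule reproduces the worked slice example exactly", {
  fp <- disk_mask(6, c(24, 24))
  vol <- array(60, c(24, 24, 5))
  vol[, , 3] <- 100
  st <- calibrated_stack(vol, 60, 0.5, "vesicle")
  m <- list(footprint = fp, label = 1L)
  im <- bouton_mean_intensity(st, m, center_slice = 3, n_flank = 2, bk = 10)
  expect_identical(im$raw_mean, (100 + 60 * 4) / 5)
  expect_identical(im$corrected_mean, 58)
  expect_false(im$clipped)

  # uniform stack, zero background: raw mean is the value itself
  u <- calibrated_stack(array(42, c(24, 24, 5)), 60, 0.5, "vesicle")
  expect_identical(bouton_mean_intensity(u, m, 3)$raw_mean, 42)

  # clipping at the stack bounds is recorded
  im2 <- bouton_mean_intensity(st, m, center_slice = 1, n_flank = 2)
  expect_true(im2$clipped)
  expect_identical(im2$slices_used, 1:3)

  # sum aggregation escape hatch
  ims <- bouton_mean_intensity(st, m, 3, slice_agg = "sum", bk = 10)
  expect_identical(ims$raw_mean, 100 + 60 * 4)

  expect_error(bouton_mean_intensity(st, list(footprint = fp & FALSE), 3),
               "empty ROI")
})

test_that("adding a constant to image and background leaves corrections unchanged", {
  fp <- disk_mask(6, c(24, 24))
  set.seed(5)
  vol <- array(runif(24 * 24 * 3, 50, 150), c(24, 24, 3))
  m <- list(footprint = fp, label = 1L)
  s1 <- calibrated_stack(vol, 60, 0.5)
  s2 <- calibrated_stack(vol + 30, 60, 0.5)
  a <- bouton_mean_intensity(s1, m, 2, bk = 20)
  b <- bouton_mean_intensity(s2, m, 2, bk = 50)
  expect_equal(a$corrected_mean, b$corrected_mean, tolerance = 1e-12)
  # flooring at zero with the raw value retained
  c_ <- bouton_mean_intensity(s1, m, 2, bk = 1e4)
  expect_identical(c_$corrected_mean, 0)
  expect_lt(c_$raw_mean - c_$bk, 0)
})

test_that("control normalization is per-experiment, exact, and idempotent", {
  df <- data.frame(corrected_mean = c(10, 10, 15),
                   group = c("control", "control", "mutant"))
  out <- normalize_to_control(df)
  expect_identical(out$normalized, c(1, 1, 1.5))
  expect_identical(mean(out$normalized[out$group == "control"]), 1)

  solo <- data.frame(corrected_mean = 7, group = "control")
  expect_identical(normalize_to_control(solo)$normalized, 1)

  # idempotence: re-normalizing normalized values changes nothing
  out2 <- out
  out2$corrected_mean <- out$normalized
  expect_identical(normalize_to_control(out2)$normalized, out$normalized)

  # two experiments never share control means
  df2 <- data.frame(corrected_mean = c(10, 20, 40, 10),
                    group = c("control", "mutant", "control", "mutant"),
                    experiment = c("e1", "e1", "e2", "e2"))
  out3 <- normalize_to_control(df2)
  brute <- c(10 / 10, 20 / 10, 40 / 40, 10 / 40)
  expect_identical(out3$normalized, brute)

  expect_error(normalize_to_control(
    data.frame(corrected_mean = 1, group = "mutant")), "control group empty")
  expect_error(normalize_to_control(
    data.frame(corrected_mean = 0, group = "control")), "not positive")
})

test_that("FM metrics reproduce exact ratios and stay in bounds without noise", {
  pair <- make_fm_pair(0.6, load_mean = 1000, noise = list(gaussian_sd = 0),
                       seed = 31)
  masks <- truth_masks(pair$truth$boutons)
  res <- fm_metrics(pair$load, pair$unload, masks)
  # noiseless: corrected load 1000, corrected unload 400 -> exactly 0.600
  expect_equal(res$per_bouton$load_mean, rep(1000, 4), tolerance = 1e-12)
  expect_equal(res$per_bouton$unload_fraction, rep(0.6, 4), tolerance = 1e-12)
  expect_identical(res$per_bouton$unload_fraction,
                   res$per_bouton$unload_fraction_raw)
  expect_equal(res$summary$mean_unload_fraction, 0.6, tolerance = 1e-12)

  same <- make_fm_pair(0, noise = list(gaussian_sd = 0), seed = 32)
  res0 <- fm_metrics(same$load, same$unload, truth_masks(same$truth$boutons))
  expect_true(all(res0$per_bouton$unload_fraction == 0))
})

test_that("planted unload fractions are recovered under default noise", {
  recovered <- sapply(1:10, function(s) {
    pair <- make_fm_pair(0.6, seed = 100 + s)
    fm_metrics(pair$load, pair$unload,
               truth_masks(pair$truth$boutons))$summary$mean_unload_fraction
  })
  expect_lt(abs(mean(recovered) - 0.6), 0.02)
})

test_that("planted per-bouton intensity ratios are recovered after normalization", {
  ratios <- sapply(1:10, function(s) {
    sc <- make_intensity_scene(c(200, 140), seed = 200 + s)  # 1 : 0.7
    masks <- truth_masks(sc$truth$boutons)
    bk <- estimate_background(sc$scene$channels$vesicle, masks, "combined")
    m1 <- bouton_mean_intensity(sc$scene$channels$vesicle, masks[[1]], 1,
                                n_flank = 0, bk = bk[1])
    m2 <- bouton_mean_intensity(sc$scene$channels$vesicle, masks[[2]], 1,
                                n_flank = 0, bk = bk[2])
    m2$corrected_mean / m1$corrected_mean
  })
  expect_lt(abs(mean(ratios) - 0.7), 0.05)
})
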