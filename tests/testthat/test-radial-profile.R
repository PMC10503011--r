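# Program B: erosion shells, equal-area bands, quartiles, mobilization ratios.

test_that("erosion shells peel the footprint exactly, outermost first", {
  one <- matrix(FALSE, 8, 8); one[4, 4] <- TRUE
  sh <- erosion_shells(list(footprint = one))
  expect_length(sh, 1)
  expect_identical(sh[[1]], one)

  sq <- matrix(FALSE, 9, 9); sq[3:7, 3:7] <- TRUE
  sh <- erosion_shells(list(footprint = sq))
  expect_identical(vapply(sh, sum, 0L), c(16L, 8L, 1L))
  expect_identical(Reduce(`|`, sh), sq)

  for (s in 1:20) {
    b <- random_mask(s + 40, area_range = c(2.5, 8))
    sh <- erosion_shells(list(footprint = b$footprint))
    expect_identical(Reduce(`|`, sh), b$footprint)  # pixel-exact union
    expect_identical(sum(vapply(sh, sum, 0L)), sum(b$footprint)) # disjoint
  }
})

# independent re-statement of the whole-shell midpoint grouping rule
oracle_shell_band <- function(shell_sizes, n_bands) {
  total <- sum(shell_sizes)
  lo <- 0
  band <- integer(length(shell_sizes))
  for (i in seq_along(shell_sizes)) {
    hi <- lo + shell_sizes[i]
    mid <- (lo + hi) / 2 / total
    band[i] <- min(n_bands, floor(mid * n_bands) + 1L)
    lo <- hi
  }
  band
}

test_that("shell-to-band grouping matches the brute-force oracle", {
  for (s in 1:15) {
    b <- random_mask(s + 70, area_range = c(2.5, 9))
    sh <- erosion_shells(list(footprint = b$footprint))
    sizes <- vapply(sh, sum, 0L)
    for (n_bands in c(10L, 4L)) {
      bands <- bands_from_shells(sh, n_bands)
      expect_identical(bands$shell_band, oracle_shell_band(sizes, n_bands))
      # exact partition of the footprint
      expect_identical(Reduce(`|`, bands$band_masks), b$footprint)
      areas_px <- vapply(bands$band_masks, sum, 0L)
      expect_identical(sum(areas_px), sum(b$footprint))
      expect_identical(bands$band_edges,
                       seq(0, 1, length.out = n_bands + 1L))
    }
  }
  b <- random_mask(99)
  sh <- erosion_shells(list(footprint = b$footprint))
  single <- bands_from_shells(sh, 1L)
  expect_identical(single$band_masks[[1]], b$footprint)
})

test_that("band densities count particles exhaustively; outer-only signal stays in band 1", {
  b <- make_bouton_geometry(1, c(6, 6), 0.2, seed = 5)[[1]]
  m <- truth_mask(b)
  pl <- plant_puncta(b, 2, 2, seed = 9)
  ps <- particles_from_truth(pl$puncta)
  rp <- radial_profile(m, ps)
  expect_identical(sum(rp$band_counts), ps$n_total)
  expect_equal(sum(rp$band_areas_um2), b$area_um2, tolerance = 1e-12)

  # all particles in the outermost shell
  sh <- erosion_shells(m)
  outer_px <- which(sh[[1]], arr.ind = TRUE)
  pts <- data.frame(y = outer_px[1:5, 1], x = outer_px[1:5, 2], amplitude = 1)
  rp1 <- radial_profile(m, particles_from_truth(pts))
  expect_gt(rp1$band_values[1], 0)
  expect_true(all(rp1$band_values[-1] == 0))

  empty <- particles_from_truth(data.frame(y = integer(), x = integer(),
                                           amplitude = numeric()))
  rp0 <- radial_profile(m, empty)
  expect_true(all(rp0$band_values == 0))
})

test_that("intensity-mode densities are linear in the signal and clip at zero", {
  b <- make_bouton_geometry(1, c(4, 4), 0.2, seed = 8)[[1]]
  m <- truth_mask(b)
  set.seed(3)
  frame <- matrix(runif(prod(dim(b$footprint)), 0, 50), nrow(b$footprint))
  r1 <- radial_profile(m, frame, mode = "intensity")
  r2 <- radial_profile(m, 2 * frame, mode = "intensity")
  expect_identical(r2$band_values, 2 * r1$band_values)

  rbk <- radial_profile(m, frame, mode = "intensity", bk = 25)
  expect_gt(rbk$clipped_intensity, 0)
  expect_true(all(rbk$band_values >= 0))
})

test_that("quartiles are rebuilt from shells, matching a direct 4-band profile", {
  b <- make_bouton_geometry(1, c(7, 7), 0.3, seed = 12)[[1]]
  m <- truth_mask(b)
  pl <- plant_puncta(b, 2, 1, seed = 4)
  ps <- particles_from_truth(pl$puncta)
  dec <- radial_profile(m, ps, n_bands = 10L)
  q <- quartile_profile(dec)
  direct <- radial_profile(m, ps, n_bands = 4L)
  expect_identical(q$band_values, direct$band_values)
  expect_identical(q$band_areas_um2, direct$band_areas_um2)
  expect_identical(q$band_edges, c(0, 0.25, 0.5, 0.75, 1))
  expect_identical(sum(q$band_counts), ps$n_total)
})

test_that("mobilization ratios are elementwise with flagged undefined bands", {
  b <- make_bouton_geometry(1, c(5, 5), 0.2, seed = 6)[[1]]
  m <- truth_mask(b)
  pl <- plant_puncta(b, 2, 1, seed = 14)
  ps <- particles_from_truth(pl$puncta)
  prof <- radial_profile(m, ps)
  same <- mobilization_ratio(prof, prof)
  expect_true(all(same$ratio[same$defined] == 1))

  doubled <- prof
  doubled$band_values <- 2 * prof$band_values
  r2 <- mobilization_ratio(doubled, prof)
  expect_true(all(r2$ratio[r2$defined] == 2))
  # zero-density bands in the denominator are undefined, not Inf
  expect_true(all(is.na(r2$ratio[!r2$defined])))

  q <- quartile_profile(prof)
  expect_error(mobilization_ratio(q, prof), "band scheme")

  zdA <- list(peripheral_density = 2, central_density = 0)
  zdB <- list(peripheral_density = 1, central_density = 0.5)
  zr <- mobilization_ratio(zdA, zdB)
  expect_identical(zr$peripheral, 2)
  expect_identical(zr$central, 0)
  zr2 <- mobilization_ratio(zdB, zdA)   # central denominator is 0
  expect_true(is.na(zr2$central))
})

test_that("peripheral-band and outermost-decile densities agree across boutons", {
  set.seed(77)
  n <- 200
  # truth spans the span of peripheral densities the stimulation studies
  # produce; a wide (log-uniform) spread so between-bouton signal dominates
  # the Poisson counting noise of the thin outer bands
  dp <- exp(runif(n, log(0.3), log(10)))
  peri <- numeric(n); outer <- numeric(n)
  for (i in seq_len(n)) {
    b <- make_bouton_geometry(1, c(6, 9), seed = 4000 + i)[[1]]
    pl <- plant_puncta(b, dp[i], dp[i] / 4, seed = 8000 + i)
    ps <- particles_from_truth(pl$puncta)
    zd <- zone_density(ps, pl$zones)
    rp <- radial_profile(truth_mask(b), ps)
    peri[i] <- zd$peripheral_density
    outer[i] <- rp$band_values[1]
  }
  expect_gt(cor(peri, outer, method = "spearman"), 0.8)
})
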