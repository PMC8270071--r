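test_that("detection band is inclusive at both bounds", {
  arr <- array(40, c(4, 4, 4))
  arr[1, 1, 1] <- 450
  arr[2, 1, 1] <- 3070
  arr[3, 1, 1] <- 449.999
  arr[4, 1, 1] <- 3070.001
  mask <- detect_calcification(ct_volume(arr, c(1, 1, 1)))
  expect_true(mask$mask[1, 1, 1])
  expect_true(mask$mask[2, 1, 1])
  expect_false(mask$mask[3, 1, 1])
  expect_false(mask$mask[4, 1, 1])
})

test_that("only in-band voxels are masked", {
  arr <- array(40, c(3, 1, 1))
  arr[1:3, 1, 1] <- c(300, 500, 3100)
  mask <- detect_calcification(ct_volume(arr, c(1, 1, 1)))
  expect_equal(as.vector(mask$mask), c(FALSE, TRUE, FALSE))
  expect_error(detect_calcification(ct_volume(arr, c(1, 1, 1)), 500, 400), "min_hu")
})

test_that("an all-soft-tissue volume yields an empty mask and zero coverage", {
  ph <- generate_phantom(small_spec())
  mask <- detect_calcification(ph$volume)
  expect_equal(sum(mask$mask), 0)
  for (wall in c("anterior", "posterior")) {
    cov <- wall_coverage(mask, ph$geometry, wall)
    expect_equal(cov$fraction, 0)
    expect_equal(nrow(cov$intervals), 0)
  }
})

test_that("coverage recovers the phantom's analytic fraction on the right wall only", {
  ph <- generate_phantom(small_spec(list(frac_plaque("anterior", 0.5))))
  mask <- detect_calcification(ph$volume)
  dz_over_L <- ph$volume$spacing[3] / (ph$geometry$z_bif - ph$geometry$z_ima)
  ant <- wall_coverage(mask, ph$geometry, "anterior")
  post <- wall_coverage(mask, ph$geometry, "posterior")
  expect_lte(abs(ant$fraction - 0.5), dz_over_L)
  expect_equal(post$fraction, 0)
})

test_that("coverage of overlapping plaques equals the union, per the rasterisation oracle", {
  L <- 36
  spec <- small_spec(list(plaque_spec("anterior", 6 + c(0, 0.2 * L)),
                          plaque_spec("anterior", 6 + c(0.1 * L, 0.3 * L))))
  ph <- generate_phantom(spec)
  mask <- detect_calcification(ph$volume)
  cov <- wall_coverage(mask, ph$geometry, "anterior")
  oracle <- rasterize_union_length(c(6, 6 + 0.1 * L), c(6 + 0.2 * L, 6 + 0.3 * L),
                                   6, 42, res = 0.1) / L
  dz_over_L <- ph$volume$spacing[3] / L
  expect_lte(abs(cov$fraction - oracle), dz_over_L)
})

test_that("coverage intervals are disjoint, sorted, inside the segment; fraction in [0,1]", {
  for (seed in c(2, 4, 6)) {
    ph <- generate_phantom(random_phantom_spec(seed, shape = c(40, 40, 48),
                                               spacing = c(1.5, 1.5, 1),
                                               z_ima = 6, z_bif = 42))
    mask <- detect_calcification(ph$volume)
    for (wall in c("anterior", "posterior")) {
      cov <- wall_coverage(mask, ph$geometry, wall)
      expect_gte(cov$fraction, 0)
      expect_lte(cov$fraction, 1)
      iv <- cov$intervals
      if (nrow(iv) > 1) {
        expect_true(all(iv[-1, "start"] > iv[-nrow(iv), "end"]))
      }
      if (nrow(iv) > 0) {
        expect_gte(min(iv[, "start"]), ph$geometry$z_ima)
        expect_lte(max(iv[, "end"]), ph$geometry$z_bif)
      }
    }
  }
})

test_that("adding a plaque never decreases the coverage fraction", {
  base <- small_spec(list(frac_plaque("anterior", 0.3)))
  more <- small_spec(list(frac_plaque("anterior", 0.3),
                          plaque_spec("anterior", c(30, 40))))
  f1 <- wall_coverage(detect_calcification(generate_phantom(base)$volume),
                      generate_phantom(base)$geometry, "anterior")$fraction
  f2 <- wall_coverage(detect_calcification(generate_phantom(more)$volume),
                      generate_phantom(more)$geometry, "anterior")$fraction
  expect_gte(f2, f1)
})

test_that("noise-free measured fractions track ground truth within one voxel z-extent", {
  for (seed in c(1, 3, 5, 8)) {
    spec <- random_phantom_spec(seed)
    spec$noise_sigma <- 0
    ph <- generate_phantom(spec)
    mask <- detect_calcification(ph$volume)
    dz_over_L <- ph$volume$spacing[3] / (ph$geometry$z_bif - ph$geometry$z_ima)
    expect_lte(abs(wall_coverage(mask, ph$geometry, "anterior")$fraction -
                     ph$truth$anterior_fraction), dz_over_L)
    expect_lte(abs(wall_coverage(mask, ph$geometry, "posterior")$fraction -
                     ph$truth$posterior_fraction), dz_over_L)
  }
})

test_that("geometry outside the volume is an error", {
  ph <- generate_phantom(small_spec())
  mask <- detect_calcification(ph$volume)
  cl <- data.frame(z = c(0, 200), x = 30, y = 30)
  bad_geom <- aorta_geometry(cl, 9, 2, z_ima = 100, z_bif = 150)
  expect_error(wall_coverage(mask, bad_geom, "anterior"), "outside")
})
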