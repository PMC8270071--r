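test_that("phantom generation is deterministic in the spec and seed", {
  spec <- small_spec(list(frac_plaque("anterior", 0.4)), noise_sigma = 10, seed = 11L)
  ph1 <- generate_phantom(spec)
  ph2 <- generate_phantom(spec)
  expect_identical(ph1$volume$data, ph2$volume$data)
  spec2 <- small_spec(list(frac_plaque("anterior", 0.4)), noise_sigma = 10, seed = 12L)
  expect_false(identical(generate_phantom(spec2)$volume$data, ph1$volume$data))
})

test_that("a plaque-free phantom has zero fractions and total score 0", {
  ph <- generate_phantom(small_spec())
  expect_equal(ph$truth$anterior_fraction, 0)
  expect_equal(ph$truth$posterior_fraction, 0)
  expect_equal(ph$truth$total_score, 0L)
})

test_that("a plaque spanning half the segment gives fraction 0.5, sub-score 2", {
  ph <- generate_phantom(small_spec(list(frac_plaque("anterior", 0.5))))
  expect_equal(ph$truth$anterior_fraction, 0.5)
  expect_equal(ph$truth$anterior_score, 2L)
  expect_equal(ph$truth$posterior_fraction, 0)
})

test_that("overlapping plaques are merged: ground truth uses the interval union", {
  # [0, 0.2L] and [0.1L, 0.3L] union to 0.3L, not 0.3L + 0.1L
  L <- 36
  spec <- small_spec(list(plaque_spec("anterior", 6 + c(0, 0.2 * L)),
                          plaque_spec("anterior", 6 + c(0.1 * L, 0.3 * L))))
  ph <- generate_phantom(spec)
  expect_equal(ph$truth$anterior_fraction, 0.3)
  # analytic fraction vs fine-grained rasterisation oracle
  oracle <- rasterize_union_length(c(6, 6 + 0.1 * L), c(6 + 0.2 * L, 6 + 0.3 * L),
                                   6, 42, res = 0.01) / L
  expect_equal(ph$truth$anterior_fraction, oracle, tolerance = 1e-9)
})

test_that("analytic fractions match a brute-force rasterisation on random specs", {
  for (seed in 1:10) {
    spec <- random_phantom_spec(seed, shape = c(40, 40, 48),
                                spacing = c(1.5, 1.5, 1), z_ima = 6, z_bif = 42)
    gt <- generate_phantom(spec)$truth
    for (wall in c("anterior", "posterior")) {
      ps <- Filter(function(p) p$wall == wall, spec$plaques)
      oracle <- rasterize_union_length(
        vapply(ps, function(p) p$z_interval[1], numeric(1)),
        vapply(ps, function(p) p$z_interval[2], numeric(1)),
        spec$z_ima, spec$z_bif, res = 0.01) / (spec$z_bif - spec$z_ima)
      measured <- if (wall == "anterior") gt$anterior_fraction else gt$posterior_fraction
      expect_equal(measured, oracle, tolerance = 1e-9)
    }
  }
})

test_that("without noise, every voxel at/above 450 HU lies inside a declared plaque", {
  spec <- small_spec(list(frac_plaque("anterior", 0.4),
                          frac_plaque("posterior", 0.7)))
  ph <- generate_phantom(spec)
  idx <- which(ph$volume$data >= 450, arr.ind = TRUE)
  expect_gt(nrow(idx), 0)
  sp <- ph$volume$spacing
  cz <- (idx[, 3] - 0.5) * sp[3]
  cy <- (idx[, 2] - 0.5) * sp[2]
  cy0 <- 40 * 1.5 / 2
  in_declared <- rep(FALSE, nrow(idx))
  for (p in spec$plaques) {
    zin <- cz >= p$z_interval[1] & cz < p$z_interval[2]
    side_ok <- if (p$wall == "anterior") cy > cy0 else cy < cy0
    in_declared <- in_declared | (zin & side_ok)
  }
  expect_true(all(in_declared))
})

test_that("ground truth JSON round-trips losslessly and flags missing keys", {
  ph <- generate_phantom(small_spec(list(frac_plaque("anterior", 0.5),
                                         frac_plaque("posterior", 0.25))))
  path <- tempfile(fileext = ".json")
  write_ground_truth(ph$truth, path)
  back <- read_ground_truth(path)
  expect_equal(back, ph$truth)
  expect_identical(back$anterior_fraction, 0.5)  # decimal-exact
  # drop a required key
  obj <- jsonlite::read_json(path)
  obj$total_score <- NULL
  jsonlite::write_json(obj, path, auto_unbox = TRUE)
  expect_error(read_ground_truth(path), "total_score")
})

test_that("invalid specs are rejected with the violated invariant named", {
  expect_error(plaque_spec("anterior", c(10, 20), intensity = 300), "450")
  expect_error(plaque_spec("anterior", c(20, 10)), "start < end")
  expect_error(plaque_spec("lateral", c(10, 20)), "anterior")
  expect_error(plaque_spec("anterior", c(10, 20), angular_halfwidth = 120), "angular")
  expect_error(small_spec(list(plaque_spec("anterior", c(1, 5)))), "z_ima")
  expect_error(phantom_spec(z_ima = 50, z_bif = 20), "z_ima")
  expect_error(phantom_spec(lumen_hu = 500), "lumen_hu")
})

test_that("the default sampler keeps fractions clear of rubric boundaries", {
  for (seed in 1:20) {
    spec <- random_phantom_spec(seed)
    gt <- generate_phantom(spec)$truth
    for (f in c(gt$anterior_fraction, gt$posterior_fraction)) {
      if (f == 0) next
      expect_gte(abs(f - 1 / 3), 0.05)
      expect_gte(abs(f - 2 / 3), 0.05)
      expect_gte(f, 0.05)
    }
  }
  # deterministic function of the seed
  expect_equal(random_phantom_spec(3), random_phantom_spec(3))
})

test_that("phantom spec JSON round-trips", {
  spec <- random_phantom_spec(9)
  path <- tempfile(fileext = ".json")
  write_phantom_spec(spec, path)
  expect_equal(read_phantom_spec(path), spec)
})
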