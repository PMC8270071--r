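test_that("identical rater columns give ICC exactly 1", {
  m <- rater_matrix(cbind(c(1, 2, 3), c(1, 2, 3)))
  for (model in c("two_way_random_absolute_single",
                  "two_way_random_absolute_average",
                  "two_way_consistency_single")) {
    res <- icc(m, model = model)
    expect_equal(res$icc, 1.0)
    expect_false(res$undefined)
  }
})

test_that("ICC matches the definitional sums-of-squares oracle on random matrices", {
  set.seed(101)
  for (rep in 1:20) {
    m <- matrix(sample(0:6, 30, replace = TRUE), 10, 3)
    if (stats::var(as.vector(m)) == 0) next
    for (model in c("two_way_random_absolute_single",
                    "two_way_random_absolute_average",
                    "two_way_consistency_single")) {
      expect_equal(icc(m, model = model)$icc, oracle_icc(m, model),
                   tolerance = 1e-10)
    }
  }
})

test_that("constant rater offsets lower absolute agreement but not consistency", {
  m <- cbind(c(1, 2, 3, 4, 2), c(2, 3, 4, 5, 3))  # rater 2 = rater 1 + 1
  abs_icc <- icc(m, "two_way_random_absolute_single")$icc
  con_icc <- icc(m, "two_way_consistency_single")$icc
  expect_lt(abs_icc, con_icc)
  expect_equal(con_icc, 1.0)
})

test_that("ICC is invariant to adding a constant to the whole matrix", {
  set.seed(5)
  m <- matrix(sample(0:5, 24, replace = TRUE), 8, 3)
  for (model in c("two_way_random_absolute_single", "two_way_consistency_single")) {
    expect_equal(icc(m, model)$icc, icc(m + 1, model)$icc, tolerance = 1e-12)
  }
})

test_that("ICC confidence bounds bracket the estimate at plausible widths", {
  m <- simulate_raters(rep(0:6, length.out = 40), 3, 0.15, seed = 3)
  res <- icc(m)
  expect_lte(res$ci_low, res$icc)
  expect_gte(res$ci_high, res$icc)
  expect_gt(res$ci_high - res$ci_low, 0)
  expect_lte(res$ci_high, 1)
})

test_that("a zero-variance matrix yields an undefined ICC, not an error", {
  res <- icc(matrix(3, 4, 3))
  expect_true(res$undefined)
  expect_true(is.na(res$icc))
  expect_error(icc(matrix(3, 1, 3)), "degenerate")
})

test_that("Spearman rho is +/-1 on monotone and antitone inputs", {
  expect_equal(spearman_rank(1:4, c(10, 20, 30, 40))$rho, 1.0)
  expect_equal(spearman_rank(1:3, 3:1)$rho, -1.0)
})

test_that("Spearman is symmetric and invariant under monotone transforms", {
  set.seed(11)
  x <- rnorm(8); y <- rnorm(8)
  a <- spearman_rank(x, y); b <- spearman_rank(y, x)
  expect_equal(a$rho, b$rho)
  expect_equal(a$p, b$p)
  expect_equal(spearman_rank(exp(x), y^3)$rho,
               spearman_rank(x, sign(y) * abs(y)^3)$rho)
})

test_that("exact permutation p-values match brute-force enumeration, including ties", {
  cases <- list(
    list(x = c(1, 2, 3, 4, 5), y = c(2, 1, 4, 3, 5)),
    list(x = c(1, 2, 2, 4, 5), y = c(3, 1, 4, 4, 5)),   # ties in both
    list(x = c(0, 3, 1, 6), y = c(2, 2, 5, 1)),
    list(x = c(1, 5, 2, 4, 3, 6, 0), y = c(0, 4, 2, 4, 3, 6, 1)))
  for (cs in cases) {
    got <- spearman_rank(cs$x, cs$y)
    want <- oracle_spearman(cs$x, cs$y)
    expect_equal(got$rho, want$rho, tolerance = 1e-12)
    expect_equal(got$p, want$p, tolerance = 1e-12)
    expect_equal(got$method, "exact")
  }
})

test_that("large-sample p-values use the t approximation and agree with cor.test", {
  set.seed(23)
  x <- rnorm(30); y <- x + rnorm(30)
  got <- spearman_rank(x, y)
  ref <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  expect_equal(got$method, "t_approx")
  expect_equal(got$rho, unname(ref$estimate), tolerance = 1e-12)
  expect_lt(got$p, 0.01)
})

test_that("constant vectors leave rho undefined", {
  res <- spearman_rank(c(2, 2, 2), c(1, 2, 3))
  expect_true(res$undefined)
})

test_that("simulated raters reproduce the truth at error_prob 0 and always differ at 1", {
  truth <- rep(0:6, length.out = 21)
  m0 <- simulate_raters(truth, 3, 0, seed = 1)
  expect_true(all(m0 == truth))
  expect_equal(icc(m0)$icc, 1.0)

  interior <- rep(3L, 20)  # interior scores cannot clip back onto the truth
  m1 <- simulate_raters(interior, 3, 1, seed = 2)
  expect_true(all(abs(m1 - 3L) == 1))

  expect_identical(simulate_raters(truth, 3, 0.3, seed = 9),
                   simulate_raters(truth, 3, 0.3, seed = 9))
  expect_false(identical(simulate_raters(truth, 3, 0.3, seed = 9),
                         simulate_raters(truth, 3, 0.3, seed = 10)))
})

test_that("agreement_stats couples the mean rater score to the calcium score", {
  truth <- rep(0:6, length.out = 28)
  m <- simulate_raters(truth, 3, 0.1, seed = 4)
  set.seed(44)
  calcium <- exp(truth + rnorm(28, 0, 0.2))  # monotone-ish companion measure
  res <- agreement_stats(m, calcium)
  expect_gt(res$icc, 0.8)
  expect_gt(res$rho, 0.8)
  expect_lt(res$rho_p, 0.001)
})

test_that("rater matrices round-trip through CSV", {
  m <- simulate_raters(rep(0:6, length.out = 12), 3, 0.2, seed = 6)
  path <- tempfile(fileext = ".csv")
  write_rater_matrix(m, path)
  back <- read_rater_matrix(path)
  expect_equal(unclass(back)[, ], unclass(m)[, ], ignore_attr = TRUE)
  expect_equal(colnames(back), colnames(m))
})
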