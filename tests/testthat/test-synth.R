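test_that("registry sampler reproduces the discretized lognormal size law", {
  reg <- sample_colony_registry(3000, c(8.06, 2.34), 0.34,
                                region = "continent", seed = 11)
  expect_s3_class(reg, "colony_registry")
  expect_true(all(reg$n_true >= 1))
  # median of the lognormal is exp(mu); at n = 3000 the sample median should
  # sit within a few percent of it on the log scale
  expect_lt(abs(log(median(reg$n_true) / exp(8.06))), 0.15)
  # log-size moments recover (mu, sigma) within 3 SE
  ln <- log(reg$n_true)
  expect_lt(abs(mean(ln) - 8.06), 3 * 2.34 / sqrt(3000))
  expect_lt(abs(sd(ln) - 2.34), 3 * 2.34 / sqrt(2 * 3000))
  # area identity and non-overlap of footprints
  expect_equal(reg$guano_area_true, reg$n_true / 0.34)
  r_px <- ceiling(sqrt(pmax(1, round(reg$guano_area_true / 900)) / pi)) + 2
  d <- as.matrix(dist(cbind(reg$x, reg$y) / 30))
  sep <- d - outer(r_px, r_px, "+")
  expect_true(all(sep[upper.tri(sep)] > 0))
})

test_that("registry sampler handles edge cases and is reproducible", {
  expect_equal(nrow(sample_colony_registry(0, c(8, 2), 0.34)), 0)
  expect_error(sample_colony_registry(5, c(8, -1), 0.34), "sigma")
  expect_error(sample_colony_registry(5, c(8, 2), 0), "density")
  a <- sample_colony_registry(40, c(6.64, 2.19), 0.52, "peninsula", seed = 7)
  b <- sample_colony_registry(40, c(6.64, 2.19), 0.52, "peninsula", seed = 7)
  expect_identical(a, b)
  # guano_area arithmetic: 340 pairs at 0.34 nests/m^2 is 1000 m^2
  reg <- make_registry(340, 0.34, x = 500, y = 500)
  expect_equal(reg$guano_area_true, 1000)
})

test_that("rendering conserves truth pixels and honours degradation", {
  lib <- spectral_library()
  # one colony of 9000 m^2 -> exactly 10 truth pixels
  reg <- make_registry(c(3060), 0.34, x = 900, y = 900, geometry = c(60, 60))
  expect_equal(reg$guano_area_true, 9000)
  sc <- render_scene(reg, lib, seed = 3)
  expect_equal(sum(sc$truth_guano_mask), 10)
  expect_equal(sc$pixel_area, 900)

  # conservation across many colonies
  reg2 <- sample_colony_registry(25, c(6.5, 1.5), 0.34, seed = 5)
  sc2 <- render_scene(reg2, lib, seed = 5)
  expect_equal(sum(sc2$truth_guano_mask),
               sum(pmax(1, round(reg2$guano_area_true / 900))))

  # full cloud: nothing valid, retrieval finds nothing
  sc3 <- render_scene(reg, lib, degradation = list(cloud_fraction = 1), seed = 3)
  expect_false(any(sc3$valid_mask))
  clf <- fit_ellipsoid(sample_training_pixels(lib, seed = 1)$guano)
  expect_equal(sum(classify_pixels(sc3, clf)), 0)

  # determinism
  expect_identical(render_scene(reg2, lib, seed = 9),
                   render_scene(reg2, lib, seed = 9))
  # footprint outside the scene is a geometry error
  reg_bad <- make_registry(9e5, 0.34, x = 30, y = 30, geometry = c(20, 20))
  expect_error(render_scene(reg_bad, lib, seed = 1), "bounds|exceed|place")
})

test_that("zero class covariance renders exact class means", {
  lib0 <- spectral_library(list(
    guano = list(mean = rep(0.4, 6), cov = matrix(0, 6, 6)),
    rock  = list(mean = rep(0.2, 6), cov = matrix(0, 6, 6))))
  reg <- make_registry(3060, 0.34, x = 450, y = 450, geometry = c(30, 30))
  bg <- matrix(2L, 30, 30)
  sc <- render_scene(reg, lib0, background_map = bg, seed = 1)
  gu <- which(sc$truth_guano_mask)
  for (b in 1:6) {
    layer <- sc$bands[, , b]
    expect_true(all(layer[gu] == 0.4))
    expect_true(all(layer[-gu] == 0.2))
  }
})

test_that("VHR observation model has the stated moments and independence", {
  # cv = 0 reproduces truth exactly
  expect_equal(simulate_vhr_observation(12345, 0)$n_vhr, 12345L)
  expect_error(simulate_vhr_observation(100, -0.1), "cv")

  # mean of repeated draws matches the lognormal mean n * exp(log(1+cv^2)/2)
  set.seed(42)
  draws <- vapply(1:10000, function(i)
    as.numeric(simulate_vhr_observation(10000, 0.1)$n_vhr), numeric(1))
  expect_lt(abs(mean(draws) / (10000 * exp(log(1.01) / 2)) - 1), 0.01)

  # descriptor re-draws with different sub-seeds are independent
  obs <- simulate_vhr_observation(10000, 0.2, seed = 1)
  a <- obs$rdraw(10000, seed = 101)
  b <- obs$rdraw(10000, seed = 202)
  expect_lt(abs(cor(a, b)), 0.03)
  expect_false(identical(a, b))
})
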