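test_that("ellipsoid fit accepts its centre and covers training pixels", {
  set.seed(1)
  x <- matrix(rnorm(473 * 6, 0.4, 0.01), 473, 6)
  clf <- fit_ellipsoid(x, coverage = 0.99)
  # decision value at the sample mean is 0, always accepted
  expect_equal(as.numeric(decision_value(clf, clf$center)), 0)
  expect_gte(clf$threshold, 0)
  # at coverage 0.99 at least floor(0.99 * 473) = 468 training pixels accepted
  acc <- sum(decision_value(clf, x) <= clf$threshold)
  expect_gte(acc, 468)
  expect_lt(acc, 473)  # but not all of them
})

test_that("decision rule matches a brute-force Mahalanobis oracle", {
  set.seed(2)
  x <- rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1), c(0.5, 0.5),
             matrix(runif(24), 12, 2))
  clf <- fit_ellipsoid(x, coverage = 0.9, bands_used = c("B1", "B2"))
  probe <- matrix(runif(100), 50, 2)
  S_inv <- solve(cov(x)); m <- colMeans(x)
  oracle <- apply(probe, 1, function(p) t(p - m) %*% S_inv %*% (p - m))
  expect_equal(as.numeric(decision_value(clf, probe)), as.numeric(oracle),
               tolerance = 1e-10)
})

test_that("fit errors on insufficient or degenerate training data", {
  expect_error(fit_ellipsoid(matrix(rnorm(36), 6, 6)), "insufficient")
  set.seed(3)
  x <- matrix(rnorm(60), 10, 6)
  x[, 6] <- x[, 5]  # singular covariance
  expect_error(fit_ellipsoid(x, regularize = FALSE), "degenerate|singular")
  clf <- fit_ellipsoid(x, regularize = TRUE)  # regularization rescues it
  expect_s3_class(clf, "ellipsoid_classifier")
  expect_error(fit_ellipsoid(matrix(rnorm(120), 20, 6), coverage = 1.2),
               "coverage")
})

test_that("classification is restricted to valid pixels and checked for schema", {
  lib <- toy_library(sep = 10)
  clf <- fit_ellipsoid(sample_training_pixels(lib, seed = 4)$guano)
  reg <- make_registry(3060, 0.34, x = 450, y = 450, geometry = c(30, 30))
  sc <- render_scene(reg, lib, background_map = matrix(2L, 30, 30), seed = 4)

  # pixels equal to the centre: all valid pixels flagged
  sc_c <- sc
  for (b in 1:6) sc_c$bands[, , b] <- clf$center[b]
  expect_equal(sum(classify_pixels(sc_c, clf)), sum(sc_c$valid_mask))

  # valid_mask all false: nothing flagged
  sc_f <- sc; sc_f$valid_mask[] <- FALSE
  expect_equal(sum(classify_pixels(sc_f, clf)), 0)

  # band-count mismatch is a schema error
  sc_b <- sc; sc_b$bands <- sc$bands[, , 1:3]
  expect_error(classify_pixels(sc_b, clf), "band-count mismatch")
})

test_that("well-separated classes give near-perfect pixel recall", {
  lib <- toy_library(sep = 10)
  # coverage 0.998 and a 2000-pixel training set: the empirical-quantile
  # threshold accepts new in-class pixels at about the coverage rate, so
  # clearing a 99% recall floor needs coverage above 0.99 and enough
  # training pixels that the realized quantile is stable
  clf <- fit_ellipsoid(sample_training_pixels(lib, 2000, seed = 5)$guano,
                       coverage = 0.998)
  reg <- sample_colony_registry(15, c(9.2, 0.4), 0.34, seed = 6)
  sc <- render_scene(reg, lib,
                     background_map = matrix(2L, attr(reg, "geometry")[1],
                                             attr(reg, "geometry")[2]),
                     seed = 6)
  flag <- classify_pixels(sc, clf)
  truth <- sc$truth_guano_mask & sc$valid_mask
  expect_gte(sum(flag & truth) / sum(truth), 0.99)
})

test_that("shrinking the threshold never grows the flagged set", {
  lib <- toy_library(sep = 6)
  clf <- fit_ellipsoid(sample_training_pixels(lib, seed = 7)$guano)
  reg <- sample_colony_registry(8, c(6.5, 1), 0.34, seed = 7)
  sc <- render_scene(reg, lib, seed = 7)
  counts <- vapply(c(1, 0.5, 0.25, 0.1), function(s) {
    c2 <- clf; c2$threshold <- clf$threshold * s
    sum(classify_pixels(sc, c2))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("acceptance is invariant under common affine band rescaling", {
  set.seed(8)
  x <- matrix(rnorm(300, 0.4, 0.02), 50, 6)
  probe <- matrix(rnorm(120, 0.4, 0.03), 20, 6)
  clf <- fit_ellipsoid(x)
  acc1 <- decision_value(clf, probe) <= clf$threshold

  sc <- runif(6, 0.5, 2); off <- runif(6, -0.1, 0.1)
  xt <- sweep(sweep(x, 2, sc, "*"), 2, off, "+")
  pt <- sweep(sweep(probe, 2, sc, "*"), 2, off, "+")
  clf2 <- fit_ellipsoid(xt)
  acc2 <- decision_value(clf2, pt) <= clf2$threshold
  expect_identical(acc1, acc2)
})
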