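test_that("lognormal size fit is the ML estimator with its SEs", {
  f <- fit_colony_size_distribution(c(exp(2), exp(4)) |> rep(2))
  expect_equal(f$mu, 3)
  expect_equal(f$sigma, 1)
  expect_equal(f$se_mu, 1 / 2)
  expect_equal(f$se_sigma, 1 / sqrt(8))
  expect_error(fit_colony_size_distribution(c(0.5, 2, 3)), ">= 1")
  expect_error(fit_colony_size_distribution(c(5, 5, 5)), "degenerate")
  expect_error(fit_colony_size_distribution(c(2, 3)), "at least 3")

  set.seed(41)
  draws <- rlnorm(20000, 8.06, 2.34)
  fr <- fit_colony_size_distribution(pmax(1, round(draws)))
  expect_lt(abs(fr$mu - 8.06), 2 * fr$se_mu + 0.02)   # +0.02 for rounding
  expect_lt(abs(fr$sigma - 2.34), 2 * fr$se_sigma + 0.02)
})

test_that("discretized size law normalizes, matches moments, is unimodal", {
  for (par in list(c(8.06, 2.34), c(6.64, 2.19))) {
    d <- discretize_size_distribution(par[1], par[2])
    expect_equal(sum(d$grid$p), 1, tolerance = 1e-12)
    expect_true(all(diff(d$grid$n) > 0))
    # grid mean within 0.5% of the closed-form lognormal mean
    m_grid <- sum(d$grid$n * d$grid$p)
    m_true <- exp(par[1] + par[2]^2 / 2)
    expect_lt(abs(m_grid / m_true - 1), 0.005)
    # bins cover at least the [1e-6, 1 - 1e-6] quantile range
    expect_lte(d$grid$bin_lo[1], qlnorm(1e-6, par[1], par[2]))
    expect_gte(max(d$grid$bin_hi), qlnorm(1 - 1e-6, par[1], par[2]))
  }
  # mass per unit log-size is unimodal in log n (first bin excluded: its
  # extent reaches down to 0 and has no finite log-width)
  d <- discretize_size_distribution(8.06, 2.34)
  g <- d$grid[-1, ]
  dens <- g$p / (log(g$bin_hi) - log(g$bin_lo))
  keep <- which(g$p > 1e-9)
  ds <- dens[keep]
  peak <- which.max(ds)
  expect_true(all(diff(ds[1:peak]) > -1e-9 * max(ds)))
  expect_true(all(diff(ds[peak:length(ds)]) < 1e-9 * max(ds)))
  expect_error(discretize_size_distribution(8, -1), "sigma")
})

test_that("conditional expectation of a missed colony's size is correct", {
  dist <- discretize_size_distribution(8.06, 2.34)
  det <- detection_model(-1.00, 4e-4)

  # constant detection: conditioning vanishes, E[N|M=0] = E[N]
  flat <- detection_model(-1, 0)
  expect_equal(expected_missing_colony_size(dist, flat),
               sum(dist$grid$n * dist$grid$p), tolerance = 1e-12)

  # Monte Carlo converges to the direct sum (the oracle)
  direct <- expected_missing_colony_size(dist, det)
  mc <- expected_missing_colony_size(dist, det, method = "monte_carlo",
                                     n_draws = 2e5, seed = 42)
  expect_lt(abs(mc / direct - 1), 0.05)
  # convergence rate: more draws, closer (averaged over seeds)
  err_small <- mean(sapply(1:5, function(s) abs(
    expected_missing_colony_size(dist, det, "monte_carlo", 1e3, s) - direct)))
  err_big <- mean(sapply(1:5, function(s) abs(
    expected_missing_colony_size(dist, det, "monte_carlo", 1e5, s) - direct)))
  expect_lt(err_big, err_small)

  # size-biased detection pulls the missed-colony mean below E[N],
  # monotonically in the slope
  e <- sapply(c(0, 1e-4, 4e-4, 1e-3), function(b1)
    expected_missing_colony_size(dist, detection_model(-1, b1)))
  expect_true(all(diff(e) < 0))
  expect_lt(e[3], sum(dist$grid$n * dist$grid$p))

  # detection certain everywhere: no missing mass
  sure <- detection_model(800, 1)
  expect_error(expected_missing_colony_size(dist, sure), "no missing mass")
})

test_that("missed-colony count is the stated Negative Binomial", {
  d <- missing_colony_count(10, 0.5)
  expect_equal(d$expectation, 10)
  # pmf normalizes
  d2 <- missing_colony_count(91, 0.7)
  expect_equal(sum(d2$pmf(0:1e6)), 1, tolerance = 1e-9)
  expect_equal(d2$expectation, 91 * 0.3 / 0.7)
  # detection nearly certain: expectation collapses to zero
  expect_lt(missing_colony_count(91, 1 - 1e-9)$expectation, 1e-6)
  expect_error(missing_colony_count(0, 0.5), "k_detected")
  expect_error(missing_colony_count(10, 1), "p_hat")
  expect_error(missing_colony_count(10, 0), "p_hat")
  # sampler moments
  s <- d2$sample(20000, seed = 43)
  expect_lt(abs(mean(s) - d2$expectation), 4 * sd(s) / sqrt(20000))
})

test_that("total missing abundance obeys the law of total expectation", {
  regions <- list(
    continent = list(dist = discretize_size_distribution(8.06, 2.34),
                     det = detection_model(-1.00, 4e-4),
                     k_detected = 91, p_hat = 0.75),
    peninsula = list(dist = discretize_size_distribution(6.64, 2.19,
                                                         region = "peninsula"),
                     det = detection_model(-1.72, 3e-4),
                     k_detected = 16, p_hat = 0.6))
  est <- total_missing_abundance(regions, n_rep = 4000, seed = 44)
  expect_s3_class(est, "missing_abundance_estimate")
  expect_true(est$ci[1] <= est$total_missing &&
              est$total_missing <= est$ci[2])
  # replicate mean matches sum over regions of E[count] * E[N|M=0]
  expected <- sum(est$per_region$expected_missing_colonies *
                  est$per_region$e_missing_size)
  mc_se <- sd(est$draws) / sqrt(length(est$draws))
  expect_lt(abs(est$total_missing - expected), 3 * mc_se)
  # p_hat -> 1 in all regions: total collapses to zero
  for (r in names(regions)) regions[[r]]$p_hat <- 0.99999
  tiny <- total_missing_abundance(regions, n_rep = 500, seed = 45)
  expect_lt(tiny$total_missing, 5e4 * 0.001)
  # reproducibility
  est2 <- total_missing_abundance(list(regions$continent), n_rep = 100, seed = 7)
  est3 <- total_missing_abundance(list(regions$continent), n_rep = 100, seed = 7)
  expect_identical(est2$draws, est3$draws)
})

test_that("overall detection probability averages the curve over sizes", {
  dist <- discretize_size_distribution(8.06, 2.34)
  det <- detection_model(-1.00, 4e-4)
  p <- overall_detection_probability(dist, det)
  expect_true(p > plogis(-1) && p < 1)
  # flat curve: equals the constant
  expect_equal(overall_detection_probability(dist, detection_model(0.3, 0)),
               plogis(0.3), tolerance = 1e-12)
})
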