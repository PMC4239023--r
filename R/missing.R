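#' Fit the lognormal colony-size law
#'
#' Colony sizes are heavily right-skewed and well described by a lognormal
#' distribution of breeding pairs. Maximum-likelihood estimates on the log
#' scale are `mu = mean(log N)` and `sigma = sqrt(mean((log N - mu)^2))`
#' (the ML, divisor-n estimator), with large-sample standard errors
#' `sigma / sqrt(n)` and `sigma / sqrt(2n)`.
#'
#' @param abundances Colony sizes in breeding pairs, all `>= 1`, `n >= 3`.
#' @param region Region label stored on the fit.
#' @return Object of class `colony_size_fit`: `mu`, `sigma`, `se_mu`,
#'   `se_sigma`, `n`, `region`.
#' @export
fit_colony_size_distribution <- function(abundances, region = "continent") {
  N <- as.numeric(abundances)
  if (length(N) < 3) stop("need at least 3 colonies")
  if (any(!is.finite(N)) || any(N < 1))
    stop("all abundances must be >= 1 breeding pair")
  ln <- log(N)
  mu <- mean(ln)
  sigma <- sqrt(mean((ln - mu)^2))
  if (sigma == 0) stop("degenerate size distribution: all abundances equal")
  structure(list(region = region, mu = mu, sigma = sigma,
                 se_mu = sigma / sqrt(length(N)),
                 se_sigma = sigma / sqrt(2 * length(N)),
                 n = length(N)),
            class = "colony_size_fit")
}

#' Discretize a lognormal colony-size law onto an integer-aligned grid
#'
#' Builds the discrete `P(N = n)` used by the missing-abundance estimator:
#' unit bins on the integers 1..`n_int` (the bin for n collects lognormal
#' mass on `(n - 1/2, n + 1/2]`, with the first bin absorbing all mass below
#' 1.5), then log-spaced bins out to the `upper_quantile` of the continuous
#' law; the grid records each bin's `[bin_lo, bin_hi)` extent. Each
#' log-spaced bin is represented by its conditional mean, so grid
#' expectations track the continuous distribution's moments closely even in
#' the long tail; probabilities are renormalized to sum to exactly 1.
#'
#' @param mu,sigma Lognormal parameters on the log scale (`sigma > 0`).
#' @param upper_quantile Upper coverage of the grid (default `1 - 1e-9`;
#'   with heavy tails, anything shorter clips a non-negligible share of the
#'   mean).
#' @param n_int Number of unit-spaced integer support points.
#' @param n_log_bins Number of log-spaced bins beyond `n_int`.
#' @param region Region label.
#' @return Object of class `colony_size_distribution`: `mu`, `sigma`,
#'   `grid` (`data.frame` with support `n` and probability `p`), `region`.
#' @export
discretize_size_distribution <- function(mu, sigma, upper_quantile = 1 - 1e-9,
                                         n_int = 1000, n_log_bins = 400,
                                         region = "continent") {
  if (!is.finite(sigma) || sigma <= 0) stop("sigma must be > 0")
  n_hi <- stats::qlnorm(upper_quantile, mu, sigma)

  n1 <- seq_len(n_int)
  edges1 <- c(0, n1 + 0.5)
  p1 <- diff(stats::plnorm(edges1, mu, sigma))
  supp <- as.numeric(n1); prob <- p1
  bin_lo <- edges1[-length(edges1)]; bin_hi <- edges1[-1]

  if (n_hi > n_int + 0.5) {
    edges2 <- exp(seq(log(n_int + 0.5), log(n_hi), length.out = n_log_bins + 1))
    lo <- edges2[-length(edges2)]; hi <- edges2[-1]
    p2 <- stats::plnorm(hi, mu, sigma) - stats::plnorm(lo, mu, sigma)
    # conditional mean of the lognormal within each bin
    m <- exp(mu + sigma^2 / 2)
    em <- m * (stats::pnorm((mu + sigma^2 - log(lo)) / sigma) -
               stats::pnorm((mu + sigma^2 - log(hi)) / sigma))
    rep_val <- ifelse(p2 > 0, em / p2, (lo + hi) / 2)
    keep <- p2 > 0
    supp <- c(supp, rep_val[keep]); prob <- c(prob, p2[keep])
    bin_lo <- c(bin_lo, lo[keep]); bin_hi <- c(bin_hi, hi[keep])
  }
  prob <- prob / sum(prob)
  structure(list(region = region, mu = mu, sigma = sigma,
                 grid = data.frame(n = supp, p = prob,
                                   bin_lo = bin_lo, bin_hi = bin_hi)),
            class = "colony_size_distribution")
}

#' Random colony sizes from a discretized size law
#'
#' @param dist A `colony_size_distribution`.
#' @param n Number of draws.
#' @param weights Optional non-negative per-support weights multiplying the
#'   grid probabilities (e.g. `1 - p_detect` to draw sizes of missed
#'   colonies).
#' @param seed Optional integer seed.
#' @return Numeric vector of sizes.
#' @export
sample_colony_sizes <- function(dist, n, weights = NULL, seed = NULL) {
  stopifnot(inherits(dist, "colony_size_distribution"))
  p <- dist$grid$p
  if (!is.null(weights)) {
    stopifnot(length(weights) == nrow(dist$grid), all(weights >= 0))
    p <- p * weights
  }
  if (sum(p) <= 0) stop("no probability mass left after weighting")
  with_seed(seed, sample(dist$grid$n, n, replace = TRUE, prob = p))
}

#' Expected size of a colony that the survey missed
#'
#' The expected abundance of an undetected colony is the conditional
#' expectation of size given non-detection,
#' `E[N | M = 0] = sum(n * (1 - p(n)) * P(n)) / sum((1 - p(n)) * P(n))`,
#' convolving the colony-size law with one minus the size-dependent
#' detection curve. Because detection improves with size, this is always
#' below the unconditional mean colony size.
#'
#' @param dist A `colony_size_distribution`.
#' @param det A `detection_model_fit` for the same region.
#' @param method `"direct_sum"` evaluates the grid exactly (the reference
#'   method); `"monte_carlo"` draws sizes from `P(n)` and self-normalizes
#'   with weights `1 - p(n)`.
#' @param n_draws Monte Carlo draws.
#' @param seed Optional integer seed.
#' @return Expected breeding pairs per missed colony (scalar).
#' @export
expected_missing_colony_size <- function(dist, det,
                                         method = c("direct_sum", "monte_carlo"),
                                         n_draws = 1e5, seed = NULL) {
  stopifnot(inherits(dist, "colony_size_distribution"),
            inherits(det, "detection_model_fit"))
  method <- match.arg(method)
  n <- dist$grid$n; P <- dist$grid$p
  miss <- 1 - detection_probability(det, n)
  if (method == "direct_sum") {
    denom <- sum(miss * P)
    if (denom < 1e-300)
      stop("no missing mass: detection is essentially certain at every size")
    sum(n * miss * P) / denom
  } else {
    with_seed(seed, {
      draws <- sample(n, n_draws, replace = TRUE, prob = P)
      w <- 1 - detection_probability(det, draws)
      if (sum(w) <= 0)
        stop("no missing mass: detection is essentially certain at every size")
      sum(draws * w) / sum(w)
    })
  }
}

#' Overall (size-averaged) detection probability
#'
#' Averages the logistic detection curve over the colony-size law:
#' `p_hat = sum(p(n) * P(n))`. Used when no colony-by-colony survey
#' comparison is available to estimate the overall detection rate
#' empirically.
#'
#' @param dist A `colony_size_distribution`.
#' @param det A `detection_model_fit`.
#' @return Scalar probability.
#' @export
overall_detection_probability <- function(dist, det) {
  sum(detection_probability(det, dist$grid$n) * dist$grid$p)
}

#' Distribution of the number of colonies the survey missed
#'
#' If a survey with overall per-colony detection probability `p_hat`
#' detected `k_detected` colonies, the number of colonies it missed is
#' modelled as Negative Binomial: the count of failures (missed colonies)
#' accumulated before `k_detected` successes in independent detection
#' trials with success probability `p_hat`. Its expectation is
#' `k_detected * (1 - p_hat) / p_hat`.
#'
#' @param k_detected Number of detected colonies, `>= 1`.
#' @param p_hat Overall detection probability in (0,1).
#' @return Object of class `missing_count_distribution` with `expectation`,
#'   and functions `pmf(x)`, `quantile(q)`, `sample(n, seed)`.
#' @export
missing_colony_count <- function(k_detected, p_hat) {
  if (k_detected < 1) stop("k_detected must be >= 1")
  if (!is.finite(p_hat) || p_hat <= 0 || p_hat >= 1)
    stop("p_hat must lie strictly in (0,1)")
  structure(list(
    k_detected = k_detected, p_hat = p_hat,
    expectation = k_detected * (1 - p_hat) / p_hat,
    pmf = function(x) stats::dnbinom(x, size = k_detected, prob = p_hat),
    quantile = function(q) stats::qnbinom(q, size = k_detected, prob = p_hat),
    sample = function(n, seed = NULL) with_seed(seed,
      stats::rnbinom(n, size = k_detected, prob = p_hat))),
    class = "missing_count_distribution")
}

#' Total abundance missing from a survey, with percentile interval
#'
#' Combines, per region, the Negative Binomial distribution of the number
#' of missed colonies with the size distribution of a missed colony: each
#' Monte Carlo replicate draws a missed-colony count, then that many sizes
#' from the `(1 - p(n))`-weighted size law, and sums across regions. The
#' point estimate is the replicate mean and the interval is a percentile
#' interval of the replicate totals.
#'
#' @param regions A list, one element per region, each a list with `dist`
#'   (a `colony_size_distribution`), `det` (a `detection_model_fit`),
#'   `k_detected`, and `p_hat` (omit or `NULL` to use
#'   [overall_detection_probability()]).
#' @param n_rep Monte Carlo replicates.
#' @param level Interval level (default 0.95).
#' @param seed Optional integer seed.
#' @return Object of class `missing_abundance_estimate`: `per_region`
#'   (data frame with `region`, `k_detected`, `p_hat`, `e_missing_size`,
#'   `expected_missing_colonies`), `total_missing` (point estimate),
#'   `ci` (length-2), `level`, `draws` (replicate totals).
#' @export
total_missing_abundance <- function(regions, n_rep = 2000, level = 0.95,
                                    seed = NULL) {
  stopifnot(length(regions) >= 1)
  with_seed(seed, {
    per <- lapply(regions, function(r) {
      p_hat <- if (is.null(r$p_hat)) overall_detection_probability(r$dist, r$det)
               else r$p_hat
      w <- 1 - detection_probability(r$det, r$dist$grid$n)
      counts <- missing_colony_count(r$k_detected, p_hat)$sample(n_rep)
      pw <- r$dist$grid$p * w
      pw <- pw / sum(pw)
      totals <- vapply(counts, function(m) {
        if (m == 0) 0 else
          sum(sample(r$dist$grid$n, m, replace = TRUE, prob = pw))
      }, numeric(1))
      list(region = r$dist$region, k_detected = r$k_detected, p_hat = p_hat,
           e_missing_size = expected_missing_colony_size(r$dist, r$det),
           expected_missing_colonies = r$k_detected * (1 - p_hat) / p_hat,
           totals = totals)
    })
    draws <- Reduce(`+`, lapply(per, `[[`, "totals"))
    a <- (1 - level) / 2
    structure(list(
      per_region = do.call(rbind, lapply(per, function(p)
        data.frame(region = p$region, k_detected = p$k_detected,
                   p_hat = p$p_hat, e_missing_size = p$e_missing_size,
                   expected_missing_colonies = p$expected_missing_colonies))),
      total_missing = mean(draws),
      ci = stats::quantile(draws, c(a, 1 - a), names = FALSE, type = 8),
      level = level, draws = draws),
      class = "missing_abundance_estimate")
  })
}

#' Serialize a missing-abundance estimate to JSON
#'
#' @param est A `missing_abundance_estimate`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_missing_report <- function(est, path) {
  rep <- list(per_region = est$per_region,
              total_missing = est$total_missing,
              ci = est$ci, level = est$level)
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @export
print.missing_abundance_estimate <- function(x, ...) {
  cat(sprintf("<missing_abundance_estimate> %.0f breeding pairs (%.0f%% CI %.0f-%.0f)\n",
              x$total_missing, 100 * x$level, x$ci[1], x$ci[2]))
  print(x$per_region)
  invisible(x)
}

#' @export
print.colony_size_fit <- function(x, ...) {
  cat(sprintf("<colony_size_fit %s> mu = %.2f (SE %.2f), sigma = %.2f (SE %.2f), n = %d\n",
              x$region, x$mu, x$se_mu, x$sigma, x$se_sigma, x$n))
  invisible(x)
}

#' @export
print.colony_size_distribution <- function(x, ...) {
  cat(sprintf("<colony_size_distribution %s> lognormal(%.2f, %.2f), %d support points\n",
              x$region, x$mu, x$sigma, nrow(x$grid)))
  invisible(x)
}
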