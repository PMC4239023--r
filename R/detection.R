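#' Fit the size-dependent detection-probability model
#'
#' The probability that a colony of `N` breeding pairs is retrieved from
#' medium-resolution imagery is modelled as logistic in raw abundance:
#' `logit(p) = beta0 + beta1 * N`. The covariate is raw `N` (not log `N`):
#' on that scale the slope is interpretable as log-odds per breeding pair
#' and matches published magnitudes of ~1e-4. Fits are always per region.
#'
#' The fit is maximum likelihood via iteratively reweighted least squares
#' with the covariate standardised internally for numerical stability; the
#' score (gradient) at the optimum is checked to have norm below 1e-8 on
#' the standardised problem and complete separation is reported as an
#' error rather than returned as a silent, divergent fit.
#'
#' @param n_pairs Abundances (breeding pairs), one per colony.
#' @param detected 0/1 outcomes (1 = retrieved). Both classes must occur.
#' @param region Region label stored on the fit.
#' @return Object of class `detection_model_fit`: `beta0`, `beta1`, `se0`,
#'   `se1` (Wald, from the observed information), `vcov`, `n`, `converged`,
#'   `region`.
#' @seealso [detection_probability()], [size_at_detection_probability()]
#' @export
fit_detection_model <- function(n_pairs, detected, region = "continent") {
  stopifnot(length(n_pairs) == length(detected))
  detected <- as.integer(detected)
  if (any(!detected %in% c(0L, 1L))) stop("detected must be 0/1")
  if (length(unique(detected)) < 2)
    stop("complete separation: both outcome classes must be present ",
         "(all colonies ", if (all(detected == 1)) "detected" else "missed", ")")
  sc <- stats::sd(n_pairs)
  if (!is.finite(sc) || sc == 0) stop("abundance covariate is constant")
  # with one covariate, complete separation is exactly orderability of the
  # two outcome classes
  if (max(n_pairs[detected == 0]) < min(n_pairs[detected == 1]) ||
      min(n_pairs[detected == 0]) > max(n_pairs[detected == 1]))
    stop("complete separation: detected and missed colonies do not overlap ",
         "in size; the logistic MLE does not exist")
  z <- n_pairs / sc

  fit <- suppressWarnings(
    stats::glm(detected ~ z, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-12, maxit = 200)))
  co <- stats::coef(fit)
  p <- stats::fitted(fit)
  grad <- c(sum(detected - p), sum(z * (detected - p)))
  gnorm <- sqrt(sum(grad^2))
  if (!fit$converged || gnorm >= 1e-8)
    stop("detection model did not converge: ",
         sprintf("gradient norm %.3g on the standardised scale", gnorm))

  V <- stats::vcov(fit)
  J <- diag(c(1, 1 / sc))          # back-transform to the raw-N scale
  Vr <- J %*% V %*% t(J)
  structure(list(region = region, beta0 = unname(co[1]),
                 beta1 = unname(co[2] / sc),
                 se0 = sqrt(Vr[1, 1]), se1 = sqrt(Vr[2, 2]),
                 vcov = Vr, n = length(detected), converged = TRUE),
            class = "detection_model_fit")
}

#' Construct a detection model from known coefficients
#'
#' Useful for interrogating published coefficient sets without refitting.
#'
#' @param beta0,beta1 Logistic intercept and slope (per breeding pair).
#' @param region Region label.
#' @param se0,se1 Optional standard errors.
#' @return A `detection_model_fit`.
#' @export
detection_model <- function(beta0, beta1, region = "continent",
                            se0 = NA_real_, se1 = NA_real_) {
  structure(list(region = region, beta0 = beta0, beta1 = beta1,
                 se0 = se0, se1 = se1, vcov = NULL, n = NA_integer_,
                 converged = NA),
            class = "detection_model_fit")
}

#' Probability that a colony of a given size is detected
#'
#' @param fit A `detection_model_fit`.
#' @param N Abundance(s) in breeding pairs, `>= 0`.
#' @return `p = 1 / (1 + exp(-(beta0 + beta1 * N)))`, in (0,1).
#' @export
detection_probability <- function(fit, N) {
  stopifnot(inherits(fit, "detection_model_fit"), all(N >= 0))
  stats::plogis(fit$beta0 + fit$beta1 * N)
}

#' Colony size at a given detection probability
#'
#' Inverts the logistic detection curve: the size `N*` at which the
#' detection probability equals `p` is `(logit(p) - beta0) / beta1`. The
#' round trip `detection_probability(fit, N*) == p` holds exactly.
#'
#' @param fit A `detection_model_fit` with nonzero slope.
#' @param p Probability (vector) in (0,1).
#' @return Size(s) in breeding pairs (may be negative for small `p` when
#'   the intercept already exceeds `logit(p)`).
#' @export
size_at_detection_probability <- function(fit, p) {
  stopifnot(inherits(fit, "detection_model_fit"),
            all(p > 0), all(p < 1))
  if (fit$beta1 == 0)
    stop("no size threshold exists: detection probability is constant (beta1 = 0)")
  (stats::qlogis(p) - fit$beta0) / fit$beta1
}

#' Detection-threshold table
#'
#' Sizes at the conventional detection probabilities, the layout used to
#' report minimum detectable colony sizes.
#'
#' @param fit A `detection_model_fit`.
#' @param p Probabilities to tabulate.
#' @return `data.frame` with `p_detection` and `colony_size`.
#' @export
detection_thresholds <- function(fit, p = c(0.5, 0.75, 0.90, 0.95, 0.99)) {
  data.frame(p_detection = p,
             colony_size = size_at_detection_probability(fit, p))
}

#' Serialize a detection fit and its threshold table to JSON
#'
#' @param fit A `detection_model_fit`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_detection_report <- function(fit, path) {
  rep <- list(region = fit$region, beta0 = fit$beta0, beta1 = fit$beta1,
              se0 = fit$se0, se1 = fit$se1, n = fit$n,
              thresholds = detection_thresholds(fit))
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @export
print.detection_model_fit <- function(x, ...) {
  cat(sprintf(paste0("<detection_model_fit %s> logit(p) = %.3f + %.3g N",
                     "  (SE %.3g, %.3g)\n"),
              x$region, x$beta0, x$beta1, x$se0, x$se1))
  invisible(x)
}
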