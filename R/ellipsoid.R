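#' Fit the spectral ellipsoid classifier from in-class training pixels
#'
#' One-class classifier for guano pixels: the training pixels define an
#' ellipsoid in 6-band spectral space, centred at the sample mean with shape
#' given by the inverse sample covariance (the stored quadratic form is the
#' "transition matrix" of the retrieval algorithm). A new pixel is accepted
#' when its squared Mahalanobis distance from the centre does not exceed a
#' threshold set at the `coverage` empirical quantile of the training pixels'
#' own distances, so by construction at least `ceiling(coverage * n)` of the
#' training pixels are accepted.
#'
#' Background (non-guano) pixels play no role in the fit: the decision rule
#' is one-class, and background training samples are used only to audit
#' commission rates.
#'
#' @param in_class_pixels Numeric matrix, one row per training pixel, one
#'   column per band.
#' @param coverage Fraction in (0,1) of training pixels the ellipsoid must
#'   enclose (default 0.99).
#' @param regularize Add `1e-6 * mean(diag(S))` to the covariance diagonal
#'   when it is numerically singular.
#' @param bands_used Band labels, defaults to the six reflective bands.
#' @return Object of class `ellipsoid_classifier`: `center` (band means),
#'   `form` (inverse covariance), `threshold` (squared-distance cutoff),
#'   `coverage`, `bands_used`, `n_train`.
#' @export
fit_ellipsoid <- function(in_class_pixels, coverage = 0.99,
                          regularize = TRUE,
                          bands_used = NULL) {
  x <- as.matrix(in_class_pixels)
  p <- ncol(x)
  if (is.null(bands_used))
    bands_used <- if (p == 6) REFLECTIVE_BANDS else paste0("B", seq_len(p))
  if (nrow(x) < p + 1)
    stop("insufficient training data: need at least ", p + 1,
         " in-class pixels for ", p, " bands")
  if (!is.finite(coverage) || coverage <= 0 || coverage >= 1)
    stop("coverage must lie in (0,1)")

  ctr <- colMeans(x)
  S <- stats::cov(x)
  if (rcond_sym(S) < 1e-12) {
    if (!regularize)
      stop("degenerate training covariance (singular); consider regularization")
    S <- S + diag(1e-6 * mean(diag(S)), p)
    if (rcond_sym(S) < 1e-12)
      stop("degenerate training covariance even after regularization")
  }
  form <- solve(S)
  d2 <- stats::mahalanobis(x, ctr, form, inverted = TRUE)
  thr <- sort(d2)[ceiling(coverage * nrow(x))]
  structure(list(center = ctr, form = form, threshold = thr,
                 coverage = coverage, bands_used = bands_used,
                 n_train = nrow(x)),
            class = "ellipsoid_classifier")
}

rcond_sym <- function(S) {
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) return(0)
  min(ev) / max(ev)
}

#' Squared Mahalanobis decision value of pixels under a classifier
#'
#' @param classifier An [fit_ellipsoid()] result.
#' @param x Matrix of band vectors (rows) or a single vector.
#' @return Numeric vector of squared distances; a pixel is in-class when the
#'   value is `<= classifier$threshold`. The value at the centre is 0.
#' @export
decision_value <- function(classifier, x) {
  x <- if (is.null(dim(x))) matrix(x, 1) else as.matrix(x)
  if (ncol(x) != length(classifier$center))
    stop("band-count mismatch: classifier uses ", length(classifier$center),
         " bands, data has ", ncol(x))
  stats::mahalanobis(x, classifier$center, classifier$form, inverted = TRUE)
}

#' Flag guano pixels in a scene
#'
#' Applies the ellipsoid decision rule to every pixel: a pixel is flagged
#' if and only if it is valid (not under cloud/shadow/water) and its band
#' vector lies inside the ellipsoid. Invalid pixels are never flagged.
#'
#' @param scene A `spectral_scene`.
#' @param classifier An `ellipsoid_classifier` whose band count matches the
#'   scene.
#' @return Logical matrix of the scene's dimensions.
#' @export
classify_pixels <- function(scene, classifier) {
  stopifnot(inherits(scene, "spectral_scene"),
            inherits(classifier, "ellipsoid_classifier"))
  d <- dim(scene$bands)
  if (d[3] != length(classifier$center))
    stop("band-count mismatch: scene has ", d[3], " bands, classifier uses ",
         length(classifier$center))
  flat <- matrix(scene$bands, d[1] * d[2], d[3])
  d2 <- decision_value(classifier, flat)
  matrix(d2 <= classifier$threshold, d[1], d[2]) & scene$valid_mask
}

#' Sample labelled training pixels from a synthetic scene's truth
#'
#' Convenience for the training stage of a synthetic run: draws band vectors
#' directly from the library's class distributions, mirroring how training
#' pixels would be digitised over known colonies and known background.
#'
#' @param library A [spectral_library()].
#' @param n_guano,n_background Training set sizes. The published survey used
#'   473 colony pixels and 10,688 background pixels; defaults are scaled to
#'   the synthetic world.
#' @param seed Integer seed.
#' @return List with matrices `guano` and `background` (class-labelled rows).
#' @export
sample_training_pixels <- function(library, n_guano = 473, n_background = 2000,
                                   seed = 1L) {
  stopifnot(inherits(library, "spectral_library"))
  with_seed(seed, {
    g <- library$classes$guano
    guano <- rmvn(n_guano, g$mean, g$cov)
    bg_classes <- setdiff(names(library$classes), "guano")
    per <- table(sample(bg_classes, n_background, replace = TRUE))
    background <- do.call(rbind, lapply(names(per), function(nm) {
      cl <- library$classes[[nm]]
      rmvn(per[[nm]], cl$mean, cl$cov)
    }))
    list(guano = guano, background = background)
  })
}

#' @export
print.ellipsoid_classifier <- function(x, ...) {
  cat(sprintf(paste0("<ellipsoid_classifier> %d bands, %d training pixels, ",
                     "coverage %.2f, threshold %.3f\n"),
              length(x$center), x$n_train, x$coverage, x$threshold))
  invisible(x)
}
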