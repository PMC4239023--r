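#' Spectral library of synthetic surface classes
#'
#' Builds the class library used to render synthetic multispectral scenes:
#' each class has a mean top-of-atmosphere (TOA) reflectance in the six
#' reflective bands (B1-B5, B7) and a 6x6 positive-definite band covariance.
#' One class must be named `"guano"`; the remainder emulate the Antarctic
#' background surface types a retrieval has to reject (exposed rock, soil,
#' snow, water, vegetation/algae).
#'
#' @param classes Named list; each element a list with `mean` (6-vector in
#'   `[0,1]`) and `cov` (6x6 positive definite). When `NULL` a default
#'   library with plausible Antarctic surface signatures is returned.
#' @param sd Baseline within-class spectral standard deviation used by the
#'   default library.
#' @return An object of class `spectral_library`.
#' @export
spectral_library <- function(classes = NULL, sd = 0.012) {
  if (is.null(classes)) {
    means <- list(
      guano      = c(0.30, 0.33, 0.36, 0.33, 0.26, 0.21),
      rock       = c(0.12, 0.14, 0.16, 0.18, 0.22, 0.20),
      soil       = c(0.18, 0.20, 0.24, 0.28, 0.32, 0.28),
      snow       = c(0.92, 0.90, 0.86, 0.78, 0.22, 0.10),
      water      = c(0.06, 0.05, 0.04, 0.03, 0.01, 0.01),
      vegetation = c(0.08, 0.10, 0.09, 0.34, 0.22, 0.11)
    )
    base_cov <- band_cov(sd)
    classes <- lapply(means, function(m) list(mean = m, cov = base_cov))
  }
  for (nm in names(classes)) {
    cl <- classes[[nm]]
    if (length(cl$mean) != 6 || any(cl$mean < 0) || any(cl$mean > 1))
      stop("class '", nm, "': mean reflectance must be a 6-vector in [0,1]")
    ev <- eigen(cl$cov, symmetric = TRUE, only.values = TRUE)$values
    # positive semi-definite required; exactly-zero covariance is permitted
    # for degenerate (noise-free) rendering
    if (any(ev < -1e-12 * max(abs(ev), 1)))
      stop("class '", nm, "': band covariance must be positive semi-definite")
  }
  if (!"guano" %in% names(classes))
    stop("spectral library must contain a class named 'guano'")
  structure(list(classes = classes), class = "spectral_library")
}

# Correlated band covariance: reflectance errors co-vary across bands
# (illumination, calibration), so use an equicorrelated structure.
band_cov <- function(sd = 0.012, rho = 0.6, p = 6) {
  s <- rep_len(sd, p)
  r <- matrix(rho, p, p); diag(r) <- 1
  (s %o% s) * r
}

#' Add a confuser class that partially overlaps the guano signature
#'
#' Commission errors in real retrievals come from surface types (certain
#' soils, algae, flying-bird guano) whose spectra sometimes fall inside the
#' guano ellipsoid. The confuser is modelled as a mixture: with probability
#' `overlap` a confuser pixel is drawn from the guano class itself, otherwise
#' from a displaced soil-like signature well outside the ellipsoid. The
#' pixel-level commission rate on confuser pixels therefore tracks
#' `overlap` (times the classifier's coverage).
#'
#' @param library A [spectral_library()].
#' @param overlap Probability in `[0,1]` that a confuser pixel is spectrally
#'   indistinguishable from guano.
#' @param name Class name to register.
#' @return The library with the confuser class added.
#' @export
add_confuser_class <- function(library, overlap, name = "confuser") {
  stopifnot(inherits(library, "spectral_library"),
            overlap >= 0, overlap <= 1)
  g <- library$classes$guano
  far <- pmin(1, pmax(0, g$mean + 0.25))  # displaced, outside any tight ellipsoid
  library$classes[[name]] <- list(mean = far, cov = g$cov,
                                  mixture_of_guano = overlap)
  library
}

#' Sample a synthetic colony registry
#'
#' Draws a registry of breeding colonies for one region. True sizes follow a
#' discretized lognormal (a rounded lognormal variate, floored at 1 breeding
#' pair); the true guano footprint area is size divided by the region's
#' apparent density; an imperfect "VHR" reference abundance is attached via
#' [simulate_vhr_observation()]. Colony locations are placed inside a scene
#' of `geometry` pixels so that footprints never overlap or touch the edge.
#'
#' @param n_colonies Number of colonies (may be 0).
#' @param size_params Length-2 vector `c(mu, sigma)` of the lognormal size
#'   law on the log scale (breeding pairs).
#' @param density Apparent density, nests per square metre of guano.
#' @param region Region label stored on every record.
#' @param seed Integer seed; fixed seed gives a bit-identical registry.
#' @param geometry `c(rows, cols)` of the target scene in pixels; `NULL`
#'   auto-sizes so footprints occupy roughly 2\% of the scene.
#' @param vhr_cv_levels,vhr_cv_probs Accuracy categories for the VHR
#'   reference counts: each colony's coefficient of variation is drawn from
#'   `vhr_cv_levels` with probabilities `vhr_cv_probs` (emulating the
#'   ordinal accuracy codes of field/VHR censuses).
#' @return A `data.frame` of class `colony_registry` with columns
#'   `colony_id`, `region`, `x`, `y` (scene-local metres, origin at the
#'   top-left pixel corner), `n_true`, `n_vhr`, `vhr_cv`,
#'   `guano_area_true` (m^2), `excluded` (logical, always `FALSE` here;
#'   carried so that analyst exclusions can be represented).
#' @export
sample_colony_registry <- function(n_colonies, size_params, density,
                                   region = "continent", seed = 1L,
                                   geometry = NULL,
                                   vhr_cv_levels = c(0.05, 0.10, 0.25, 0.50),
                                   vhr_cv_probs = c(0.35, 0.35, 0.20, 0.10)) {
  mu <- size_params[[1]]; sigma <- size_params[[2]]
  if (!is.finite(sigma) || sigma <= 0) stop("sigma must be > 0")
  if (!is.finite(density) || density <= 0) stop("density must be > 0")
  if (n_colonies < 0) stop("n_colonies must be >= 0")
  check_region(region)

  empty <- data.frame(colony_id = character(), region = character(),
                      x = numeric(), y = numeric(), n_true = integer(),
                      n_vhr = integer(), vhr_cv = numeric(),
                      guano_area_true = numeric(), excluded = logical(),
                      stringsAsFactors = FALSE)
  class(empty) <- c("colony_registry", "data.frame")
  if (n_colonies == 0) return(empty)

  with_seed(seed, {
    n_true <- pmax(1, round(stats::rlnorm(n_colonies, mu, sigma)))
    guano_area <- n_true / density
    npix <- pmax(1L, as.integer(round(guano_area / PIXEL_AREA)))
    radii <- ceiling(sqrt(npix / pi)) + 2L          # footprint radius, pixels

    if (is.null(geometry)) {
      side <- max(64L, ceiling(sqrt(sum(npix) * 50)), 4L * max(radii) + 8L)
      geometry <- c(side, side)
    }
    rows <- geometry[1]; cols <- geometry[2]

    # rejection-sample centres so footprints neither overlap nor leave scene
    cx <- numeric(n_colonies); cy <- numeric(n_colonies)
    ord <- order(radii, decreasing = TRUE)  # place big colonies first
    for (i in ord) {
      r <- radii[i]
      if (2 * r + 2 >= min(rows, cols))
        stop("colony footprint exceeds scene bounds; enlarge geometry")
      ok <- FALSE
      for (try in 1:5000) {
        px <- stats::runif(1, r + 1, cols - r - 1)
        py <- stats::runif(1, r + 1, rows - r - 1)
        placed <- which(cx > 0)
        placed <- placed[placed != i]
        if (length(placed) == 0 ||
            all(sqrt((cx[placed] - px)^2 + (cy[placed] - py)^2) >
                radii[placed] + r + 1)) {
          cx[i] <- px; cy[i] <- py; ok <- TRUE; break
        }
      }
      if (!ok) stop("could not place colonies without overlap; enlarge geometry")
    }

    cvs <- sample(vhr_cv_levels, n_colonies, replace = TRUE, prob = vhr_cv_probs)
    n_vhr <- vapply(seq_len(n_colonies), function(i)
      simulate_vhr_observation(n_true[i], cvs[i])$n_vhr, numeric(1))

    out <- data.frame(
      colony_id = sprintf("%s-%04d", substr(region, 1, 3), seq_len(n_colonies)),
      region = region,
      x = cx * PIXEL_SIZE, y = cy * PIXEL_SIZE,
      n_true = as.integer(n_true), n_vhr = as.integer(n_vhr),
      vhr_cv = cvs, guano_area_true = guano_area,
      excluded = FALSE, stringsAsFactors = FALSE)
    class(out) <- c("colony_registry", "data.frame")
    attr(out, "geometry") <- c(rows, cols)
    out
  })
}

#' Simulate one VHR reference observation of a colony
#'
#' The reference ("VHR") abundance of a colony is not the truth: it carries
#' its own sampling distribution. The observation is modelled as a rounded
#' lognormal variate with median `n_true` and log-scale standard deviation
#' `sqrt(log(1 + cv^2))`, so `cv` is the coefficient of variation of the
#' underlying continuous observation. The returned descriptor supports
#' repeated independent draws from the colony's sampling distribution
#' (centred on the observed value), as needed for the aggregation null.
#'
#' @param n_true True abundance in breeding pairs.
#' @param cv Non-negative coefficient of variation; `cv = 0` reproduces
#'   `n_true` exactly.
#' @param seed Optional integer seed.
#' @return A list of class `vhr_observation` with `n_vhr` (integer),
#'   `sdlog`, and `rdraw(n, seed)`, a function producing `n` independent
#'   re-draws centred on `n_vhr`.
#' @export
simulate_vhr_observation <- function(n_true, cv, seed = NULL) {
  if (!is.finite(cv) || cv < 0) stop("cv must be >= 0")
  stopifnot(n_true >= 0)
  sdlog <- sqrt(log(1 + cv^2))
  n_vhr <- if (cv == 0) as.numeric(n_true) else
    with_seed(seed, round(stats::rlnorm(1, log(n_true), sdlog)))
  obs <- list(n_vhr = as.integer(n_vhr), sdlog = sdlog)
  obs$rdraw <- function(n = 1, seed = NULL) with_seed(seed,
    round(stats::rlnorm(n, log(max(obs$n_vhr, 1)), sdlog)))
  class(obs) <- "vhr_observation"
  obs
}

# Vectorised independent VHR re-draws for a whole registry (one draw each).
vhr_redraw <- function(n_vhr, cv) {
  sdlog <- sqrt(log(1 + cv^2))
  round(stats::rlnorm(length(n_vhr), log(pmax(n_vhr, 1)), sdlog))
}

#' Render a synthetic multispectral scene
#'
#' Rasterises a colony registry into a 6-band TOA reflectance scene with
#' truth masks. Every pixel belongs to a surface class from the spectral
#' library; colony footprints are contiguous blobs of `"guano"`-class pixels
#' grown by nearest-pixel accretion around the colony centre, with
#' `round(guano_area_true / 900)` pixels (minimum 1). Each pixel's band
#' vector is drawn from its class's multivariate normal and clamped to
#' `[0,1]`. Scene degradation emulates unusable imagery: a rectangular cloud
#' patch, a rectangular shadow patch, and independent per-pixel dropout,
#' all of which clear `valid_mask` (as does water background).
#'
#' @param registry A `colony_registry` (may be empty).
#' @param library A [spectral_library()].
#' @param geometry `c(rows, cols)`; defaults to the geometry recorded on the
#'   registry.
#' @param background_map Integer matrix of class indices into
#'   `names(library$classes)`, or `NULL` to sample a background of rock,
#'   snow, soil and water.
#' @param degradation List with any of `cloud_fraction`, `shadow_fraction`
#'   (scene-area fractions covered by one rectangular patch each) and
#'   `dropout` (independent per-pixel invalidity rate). Dropout is what makes
#'   omission size-dependent: a colony is lost only if every one of its
#'   pixels is invalid or misclassified, which is far more likely for small
#'   footprints.
#' @param seed Integer seed; fixed seed gives a bit-identical scene.
#' @param scene_id Identifier stored on the scene.
#' @return An object of class `spectral_scene`: list with `bands`
#'   (rows x cols x 6 array), `valid_mask`, `truth_guano_mask` (logical
#'   matrices), `class_map` (integer matrix), `pixel_area` (900),
#'   `band_names`, `scene_id`.
#' @export
render_scene <- function(registry, library, geometry = NULL,
                         background_map = NULL,
                         degradation = list(), seed = 1L,
                         scene_id = "scene-1") {
  stopifnot(inherits(library, "spectral_library"))
  deg <- utils::modifyList(list(cloud_fraction = 0, shadow_fraction = 0,
                                dropout = 0), degradation)
  if (is.null(geometry)) geometry <- attr(registry, "geometry")
  if (is.null(geometry)) stop("geometry required when registry carries none")
  rows <- geometry[1]; cols <- geometry[2]
  cls_names <- names(library$classes)
  guano_idx <- match("guano", cls_names)

  with_seed(seed, {
    if (is.null(background_map)) {
      w <- c(rock = 0.35, snow = 0.40, soil = 0.15, water = 0.10,
             confuser = 0.05)
      pool <- intersect(names(w), cls_names)
      w <- w[pool]
      background_map <- matrix(match(sample(pool, rows * cols, replace = TRUE,
                                            prob = w / sum(w)), cls_names),
                               rows, cols)
    }
    stopifnot(all(dim(background_map) == c(rows, cols)))
    class_map <- background_map

    truth <- matrix(FALSE, rows, cols)
    if (nrow(registry) > 0) {
      for (i in seq_len(nrow(registry))) {
        npix <- max(1L, as.integer(round(registry$guano_area_true[i] / PIXEL_AREA)))
        idx <- footprint_pixels(registry$y[i] / PIXEL_SIZE,
                                registry$x[i] / PIXEL_SIZE, npix, rows, cols)
        if (is.null(idx))
          stop("colony ", registry$colony_id[i], " footprint exceeds scene bounds")
        truth[idx] <- TRUE
        class_map[idx] <- guano_idx
      }
    }

    # draw reflectances class by class
    bands <- array(NA_real_, c(rows, cols, 6))
    flat <- matrix(NA_real_, rows * cols, 6)
    for (k in seq_along(cls_names)) {
      sel <- which(class_map == k)
      if (length(sel) == 0) next
      cl <- library$classes[[k]]
      n <- length(sel)
      mix <- cl$mixture_of_guano
      if (!is.null(mix) && mix > 0) {
        from_guano <- stats::runif(n) < mix
        g <- library$classes[[guano_idx]]
        flat[sel[from_guano], ]  <- rmvn(sum(from_guano), g$mean, g$cov)
        flat[sel[!from_guano], ] <- rmvn(sum(!from_guano), cl$mean, cl$cov)
      } else {
        flat[sel, ] <- rmvn(n, cl$mean, cl$cov)
      }
    }
    flat <- pmin(pmax(flat, 0), 1)
    for (b in 1:6) bands[, , b] <- matrix(flat[, b], rows, cols)

    valid <- matrix(TRUE, rows, cols)
    water_idx <- match("water", cls_names)
    if (!is.na(water_idx)) valid[class_map == water_idx] <- FALSE
    valid <- valid & !rect_patch(rows, cols, deg$cloud_fraction) &
                     !rect_patch(rows, cols, deg$shadow_fraction)
    if (deg$dropout > 0)
      valid <- valid & matrix(stats::runif(rows * cols) >= deg$dropout, rows, cols)

    structure(list(bands = bands, valid_mask = valid,
                   truth_guano_mask = truth, class_map = class_map,
                   pixel_area = PIXEL_AREA, band_names = REFLECTIVE_BANDS,
                   scene_id = scene_id),
              class = "spectral_scene")
  })
}

# npix pixel indices nearest to centre (row0, col0), deterministic tie-break
# (distance, then row, then col): a square-ish blob grown by accretion.
footprint_pixels <- function(row0, col0, npix, rows, cols) {
  r <- ceiling(sqrt(npix / pi)) + 2L
  ri <- max(1L, floor(row0 - r)):min(rows, ceiling(row0 + r))
  ci <- max(1L, floor(col0 - r)):min(cols, ceiling(col0 + r))
  grid <- expand.grid(row = ri, col = ci)
  d2 <- (grid$row - 0.5 - row0)^2 + (grid$col - 0.5 - col0)^2
  o <- order(d2, grid$row, grid$col)
  if (length(o) < npix) return(NULL)
  sel <- grid[o[seq_len(npix)], ]
  cbind(sel$row, sel$col)
}

# One random rectangle covering ~frac of the scene (frac = 1 covers all).
rect_patch <- function(rows, cols, frac) {
  m <- matrix(FALSE, rows, cols)
  if (frac <= 0) return(m)
  if (frac >= 1) return(!m)
  aspect <- stats::runif(1, 0.5, 2)
  h <- min(rows, max(1L, round(sqrt(frac * rows * cols * aspect))))
  w <- min(cols, max(1L, round(frac * rows * cols / h)))
  r0 <- sample.int(rows - h + 1L, 1); c0 <- sample.int(cols - w + 1L, 1)
  m[r0:(r0 + h - 1L), c0:(c0 + w - 1L)] <- TRUE
  m
}

# Multivariate normal draws via Cholesky (zero covariance allowed).
rmvn <- function(n, mean, cov) {
  if (n == 0) return(matrix(numeric(0), 0, length(mean)))
  if (all(cov == 0)) return(matrix(mean, n, length(mean), byrow = TRUE))
  z <- matrix(stats::rnorm(n * length(mean)), n)
  sweep(z %*% chol(cov), 2, mean, "+")
}

#' @export
print.spectral_scene <- function(x, ...) {
  d <- dim(x$bands)
  cat(sprintf("<spectral_scene '%s'> %d x %d px, %d bands; %d valid, %d truth-guano px\n",
              x$scene_id, d[1], d[2], d[3], sum(x$valid_mask),
              sum(x$truth_guano_mask)))
  invisible(x)
}

#' @export
print.colony_registry <- function(x, ...) {
  cat(sprintf("<colony_registry> %d colonies (%s); %s breeding pairs total\n",
              nrow(x), paste(unique(x$region), collapse = "+"),
              format(sum(x$n_true), big.mark = ",")))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 5))
  invisible(x)
}
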