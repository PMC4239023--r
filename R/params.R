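#' Region parameter sets for the Adelie survey
#'
#' Default parameter blocks for the two survey strata. The continent and the
#' Antarctic Peninsula (AP) behave differently in every stage of the pipeline:
#' they have different colony-size laws, different apparent densities linking
#' guano area to breeding pairs, and different size-dependent detection
#' curves, so all model fitting in this package is stratified by region and
#' never pooled.
#'
#' The defaults are the published survey values: lognormal colony-size
#' parameters (mu, sigma on the log scale, breeding pairs), apparent density
#' (nests per square metre of detected guano), and logistic detection
#' coefficients (log-odds intercept `beta0` and slope `beta1` per breeding
#' pair).
#'
#' @param region `"continent"` or `"peninsula"`.
#' @return A list with elements `region`, `mu`, `sigma`, `density`,
#'   `beta0`, `beta1`, and `n_colonies` (a typical stratum size for
#'   simulation).
#' @examples
#' region_params("continent")$density  # 0.34 nests/m^2
#' @export
region_params <- function(region = c("continent", "peninsula")) {
  region <- match.arg(region)
  switch(region,
    continent = list(region = "continent", mu = 8.06, sigma = 2.34,
                     density = 0.34, beta0 = -1.00, beta1 = 4e-4,
                     n_colonies = 180L),
    peninsula = list(region = "peninsula", mu = 6.64, sigma = 2.19,
                     density = 0.52, beta0 = -1.72, beta1 = 3e-4,
                     n_colonies = 64L)
  )
}

#' @rdname region_params
#' @export
survey_regions <- function() c("continent", "peninsula")

# Validate a region label, with a schema-style error naming the offender.
check_region <- function(region) {
  bad <- setdiff(unique(as.character(region)), survey_regions())
  if (length(bad) > 0)
    stop("unknown region label(s): ", paste(bad, collapse = ", "),
         " (expected one of: ", paste(survey_regions(), collapse = ", "), ")",
         call. = FALSE)
  invisible(as.character(region))
}

# Area of one sensor pixel in square metres (30 m x 30 m).
PIXEL_AREA <- 900
PIXEL_SIZE <- 30

# Landsat-7 ETM+ reflective band labels in classifier order.
REFLECTIVE_BANDS <- c("B1", "B2", "B3", "B4", "B5", "B7")

#' Derive a stage-specific sub-seed from a master seed
#'
#' Every stochastic stage of a pipeline run receives its own deterministic
#' sub-seed so stages can be re-run independently while the whole run stays
#' reproducible from one master seed. The value is kept strictly below
#' 2^31 - 1.
#'
#' @param master Master seed (single number).
#' @param stage Integer stage index.
#' @return An integer seed.
#' @export
derive_seed <- function(master, stage) {
  stopifnot(is.numeric(master), length(master) == 1)
  h <- (as.double(master) %% 2147483647) * 48271 + stage * 15485863
  as.integer(h %% 2147483629 + 1)
}

with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}
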