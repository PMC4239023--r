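#' Default run configuration for the synthetic survey pipeline
#'
#' The defaults reproduce the published survey's parameter world: per-region
#' lognormal colony-size laws, apparent densities, registry sizes of roughly
#' 180 continental and 64 Peninsula colonies, a 473-pixel guano training
#' set, 0.99 ellipsoid coverage, and the degradation levels under which
#' omission becomes size-dependent.
#'
#' @return A `run_config` list; see [run_pipeline()] for the fields.
#' @export
default_run_config <- function() {
  list(
    seed = 1L,
    regions = list(
      continent = list(n_colonies = 180L, mu = 8.06, sigma = 2.34,
                       density = 0.34),
      peninsula = list(n_colonies = 64L, mu = 6.64, sigma = 2.19,
                       density = 0.52)
    ),
    confuser_overlap = 0,
    n_train_guano = 473L,
    n_train_background = 2000L,
    coverage = 0.99,
    degradation = list(cloud_fraction = 0.05, shadow_fraction = 0.03,
                       dropout = 0.35),
    connectivity = 8,
    merge_radius = 0,
    min_pixels = 1,
    max_match_distance = 3000,
    level = 0.95,
    n_draws_total = 2000L,
    n_rep_missing = 1000L,
    aggregation = list(k_grid = c(1L, 5L, 10L, 20L, 40L), n_rep = 500L,
                       alpha = 0.05),
    out_dir = NULL
  )
}

validate_run_config <- function(cfg) {
  stopifnot(is.list(cfg), is.numeric(cfg$seed))
  for (r in names(cfg$regions)) {
    check_region(r)
    blk <- cfg$regions[[r]]
    if (!all(c("n_colonies", "mu", "sigma", "density") %in% names(blk)))
      stop("region block '", r, "' must have n_colonies, mu, sigma, density")
    if (blk$sigma <= 0 || blk$density <= 0)
      stop("region block '", r, "': sigma and density must be > 0")
  }
  stopifnot(cfg$coverage > 0, cfg$coverage < 1,
            cfg$connectivity %in% c(4, 8),
            cfg$max_match_distance > 0, cfg$level > 0, cfg$level < 1)
  class(cfg) <- c("run_config", "list")
  cfg
}

#' Run the full synthetic survey pipeline
#'
#' End-to-end orchestration: simulate registries and scenes, train the
#' spectral classifier, retrieve and group guano pixels, score detection
#' outcomes, fit the detection, abundance and colony-size models, estimate
#' the abundance missing due to non-detection, probe aggregation
#' equivalence, and assemble the corrected survey total. Every stochastic
#' stage draws its own sub-seed from `config$seed`, so a repeated run with
#' the same configuration produces a byte-identical report.
#'
#' When `config$out_dir` is set, the stage interface files (registry and
#' candidate CSVs, scene containers, JSON reports) are written there.
#'
#' @param config A `run_config` list, e.g. [default_run_config()] or
#'   [read_run_config()].
#' @param quiet Suppress per-stage log lines.
#' @return A `pipeline_report` list; see the `report` element written to
#'   JSON for the flattened form.
#' @export
run_pipeline <- function(config = default_run_config(), quiet = TRUE) {
  cfg <- validate_run_config(config)
  say <- function(...) if (!quiet) message(sprintf(...))
  library <- spectral_library()
  if (cfg$confuser_overlap > 0)
    library <- add_confuser_class(library, cfg$confuser_overlap)

  regions <- names(cfg$regions)
  per <- list()
  for (ri in seq_along(regions)) {
    rg <- regions[ri]
    blk <- cfg$regions[[rg]]
    registry <- sample_colony_registry(
      blk$n_colonies, c(blk$mu, blk$sigma), blk$density, region = rg,
      seed = derive_seed(cfg$seed, 10 + ri))
    scene <- render_scene(registry, library,
                          degradation = cfg$degradation,
                          seed = derive_seed(cfg$seed, 20 + ri),
                          scene_id = paste0("scene-", rg))
    train <- sample_training_pixels(library, cfg$n_train_guano,
                                    cfg$n_train_background,
                                    seed = derive_seed(cfg$seed, 30 + ri))
    clf <- fit_ellipsoid(train$guano, coverage = cfg$coverage)
    mask <- classify_pixels(scene, clf)
    cands <- extract_candidates(mask, connectivity = cfg$connectivity,
                                merge_radius = cfg$merge_radius,
                                min_pixels = cfg$min_pixels,
                                scene_id = scene$scene_id)
    mo <- match_outcomes(cands, registry, cfg$max_match_distance)
    say("[%s] %d colonies, %d px flagged, %d candidates, %d detected, %d omitted, %d commissions",
        rg, nrow(registry), sum(mask), nrow(cands), mo$summary$n_both,
        mo$summary$n_omission, mo$summary$n_commission)

    col <- mo$colonies
    det <- tryCatch(
      fit_detection_model(col$n_vhr, col$detected, region = rg),
      error = function(e) NULL)   # e.g. every colony detected
    detd <- col[col$detected == 1 & !is.na(col$guano_area), , drop = FALSE]
    ab <- if (nrow(detd) >= 1)
      fit_abundance_model(detd$guano_area, detd$n_vhr, region = rg) else NULL
    size_fit <- fit_colony_size_distribution(pmax(col$n_vhr, 1), region = rg)
    dist <- discretize_size_distribution(size_fit$mu, size_fit$sigma,
                                         region = rg)
    per[[rg]] <- list(registry = registry, scene = scene, classifier = clf,
                      mask_flagged = sum(mask), candidates = cands,
                      outcomes = mo, detection = det, abundance = ab,
                      size_fit = size_fit, size_dist = dist)
  }

  # missing abundance across regions with an estimable detection model
  miss_inputs <- list()
  for (rg in regions) {
    p <- per[[rg]]
    s <- p$outcomes$summary
    if (!is.null(p$detection) && s$n_both >= 1 && s$p_hat < 1)
      miss_inputs[[rg]] <- list(dist = p$size_dist, det = p$detection,
                                k_detected = s$n_both, p_hat = s$p_hat)
  }
  missing <- if (length(miss_inputs) > 0)
    total_missing_abundance(miss_inputs, n_rep = cfg$n_rep_missing,
                            level = cfg$level,
                            seed = derive_seed(cfg$seed, 40)) else NULL

  # corrected survey total: detected-total draws + missing-total draws
  nd <- cfg$n_draws_total
  detected_draws <- numeric(nd)
  detected_point <- 0
  for (ri in seq_along(regions)) {
    rg <- regions[ri]
    p <- per[[rg]]
    detd <- p$outcomes$colonies
    detd <- detd[detd$detected == 1 & !is.na(detd$guano_area), , drop = FALSE]
    if (nrow(detd) == 0 || is.null(p$abundance)) next
    detected_draws <- detected_draws +
      predict_abundance_total(p$abundance, detd$guano_area, n_draws = nd,
                              seed = derive_seed(cfg$seed, 50 + ri))
    detected_point <- detected_point + sum(detd$guano_area * exp(p$abundance$beta))
  }
  total_draws <- detected_draws
  if (!is.null(missing)) {
    md <- missing$draws
    total_draws <- total_draws +
      md[((seq_len(nd) - 1) %% length(md)) + 1]
  }
  a <- (1 - cfg$level) / 2
  true_total <- sum(vapply(per, function(p) sum(p$registry$n_true), numeric(1)))
  total_est <- list(
    true_total = true_total,
    detected_point = detected_point,
    missing_point = if (is.null(missing)) 0 else missing$total_missing,
    estimate = detected_point +
      (if (is.null(missing)) 0 else missing$total_missing),
    ci = stats::quantile(total_draws, c(a, 1 - a), names = FALSE, type = 8),
    level = cfg$level)
  total_est$covered <- total_est$ci[1] <= true_total &&
    true_total <= total_est$ci[2]

  # aggregation over pooled detected colonies
  pooled <- do.call(rbind, lapply(regions, function(rg) {
    col <- per[[rg]]$outcomes$colonies
    col <- col[col$detected == 1 & !is.na(col$guano_area), , drop = FALSE]
    if (nrow(col) == 0) return(NULL)
    data.frame(region = col$region, guano_area = col$guano_area,
               n_vhr = pmax(col$n_vhr, 1), vhr_cv = col$vhr_cv)
  }))
  fits <- lapply(per, `[[`, "abundance")
  agg <- NULL
  if (length(cfg$aggregation$k_grid) > 0 && !is.null(pooled) &&
      nrow(pooled) >= max(cfg$aggregation$k_grid)) {
    agg <- find_equivalence_scale(pooled, fits,
                                  k_grid = cfg$aggregation$k_grid,
                                  alpha = cfg$aggregation$alpha,
                                  n_rep = cfg$aggregation$n_rep,
                                  seed = derive_seed(cfg$seed, 60))
  }

  report <- build_report(cfg, per, missing, total_est, agg)
  if (!is.null(cfg$out_dir)) write_outputs(cfg, per, missing, report)
  structure(list(config = cfg, per_region = per, missing = missing,
                 total = total_est, aggregation = agg, report = report),
            class = "pipeline_report")
}

# Flatten the run into a plain, JSON-stable list.
build_report <- function(cfg, per, missing, total_est, agg) {
  rr <- lapply(per, function(p) {
    s <- p$outcomes$summary
    list(
      n_colonies = nrow(p$registry),
      true_total = sum(p$registry$n_true),
      pixels_flagged = p$mask_flagged,
      n_candidates = s$n_candidates,
      n_both = s$n_both, n_omission = s$n_omission,
      n_commission = s$n_commission,
      commission_rate = s$commission_rate,
      p_hat = s$p_hat,
      detection = if (is.null(p$detection)) NULL else
        p$detection[c("beta0", "beta1", "se0", "se1")],
      abundance = if (is.null(p$abundance)) NULL else
        list(beta = p$abundance$beta, se = p$abundance$se,
             apparent_density = exp(p$abundance$beta),
             tau_log_resid = p$abundance$tau_log_resid),
      size_law = p$size_fit[c("mu", "sigma", "se_mu", "se_sigma")])
  })
  list(seed = cfg$seed,
       regions = rr,
       missing = if (is.null(missing)) NULL else list(
         per_region = missing$per_region,
         total_missing = missing$total_missing,
         ci = missing$ci, level = missing$level),
       total = total_est,
       aggregation = if (is.null(agg)) NULL else list(
         k_equivalent = if (agg$reached) agg$k_equivalent else "not reached",
         alpha = agg$alpha, profile = agg$profile))
}

write_outputs <- function(cfg, per, missing, report) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  for (rg in names(per)) {
    p <- per[[rg]]
    write_registry(p$registry, file.path(cfg$out_dir, paste0("registry_", rg, ".csv")))
    write_scene(p$scene, file.path(cfg$out_dir, paste0("scene_", rg)))
    cands <- p$candidates
    write_candidates(cands, file.path(cfg$out_dir, paste0("candidates_", rg, ".csv")))
    if (nrow(cands) > 0)
      write_kml(cands, file.path(cfg$out_dir, paste0("candidates_", rg, ".kml")))
    if (!is.null(p$detection))
      write_detection_report(p$detection,
                             file.path(cfg$out_dir, paste0("detection_", rg, ".json")))
  }
  if (!is.null(missing))
    write_missing_report(missing, file.path(cfg$out_dir, "missing_abundance.json"))
  jsonlite::write_json(report, file.path(cfg$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(cfg$out_dir)
}

#' @export
print.pipeline_report <- function(x, ...) {
  t <- x$total
  cat("<pipeline_report>\n")
  for (rg in names(x$per_region)) {
    s <- x$per_region[[rg]]$outcomes$summary
    cat(sprintf("  %-10s %3d colonies: %3d detected, %3d omitted, %2d commissions\n",
                rg, s$n_registry, s$n_both, s$n_omission, s$n_commission))
  }
  cat(sprintf("  survey total %.0f (true %.0f), %.0f%% CI [%.0f, %.0f], covered: %s\n",
              t$estimate, t$true_total, 100 * t$level, t$ci[1], t$ci[2],
              t$covered))
  invisible(x)
}
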