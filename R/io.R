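#' Read and write colony registries as CSV
#'
#' UTF-8 CSV with a header row and the colony-record columns
#' (`colony_id`, `region`, `x`, `y`, `n_true`, `n_vhr`, `vhr_cv`,
#' `guano_area_true`, `excluded`). Region labels are validated on read.
#'
#' @param registry A `colony_registry`.
#' @param path File path.
#' @return `write_registry` returns `path` invisibly; `read_registry`
#'   returns a `colony_registry`.
#' @export
write_registry <- function(registry, path) {
  utils::write.csv(as.data.frame(registry), path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_registry
#' @export
read_registry <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  required <- c("colony_id", "region", "x", "y", "n_true", "n_vhr",
                "vhr_cv", "guano_area_true", "excluded")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0)
    stop("registry file is missing column(s): ", paste(missing, collapse = ", "))
  check_region(df$region)
  df$n_true <- as.integer(df$n_true); df$n_vhr <- as.integer(df$n_vhr)
  df$excluded <- as.logical(df$excluded)
  class(df) <- c("colony_registry", "data.frame")
  df
}

#' Read and write spectral scenes
#'
#' Portable scene container: `<stem>.tif` holds the six reflectance bands as
#' a multipage float32 TIFF (band order B1..B5, B7), `<stem>_masks.tif`
#' holds the validity and truth masks as uint8 pages, and `<stem>.json` is a
#' sidecar with scene id, dimensions, band names and pixel area. The
#' write-then-read round trip preserves reflectances to float32 precision
#' and masks exactly.
#'
#' @param scene A `spectral_scene`.
#' @param stem Path stem (no extension).
#' @return `write_scene` returns `stem` invisibly; `read_scene` returns a
#'   `spectral_scene`.
#' @export
write_scene <- function(scene, stem) {
  stopifnot(inherits(scene, "spectral_scene"))
  d <- dim(scene$bands)
  tiff::writeTIFF(lapply(1:d[3], function(b) scene$bands[, , b]),
                  paste0(stem, ".tif"), bits.per.sample = 32)
  tiff::writeTIFF(list(scene$valid_mask * 1, scene$truth_guano_mask * 1),
                  paste0(stem, "_masks.tif"), bits.per.sample = 8)
  meta <- list(scene_id = scene$scene_id, rows = d[1], cols = d[2],
               n_bands = d[3], band_names = scene$band_names,
               pixel_area = scene$pixel_area,
               masks = c("valid_mask", "truth_guano_mask"))
  jsonlite::write_json(meta, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(stem)
}

#' @rdname write_scene
#' @export
read_scene <- function(stem) {
  jpath <- paste0(stem, ".json")
  if (!file.exists(jpath)) stop("missing scene sidecar: ", jpath)
  meta <- jsonlite::read_json(jpath, simplifyVector = TRUE)
  for (f in c("scene_id", "rows", "cols", "n_bands", "band_names", "pixel_area"))
    if (is.null(meta[[f]])) stop("scene sidecar is missing field: ", f)
  pages <- tiff::readTIFF(paste0(stem, ".tif"), all = TRUE)
  if (length(pages) != meta$n_bands)
    stop("band file has ", length(pages), " pages, sidecar declares ",
         meta$n_bands)
  bands <- array(NA_real_, c(meta$rows, meta$cols, meta$n_bands))
  for (b in seq_along(pages)) {
    if (!all(dim(pages[[b]]) == c(meta$rows, meta$cols)))
      stop("band ", b, " dimensions disagree with sidecar")
    bands[, , b] <- pages[[b]]
  }
  masks <- tiff::readTIFF(paste0(stem, "_masks.tif"), all = TRUE)
  structure(list(bands = bands,
                 valid_mask = matrix(masks[[1]] > 0.5, meta$rows, meta$cols),
                 truth_guano_mask = matrix(masks[[2]] > 0.5, meta$rows, meta$cols),
                 class_map = NULL,
                 pixel_area = meta$pixel_area,
                 band_names = meta$band_names,
                 scene_id = meta$scene_id),
            class = "spectral_scene")
}

#' Write retrieval candidates (with outcomes, if matched) to CSV
#'
#' @param candidates A `retrieval_candidates` data frame, optionally
#'   augmented with `matched_colony_id` and `outcome` columns.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_candidates <- function(candidates, path) {
  utils::write.csv(as.data.frame(candidates), path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Export candidate placemarks as KML
#'
#' Writes one KML placemark per candidate. Scene-local metric coordinates
#' are mapped to synthetic longitude/latitude around an `origin` using a
#' simple equirectangular conversion; for synthetic scenes the coordinates
#' are only meaningful relative to one another.
#'
#' @param candidates A `retrieval_candidates` data frame.
#' @param path Output `.kml` file.
#' @param origin `c(lon, lat)` mapped to scene coordinate (0, 0).
#' @return `path`, invisibly.
#' @export
write_kml <- function(candidates, path, origin = c(0, -70)) {
  lat <- origin[2] - candidates$centroid_y / 111320
  lon <- origin[1] + candidates$centroid_x /
    (111320 * cos(origin[2] * pi / 180))
  pm <- sprintf(paste0(
    "    <Placemark><name>%s</name>",
    "<description>pixels=%d area_m2=%.0f</description>",
    "<Point><coordinates>%.8f,%.8f,0</coordinates></Point></Placemark>"),
    candidates$candidate_id, candidates$pixel_count, candidates$guano_area,
    lon, lat)
  writeLines(c('<?xml version="1.0" encoding="UTF-8"?>',
               '<kml xmlns="http://www.opengis.net/kml/2.2">',
               "  <Document>", pm, "  </Document>", "</kml>"), path)
  invisible(path)
}

#' Read a survey comparison table (CSV or XLSX)
#'
#' Loads a colony-by-colony survey table of the kind used to calibrate the
#' detection and abundance models: one row per known colony with its region,
#' reference abundance, retrieved pixel count and detection flag. Accepts
#' CSV, or XLSX when the `readxl` package is installed. Column names are
#' matched case-insensitively against the canonical set and must include
#' `region`, `abundance`, and `detected`; `pixels` is optional but required
#' for rank-correlation and abundance-model work.
#'
#' @param path CSV or XLSX file.
#' @return `data.frame` with lower-cased canonical names.
#' @export
read_survey_table <- function(path) {
  if (!file.exists(path)) stop("survey table not found: ", path)
  df <- if (grepl("\\.xlsx?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("readxl", quietly = TRUE))
      stop("reading XLSX requires the readxl package; supply a CSV instead")
    as.data.frame(readxl::read_excel(path))
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
  names(df) <- tolower(names(df))
  required <- c("region", "abundance", "detected")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0)
    stop("survey table is missing column(s): ", paste(missing, collapse = ", "))
  check_region(df$region)
  df
}

#' Read a pipeline run configuration
#'
#' Flat YAML key-value file validated against the run-configuration schema;
#' omitted keys fall back to [default_run_config()] values.
#'
#' @param path YAML file, or `NULL` for the defaults.
#' @return A validated `run_config` list.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- default_run_config()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    unknown <- setdiff(names(user), names(cfg))
    if (length(unknown) > 0)
      stop("unknown config key(s): ", paste(unknown, collapse = ", "))
    cfg <- utils::modifyList(cfg, user)
  }
  validate_run_config(cfg)
}
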