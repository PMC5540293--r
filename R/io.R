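TRACK_COLS <- c("whale_id", "timestamp", "lon", "lat", "location_class")

#' Read an Argos-style fix table from CSV
#'
#' Expected header: `whale_id, timestamp, lon, lat, location_class`
#' (optionally `duplicate_group`). Timestamps are parsed as UTC at second
#' precision. Rows with unparseable timestamps or out-of-range coordinates
#' are rejected with their line numbers.
#'
#' @param path CSV file path.
#' @return Tibble of fixes.
#' @export
read_tracks <- function(path) {
  header <- strsplit(readr::read_lines(path, n_max = 1), ",")[[1]]
  missing <- setdiff(TRACK_COLS, trimws(header))
  if (length(missing) > 0) {
    stop_bad_input("track file missing column(s): ", paste(missing, collapse = ", "))
  }
  x <- readr::read_csv(path, show_col_types = FALSE,
                       col_types = readr::cols(
                         whale_id = readr::col_character(),
                         timestamp = readr::col_datetime(),
                         lon = readr::col_double(),
                         lat = readr::col_double(),
                         location_class = readr::col_character(),
                         .default = readr::col_guess()
                       ))
  missing <- setdiff(TRACK_COLS, names(x))
  if (length(missing) > 0) {
    stop_bad_input("track file missing column(s): ", paste(missing, collapse = ", "))
  }
  bad <- is.na(x$timestamp) | is.na(x$lon) | is.na(x$lat) |
    abs(x$lon) > 180 | abs(x$lat) > 90
  if (any(bad)) {
    stop_bad_input("malformed track rows at data line(s): ",
                   paste(utils::head(which(bad), 10), collapse = ", "))
  }
  x$timestamp <- lubridate::with_tz(x$timestamp, "UTC")
  x
}

#' Write an Argos-style fix table to CSV
#'
#' Timestamps are written as UTC `YYYY-MM-DDTHH:MM:SSZ` so that
#' `read_tracks(write_tracks(x))` round-trips at second precision.
#'
#' @param fixes Tibble of fixes.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(fixes, path) {
  out <- fixes
  out$timestamp <- format(lubridate::with_tz(out$timestamp, "UTC"),
                          "%Y-%m-%dT%H:%M:%SZ")
  readr::write_csv(out, path)
  invisible(path)
}

#' Write a shoreline to GeoJSON
#'
#' A minimal WGS84 GeoJSON FeatureCollection: the polyline as a LineString
#' feature and the river mouth as a Point feature.
#'
#' @param shoreline A [make_shoreline()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_shoreline_geojson <- function(shoreline, path) {
  fc <- list(
    type = "FeatureCollection",
    features = list(
      list(type = "Feature",
           properties = list(role = "shoreline"),
           geometry = list(type = "LineString",
                           coordinates = unname(purrr::map2(
                             shoreline$vertices$lon, shoreline$vertices$lat, c)))),
      list(type = "Feature",
           properties = list(role = "river_mouth"),
           geometry = list(type = "Point",
                           coordinates = unname(c(shoreline$river_mouth[["lon"]],
                                                  shoreline$river_mouth[["lat"]]))))
    )
  )
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = 10)
  invisible(path)
}

#' Read a shoreline from GeoJSON
#'
#' @param path GeoJSON file written by [write_shoreline_geojson()] (or any
#'   FeatureCollection with a LineString and a Point feature).
#' @return A `shoreline` object.
#' @export
read_shoreline_geojson <- function(path) {
  fc <- jsonlite::read_json(path)
  types <- purrr::map_chr(fc$features, ~ .x$geometry$type)
  line <- fc$features[[which(types == "LineString")[1]]]
  pt <- fc$features[[which(types == "Point")[1]]]
  coords <- purrr::map(line$geometry$coordinates, unlist)
  structure(
    list(vertices = tibble(lon = purrr::map_dbl(coords, 1),
                           lat = purrr::map_dbl(coords, 2)),
         river_mouth = c(lon = pt$geometry$coordinates[[1]],
                         lat = pt$geometry$coordinates[[2]])),
    class = "shoreline"
  )
}

#' Export a utilization distribution as an ESRI ASCII grid
#'
#' Writes the density matrix in the plain-text ESRI ASCII raster format
#' (ncols/nrows/xllcorner/yllcorner/cellsize header, rows from north to
#' south), with coordinates in the local projected km frame.
#'
#' @param ud A [kde_ud()] grid.
#' @param path Output `.asc` path.
#' @return `path`, invisibly.
#' @export
write_ud_asc <- function(ud, path) {
  stopifnot(inherits(ud, "ud_grid"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", length(ud$x)),
    paste("nrows", length(ud$y)),
    paste("xllcorner", ud$x[1] - ud$cell_km / 2),
    paste("yllcorner", ud$y[1] - ud$cell_km / 2),
    paste("cellsize", ud$cell_km),
    "NODATA_value -9999"
  ), con)
  for (j in rev(seq_along(ud$y))) {   # north row first
    writeLines(paste(format(ud$z[, j], digits = 10, scientific = TRUE,
                            trim = TRUE), collapse = " "), con)
  }
  invisible(path)
}

#' Read an ESRI ASCII grid written by [write_ud_asc()]
#'
#' @param path `.asc` path.
#' @return A `ud_grid`-like list with `x`, `y`, `z`, `cell_km`.
#' @export
read_ud_asc <- function(path) {
  lines <- readr::read_lines(path)
  hdr <- strsplit(tolower(lines[1:6]), "\\s+")
  val <- function(key) {
    as.numeric(hdr[[which(vapply(hdr, `[[`, "", 1) == key)]][2])
  }
  ncols <- val("ncols"); nrows <- val("nrows"); cell <- val("cellsize")
  x0 <- val("xllcorner"); y0 <- val("yllcorner")
  z_rows <- lapply(lines[7:(6 + nrows)], function(l) as.numeric(strsplit(trimws(l), "\\s+")[[1]]))
  z <- t(do.call(rbind, rev(z_rows)))   # back to [x, y] orientation
  structure(list(x = x0 + cell / 2 + cell * (seq_len(ncols) - 1),
                 y = y0 + cell / 2 + cell * (seq_len(nrows) - 1),
                 z = z, cell_km = cell,
                 h = NA_real_, n_points = NA_integer_),
            class = "ud_grid")
}

#' Packaged deployment and survey fixtures
#'
#' Small plain-text tables shipped with the package: the 13 tag deployments
#' (year, tag, model, date, longevity, sex, body length) and the 17
#' high-tide aerial surveys (date, time window, tide phase). Row counts and
#' schemas are verified on load.
#'
#' @return `load_deployments()`: a 13-row tibble; `load_surveys()`: a
#'   17-row tibble.
#' @export
load_deployments <- function() {
  path <- system.file("extdata", "deployments.csv", package = "estuaryuse",
                      mustWork = TRUE)
  x <- readr::read_csv(path, show_col_types = FALSE)
  check_fixture(x, n = 13, cols = c("year", "tag", "model", "deploy_date",
                                    "longevity_days", "sex", "length_cm"))
  x
}

#' @rdname load_deployments
#' @export
load_surveys <- function() {
  path <- system.file("extdata", "surveys.csv", package = "estuaryuse",
                      mustWork = TRUE)
  x <- readr::read_csv(path, show_col_types = FALSE)
  check_fixture(x, n = 17, cols = c("year", "date", "time", "tide"))
  x
}

check_fixture <- function(x, n, cols) {
  if (nrow(x) != n || !all(cols %in% names(x))) {
    stop_bad_input(sprintf("fixture integrity check failed: expected %d rows with columns %s",
                           n, paste(cols, collapse = ", ")))
  }
  invisible(x)
}

#' Run the full synthetic analysis pipeline
#'
#' Simulate tracks, run Argos quality control, compute daily median
#' locations and distance covariates against the funnel shoreline fixture,
#' estimate the migration change point from the pooled daily distance
#' series, classify wet/dry years from a simulated discharge series, build
#' the pre-change-point utilization distribution and estuary polygon, fit
#' the AR1 log-distance models, and simulate and summarise one aerial
#' survey. Every stage's output is returned in one named list; all
#' randomness flows from the seeds in the arguments.
#'
#' @param config A [sim_config()] for the telemetry simulation.
#' @param year_means Named per-year seasonal mean discharges (m^3/s) for
#'   the hydrology stage.
#' @param baseline_mean Baseline discharge (m^3/s) against which study
#'   years are classified.
#' @param n_survey_whales Whales present in the simulated survey.
#' @param out_dir Optional directory; if given, CSV/JSON/GeoJSON outputs
#'   are written there.
#' @param contour_levels Probability-contour levels for the UD stage.
#' @return Named list with elements `fixes`, `qc`, `daily`, `pooled`,
#'   `changepoint`, `hydrology`, `ud`, `contours`, `estuary`, `models`,
#'   `survey`, and `seeds`.
#' @export
run_pipeline <- function(config = sim_config(),
                         year_means = c(`2002` = 3131, `2003` = 2165,
                                        `2004` = 2831, `2005` = 5163),
                         baseline_mean = 3331,
                         n_survey_whales = 500,
                         out_dir = NULL,
                         contour_levels = c(25, 50, 75, 95)) {
  fixes <- simulate_tracks(config)
  qc <- qc_tracks(fixes)
  shore <- make_shoreline()
  daily <- daily_summaries(qc$fixes, mouth = port_nelson(), shoreline = shore)
  pooled <- pooled_daily_distance(daily)
  cp <- cumulative_sign_changepoint(dplyr::select(pooled, "day_of_year", "distance"))

  discharge <- simulate_discharge(year_means, seed = config$seed)
  hydro <- classify_wet_dry(seasonal_means(discharge), baseline_mean = baseline_mean)

  pre <- dplyr::filter(daily, .data$day_of_year < cp$change_doy)
  xy <- project_local(cbind(pre$median_lon, pre$median_lat))
  h <- lscv_bandwidth(xy)$h
  ud <- kde_ud(xy, h, cell_km = 1)
  contours <- probability_contours(ud, contour_levels)
  estuary <- estuary_polygon(xy)

  model_data <- daily %>%
    dplyr::filter(.data$dist_mouth > 0, .data$dist_shore > 0) %>%
    dplyr::mutate(tide = tide_height_fun(
      as.numeric(.data$date - config$start_date) + 0.5,
      amplitude = config$tide_amplitude))
  models <- rank_models(list(
    fit_model(model_data, "dist_mouth", character(), method = "ML"),
    fit_model(model_data, "dist_mouth", "tide", method = "ML"),
    fit_model(model_data, "dist_mouth", c("tide", "day_of_year"), method = "ML")
  ))

  design <- survey_design()
  records <- simulate_survey(design, n_whales = n_survey_whales,
                             seed = config$seed + 17L)
  blocks <- bin_to_blocks(records, design)
  survey <- list(
    design = design, records = records, blocks = blocks,
    coverage = coverage_fraction(design),
    weighted_dist_shore = density_weighted_distance(blocks, "shore"),
    abundance_index = abundance_index(blocks, coverage_fraction(design))
  )

  out <- list(fixes = fixes, qc = qc$report, daily = daily, pooled = pooled,
              changepoint = cp, hydrology = hydro, ud = ud,
              contours = contours, estuary = estuary, models = models,
              survey = survey, seeds = c(sim = config$seed))
  if (!is.null(out_dir)) write_pipeline_outputs(out, shore, out_dir)
  out
}

write_pipeline_outputs <- function(out, shore, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_tracks(out$fixes, file.path(out_dir, "fixes.csv"))
  readr::write_csv(out$daily, file.path(out_dir, "daily_summaries.csv"))
  readr::write_csv(out$pooled, file.path(out_dir, "pooled_distance.csv"))
  readr::write_csv(out$hydrology, file.path(out_dir, "wet_dry.csv"))
  readr::write_csv(out$models, file.path(out_dir, "model_ranking.csv"))
  readr::write_csv(out$survey$blocks, file.path(out_dir, "survey_blocks.csv"))
  write_shoreline_geojson(shore, file.path(out_dir, "shoreline.geojson"))
  jsonlite::write_json(
    list(qc = as.list(out$qc),
         change_doy = out$changepoint$change_doy,
         max_abs_cumsum = out$changepoint$max_abs_cumsum,
         estuary = out$estuary[c("area_km2", "alongshore_km", "offshore_km", "method")],
         survey = list(coverage = out$survey$coverage,
                       abundance_index = out$survey$abundance_index),
         seeds = as.list(out$seeds)),
    file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
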