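#' Geodesic distance between points in kilometres
#'
#' WGS84 geodesic (ellipsoidal) distance. Both arguments are recycled, so a
#' single point can be compared against a whole track.
#'
#' @param a,b Coordinates: a length-2 `c(lon, lat)` vector, a two-column
#'   matrix, or a data frame with `lon`/`lat` columns.
#' @return Numeric vector of distances in km.
#' @export
#' @examples
#' geodesic_km(c(-92.6, 57.0), c(-92.6, 58.0))
geodesic_km <- function(a, b) {
  a <- as_lonlat_matrix(a)
  b <- as_lonlat_matrix(b)
  if (any(abs(a[, 2]) > 90) || any(abs(b[, 2]) > 90) ||
      any(abs(a[, 1]) > 180) || any(abs(b[, 1]) > 180) ||
      anyNA(a) || anyNA(b)) {
    stop_bad_input("invalid coordinates: lon must be in [-180, 180], lat in [-90, 90]")
  }
  geosphere::distGeo(a, b) / 1000
}

as_lonlat_matrix <- function(p) {
  if (is.data.frame(p)) {
    stopifnot(all(c("lon", "lat") %in% names(p)))
    return(cbind(p$lon, p$lat))
  }
  if (is.matrix(p)) return(p)
  matrix(as.numeric(p), ncol = 2)
}

#' Project longitude/latitude to local kilometre coordinates
#'
#' Azimuthal-equidistant projection centred on `centre`: each point maps to
#' `(d sin(theta), d cos(theta))` where `d` is its geodesic distance from the
#' centre (km) and `theta` its initial bearing. Distances and bearings from
#' the centre are exact; the projection is used for kernel density estimation,
#' hulls and the survey grid, where a planar frame is required.
#'
#' @param p Points (see [geodesic_km()] for accepted forms).
#' @param centre `c(lon, lat)` projection centre; defaults to [port_nelson()].
#' @return Tibble with columns `x`, `y` in km (x east, y north).
#' @export
project_local <- function(p, centre = port_nelson()) {
  p <- as_lonlat_matrix(p)
  d <- geosphere::distGeo(matrix(centre, ncol = 2)[rep(1, nrow(p)), , drop = FALSE], p) / 1000
  brg <- geosphere::bearing(matrix(centre, ncol = 2)[rep(1, nrow(p)), , drop = FALSE], p)
  brg[is.na(brg)] <- 0  # coincident with centre
  tibble(x = d * sin(brg * pi / 180), y = d * cos(brg * pi / 180))
}

#' Inverse of [project_local()]
#'
#' @param xy Tibble/matrix with `x`, `y` km columns.
#' @inheritParams project_local
#' @return Tibble with `lon`, `lat` columns.
#' @export
unproject_local <- function(xy, centre = port_nelson()) {
  if (is.data.frame(xy)) xy <- cbind(xy$x, xy$y)
  d <- sqrt(xy[, 1]^2 + xy[, 2]^2) * 1000
  brg <- atan2(xy[, 1], xy[, 2]) * 180 / pi
  out <- geosphere::destPoint(matrix(port_nelson_like(centre), ncol = 2)[rep(1, nrow(xy)), , drop = FALSE], brg, d)
  tibble(lon = out[, 1], lat = out[, 2])
}

port_nelson_like <- function(centre) c(centre[[1]], centre[[2]])

#' Day of year
#'
#' 1-based ordinal day within the year, leap-aware (9 August is day 221 in a
#' common year; 8 August is day 221 in a leap year).
#'
#' @param date A `Date`, date-time, or something coercible via [as.Date()].
#' @return Integer day of year (1-366).
#' @export
#' @examples
#' doy(as.Date("2003-08-09"))  # 221
#' doy(as.Date("2004-08-08"))  # 221
doy <- function(date) {
  lubridate::yday(as.Date(date, tz = "UTC"))
}

#' Minimum geodesic distance from a point to a shoreline polyline
#'
#' The polyline is densified to at most 100 m vertex spacing and the minimum
#' geodesic point-to-vertex distance returned, so the worst-case
#' discretisation error is ~50 m.
#'
#' @param p Point(s), `c(lon, lat)` or a two-column object.
#' @param shoreline A [shoreline] object (or any list with a `vertices`
#'   tibble of `lon`/`lat`).
#' @return Numeric vector of distances in km.
#' @export
dist_to_shoreline <- function(p, shoreline) {
  v <- shoreline$vertices
  if (is.null(v) || nrow(v) == 0) stop_bad_input("shoreline has no vertices")
  if (nrow(v) == 1) {
    warning("degenerate single-vertex shoreline; returning distance to that vertex")
    return(geodesic_km(p, c(v$lon, v$lat)))
  }
  dense <- densify_polyline(v, max_spacing_km = 0.1)
  p <- as_lonlat_matrix(p)
  vapply(seq_len(nrow(p)), function(i) {
    min(geosphere::distGeo(p[i, , drop = FALSE], cbind(dense$lon, dense$lat))) / 1000
  }, numeric(1))
}

densify_polyline <- function(v, max_spacing_km = 0.1) {
  segs <- purrr::map(seq_len(nrow(v) - 1), function(i) {
    a <- c(v$lon[i], v$lat[i]); b <- c(v$lon[i + 1], v$lat[i + 1])
    d <- geodesic_km(a, b)
    n <- max(1L, ceiling(d / max_spacing_km))
    t <- seq(0, 1, length.out = n + 1L)
    tibble(lon = a[1] + t * (b[1] - a[1]), lat = a[2] + t * (b[2] - a[2]))
  })
  dplyr::distinct(dplyr::bind_rows(segs))
}

#' Daily median locations and distance covariates
#'
#' Collapses quality-controlled fixes to one row per whale per UTC calendar
#' day: the componentwise median of longitude and latitude, with distance to
#' the river mouth and (optionally) to the nearest shoreline evaluated at
#' that median location. Daily medians, rather than all fixes, damp the
#' effect of duty-cycled and unevenly sampled Argos fixes.
#'
#' @param fixes Tibble of fixes with `whale_id`, `timestamp`, `lon`, `lat`.
#' @param mouth `c(lon, lat)` of the river mouth; default [port_nelson()].
#' @param shoreline Optional [shoreline] for the `dist_shore` covariate;
#'   if `NULL` the column is `NA`.
#' @return Tibble with one row per whale-day: `whale_id`, `date`, `year`,
#'   `day_of_year`, `median_lon`, `median_lat`, `dist_mouth`, `dist_shore`,
#'   `n_fixes`.
#' @export
daily_summaries <- function(fixes, mouth = port_nelson(), shoreline = NULL) {
  stopifnot(all(c("whale_id", "timestamp", "lon", "lat") %in% names(fixes)))
  out <- fixes %>%
    dplyr::mutate(date = as.Date(lubridate::with_tz(.data$timestamp, "UTC"))) %>%
    dplyr::group_by(.data$whale_id, .data$date) %>%
    dplyr::summarise(
      median_lon = stats::median(.data$lon),
      median_lat = stats::median(.data$lat),
      n_fixes = dplyr::n(),
      .groups = "drop"
    ) %>%
    dplyr::mutate(
      year = as.integer(format(.data$date, "%Y")),
      day_of_year = doy(.data$date),
      dist_mouth = geodesic_km(cbind(.data$median_lon, .data$median_lat), mouth)
    )
  out$dist_shore <- if (is.null(shoreline)) NA_real_ else {
    dist_to_shoreline(cbind(out$median_lon, out$median_lat), shoreline)
  }
  dplyr::select(
    out, "whale_id", "date", "year", "day_of_year",
    "median_lon", "median_lat", "dist_mouth", "dist_shore", "n_fixes"
  )
}

#' Pool daily whale distances across individuals
#'
#' For each day of year, pools `dist_mouth` across whales with data that day.
#' The default pooling statistic is the median; the mean is available since
#' either reading of "pooled daily distance" is defensible. Days with no
#' data are absent from the output (missing, not zero).
#'
#' @param summaries Output of [daily_summaries()].
#' @param stat `"median"` (default) or `"mean"`.
#' @return Tibble with `day_of_year`, `distance` (km) and `n_whales`,
#'   ordered by day.
#' @export
pooled_daily_distance <- function(summaries, stat = c("median", "mean")) {
  stat <- match.arg(stat)
  f <- if (stat == "median") stats::median else mean
  summaries %>%
    dplyr::group_by(.data$day_of_year) %>%
    dplyr::summarise(
      distance = f(.data$dist_mouth),
      n_whales = dplyr::n_distinct(.data$whale_id),
      .groups = "drop"
    ) %>%
    dplyr::arrange(.data$day_of_year)
}
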