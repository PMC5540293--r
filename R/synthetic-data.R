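#' Simulation configuration for synthetic beluga tracks
#'
#' Bundles every knob of the two-phase movement simulator. The defaults
#' emulate the study system: ~13 tagged whales resident near the Nelson
#' River mouth through early August (day of year 221), then migrating
#' northeast along the coast; duty-cycled Argos sampling with
#' class-dependent location error.
#'
#' Residency is a discrete-time mean-reverting (Ornstein-Uhlenbeck-like)
#' walk around `residency_center` whose stationary standard deviation per
#' axis equals `residency_sd`; the correlation time is `tau_days`. A
#' cross-shore (north-south) offset proportional to tide height couples
#' positions to the semidiurnal tide. On and after `switch_doy` whales
#' drift along `migration_bearing` at `migration_speed`. Argos noise is
#' isotropic Gaussian with a class-specific standard deviation.
#'
#' @param n_whales Number of tagged whales.
#' @param start_date,end_date Deployment window (`Date` or string).
#' @param switch_doy Day of year on which migration begins.
#' @param residency_center `c(lon, lat)` of the residency centre.
#' @param residency_sd Stationary spread of the residency walk, km per axis.
#' @param tau_days Correlation time of the residency walk, days.
#' @param tide_coupling Cross-shore displacement per metre of tide height
#'   (km/m).
#' @param tide_amplitude Tidal amplitude fed to the internal tide signal, m.
#' @param migration_bearing Degrees clockwise from north.
#' @param migration_speed Km per day during migration.
#' @param fixes_per_day Mean Argos fixes per day (Poisson duty cycle).
#' @param argos_class_probs Named probabilities over location classes; must
#'   sum to 1.
#' @param argos_error_sd Named per-class isotropic error SD, km.
#' @param dup_fraction Fraction of fixes duplicated at the same timestamp
#'   with a (usually worse) class, exercising duplicate resolution.
#' @param seed Integer seed; identical seed and config give identical output.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_whales = 13,
                       start_date = "2003-07-05",
                       end_date = "2003-09-15",
                       switch_doy = 221,
                       residency_center = c(lon = -92.30, lat = 57.25),
                       residency_sd = 8,
                       tau_days = 1,
                       tide_coupling = 1,
                       tide_amplitude = 2,
                       migration_bearing = 35,
                       migration_speed = 30,
                       fixes_per_day = 8,
                       argos_class_probs = c(`3` = 0.08, `2` = 0.12, `1` = 0.15,
                                             `0` = 0.20, A = 0.25, B = 0.20),
                       argos_error_sd = c(`3` = 0.25, `2` = 0.5, `1` = 1.5,
                                          `0` = 5, A = 10, B = 20),
                       dup_fraction = 0.05,
                       seed = 1L) {
  start_date <- as.Date(start_date); end_date <- as.Date(end_date)
  if (!(start_date < end_date)) stop_bad_input("start_date must precede end_date")
  if (residency_sd < 0) stop_bad_input("residency_sd must be >= 0")
  if (migration_speed < 0) stop_bad_input("migration_speed must be >= 0")
  if (abs(sum(argos_class_probs) - 1) > 1e-8) {
    stop_bad_input("argos_class_probs must sum to 1")
  }
  if (!all(names(argos_class_probs) %in% names(argos_error_sd))) {
    stop_bad_input("every class in argos_class_probs needs an error SD")
  }
  structure(
    list(
      n_whales = as.integer(n_whales), start_date = start_date,
      end_date = end_date, switch_doy = as.integer(switch_doy),
      residency_center = c(lon = residency_center[[1]], lat = residency_center[[2]]),
      residency_sd = residency_sd, tau_days = tau_days,
      tide_coupling = tide_coupling, tide_amplitude = tide_amplitude,
      migration_bearing = migration_bearing, migration_speed = migration_speed,
      fixes_per_day = fixes_per_day, argos_class_probs = argos_class_probs,
      argos_error_sd = argos_error_sd, dup_fraction = dup_fraction,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

# Deterministic tide signal: semidiurnal carrier with fortnightly
# (spring/neap) amplitude modulation. t_days is time in days from an
# arbitrary origin; returns height in metres (mean sea level 0).
tide_height_fun <- function(t_days, amplitude = 2, spring_neap_period = 14.77,
                            semidiurnal_period_hours = 12.42, mod_depth = 0.45) {
  env <- (1 + mod_depth * cos(2 * pi * t_days / spring_neap_period)) / (1 + mod_depth)
  amplitude * env * cos(2 * pi * t_days / (semidiurnal_period_hours / 24))
}

#' Simulate Argos-style tracks for all tagged whales
#'
#' Runs the two-phase movement model of [sim_config()] for each whale and
#' stacks the results. Each whale uses an independent RNG stream derived
#' from the config seed, so per-whale output does not depend on
#' `n_whales`.
#'
#' @param config A [sim_config()].
#' @return Tibble of fixes: `whale_id`, `timestamp` (POSIXct UTC), `lon`,
#'   `lat`, `location_class`, sorted by time within whale.
#' @export
simulate_tracks <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  dplyr::bind_rows(purrr::map(seq_len(config$n_whales) - 1L,
                              ~ simulate_whale_track(config, .x)))
}

#' Simulate a single whale's track
#'
#' @inheritParams simulate_tracks
#' @param whale_index 0-based whale index, `< n_whales`.
#' @return Tibble of fixes for one whale (see [simulate_tracks()]).
#' @export
simulate_whale_track <- function(config, whale_index) {
  stopifnot(inherits(config, "sim_config"))
  if (whale_index >= config$n_whales) stop_bad_input("whale_index must be < n_whales")
  if (config$fixes_per_day <= 0) stop_bad_input("fixes_per_day must be positive")
  with_seed(config$seed + 7919L * (whale_index + 1L), {
    days <- seq(config$start_date, config$end_date, by = "day")
    n_per_day <- rpois(length(days), config$fixes_per_day)
    day_idx <- rep(seq_along(days), n_per_day)
    frac <- sort_within(runif(sum(n_per_day)), day_idx)
    t_days <- (day_idx - 1) + frac                    # days since start, continuous
    timestamp <- as.POSIXct(days[1], tz = "UTC") + t_days * 86400

    n <- length(t_days)
    if (n == 0) {
      return(tibble(whale_id = character(), timestamp = as.POSIXct(character(), tz = "UTC"),
                    lon = numeric(), lat = numeric(), location_class = character()))
    }

    # residency OU component (km, local frame around residency_center)
    ou <- matrix(0, n, 2)
    if (config$residency_sd > 0) {
      ou[1, ] <- rnorm(2, 0, config$residency_sd)
      if (n > 1) {
        dt <- diff(t_days)
        rho <- exp(-dt / config$tau_days)
        innov_sd <- config$residency_sd * sqrt(1 - rho^2)
        for (i in 2:n) {
          ou[i, ] <- rho[i - 1] * ou[i - 1, ] + rnorm(2, 0, innov_sd[i - 1])
        }
      }
    }

    # migration drift from the start of switch_doy
    switch_date <- as.Date(config$switch_doy - 1,
                           origin = as.Date(sprintf("%d-01-01", lubridate::year(config$start_date))))
    d_since <- pmax(0, t_days - as.numeric(switch_date - config$start_date))
    brg <- config$migration_bearing * pi / 180
    drift <- cbind(sin(brg), cos(brg))[rep(1, n), , drop = FALSE] *
      (config$migration_speed * d_since)

    # cross-shore tide coupling (north-south axis)
    tide <- tide_height_fun(t_days, amplitude = config$tide_amplitude)
    tide_off <- cbind(0, config$tide_coupling * tide)

    cls <- sample(names(config$argos_class_probs), n, replace = TRUE,
                  prob = config$argos_class_probs)
    err_sd <- unname(config$argos_error_sd[cls])
    err <- matrix(rnorm(2 * n, 0, err_sd), n, 2)

    xy <- ou + drift + tide_off + err
    ll <- unproject_local(xy, centre = config$residency_center)
    out <- tibble(
      whale_id = sprintf("PTT%03d", whale_index + 1L),
      timestamp = timestamp, lon = ll$lon, lat = ll$lat,
      location_class = cls
    )

    # duplicate Argos messages: same timestamp, independent error, random class
    if (config$dup_fraction > 0 && n > 0) {
      dup <- which(runif(n) < config$dup_fraction)
      if (length(dup) > 0) {
        cls2 <- sample(names(config$argos_class_probs), length(dup), replace = TRUE,
                       prob = config$argos_class_probs)
        err2 <- matrix(rnorm(2 * length(dup), 0, unname(config$argos_error_sd[cls2])),
                       length(dup), 2)
        ll2 <- unproject_local(xy[dup, , drop = FALSE] - err[dup, , drop = FALSE] + err2,
                               centre = config$residency_center)
        out <- dplyr::bind_rows(out, tibble(
          whale_id = out$whale_id[dup], timestamp = out$timestamp[dup],
          lon = ll2$lon, lat = ll2$lat, location_class = cls2
        ))
      }
    }
    dplyr::arrange(out, .data$timestamp)
  })
}

sort_within <- function(x, group) {
  unlist(lapply(split(x, group), sort), use.names = FALSE)
}

#' Simulate a daily river-discharge series
#'
#' One value per day per year over `season`, with mean equal to the
#' requested year mean and i.i.d. Gaussian noise. With `noise_sd = 0` the
#' series is exactly constant at the year mean, so the seasonal-window mean
#' recovers it exactly.
#'
#' @param year_means Named numeric vector, names are years, values are the
#'   target 14 July - 31 August mean discharge (m^3/s).
#' @param noise_sd Daily noise SD (m^3/s).
#' @param seed Integer seed.
#' @param season Character `c(from, to)` month-day bounds of the generated
#'   series (default mid-June through September).
#' @return Tibble `date`, `year`, `discharge` (m^3/s).
#' @export
simulate_discharge <- function(year_means, noise_sd = 150, seed = 1L,
                               season = c("06-15", "09-30")) {
  if (length(year_means) == 0) stop_bad_input("year_means must be non-empty")
  if (any(year_means <= 0)) stop_bad_input("year_means must be positive")
  yrs <- as.integer(names(year_means))
  if (anyNA(yrs)) stop_bad_input("year_means must be named by year")
  with_seed(seed, {
    dplyr::bind_rows(purrr::map2(yrs, unname(year_means), function(y, m) {
      dates <- seq(as.Date(sprintf("%d-%s", y, season[1])),
                   as.Date(sprintf("%d-%s", y, season[2])), by = "day")
      tibble(date = dates, year = y,
             discharge = pmax(1, m + rnorm(length(dates), 0, noise_sd)))
    }))
  })
}

#' Simulate a tide-height series with spring/neap modulation
#'
#' Semidiurnal oscillation (period 12.42 h) whose amplitude is modulated on
#' the fortnightly spring/neap cycle. High tides (strict local maxima of the
#' sampled series) are flagged spring or neap by whether their height is at
#' or above the median high-tide height.
#'
#' @param amplitude Peak spring amplitude, m (0 gives a flat series with no
#'   highs flagged).
#' @param spring_neap_period Fortnightly modulation period, days.
#' @param days Length of the series, days.
#' @param start Start time (POSIXct UTC or coercible).
#' @param dt_minutes Sampling interval.
#' @param noise_sd Optional Gaussian noise SD, m.
#' @param seed Integer seed (used only if `noise_sd > 0`).
#' @return Tibble of class `tide_series`: `time`, `height`; the flagged
#'   highs are available via [high_tides()].
#' @export
simulate_tides <- function(amplitude = 2, spring_neap_period = 14.77, days = 92,
                           start = as.POSIXct("2003-07-01", tz = "UTC"),
                           dt_minutes = 10, noise_sd = 0, seed = 1L) {
  if (amplitude < 0) stop_bad_input("amplitude must be >= 0")
  t_days <- seq(0, days, by = dt_minutes / 1440)
  h <- tide_height_fun(t_days, amplitude = amplitude,
                       spring_neap_period = spring_neap_period)
  if (noise_sd > 0) h <- h + with_seed(seed, rnorm(length(h), 0, noise_sd))
  series <- tibble(time = as.POSIXct(start, tz = "UTC") + t_days * 86400, height = h)
  n <- nrow(series)
  is_max <- c(FALSE, h[2:(n - 1)] > h[1:(n - 2)] & h[2:(n - 1)] > h[3:n], FALSE)
  highs <- series[is_max, ]
  if (nrow(highs) > 0) {
    highs$phase <- ifelse(highs$height >= stats::median(highs$height), "spring", "neap")
  } else {
    highs$phase <- character(0)
  }
  attr(series, "highs") <- highs
  class(series) <- c("tide_series", class(series))
  series
}

#' High tides flagged on a simulated tide series
#'
#' @param tides Output of [simulate_tides()].
#' @return Tibble `time`, `height`, `phase` ("spring"/"neap").
#' @export
high_tides <- function(tides) attr(tides, "highs")

#' Funnel-shaped synthetic shoreline fixture
#'
#' A V-shaped polyline opening seaward (northward) with the river mouth at
#' its apex, emulating a funnel-shaped estuary whose offshore extent is
#' `scale_km`.
#'
#' @param scale_km Offshore (northward) extent of the funnel arms, km.
#' @param river_mouth `c(lon, lat)` apex; default [port_nelson()].
#' @param half_angle_deg Half-opening angle of the funnel from north.
#' @param vertex_spacing_km Approximate spacing of generated vertices.
#' @return A list of class `shoreline`: `vertices` tibble (`lon`, `lat`)
#'   and `river_mouth`.
#' @export
make_shoreline <- function(scale_km = 60, river_mouth = port_nelson(),
                           half_angle_deg = 35, vertex_spacing_km = 2) {
  if (scale_km <= 0) stop_bad_input("scale_km must be positive")
  arm_len <- scale_km / cos(half_angle_deg * pi / 180)
  s <- seq(vertex_spacing_km, arm_len, by = vertex_spacing_km)
  if (length(s) == 0 || max(s) < arm_len) s <- c(s, arm_len)
  ang_w <- (-half_angle_deg) * pi / 180
  ang_e <- half_angle_deg * pi / 180
  west <- cbind(sin(ang_w), cos(ang_w))[rep(1, length(s)), ] * s
  east <- cbind(sin(ang_e), cos(ang_e))[rep(1, length(s)), ] * s
  xy <- rbind(west[rev(seq_along(s)), , drop = FALSE], c(0, 0), east)
  ll <- unproject_local(xy, centre = river_mouth)
  structure(
    list(vertices = ll,
         river_mouth = c(lon = river_mouth[[1]], lat = river_mouth[[2]])),
    class = "shoreline"
  )
}

#' Deterministic strip counts for known whale positions
#'
#' Core of the survey simulator: given whale positions in the local survey
#' frame (km), counts each whale once in the 1-km interval of the single
#' transect whose strip contains it; whales outside every strip are not
#' recorded.
#'
#' @param positions Matrix/tibble of whale `x`, `y` (km, survey frame:
#'   transects run in y, shore at y = 0).
#' @param design A [survey_design()].
#' @return Tibble `transect`, `interval`, `side` ("L"/"R"), `count`; only
#'   non-zero cells.
#' @export
strip_counts <- function(positions, design) {
  if (is.data.frame(positions)) positions <- cbind(positions$x, positions$y)
  if (design$strip_halfwidth_km == 0) {
    warning("zero strip width: all counts zero")
    return(tibble(transect = integer(), interval = integer(),
                  side = character(), count = integer()))
  }
  x <- positions[, 1]; y <- positions[, 2]
  tx <- design$transect_x
  nearest <- vapply(x, function(xi) which.min(abs(xi - tx)), integer(1))
  offset <- x - tx[nearest]
  inside <- abs(offset) <= design$strip_halfwidth_km &
    y >= 0 & y <= design$transect_length_km
  tibble(
    transect = nearest[inside],
    interval = pmin(floor(y[inside] / design$interval_km) + 1L,
                    design$n_intervals),
    side = ifelse(offset[inside] < 0, "L", "R")
  ) %>%
    dplyr::count(.data$transect, .data$interval, .data$side, name = "count") %>%
    dplyr::mutate(interval = as.integer(.data$interval))
}

#' Simulate one aerial strip-transect survey
#'
#' Draws whale positions from a density surface over the survey frame by
#' rejection sampling, then records them with [strip_counts()]: a whale is
#' counted once, in the 15-second (1-km) interval of the strip that
#' contains it, on the side it falls.
#'
#' @param design A [survey_design()].
#' @param n_whales Number of whales present in the survey frame.
#' @param density Optional function `(x, y) -> relative density` over the
#'   frame; `NULL` means uniform.
#' @param seed Integer seed.
#' @return Tibble of sighting records (`transect`, `interval`, `side`,
#'   `count`) with the simulated positions attached as attribute
#'   `"positions"`.
#' @export
simulate_survey <- function(design, n_whales, density = NULL, seed = 1L) {
  stopifnot(inherits(design, "survey_design"))
  xr <- range(design$transect_x) + c(-1, 1) * design$spacing_km / 2
  with_seed(seed, {
    pos <- matrix(NA_real_, 0, 2)
    if (is.null(density)) {
      pos <- cbind(runif(n_whales, xr[1], xr[2]),
                   runif(n_whales, 0, design$transect_length_km))
    } else {
      # rejection sampling against the max over a coarse evaluation grid
      gx <- seq(xr[1], xr[2], length.out = 80)
      gy <- seq(0, design$transect_length_km, length.out = 80)
      fmax <- max(outer(gx, gy, density)) * 1.05
      while (nrow(pos) < n_whales) {
        m <- 4 * (n_whales - nrow(pos)) + 16
        cx <- runif(m, xr[1], xr[2]); cy <- runif(m, 0, design$transect_length_km)
        keep <- runif(m) * fmax < density(cx, cy)
        pos <- rbind(pos, cbind(cx[keep], cy[keep]))
      }
      pos <- pos[seq_len(n_whales), , drop = FALSE]
    }
    rec <- strip_counts(pos, design)
    attr(rec, "positions") <- pos
    rec
  })
}
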