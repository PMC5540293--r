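# Build a small fix table by hand for QC tests.
make_fixes <- function(whale = "W1", t_hours, lon, lat, cls = "3",
                       t0 = as.POSIXct("2003-08-01 00:00:00", tz = "UTC")) {
  tibble::tibble(
    whale_id = whale,
    timestamp = t0 + t_hours * 3600,
    lon = lon, lat = lat,
    location_class = rep_len(cls, length(t_hours))
  )
}

# Independent brute-force forward speed filter: re-derivation used as the
# oracle for filter_speed.
oracle_speed_filter <- function(fixes, vmax) {
  keep <- 1L
  for (i in seq_len(nrow(fixes))[-1]) {
    a <- keep[length(keep)]
    dt_h <- as.numeric(difftime(fixes$timestamp[i], fixes$timestamp[a], units = "hours"))
    d_km <- geosphere::distGeo(c(fixes$lon[a], fixes$lat[a]),
                               c(fixes$lon[i], fixes$lat[i])) / 1000
    ok <- if (dt_h <= 0) d_km == 0 else d_km / dt_h < vmax
    if (ok) keep <- c(keep, i)
  }
  fixes[keep, ]
}

# Naive double-loop bivariate normal KDE, the oracle for kde_ud.
oracle_kde <- function(xy, h, gx, gy) {
  z <- matrix(0, length(gx), length(gy))
  for (i in seq_along(gx)) for (j in seq_along(gy)) {
    z[i, j] <- mean(exp(-((gx[i] - xy[, 1])^2 + (gy[j] - xy[, 2])^2) / (2 * h^2))) /
      (2 * pi * h^2)
  }
  z
}

# Double-loop LSCV criterion, the oracle for lscv_bandwidth's closed form.
oracle_lscv <- function(xy, h) {
  n <- nrow(xy)
  int_f2 <- 0
  loo <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    d2 <- sum((xy[i, ] - xy[j, ])^2)
    int_f2 <- int_f2 + exp(-d2 / (4 * h^2)) / (4 * pi * h^2) / n^2
    if (i != j) loo <- loo + exp(-d2 / (2 * h^2)) / (2 * pi * h^2)
  }
  int_f2 - 2 * loo / (n * (n - 1))
}
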