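#' Seasonal (14 July - 31 August) mean discharge per year
#'
#' Arithmetic mean of daily discharge within the seasonal window, inclusive
#' of both endpoints (a 49-day window). Gaps up to 10% of the window are
#' tolerated with a warning; larger gaps are an error.
#'
#' @param discharge Tibble with `date` and `discharge` (m^3/s) columns.
#' @param years Years to summarise; default every year present.
#' @param window Character `c(from, to)` month-day bounds.
#' @return Tibble `year`, `seasonal_mean`, `n_days`.
#' @export
seasonal_means <- function(discharge, years = NULL,
                           window = c("07-14", "08-31")) {
  stopifnot(all(c("date", "discharge") %in% names(discharge)))
  if (any(discharge$discharge <= 0, na.rm = TRUE)) {
    stop_bad_input("discharge values must be positive")
  }
  discharge <- dplyr::mutate(discharge, year = lubridate::year(.data$date))
  years <- years %||% sort(unique(discharge$year))
  purrr::map_dfr(years, function(y) {
    lo <- as.Date(sprintf("%d-%s", y, window[1]))
    hi <- as.Date(sprintf("%d-%s", y, window[2]))
    expected <- as.integer(hi - lo) + 1L
    d <- dplyr::filter(discharge, .data$date >= lo, .data$date <= hi,
                       !is.na(.data$discharge))
    if (nrow(d) < 0.9 * expected) {
      stop_bad_input(sprintf(">10%% of the %d-day window missing for %d (%d days present)",
                             expected, y, nrow(d)))
    }
    if (nrow(d) < expected) {
      warning(sprintf("year %d: %d of %d window days missing", y,
                      expected - nrow(d), expected))
    }
    tibble(year = y, seasonal_mean = mean(d$discharge), n_days = nrow(d))
  })
}

#' Percent deviation of a yearly mean from the baseline
#'
#' `100 * (year_mean - baseline_mean) / baseline_mean`. Returned unrounded;
#' [classify_wet_dry()] reports the integer-rounded value alongside.
#'
#' @param year_mean,baseline_mean Discharge means, m^3/s; `baseline_mean`
#'   must be positive. Vectorised over `year_mean`.
#' @return Percent deviation (numeric).
#' @export
#' @examples
#' round(percent_deviation(5176, 3331))  # +55
#' round(percent_deviation(2167, 3331))  # -35
percent_deviation <- function(year_mean, baseline_mean) {
  if (any(baseline_mean <= 0)) stop_bad_input("baseline_mean must be positive")
  100 * (year_mean - baseline_mean) / baseline_mean
}

#' Classify study years as wet or dry
#'
#' A year is "wet" when its seasonal mean discharge exceeds the baseline
#' (percent deviation > 0, by default) and "dry" otherwise -- at-or-below
#' average years, including exactly average ones, are dry. The baseline is
#' the mean of the yearly seasonal means over the reference period (not the
#' grand mean of days), matching a by-year averaging convention.
#'
#' @param seasonal Tibble from [seasonal_means()] covering the reference
#'   period (baseline computed from all its rows), or a named vector of
#'   yearly means.
#' @param study_years Years to classify; default all.
#' @param baseline_mean Optional override of the baseline (m^3/s).
#' @param wet_threshold Deviation (percent) strictly above which a year is
#'   wet; default 0.
#' @return Tibble `year`, `seasonal_mean`, `baseline_mean`,
#'   `deviation_pct` (unrounded), `deviation_pct_int`, `label`.
#' @export
classify_wet_dry <- function(seasonal, study_years = NULL,
                             baseline_mean = NULL, wet_threshold = 0) {
  UseMethod("classify_wet_dry")
}

#' Label percent deviations as wet or dry
#'
#' Convenience wrapper of the wet/dry rule for already-computed percent
#' deviations: wet iff deviation > `wet_threshold` (default 0).
#'
#' @param deviation_pct Numeric percent deviations (may be named by year).
#' @param wet_threshold Strict wet threshold, percent.
#' @return Character vector of `"wet"`/`"dry"` labels.
#' @export
#' @examples
#' classify_deviations(c(-6, -35, -15, 55))  # dry dry dry wet
classify_deviations <- function(deviation_pct, wet_threshold = 0) {
  out <- ifelse(deviation_pct > wet_threshold, "wet", "dry")
  names(out) <- names(deviation_pct)
  out
}

#' @export
classify_wet_dry.default <- function(seasonal, study_years = NULL,
                                     baseline_mean = NULL, wet_threshold = 0) {
  classify_wet_dry.data.frame(
    tibble(year = as.integer(names(seasonal)), seasonal_mean = unname(seasonal)),
    study_years = study_years, baseline_mean = baseline_mean,
    wet_threshold = wet_threshold
  )
}

#' @export
classify_wet_dry.data.frame <- function(seasonal, study_years = NULL,
                                        baseline_mean = NULL, wet_threshold = 0) {
  baseline_mean <- baseline_mean %||% mean(seasonal$seasonal_mean)
  study_years <- study_years %||% seasonal$year
  seasonal %>%
    dplyr::filter(.data$year %in% study_years) %>%
    dplyr::mutate(
      baseline_mean = baseline_mean,
      deviation_pct = percent_deviation(.data$seasonal_mean, baseline_mean),
      deviation_pct_int = round(.data$deviation_pct),
      label = ifelse(.data$deviation_pct > wet_threshold, "wet", "dry")
    )
}
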