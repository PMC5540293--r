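#' Strip-transect aerial survey design
#'
#' Parallel transects perpendicular to the shore (running offshore in +y of
#' the local survey frame; shore at y = 0), each observed as a strip of
#' `strip_halfwidth_km` on both sides and divided into `interval_km`-long
#' counting intervals (the 15-second observation bins at survey speed).
#'
#' @param n_transects Number of transects (default 10).
#' @param spacing_km Distance between adjacent transects (default 3.7).
#' @param strip_halfwidth_km Observed half-width per side (default 0.35).
#' @param transect_length_km Offshore extent of each transect (default 40).
#' @param interval_km Counting-interval length (default 1).
#' @param altitude_m Survey altitude, metadata only (default 305).
#' @param origin `c(lon, lat)` mapped to the frame origin (mouth); default
#'   [port_nelson()].
#' @return List of class `survey_design`; `transect_x` holds transect
#'   x-positions centred on 0, `n_intervals` the intervals per transect.
#' @export
survey_design <- function(n_transects = 10, spacing_km = 3.7,
                          strip_halfwidth_km = 0.35, transect_length_km = 40,
                          interval_km = 1, altitude_m = 305,
                          origin = port_nelson()) {
  if (spacing_km <= 0) stop_bad_input("spacing_km must be positive")
  if (strip_halfwidth_km < 0) stop_bad_input("strip_halfwidth_km must be >= 0")
  structure(
    list(n_transects = as.integer(n_transects), spacing_km = spacing_km,
         strip_halfwidth_km = strip_halfwidth_km,
         transect_length_km = transect_length_km, interval_km = interval_km,
         altitude_m = altitude_m, origin = origin,
         transect_x = (seq_len(n_transects) - (n_transects + 1) / 2) * spacing_km,
         n_intervals = as.integer(ceiling(transect_length_km / interval_km))),
    class = "survey_design"
  )
}

#' Direct sampling coverage of a strip-transect design
#'
#' `(2 * strip half-width) / transect spacing`, capped at 1. With 350 m
#' half-strips 3.7 km apart this is 0.7/3.7, about 19%.
#'
#' @param design A [survey_design()].
#' @return Proportion in `[0, 1]`.
#' @export
#' @examples
#' coverage_fraction(survey_design())  # ~0.189
coverage_fraction <- function(design) {
  min(1, 2 * design$strip_halfwidth_km / design$spacing_km)
}

#' Bin sighting records into survey blocks
#'
#' Each 1-km interval of each transect becomes one sampling block of
#' `interval_km x 2 * strip_halfwidth_km` (1.0 x 0.7 km, i.e. 0.7 km^2, by
#' default), with both aircraft sides pooled. Counts are summed per block;
#' density is count per block area. Distances are computed in the survey
#' frame: `dist_shore` is the block centre's offshore coordinate (shore at
#' y = 0) and `dist_mouth` its distance from the frame origin.
#'
#' @param records Sighting records (`transect`, `interval`, `side`,
#'   `count`) as from [simulate_survey()].
#' @param design The [survey_design()].
#' @param complete Include zero-count blocks for all design intervals
#'   (default TRUE).
#' @return Tibble of blocks: `block_id`, `transect`, `interval`, `x`, `y`,
#'   `count`, `area_km2`, `density`, `dist_shore`, `dist_mouth`.
#' @export
bin_to_blocks <- function(records, design, complete = TRUE) {
  stopifnot(inherits(design, "survey_design"))
  bad <- records$transect < 1 | records$transect > design$n_transects |
    records$interval < 1 | records$interval > design$n_intervals
  if (any(bad)) {
    stop_bad_input("records reference transects/intervals outside the design: rows ",
                   paste(utils::head(which(bad), 5), collapse = ", "))
  }
  counts <- records %>%
    dplyr::group_by(.data$transect, .data$interval) %>%
    dplyr::summarise(count = sum(.data$count), .groups = "drop")
  if (complete) {
    grid <- tidyr::expand_grid(transect = seq_len(design$n_transects),
                               interval = seq_len(design$n_intervals))
    counts <- dplyr::left_join(grid, counts, by = c("transect", "interval")) %>%
      dplyr::mutate(count = dplyr::coalesce(.data$count, 0L))
  }
  area <- design$interval_km * 2 * design$strip_halfwidth_km
  counts %>%
    dplyr::mutate(
      block_id = sprintf("T%02d-I%03d", .data$transect, .data$interval),
      x = design$transect_x[.data$transect],
      y = (.data$interval - 0.5) * design$interval_km,
      area_km2 = area,
      density = .data$count / area,
      dist_shore = .data$y,
      dist_mouth = sqrt(.data$x^2 + .data$y^2)
    ) %>%
    dplyr::select("block_id", "transect", "interval", "x", "y", "count",
                  "area_km2", "density", "dist_shore", "dist_mouth")
}

#' Density-weighted mean distance across survey blocks
#'
#' Mean of a block distance covariate weighted by block counts,
#' `sum(c_i d_i) / sum(c_i)`, with a standard error from the count-weighted
#' variance: `SE = sqrt( sum(c_i (d_i - m)^2) / (C - 1) / C )` where C is
#' the total count.
#'
#' @param blocks Block table from [bin_to_blocks()].
#' @param which `"shore"` or `"mouth"`.
#' @return Tibble `which`, `weighted_mean` (km), `se`, `total_count`.
#' @export
density_weighted_distance <- function(blocks, which = c("shore", "mouth")) {
  which <- match.arg(which)
  d <- blocks[[paste0("dist_", which)]]
  c_i <- blocks$count
  C <- sum(c_i)
  if (C <= 0) stop_bad_input("all block counts are zero")
  m <- sum(c_i * d) / C
  se <- if (C > 1) sqrt(sum(c_i * (d - m)^2) / (C - 1) / C) else 0
  tibble(which = which, weighted_mean = m, se = se, total_count = C)
}

#' Uncorrected abundance index from strip counts
#'
#' Total count divided by the design's coverage fraction. This is an
#' *index*: no correction for perception or availability bias is applied.
#'
#' @param blocks Block table (or anything with a `count` column).
#' @param coverage Coverage proportion in (0, 1].
#' @return Index of whales present in the surveyed area.
#' @export
abundance_index <- function(blocks, coverage) {
  if (coverage <= 0 || coverage > 1) stop_bad_input("coverage must be in (0, 1]")
  sum(blocks$count) / coverage
}

#' Rank quasi-Poisson density models over covariate subsets
#'
#' Fits log-link Poisson-family GLMs of block counts on each covariate
#' subset, with `log(area)` as offset, and ranks them by QAICc: the
#' quasi-likelihood criterion using the overdispersion estimate c-hat from
#' the richest model, `QAICc = -2 logLik / c-hat + 2k + 2k(k+1)/(n-k-1)`
#' (k includes the dispersion parameter). Overdispersed counts are the norm
#' for aggregated whales, hence the quasi-likelihood treatment.
#'
#' @param blocks Block table ([bin_to_blocks()]), plus any covariate
#'   columns such as `year` or `survey`.
#' @param covariate_sets List of character vectors of covariate names; the
#'   default compares the intercept-only model with every single covariate
#'   and the full set of supplied `covariates`.
#' @param covariates Covariates used to build the default sets.
#' @return Tibble of class `model_ranking` with `model`, `k`, `loglik`
#'   (quasi-corrected), `aicc` (QAICc), `delta`, `weight`, plus `c_hat` as
#'   an attribute.
#' @export
density_model <- function(blocks,
                          covariates = intersect(c("year", "survey", "dist_shore", "dist_mouth"),
                                                 names(blocks)),
                          covariate_sets = NULL) {
  if (is.null(covariate_sets)) {
    covariate_sets <- c(list(character(0)), as.list(covariates))
    if (length(covariates) > 1) covariate_sets <- c(covariate_sets, list(covariates))
  }
  df <- as.data.frame(blocks)
  df$.off <- log(df$area_km2)
  fits <- purrr::map(covariate_sets, function(cv) {
    form <- if (length(cv) == 0) count ~ 1 + offset(.off) else {
      stats::as.formula(paste("count ~", paste(cv, collapse = " + "), "+ offset(.off)"))
    }
    glm(form, data = df, family = poisson())
  })
  rich <- fits[[which.max(vapply(fits, function(f) length(coef(f)), numeric(1)))]]
  c_hat <- max(1, sum(resid(rich, type = "pearson")^2) / rich$df.residual)
  scores <- purrr::map2_dfr(fits, covariate_sets, function(f, cv) {
    tibble(model = paste(c("(Int)", cv), collapse = " + "),
           k = length(coef(f)) + 1,           # + dispersion
           loglik = as.numeric(logLik(f)) / c_hat)
  })
  out <- rank_models(scores, n = nrow(df))
  attr(out, "c_hat") <- c_hat
  attr(out, "fits") <- fits
  out
}
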