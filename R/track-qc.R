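ARGOS_CLASSES <- c("3", "2", "1", "0", "A", "B", "Z")
GUARANTEED_CLASSES <- c("3", "2", "1")

# Quality order: 3 best, then 2, 1, 0, A, B, Z.
argos_class_rank <- function(cls) {
  match(as.character(cls), ARGOS_CLASSES)
}

#' Resolve duplicate Argos messages, keeping the best location
#'
#' Argos often delivers several location solutions for one transmission.
#' Within each duplicate group (an explicit `duplicate_group` column if
#' present, otherwise identical `whale_id` + `timestamp`), the fix with the
#' highest location class is kept; ties go to the earliest-received record
#' (first row in input order). Output is time-sorted within whale.
#'
#' @param fixes Tibble with `whale_id`, `timestamp`, `lon`, `lat`,
#'   `location_class`, optionally `duplicate_group`.
#' @return Tibble with one fix per duplicate group.
#' @export
dedupe_best <- function(fixes) {
  if (nrow(fixes) == 0) return(fixes)
  key <- if ("duplicate_group" %in% names(fixes) && !all(is.na(fixes$duplicate_group))) {
    paste(fixes$whale_id, fixes$duplicate_group)
  } else {
    paste(fixes$whale_id, format(fixes$timestamp, "%Y-%m-%d %H:%M:%S"))
  }
  fixes %>%
    dplyr::mutate(.grp = key, .ord = dplyr::row_number(),
                  .rank = argos_class_rank(.data$location_class)) %>%
    dplyr::arrange(.data$.grp, .data$.rank, .data$.ord) %>%
    dplyr::distinct(.data$.grp, .keep_all = TRUE) %>%
    dplyr::arrange(.data$whale_id, .data$timestamp, .data$.ord) %>%
    dplyr::select(-".grp", -".ord", -".rank")
}

#' Filter fixes by Argos location class
#'
#' Keeps only fixes whose location class is in `allowed_classes`; the
#' default retains the "guaranteed" precision classes 3, 2 and 1
#' (nominal accuracy between 250 m and 1.5 km). Class Z and missing
#' classes always fail the screen.
#'
#' @param fixes Tibble with a `location_class` column.
#' @param allowed_classes Character vector of classes to retain.
#' @return Filtered tibble, order preserved.
#' @export
filter_quality <- function(fixes, allowed_classes = GUARANTEED_CLASSES) {
  cls <- as.character(fixes$location_class)
  bad <- !is.na(cls) & !(cls %in% ARGOS_CLASSES)
  if (any(bad)) {
    stop_bad_input("unknown Argos location class ", paste(unique(cls[bad]), collapse = ", "),
                   " at row(s) ", paste(utils::head(which(bad), 5), collapse = ", "))
  }
  fixes[!is.na(cls) & cls %in% allowed_classes, , drop = FALSE]
}

#' Travel-rate (speed) filter
#'
#' Forward single-pass screen per whale: starting from the first fix
#' (always retained), a fix is dropped when the great-circle speed from the
#' last *retained* fix is at or above `vmax`; otherwise it becomes the new
#' anchor. A later fix sharing its predecessor's timestamp at a different
#' position (infinite implied speed) is dropped. All retained
#' fix-to-fix speeds are below `vmax`.
#'
#' @param fixes Tibble of fixes, time-sorted within whale.
#' @param vmax Maximum plausible travel rate, km/h (default 3.5).
#' @return Filtered tibble.
#' @export
filter_speed <- function(fixes, vmax = 3.5) {
  if (nrow(fixes) == 0) return(fixes)
  keep <- unlist(lapply(split(seq_len(nrow(fixes)), fixes$whale_id), function(idx) {
    ts <- as.numeric(fixes$timestamp[idx])
    if (is.unsorted(ts)) stop_bad_input("fixes must be time-sorted within whale")
    pts <- cbind(fixes$lon[idx], fixes$lat[idx])
    retained <- logical(length(idx))
    retained[1] <- TRUE
    last <- 1L
    for (i in seq_along(idx)[-1]) {
      dt_h <- (ts[i] - ts[last]) / 3600
      d_km <- geodesic_km(pts[last, ], pts[i, ])
      if (dt_h <= 0) {
        if (d_km > 0) next   # same time, different place: drop
        speed <- 0
      } else {
        speed <- d_km / dt_h
      }
      if (speed < vmax) {
        retained[i] <- TRUE
        last <- i
      }
    }
    idx[retained]
  }), use.names = FALSE)
  fixes[sort(keep), , drop = FALSE]
}

#' Quality-control retention report
#'
#' Record counts through the dedupe / class / speed stages and the overall
#' retention fraction. Errors if counts are not non-increasing through the
#' chain (the stages must have been run on the same input).
#'
#' @param n_input,n_after_dedupe,n_after_quality,n_after_speed Stage counts,
#'   or pass the stage tibbles themselves.
#' @return A one-row tibble of class `qc_report` with the counts and
#'   `retention_fraction`.
#' @export
qc_report <- function(n_input, n_after_dedupe, n_after_quality, n_after_speed) {
  cnt <- vapply(list(n_input, n_after_dedupe, n_after_quality, n_after_speed),
                function(x) if (is.data.frame(x)) nrow(x) else as.integer(x), integer(1))
  if (is.unsorted(rev(cnt))) {
    stop_bad_input("stage counts must be non-increasing: ", paste(cnt, collapse = " -> "))
  }
  out <- tibble(
    n_input = cnt[1], n_after_dedupe = cnt[2], n_after_quality = cnt[3],
    n_after_speed = cnt[4],
    retention_fraction = if (cnt[1] > 0) cnt[4] / cnt[1] else NA_real_
  )
  class(out) <- c("qc_report", class(out))
  out
}

#' Run the full Argos quality-control chain
#'
#' [dedupe_best()], then [filter_quality()], then [filter_speed()].
#'
#' @inheritParams dedupe_best
#' @inheritParams filter_quality
#' @inheritParams filter_speed
#' @return List with `fixes` (the analysis-grade set) and `report`
#'   (a [qc_report()]).
#' @export
qc_tracks <- function(fixes, allowed_classes = GUARANTEED_CLASSES, vmax = 3.5) {
  deduped <- dedupe_best(fixes)
  quality <- filter_quality(deduped, allowed_classes)
  final <- filter_speed(quality, vmax)
  list(fixes = final,
       report = qc_report(fixes, deduped, quality, final))
}
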