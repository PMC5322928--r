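# Ground-truth derivations and the seasonal detection criterion.
#
# Two kinds of independent field data validate the social-media signal:
# repeated surveys measuring the volume of aestivating moth patches
# (width x height x depth per patch, summed per survey and expressed as a
# percentage of the season total) and long-run monthly bird-count data
# summed into a 12-month sighting profile.

#' Percent of total patch volume per survey
#'
#' Each survey contributes the summed volume of all measured patches
#' (width x height x depth, cm^3). Percentages normalise over all surveys of
#' the season, so the series sums to 100. Rows with all three dimensions
#' equal to zero mark a survey where no patches were found.
#'
#' @param surveys data frame with columns `survey_date`, `site_id`,
#'   `width_cm`, `height_cm`, `depth_cm` (one row per patch).
#' @return a data frame of class `ground_truth_series` with columns
#'   `survey_date`, `total_volume_cm3`, `percent_volume`, ordered by date.
#' @examples
#' percent_volume(data.frame(survey_date = c("2014-10-01", "2014-11-01"),
#'   site_id = "s1", width_cm = c(10, 10), height_cm = c(5, 5),
#'   depth_cm = c(2, 6)))
#' @export
percent_volume <- function(surveys) {
  need <- c("survey_date", "site_id", "width_cm", "height_cm", "depth_cm")
  missing_cols <- setdiff(need, names(surveys))
  if (length(missing_cols)) {
    stop("survey table missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (!nrow(surveys)) stop("need at least one survey", call. = FALSE)
  dims <- surveys[c("width_cm", "height_cm", "depth_cm")]
  if (any(is.na(as.matrix(dims))) || any(as.matrix(dims) < 0)) {
    stop("patch dimensions must be non-negative numbers", call. = FALSE)
  }
  vol <- surveys$width_cm * surveys$height_cm * surveys$depth_cm
  date <- as.Date(surveys$survey_date)
  if (any(is.na(date))) stop("unparseable survey dates", call. = FALSE)
  total <- tapply(vol, as.character(date), sum)
  total <- total[order(as.Date(names(total)))]
  if (sum(total) == 0) {
    stop("all patch volumes are zero: no season signal to normalise", call. = FALSE)
  }
  out <- data.frame(survey_date = as.Date(names(total)),
                    total_volume_cm3 = as.numeric(total),
                    percent_volume = 100 * as.numeric(total) / sum(total))
  rownames(out) <- NULL
  class(out) <- c("ground_truth_series", "data.frame")
  out
}

#' Monthly sighting profile from historical counts
#'
#' Sums counts per calendar month over all years on record and expresses
#' each month as a percentage of the total, giving the 12-month migration
#' profile used as ground truth where year-by-year data are incomplete.
#'
#' @param records data frame with columns `month` (1-12) and `count`
#'   (non-negative; the same month may appear once per year).
#' @return a data frame of class `monthly_profile` with columns `month`
#'   (1-12) and `percent` (sums to 100).
#' @export
monthly_profile <- function(records) {
  if (!all(c("month", "count") %in% names(records))) {
    stop("need columns month and count", call. = FALSE)
  }
  m <- as.integer(records$month)
  if (any(is.na(m) | m < 1L | m > 12L)) stop("month must be 1..12", call. = FALSE)
  if (any(is.na(records$count) | records$count < 0)) {
    stop("counts must be non-negative", call. = FALSE)
  }
  sums <- vapply(1:12, function(k) sum(records$count[m == k]), numeric(1))
  if (sum(sums) == 0) stop("all counts are zero", call. = FALSE)
  out <- data.frame(month = 1:12, percent = 100 * sums / sum(sums))
  class(out) <- c("monthly_profile", "data.frame")
  out
}

#' Spring windows intersecting a coverage period
#'
#' One Southern-Hemisphere Spring window (1 September - 30 November,
#' inclusive) per year in which the window intersects the period. Seasons
#' are labelled by their Spring year.
#'
#' @param period a [coverage_period()].
#' @return data frame with columns `year`, `start`, `end`.
#' @export
spring_windows <- function(period) {
  stopifnot(inherits(period, "coverage_period"))
  years <- seq(as.integer(format(period$start, "%Y")) - 1L,
               as.integer(format(period$end, "%Y")))
  out <- do.call(rbind, lapply(years, function(y) {
    data.frame(year = y,
               start = as.Date(sprintf("%d-09-01", y)),
               end = as.Date(sprintf("%d-11-30", y)))
  }))
  # keep windows overlapping [start, end); window itself is inclusive
  keep <- out$end >= period$start & out$start < period$end
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Score detections against seasonal truth
#'
#' A season counts as detected when at least one upper (UDB) violation falls
#' in a week overlapping its Spring window; the detection delay is measured
#' from the true arrival date to the start of the first such week (so it can
#' be slightly negative when the violation week begins before the arrival
#' date). Upper violations overlapping no window are out-of-season alarms,
#' the signature of confounder bursts unrelated to the migration.
#'
#' @param events data frame with `week_start`, `direction`
#'   (from [detect_events()] / [detect_arrivals()]).
#' @param windows Spring windows from [spring_windows()].
#' @param arrival_dates optional true arrival dates, matched to windows by
#'   order (known for synthetic streams; for real streams a media-reported
#'   first sighting can anchor a season).
#' @return an object of class `detection_metrics`: data frame `seasons`
#'   (`year`, `detected`, `first_detection_week`, `delay_days`) plus
#'   `out_of_season_alarms` (count of upper violations outside all windows).
#' @export
evaluate_detections <- function(events, windows, arrival_dates = NULL) {
  stopifnot(all(c("year", "start", "end") %in% names(windows)))
  if (!is.null(arrival_dates)) {
    arrival_dates <- as.Date(arrival_dates)
    stopifnot(length(arrival_dates) == nrow(windows))
  }
  up <- events[events$direction == "upper", , drop = FALSE]
  wk_start <- as.Date(up$week_start)
  wk_end <- wk_start + 6L   # inclusive week end
  in_window <- function(w) wk_end >= windows$start[w] & wk_start <= windows$end[w]
  seasons <- do.call(rbind, lapply(seq_len(nrow(windows)), function(w) {
    hitw <- in_window(w)
    detected <- any(hitw)
    first_wk <- if (detected) min(wk_start[hitw]) else as.Date(NA)
    delay <- if (detected && !is.null(arrival_dates)) {
      as.integer(first_wk - arrival_dates[w])
    } else NA_integer_
    data.frame(year = windows$year[w], detected = detected,
               first_detection_week = first_wk, delay_days = delay)
  }))
  if (is.null(seasons)) {
    seasons <- data.frame(year = integer(), detected = logical(),
                          first_detection_week = as.Date(character()),
                          delay_days = integer())
  }
  any_window <- if (nrow(up)) {
    Reduce(`|`, lapply(seq_len(nrow(windows)), in_window),
           accumulate = FALSE) %||% rep(FALSE, nrow(up))
  } else logical(0)
  if (!nrow(windows)) any_window <- rep(FALSE, nrow(up))
  structure(list(seasons = seasons,
                 out_of_season_alarms = sum(!any_window)),
            class = "detection_metrics")
}

#' @export
print.detection_metrics <- function(x, ...) {
  cat("Season detection:\n")
  print(x$seasons, row.names = FALSE)
  cat(sprintf("Out-of-season upper alarms: %d\n", x$out_of_season_alarms))
  invisible(x)
}
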