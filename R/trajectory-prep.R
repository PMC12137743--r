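#' Aggregate raw vital-sign observations into an hourly panel
#'
#' Bins each observation into the half-open hour `[h, h + 1)` with
#' `h = floor(time_from_admission)` and averages multiple measurements of
#' the same channel within an hour. Observations at or beyond 12 hours are
#' windowed out. The returned panel is unstandardised; its observed-hour
#' mask marks hours with at least one channel present (the complete-hour
#' rule is applied separately by [filter_complete_hours()]).
#'
#' @param records Data frame with columns `patient_id`,
#'   `time_from_admission` (hours, non-negative), `channel` (one of
#'   `"SBP"`, `"DBP"`, `"HR"`, `"RR"`, `"TEMP"`) and `value`.
#' @return A `trajectory_panel` on the natural measurement scale.
#' @export
hourly_aggregate <- function(records) {
  records <- tibble::as_tibble(records)
  req <- c("patient_id", "time_from_admission", "channel", "value")
  if (!all(req %in% names(records))) {
    abort(paste("records must have columns:", paste(req, collapse = ", ")))
  }
  bad <- setdiff(unique(records$channel), VITAL_CHANNELS)
  if (length(bad)) {
    abort(paste0("unknown channel(s): ", paste(bad, collapse = ", ")))
  }
  if (any(records$time_from_admission < 0, na.rm = TRUE)) {
    abort("time_from_admission must be non-negative")
  }
  records <- dplyr::filter(records, .data$time_from_admission < 12)

  agg <- records |>
    dplyr::mutate(hour = floor(.data$time_from_admission)) |>
    dplyr::summarise(value = mean(.data$value),
                     .by = c("patient_id", "hour", "channel"))

  ids <- sort(unique(as.character(agg$patient_id)))
  values <- array(NA_real_, dim = c(length(ids), 12, 5))
  i <- match(as.character(agg$patient_id), ids)
  h <- as.integer(agg$hour) + 1L
  ch <- match(agg$channel, VITAL_CHANNELS)
  values[cbind(i, h, ch)] <- agg$value
  mask <- apply(values, c(1, 2), function(v) any(is.finite(v)))
  new_trajectory_panel(values, mask, ids)
}

#' Keep only hours with all five vital signs present
#'
#' Any hour in which one or more of the five channels is missing is
#' dropped entirely: the observed-hour mask becomes `TRUE` only where all
#' channels are finite, and values in masked-out hours are removed.
#'
#' @param panel An unstandardised `trajectory_panel`.
#' @return The filtered `trajectory_panel`.
#' @export
filter_complete_hours <- function(panel) {
  complete <- apply(panel$values, c(1, 2), function(v) all(is.finite(v)))
  values <- panel$values
  values[array(rep(!complete, 5), dim = dim(values))] <- NA_real_
  new_trajectory_panel(values, complete, panel$patient_id,
                       stats = panel$stats, standardized = panel$standardized)
}

#' Apply cohort inclusion and exclusion rules
#'
#' Keeps the first ICU stay per patient, patients aged 18 or over, ICU
#' length of stay of at least 24 hours, and at least two observed hours
#' of complete vital signs within the 12-hour window. Rules are applied
#' in that order and each patient is counted under the first rule that
#' excludes them; patients missing age or LOS are excluded with reason
#' `"missing eligibility field"`.
#'
#' @param panel A `trajectory_panel` (after the complete-hour filter).
#' @param baseline Data frame with columns `patient_id`, `age`,
#'   `icu_los_hours` and optionally `stay_number` (admission ordinal;
#'   assumed 1 when absent).
#' @param min_hours Minimum observed hours required (default 2).
#' @return A list with `panel` (included patients), `report` (tibble of
#'   exclusion reasons and counts, in application order) and `excluded`
#'   (tibble of `patient_id`, `reason`).
#' @export
apply_inclusion <- function(panel, baseline, min_hours = 2) {
  baseline <- tibble::as_tibble(baseline)
  if (!all(c("patient_id", "age", "icu_los_hours") %in% names(baseline))) {
    abort("baseline must have columns patient_id, age, icu_los_hours")
  }
  if (!"stay_number" %in% names(baseline)) baseline$stay_number <- 1L

  info <- tibble::tibble(patient_id = panel$patient_id) |>
    dplyr::left_join(baseline, by = "patient_id")
  reason <- rep(NA_character_, nrow(info))

  miss <- is.na(info$age) | is.na(info$icu_los_hours)
  first <- !is.na(info$stay_number) & info$stay_number > 1
  reason[is.na(reason) & first] <- "not first ICU stay"
  reason[is.na(reason) & miss] <- "missing eligibility field"
  reason[is.na(reason) & info$age < 18] <- "age under 18"
  reason[is.na(reason) & info$icu_los_hours < 24] <- "ICU LOS under 24 h"
  reason[is.na(reason) & observed_hours(panel) < min_hours] <-
    "fewer than 2 observed hours"

  order_levels <- c("not first ICU stay", "missing eligibility field",
                    "age under 18", "ICU LOS under 24 h",
                    "fewer than 2 observed hours")
  report <- tibble::tibble(reason = order_levels) |>
    dplyr::left_join(
      tibble::tibble(reason = reason[!is.na(reason)]) |>
        dplyr::count(.data$reason, name = "n_excluded"),
      by = "reason") |>
    tidyr::replace_na(list(n_excluded = 0L))

  keep <- is.na(reason)
  list(
    panel = panel_subset(panel, keep),
    report = report,
    excluded = tibble::tibble(patient_id = panel$patient_id[!keep],
                              reason = reason[!keep])
  )
}

#' Z-score standardise a trajectory panel per channel
#'
#' Standardisation pools all patients and observed hours per channel.
#' When `stats` is supplied (e.g. development-cohort statistics applied
#' to a validation cohort) those means/SDs are used unchanged, keeping
#' the MSE-based external assignment on a consistent scale.
#'
#' @param panel An unstandardised `trajectory_panel`.
#' @param stats Optional tibble with columns `channel`, `mean`, `sd`.
#' @return The standardised `trajectory_panel`; the statistics used are
#'   stored in its `stats` field.
#' @export
zscore_panel <- function(panel, stats = NULL) {
  if (panel$standardized) abort("panel is already standardized")
  if (is.null(stats)) {
    stats <- purrr::map_dfr(seq_along(VITAL_CHANNELS), function(ci) {
      v <- panel$values[, , ci][panel$mask]
      v <- v[is.finite(v)]
      if (length(v) < 2) abort("need >= 2 observed cells per channel")
      tibble::tibble(channel = VITAL_CHANNELS[ci],
                     mean = mean(v), sd = sd(v))
    })
  } else {
    stats <- tibble::as_tibble(stats)[, c("channel", "mean", "sd")]
    stats <- stats[match(VITAL_CHANNELS, stats$channel), ]
  }
  if (any(!is.finite(stats$sd)) || any(stats$sd <= 0)) {
    abort("degenerate channel: zero or undefined standard deviation")
  }
  values <- panel$values
  for (ci in seq_along(VITAL_CHANNELS)) {
    values[, , ci] <- (values[, , ci] - stats$mean[ci]) / stats$sd[ci]
  }
  new_trajectory_panel(values, panel$mask, panel$patient_id,
                       stats = stats, standardized = TRUE)
}

#' Invert z-scoring on a standardised panel
#' @param panel A standardised `trajectory_panel`.
#' @param stats Optional statistics; defaults to those stored in `panel`.
#' @return A `trajectory_panel` on the natural scale.
#' @export
unscale_panel <- function(panel, stats = NULL) {
  stats <- stats %||% panel$stats
  if (is.null(stats)) abort("no standardization stats available")
  stats <- tibble::as_tibble(stats)
  stats <- stats[match(VITAL_CHANNELS, stats$channel), ]
  values <- panel$values
  for (ci in seq_along(VITAL_CHANNELS)) {
    values[, , ci] <- values[, , ci] * stats$sd[ci] + stats$mean[ci]
  }
  new_trajectory_panel(values, panel$mask, panel$patient_id,
                       stats = stats, standardized = FALSE)
}

#' Convert Fahrenheit temperature observations to Celsius
#'
#' The panel pipeline accepts temperature in degrees Celsius only; readers
#' holding Fahrenheit data can pre-convert with this helper.
#'
#' @param records Long-format vitals data frame.
#' @return The data frame with `TEMP` values converted.
#' @export
convert_temp_f_to_c <- function(records) {
  dplyr::mutate(records, value = ifelse(.data$channel == "TEMP",
                                        (.data$value - 32) * 5 / 9,
                                        .data$value))
}

#' Run the full trajectory-preparation pipeline
#'
#' Fixed order: hourly aggregation, complete-hour filtering, inclusion
#' rules, z-scoring. No imputation is performed: incomplete hours are
#' simply omitted.
#'
#' @inheritParams hourly_aggregate
#' @inheritParams apply_inclusion
#' @param stats Optional standardisation statistics (see [zscore_panel()]).
#' @return A list with `panel` (standardised), `stats` and `exclusions`.
#' @export
prepare_trajectories <- function(records, baseline, stats = NULL) {
  res <- hourly_aggregate(records) |>
    filter_complete_hours() |>
    apply_inclusion(baseline)
  panel <- zscore_panel(res$panel, stats = stats)
  list(panel = panel, stats = panel$stats, exclusions = res$report)
}
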