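#' Hourly multi-channel trajectory panel
#'
#' A `trajectory_panel` holds, for each patient, a 12 x 5 matrix of hourly
#' vital-sign values (hours 0-11 after ICU admission x channels SBP, DBP,
#' HR, RR, TEMP) together with an observed-hour mask. An hour counts as
#' observed only when all five channels are present, mirroring the
#' complete-hour rule used during trajectory preparation. The panel also
#' carries the per-channel mean/SD used for z-scoring, so that external
#' cohorts can be standardised on the development scale.
#'
#' @param values Numeric array `[n_patients, 12, 5]`; `NA` marks missing
#'   cells.
#' @param mask Logical matrix `[n_patients, 12]`; `TRUE` where the hour is
#'   observed.
#' @param patient_id Character vector of patient identifiers.
#' @param stats `NULL`, or a tibble with columns `channel`, `mean`, `sd`
#'   recording the standardisation statistics.
#' @param standardized Logical; whether `values` are on the z-score scale.
#' @return An object of class `trajectory_panel`.
#' @export
new_trajectory_panel <- function(values, mask, patient_id,
                                 stats = NULL, standardized = FALSE) {
  stopifnot(length(dim(values)) == 3, dim(values)[2] == 12,
            dim(values)[3] == 5, is.matrix(mask),
            nrow(mask) == dim(values)[1], ncol(mask) == 12,
            length(patient_id) == dim(values)[1])
  dimnames(values) <- list(patient_id, 0:11, VITAL_CHANNELS)
  dimnames(mask) <- list(patient_id, 0:11)
  structure(
    list(values = values, mask = mask, patient_id = as.character(patient_id),
         stats = stats, standardized = isTRUE(standardized)),
    class = "trajectory_panel"
  )
}

#' @export
print.trajectory_panel <- function(x, ...) {
  cat(sprintf(
    "<trajectory_panel> %d patients, %d observed hours (of %d), %s scale\n",
    n_patients(x), sum(x$mask), length(x$mask),
    if (x$standardized) "z-score" else "natural"))
  invisible(x)
}

#' Number of patients in a trajectory panel
#' @param panel A `trajectory_panel`.
#' @return Integer count.
#' @export
n_patients <- function(panel) length(panel$patient_id)

#' Tidy a trajectory panel into a long tibble
#'
#' @param x A `trajectory_panel`.
#' @param ... Unused.
#' @return A tibble with columns `patient_id`, `hour`, `channel`, `value`,
#'   restricted to observed hours.
#' @export
tidy.trajectory_panel <- function(x, ...) {
  idx <- which(!is.na(x$values), arr.ind = TRUE)
  keep <- x$mask[idx[, 1:2, drop = FALSE]]
  idx <- idx[keep, , drop = FALSE]
  tibble::tibble(
    patient_id = x$patient_id[idx[, 1]],
    hour = idx[, 2] - 1L,
    channel = VITAL_CHANNELS[idx[, 3]],
    value = x$values[idx]
  ) |>
    dplyr::arrange(.data$patient_id, .data$hour, .data$channel)
}

#' Subset a trajectory panel by patient
#' @param panel A `trajectory_panel`.
#' @param keep Logical or integer index over patients.
#' @return A `trajectory_panel` with the selected patients.
#' @export
panel_subset <- function(panel, keep) {
  new_trajectory_panel(
    panel$values[keep, , , drop = FALSE],
    panel$mask[keep, , drop = FALSE],
    panel$patient_id[keep],
    stats = panel$stats, standardized = panel$standardized
  )
}

# number of observed hours per patient
observed_hours <- function(panel) rowSums(panel$mask)

# flatten to an [n, 60] matrix (hour-major within channel blocks) plus a
# matching [n, 60] logical mask; used by the EM and MSE code paths.
panel_flat <- function(panel) {
  n <- n_patients(panel)
  y <- matrix(panel$values, nrow = n)            # columns: 12 hours x 5 channels
  m <- panel$mask[, rep(1:12, times = 5), drop = FALSE]
  m[is.na(y)] <- FALSE
  y[!m] <- 0
  list(y = y, m = m)
}
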