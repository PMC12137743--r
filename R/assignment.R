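#' Assign patients to subphenotypes by mean squared error
#'
#' For each patient, computes the mean squared error between the observed
#' standardised trajectory and each class's fitted mean curves, averaged
#' over the patient's observed (hour, channel) cells, and assigns the
#' class with the lowest MSE. This is how external-cohort and
#' truncated-window patients are labelled with a frozen model.
#'
#' @param model A `gbmtm_fit`.
#' @param panel A `trajectory_panel` standardised on the model's scale.
#' @return An object of class `mse_table`: a tibble with `patient_id`,
#'   one `mse_k` column per class, `assigned` (class index) and `margin`
#'   (second-best minus best MSE). Patients with no observed hours are
#'   excluded and listed in the `excluded` attribute.
#' @export
assign_by_mse <- function(model, panel) {
  flat <- panel_flat(panel)
  nobs <- observed_hours(panel)
  excluded <- panel$patient_id[nobs == 0]
  X <- time_basis(0:11, model$order)
  n <- n_patients(panel)
  ncells <- rowSums(flat$m)
  mse <- matrix(NA_real_, n, model$K)
  for (k in seq_len(model$K)) {
    mu <- as.vector(X %*% t(model$coeffs[k, , ]))
    d <- (flat$y - rep(mu, each = n)) * flat$m
    mse[, k] <- rowSums(d * d) / pmax(ncells, 1)
  }
  keep <- nobs > 0
  mse_k <- mse[keep, , drop = FALSE]
  assigned <- apply(mse_k, 1, which.min)     # ties -> lowest class index
  n_tie <- sum(apply(mse_k, 1, function(r) sum(r == min(r)) > 1))
  if (n_tie > 0) inform(sprintf("%d MSE tie(s) broken by lowest class index",
                                n_tie))
  margin <- apply(mse_k, 1, function(r) {
    s <- sort(r)
    if (length(s) > 1) s[2] - s[1] else 0
  })
  out <- tibble::as_tibble(as.data.frame(mse_k)) |>
    setNames(paste0("mse_", seq_len(model$K)))
  out <- dplyr::bind_cols(
    tibble::tibble(patient_id = panel$patient_id[keep]), out,
    tibble::tibble(assigned = as.integer(assigned), margin = margin))
  structure(out, excluded = excluded, class = c("mse_table", class(out)))
}

#' Truncate a trajectory panel to the first H hours
#'
#' Masks all hours at or beyond `H`. Patients left with fewer than two
#' observed hours are flagged (attribute `flagged`), not dropped.
#'
#' @param panel A `trajectory_panel`.
#' @param H Number of hours retained, 1-12.
#' @return The truncated `trajectory_panel`.
#' @export
truncate_hours <- function(panel, H) {
  if (!is_count(H) || H < 1 || H > 12) abort("H must be in 1..12")
  if (H == 12) return(panel)
  mask <- panel$mask
  mask[, (H + 1):12] <- FALSE
  values <- panel$values
  values[, (H + 1):12, ] <- NA_real_
  out <- new_trajectory_panel(values, mask, panel$patient_id,
                              stats = panel$stats,
                              standardized = panel$standardized)
  attr(out, "flagged") <- panel$patient_id[rowSums(mask) < 2]
  out
}

#' Agreement between truncated-window and full 12-hour assignment
#'
#' The reference label is the MSE-based assignment on the full 12-hour
#' panel; agreement is the fraction of patients whose MSE assignment
#' using only the first `H` hours matches it. Patients flagged at
#' truncation (fewer than 2 observed hours remaining) are excluded from
#' the denominator.
#'
#' @param model A `gbmtm_fit`.
#' @param panel The fully prepared standardised `trajectory_panel`.
#' @param H Hours of data used for the early assignment (6-12).
#' @return A one-row tibble with `H`, `agreement`, `n_compared`,
#'   `n_excluded`.
#' @export
early_agreement <- function(model, panel, H) {
  if (!is_count(H) || H < 6 || H > 12) abort("H must be in 6..12")
  full <- assign_by_mse(model, panel)
  trunc <- truncate_hours(panel, H)
  flagged <- attr(trunc, "flagged") %||% character(0)
  keep <- setdiff(panel$patient_id, flagged)
  if (!length(keep)) abort("no patients with enough observed hours at H")
  early <- assign_by_mse(model, panel_subset(trunc,
                                             panel$patient_id %in% keep))
  ref <- full$assigned[match(keep, full$patient_id)]
  est <- early$assigned[match(keep, early$patient_id)]
  ok <- !is.na(ref) & !is.na(est)
  tibble::tibble(H = H, agreement = mean(ref[ok] == est[ok]),
                 n_compared = sum(ok),
                 n_excluded = n_patients(panel) - sum(ok))
}

#' Agreement summary across early-window lengths
#'
#' @param model A `gbmtm_fit`.
#' @param panel A standardised `trajectory_panel`.
#' @param hours Window lengths to evaluate (default 6:12).
#' @return A tibble with one row per `H`.
#' @export
agreement_by_hours <- function(model, panel, hours = 6:12) {
  purrr::map_dfr(hours, function(H) early_agreement(model, panel, H))
}
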