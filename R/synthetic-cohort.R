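#' Default class trajectory templates
#'
#' Order-2 polynomial mean curves per class and channel, on the z-score
#' scale with the time covariate scaled to `h/11` in `[0, 1]`. The four
#' classes reproduce the qualitative vital-sign patterns of the four ICU
#' acute-pancreatitis subphenotypes: A (hyperinflammatory) runs hot, fast
#' and tachypneic; B (hypertensive) has elevated blood pressures;
#' C (hypotensive) has depressed blood pressures; D (hypoinflammatory) is
#' hypothermic, bradycardic and bradypneic.
#'
#' @return A numeric array `[4 classes, 5 channels, 3 coefficients]`
#'   (ascending powers of the scaled hour).
#' @export
default_class_templates <- function() {
  tpl <- array(0, dim = c(4, 5, 3),
               dimnames = list(PHENOTYPE_LEVELS, VITAL_CHANNELS,
                               paste0("b", 0:2)))
  #            SBP              DBP              HR               RR               TEMP
  tpl["A", , ] <- t(cbind(
    c(-0.2, -0.3, 0.2), c(-0.1, -0.2, 0.1), c(1.3, 0.4, -0.5),
    c(1.2, 0.3, -0.4), c(1.4, -0.3, 0.1)))
  tpl["B", , ] <- t(cbind(
    c(1.4, -0.4, 0.2), c(1.2, -0.3, 0.1), c(0.1, 0.2, -0.1),
    c(0.0, 0.1, 0.0), c(0.0, 0.1, -0.1)))
  tpl["C", , ] <- t(cbind(
    c(-1.3, 0.2, -0.2), c(-1.2, 0.3, -0.2), c(0.3, -0.2, 0.2),
    c(0.2, 0.0, 0.1), c(0.1, 0.0, 0.0)))
  tpl["D", , ] <- t(cbind(
    c(0.1, 0.0, 0.1), c(0.0, 0.1, 0.0), c(-1.1, -0.2, 0.3),
    c(-1.0, -0.1, 0.2), c(-1.2, 0.2, -0.1)))
  tpl
}

# natural-unit location/scale used to map templates to measurement units
CHANNEL_LOC <- c(SBP = 120, DBP = 70, HR = 85, RR = 18, TEMP = 36.8)
CHANNEL_SCALE <- c(SBP = 20, DBP = 12, HR = 15, RR = 4, TEMP = 0.7)

#' Configuration for the synthetic cohort generator
#'
#' Defaults are calibrated to the published development-cohort estimates:
#' class mixing proportions 14.1/17.6/27.0/41.2% (normalised to sum to 1),
#' 30-day hazards set so the adjusted hazard ratios versus the reference
#' hypertensive class B are A = 3.38, C = 1.87, D = 0.77, per-class
#' ICU-mortality baselines 12.5/5.0/6.7/2.0%, fluid-risk bowls centred at
#' the reported lowest-risk fluid ranges, and a protective lactated
#' Ringer's hazard multiplier of 0.48 in the hypotensive class C.
#'
#' @param n_patients Number of patients.
#' @param class_proportions Length-4 probability vector (A, B, C, D).
#' @param class_templates `[4, 5, 3]` array of polynomial coefficients on
#'   the z-score scale (see [default_class_templates()]).
#' @param noise_sd Residual SD per channel on the z-score scale (scalar or
#'   length 5).
#' @param ar1_rho Within-patient serial correlation of hourly noise in
#'   `[0, 1)`; 0 means independent hourly noise, matching the conditional
#'   independence assumed by the trajectory mixture model.
#' @param missing_rate Probability that an individual (patient, hour,
#'   channel) observation is dropped, in `[0, 1)`.
#' @param survival_hazards Named per-class daily hazard of 30-day death;
#'   class B is the reference.
#' @param fluid_optima `[4, 2]` matrix of per-class (day-1, day-2) fluid
#'   volumes (mL) at the bottom of the mortality-risk bowl.
#' @param fluid_sd SD (mL) of the truncated-normal fluid volumes.
#' @param fluid_offset Added (mL) to the sampling mean of fluid volumes
#'   relative to the class optimum (clinicians tend to run slightly above
#'   the optimum, so the default is +300 mL).
#' @param fluid_risk_curvature Steepness of the risk surface, in log-odds
#'   of ICU death per squared litre of distance from the class optimum.
#'   Either a scalar (symmetric isotropic bowl) or a named length-3
#'   vector `c(day1_below, day1_above, day2)`. The default
#'   `c(60, 1.2, 0.15)` encodes a steep under-resuscitation wall below
#'   the day-1 optimum, a gentle fluid-overload slope above it, and a
#'   mild day-2 dependence, which reproduces narrow day-1 lowest-risk
#'   ranges with broader day-2 tolerance.
#' @param baseline_icu_death Per-class ICU-death probability at the
#'   optimum.
#' @param ringer_hr_classC Hazard (and odds) multiplier for lactated
#'   Ringer's receipt in class C.
#' @param ringer_rate Probability of receiving Ringer's within 48 h.
#' @param age_loghr Log-hazard per year of age (0 by default so crude and
#'   adjusted contrasts coincide).
#' @param confounded If `TRUE`, shifts age distributions by class so that
#'   crude and adjusted Cox contrasts differ.
#' @param seed Integer seed.
#' @return A `generator_config` list, validated.
#' @export
generator_config <- function(n_patients = 2612,
                             class_proportions = c(0.141, 0.176, 0.270, 0.412),
                             class_templates = default_class_templates(),
                             noise_sd = 0.5,
                             ar1_rho = 0,
                             missing_rate = 0.1,
                             survival_hazards = NULL,
                             fluid_optima = NULL,
                             fluid_sd = 700,
                             fluid_offset = 300,
                             fluid_risk_curvature = c(day1_below = 60,
                                                      day1_above = 1.2,
                                                      day2 = 0.15),
                             baseline_icu_death = c(A = 0.125, B = 0.050,
                                                    C = 0.067, D = 0.020),
                             ringer_hr_classC = 0.48,
                             ringer_rate = 0.5,
                             age_loghr = 0,
                             confounded = FALSE,
                             seed = 1L) {
  if (!is_count(n_patients)) abort("n_patients must be a positive count")
  if (length(class_proportions) != 4 || any(class_proportions <= 0)) {
    abort("class_proportions must be 4 positive probabilities")
  }
  class_proportions <- class_proportions / sum(class_proportions)
  if (abs(sum(class_proportions) - 1) > 1e-12) abort("proportions must sum to 1")
  if (length(noise_sd) == 1) noise_sd <- rep(noise_sd, 5)
  if (any(noise_sd < 0)) abort("noise_sd must be non-negative")
  if (ar1_rho < 0 || ar1_rho >= 1) abort("ar1_rho must be in [0, 1)")
  if (missing_rate < 0 || missing_rate >= 1) abort("missing_rate must be in [0, 1)")
  if (is.null(survival_hazards)) {
    # B calibrated to ~5% 30-day mortality; A, C, D by published HRs
    lambda_b <- -log(1 - 0.05) / 30
    survival_hazards <- c(A = 3.38, B = 1, C = 1.87, D = 0.77) * lambda_b
  }
  if (any(survival_hazards < 0)) abort("survival hazards must be non-negative")
  if (is.null(fluid_optima)) {
    fluid_optima <- rbind(A = c(4200, 3500), B = c(4050, 900),
                          C = c(4500, 2800), D = c(3300, 2000))
    colnames(fluid_optima) <- c("day1", "day2")
  }
  if (any(baseline_icu_death <= 0 | baseline_icu_death >= 1)) {
    abort("baseline_icu_death must be probabilities in (0, 1)")
  }
  if (length(fluid_risk_curvature) == 1) {
    fluid_risk_curvature <- rep(fluid_risk_curvature, 3)
  }
  if (length(fluid_risk_curvature) != 3 || any(fluid_risk_curvature < 0)) {
    abort("fluid_risk_curvature must be a non-negative scalar or length-3 vector")
  }
  fluid_risk_curvature <- setNames(as.numeric(fluid_risk_curvature),
                                   c("day1_below", "day1_above", "day2"))
  if (ringer_hr_classC <= 0) abort("ringer_hr_classC must be positive")
  structure(
    list(n_patients = as.integer(n_patients),
         class_proportions = setNames(class_proportions, PHENOTYPE_LEVELS),
         class_templates = class_templates,
         noise_sd = setNames(noise_sd, VITAL_CHANNELS),
         ar1_rho = ar1_rho, missing_rate = missing_rate,
         survival_hazards = survival_hazards,
         fluid_optima = fluid_optima, fluid_sd = fluid_sd,
         fluid_offset = fluid_offset,
         fluid_risk_curvature = fluid_risk_curvature,
         baseline_icu_death = baseline_icu_death,
         ringer_hr_classC = ringer_hr_classC, ringer_rate = ringer_rate,
         age_loghr = age_loghr, confounded = isTRUE(confounded),
         seed = as.integer(seed)),
    class = "generator_config")
}

#' Generate a complete synthetic ICU cohort
#'
#' Draws latent class labels, hourly vital-sign trajectories (class
#' template plus Gaussian, optionally AR(1), noise on the z-score scale,
#' mapped to natural measurement units), demographic/lab baselines,
#' 30-day survival records and day-1/day-2 fluid records with ICU-death
#' flags. Deterministic given the config seed.
#'
#' @param config A [generator_config()].
#' @return A list of class `synthetic_cohort` with tibbles `raw_vitals`,
#'   `truth_labels`, `baseline`, `survival`, `fluids`.
#' @export
generate_cohort <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  n <- config$n_patients
  ids <- sprintf("P%05d", seq_len(n))
  labels <- sample(PHENOTYPE_LEVELS, n, replace = TRUE,
                   prob = config$class_proportions)

  raw_vitals <- generate_vitals(ids, labels, config)
  if (config$missing_rate > 0) {
    raw_vitals <- inject_missingness(raw_vitals, config$missing_rate,
                                     seed = config$seed + 1L)
  }
  baseline <- generate_baseline(ids, labels, config)
  fluids <- generate_fluids_and_icu_death(labels, config, patient_id = ids)
  survival <- generate_survival(labels, config, patient_id = ids,
                                covariates = baseline,
                                ringer = fluids$ringer)
  structure(
    list(raw_vitals = raw_vitals,
         truth_labels = tibble::tibble(patient_id = ids, phenotype = labels),
         baseline = baseline, survival = survival, fluids = fluids,
         config = config),
    class = "synthetic_cohort")
}

# hourly trajectories in natural units, one row per (patient, hour, channel)
generate_vitals <- function(ids, labels, config) {
  n <- length(ids)
  tb <- time_basis(0:11, 2)                       # 12 x 3
  k_idx <- match(labels, PHENOTYPE_LEVELS)
  out <- vector("list", 5)
  for (ci in seq_along(VITAL_CHANNELS)) {
    mu_k <- tb %*% t(config$class_templates[, ci, ])   # 12 x 4
    eps <- matrix(rnorm(n * 12, sd = config$noise_sd[ci]), n, 12)
    if (config$ar1_rho > 0) {
      rho <- config$ar1_rho
      for (h in 2:12) {
        eps[, h] <- rho * eps[, h - 1] + sqrt(1 - rho^2) * eps[, h]
      }
    }
    z <- t(mu_k)[k_idx, ] + eps                       # n x 12 on z scale
    nat <- CHANNEL_LOC[ci] + CHANNEL_SCALE[ci] * z
    out[[ci]] <- tibble::tibble(
      patient_id = rep(ids, times = 12),
      time_from_admission = rep(0:11, each = n),
      channel = VITAL_CHANNELS[ci],
      value = as.vector(nat))
  }
  dplyr::bind_rows(out) |>
    dplyr::arrange(.data$patient_id, .data$time_from_admission, .data$channel)
}

# demographics, ICU LOS, a few labs and comorbidity flags; labs and
# comorbidities follow class-specific marginals only
generate_baseline <- function(ids, labels, config) {
  n <- length(ids)
  k <- match(labels, PHENOTYPE_LEVELS)
  age_shift <- if (config$confounded) c(0, -2, 3, 5)[k] else 0
  age <- pmin(pmax(rnorm(n, 47 + age_shift, 12), 18), 95)
  gender <- sample(c("Male", "Female"), n, TRUE, prob = c(0.66, 0.34))
  los_med <- c(A = 10, B = 9, C = 7, D = 3)[k]
  icu_los_days <- exp(rnorm(n, log(los_med), 0.6))
  como <- function(p) rbinom(n, 1, p[k]) == 1
  tibble::tibble(
    patient_id = ids,
    age = age, gender = gender, race = "Asia",
    stay_number = 1L,
    icu_los_hours = pmax(icu_los_days * 24, 25),
    wbc = rnorm(n, c(16, 12, 11, 9)[k], 3),
    crp = pmax(rnorm(n, c(180, 110, 120, 70)[k], 40), 1),
    creatinine = pmax(rnorm(n, c(1.6, 1.0, 1.1, 0.9)[k], 0.4), 0.2),
    amylase = pmax(rnorm(n, c(900, 700, 500, 650)[k], 250), 30),
    congestive_heart_failure = como(c(0.089, 0.061, 0.081, 0.049)),
    chronic_pulmonary_disease = como(c(0.030, 0.037, 0.031, 0.067)),
    diabetes = como(c(0.230, 0.217, 0.211, 0.203)),
    liver_disease = como(c(0.460, 0.449, 0.402, 0.451)),
    renal_disease = como(c(0.111, 0.078, 0.093, 0.050)),
    malignant_tumor = como(c(0.033, 0.030, 0.034, 0.136)))
}

#' Generate 30-day survival records for labelled patients
#'
#' Event times are exponential with class-specific daily hazard and
#' administrative censoring at 30 days, so hazards are proportional by
#' construction and Cox recovery is well-posed. Covariates are generated
#' independently of class by default, making crude and adjusted contrasts
#' coincide in truth.
#'
#' @param labels Character vector of class labels in `{A, B, C, D}`.
#' @param config A [generator_config()].
#' @param patient_id Optional ids (defaults to sequential).
#' @param covariates Optional baseline tibble supplying age/gender/race
#'   (generated independently when `NULL`).
#' @param ringer Optional logical vector; when supplied, class-C patients
#'   receiving Ringer's have their hazard multiplied by
#'   `ringer_hr_classC`.
#' @return A tibble with `patient_id`, `time` (days in `(0, 30]`),
#'   `event`, `phenotype`, `age`, `gender`, `race`.
#' @export
generate_survival <- function(labels, config, patient_id = NULL,
                              covariates = NULL, ringer = NULL) {
  if (!all(labels %in% PHENOTYPE_LEVELS)) abort("labels must be in {A,B,C,D}")
  if (any(config$survival_hazards < 0)) abort("hazards must be non-negative")
  n <- length(labels)
  patient_id <- patient_id %||% sprintf("P%05d", seq_len(n))
  if (is.null(covariates)) {
    covariates <- tibble::tibble(
      patient_id = patient_id,
      age = pmin(pmax(rnorm(n, 47, 12), 18), 95),
      gender = sample(c("Male", "Female"), n, TRUE, prob = c(0.66, 0.34)),
      race = "Asia")
  }
  haz <- unname(config$survival_hazards[labels])
  if (!is.null(ringer)) {
    haz <- haz * ifelse(labels == "C" & ringer, config$ringer_hr_classC, 1)
  }
  if (config$age_loghr != 0) {
    haz <- haz * exp(config$age_loghr * (covariates$age - 47))
  }
  t_event <- ifelse(haz > 0, rexp(n, rate = pmax(haz, 1e-300)), Inf)
  time <- pmin(t_event, 30)
  tibble::tibble(
    patient_id = patient_id,
    time = pmax(time, 1e-8),
    event = t_event <= 30,
    phenotype = labels,
    age = covariates$age, gender = covariates$gender,
    race = covariates$race %||% "Asia")
}

#' Generate fluid-intake records and ICU-death flags
#'
#' Day-1 and day-2 intake volumes are truncated normal around the class
#' optimum (plus `fluid_offset`), floored at 0. The probability of ICU
#' death is `plogis(qlogis(baseline) + bump)` where the risk bump is
#' `c_d1 * ((day1 - opt1)/1000)^2 + c_d2 * ((day2 - opt2)/1000)^2`, with
#' the day-1 curvature taking its below- or above-optimum value
#' depending on the side (see [generator_config()]); class-C patients
#' receiving Ringer's additionally have their log-odds shifted by
#' `log(ringer_hr_classC)`.
#'
#' @inheritParams generate_survival
#' @return A tibble with `patient_id`, `phenotype`, `day1_ml`, `day2_ml`,
#'   `ringer`, `icu_death`.
#' @export
generate_fluids_and_icu_death <- function(labels, config, patient_id = NULL) {
  if (!all(labels %in% PHENOTYPE_LEVELS)) abort("labels must be in {A,B,C,D}")
  n <- length(labels)
  patient_id <- patient_id %||% sprintf("P%05d", seq_len(n))
  k <- match(labels, PHENOTYPE_LEVELS)
  opt <- config$fluid_optima[k, , drop = FALSE]
  day1 <- pmax(rnorm(n, opt[, 1] + config$fluid_offset, config$fluid_sd), 0)
  day2 <- pmax(rnorm(n, opt[, 2] + config$fluid_offset, config$fluid_sd), 0)
  ringer <- runif(n) < config$ringer_rate
  cv <- config$fluid_risk_curvature
  e1 <- (day1 - opt[, 1]) / 1000
  e2 <- (day2 - opt[, 2]) / 1000
  bump <- ifelse(e1 < 0, cv[["day1_below"]], cv[["day1_above"]]) * e1^2 +
    cv[["day2"]] * e2^2
  logit <- qlogis(unname(config$baseline_icu_death[k])) + bump +
    ifelse(labels == "C" & ringer, log(config$ringer_hr_classC), 0)
  tibble::tibble(
    patient_id = patient_id, phenotype = labels,
    day1_ml = day1, day2_ml = day2, ringer = ringer,
    icu_death = runif(n) < plogis(logit))
}

#' Drop individual vital-sign observations completely at random
#'
#' @param raw_vitals Long-format vitals tibble.
#' @param missing_rate Probability each (patient, hour, channel) value is
#'   dropped, in `[0, 1)`.
#' @param seed Integer seed; identical seeds give identical output.
#' @return The thinned vitals tibble.
#' @export
inject_missingness <- function(raw_vitals, missing_rate, seed = 1L) {
  if (missing_rate < 0 || missing_rate >= 1) abort("missing_rate must be in [0, 1)")
  if (missing_rate == 0) return(raw_vitals)
  set.seed(as.integer(seed))
  keep <- runif(nrow(raw_vitals)) >= missing_rate
  raw_vitals[keep, , drop = FALSE]
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d patients; class shares: %s\n",
              nrow(x$truth_labels),
              paste(sprintf("%s %.1f%%", PHENOTYPE_LEVELS,
                            100 * prop.table(table(factor(x$truth_labels$phenotype,
                                                          PHENOTYPE_LEVELS)))),
                    collapse = ", ")))
  invisible(x)
}

#' Match fitted mixture classes to generator template classes
#'
#' Fitted class indices are arbitrary (label switching); this helper maps
#' each fitted class to the generator template it is closest to. Because
#' pooled z-scoring of a mixture recentres each channel by the mixture
#' mean, the templates are first passed through the same affine map
#' implied by the panel's standardisation statistics before distances are
#' computed. The assignment minimises total squared curve distance over
#' all permutations.
#'
#' @param model A fitted `gbmtm_fit` with `K = 4`.
#' @param config The [generator_config()] used to simulate the data.
#' @param stats Standardisation statistics of the fitted panel (tibble
#'   `channel`, `mean`, `sd` on the natural scale).
#' @return Character vector of length `K`: `template_of[k]` is the
#'   template class (`"A"`..`"D"`) matched to fitted class `k`.
#' @export
match_template_classes <- function(model, config, stats) {
  stopifnot(model$K == 4)
  tb <- time_basis(0:11, 2)
  stats <- tibble::as_tibble(stats)
  stats <- stats[match(VITAL_CHANNELS, stats$channel), ]
  # template curves mapped to the fitted panel's z scale
  tpl_z <- array(0, dim = c(4, 12, 5))
  for (ci in 1:5) {
    nat <- CHANNEL_LOC[ci] + CHANNEL_SCALE[ci] *
      (tb %*% t(config$class_templates[, ci, ]))     # 12 x 4, natural units
    tpl_z[, , ci] <- t((nat - stats$mean[ci]) / stats$sd[ci])
  }
  fit_curves <- array(0, dim = c(4, 12, 5))
  for (k in 1:4) for (ci in 1:5) {
    fit_curves[k, , ci] <- class_mean_curve(model, k, VITAL_CHANNELS[ci], 0:11)$value
  }
  cost <- matrix(0, 4, 4)   # fitted k x template t
  for (k in 1:4) for (tt in 1:4) {
    cost[k, tt] <- sum((fit_curves[k, , ] - tpl_z[tt, , ])^2)
  }
  perms <- permutations_4()
  totals <- apply(perms, 1, function(p) sum(cost[cbind(1:4, p)]))
  best <- perms[which.min(totals), ]
  PHENOTYPE_LEVELS[best]
}

# all permutations of 1:4
permutations_4 <- function() {
  p <- expand.grid(a = 1:4, b = 1:4, c = 1:4, d = 1:4)
  p <- p[apply(p, 1, function(r) length(unique(r)) == 4), ]
  as.matrix(p)
}
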