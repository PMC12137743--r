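# End-to-end orchestration: simulate -> prep -> fit -> select_k ->
# assign -> outcomes -> treatment. Every stage reads only prior-stage
# files from the artifact directory and writes its own outputs there, so
# downstream stages can be rerun in isolation and reproduce identical
# files (per-stage seeds are derived deterministically from the global
# seed).

PIPELINE_STAGES <- c("simulate", "prep", "fit", "select_k", "assign",
                     "outcomes", "treatment")

#' Default pipeline configuration
#'
#' A demo-scale study: an 800-patient synthetic cohort, candidate K from
#' 2 to 5 with 30 consensus resamples, cubic trajectory polynomials, and
#' the default fluid/survival calibration.
#'
#' @param n_patients Cohort size.
#' @param seed Global seed (expanded into per-stage seeds).
#' @param k_min,k_max Candidate class-count range.
#' @param n_resamples Consensus resamples per K.
#' @param subsample_frac Consensus subsample fraction.
#' @param order Polynomial degree.
#' @param n_restarts Full-fit EM restarts.
#' @param generator Optional [generator_config()] override.
#' @return A named list understood by [run_pipeline()].
#' @export
default_pipeline_config <- function(n_patients = 800, seed = 1L,
                                    k_min = 2, k_max = 5,
                                    n_resamples = 30, subsample_frac = 0.8,
                                    order = 3, n_restarts = 5,
                                    generator = NULL) {
  list(n_patients = n_patients, seed = as.integer(seed),
       k_min = k_min, k_max = k_max, n_resamples = n_resamples,
       subsample_frac = subsample_frac, order = order,
       n_restarts = n_restarts, generator = generator)
}

#' Run the subphenotyping pipeline end to end
#'
#' @param config A list from [default_pipeline_config()], or a path to a
#'   YAML file with the same keys.
#' @param out_dir Artifact directory (created if needed; existing stage
#'   outputs are overwritten by the stages being run).
#' @param stages Stages to execute, in pipeline order (default: all).
#' @return The run manifest (also written to `run_manifest.json`),
#'   invisibly.
#' @export
run_pipeline <- function(config = default_pipeline_config(),
                         out_dir, stages = PIPELINE_STAGES) {
  if (is.character(config) && length(config) == 1) {
    config <- modifyList(default_pipeline_config(),
                         yaml::read_yaml(config))
  }
  stages <- match.arg(stages, PIPELINE_STAGES, several.ok = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- derive_seeds(config$seed, PIPELINE_STAGES)
  gen <- config$generator %||%
    generator_config(n_patients = config$n_patients, seed = seeds[["simulate"]])

  t_start <- Sys.time()
  for (st in PIPELINE_STAGES[PIPELINE_STAGES %in% stages]) {
    inform(sprintf("[pipeline] stage %s", st))
    switch(st,
      simulate = stage_simulate(gen, out_dir),
      prep = stage_prep(out_dir),
      fit = stage_fit(config, out_dir, seeds[["fit"]]),
      select_k = stage_select(config, out_dir, seeds[["select_k"]]),
      assign = stage_assign(config, gen, out_dir),
      outcomes = stage_outcomes(out_dir),
      treatment = stage_treatment(config, out_dir, seeds[["treatment"]]))
  }
  manifest <- build_manifest(config, seeds, out_dir, t_start)
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

wcsv <- function(df, dir, name) {
  utils::write.csv(df, file.path(dir, name), row.names = FALSE)
}
rcsv <- function(dir, name) {
  tibble::as_tibble(utils::read.csv(file.path(dir, name)))
}

stage_simulate <- function(gen, dir) {
  co <- generate_cohort(gen)
  wcsv(co$raw_vitals, dir, "vitals.csv")
  wcsv(co$baseline, dir, "baseline.csv")
  wcsv(co$survival, dir, "survival.csv")
  wcsv(co$fluids, dir, "fluids.csv")
  wcsv(co$truth_labels, dir, "truth.csv")
}

stage_prep <- function(dir) {
  vit <- rcsv(dir, "vitals.csv")
  base <- rcsv(dir, "baseline.csv")
  prep <- prepare_trajectories(vit, base)
  wcsv(tidy(prep$panel), dir, "panel.csv")
  wcsv(prep$stats, dir, "stats.csv")
  wcsv(prep$exclusions, dir, "exclusions.csv")
}

read_panel <- function(dir) {
  df <- rcsv(dir, "panel.csv")
  stats <- rcsv(dir, "stats.csv")
  panel_from_long(df, standardized = TRUE, stats = stats)
}

#' Rebuild a trajectory panel from a tidy long table
#'
#' @param df Tibble with `patient_id`, `hour`, `channel`, `value`
#'   (observed complete hours only).
#' @param standardized Whether values are on the z-score scale.
#' @param stats Optional standardisation statistics.
#' @return A `trajectory_panel`.
#' @export
panel_from_long <- function(df, standardized = FALSE, stats = NULL) {
  ids <- sort(unique(as.character(df$patient_id)))
  values <- array(NA_real_, dim = c(length(ids), 12, 5))
  values[cbind(match(as.character(df$patient_id), ids),
               as.integer(df$hour) + 1L,
               match(df$channel, VITAL_CHANNELS))] <- df$value
  mask <- apply(values, c(1, 2), function(v) all(is.finite(v)))
  values[array(rep(!mask, 5), dim = dim(values))] <- NA_real_
  new_trajectory_panel(values, mask, ids, stats = stats,
                       standardized = standardized)
}

stage_fit <- function(config, dir, seed) {
  panel <- read_panel(dir)
  ks <- config$k_min:config$k_max
  ic <- sensitivity_table(
    panel, K_range = ks,
    fit_opts = list(order = config$order, n_restarts = config$n_restarts),
    seed = seed, keep_models = TRUE)
  for (K in ks) {
    m <- attr(ic, "models")[[as.character(K)]]
    if (!is.null(m)) write_gbmtm(m, file.path(dir, sprintf("model_K%d.json", K)))
  }
  wcsv(dplyr::select(ic, -dplyr::any_of("error")), dir, "ic_table.csv")
}

stage_select <- function(config, dir, seed) {
  panel <- read_panel(dir)
  cons <- consensus_cluster(
    panel, K_range = config$k_min:config$k_max,
    n_resamples = config$n_resamples,
    subsample_frac = config$subsample_frac,
    fit_opts = list(order = config$order, n_restarts = 3),
    seed = seed)
  ic <- rcsv(dir, "ic_table.csv")
  sel <- select_k(cons, ic)
  wcsv(sel$criteria, dir, "selection.csv")
  jsonlite::write_json(list(chosen_K = sel$chosen_K),
                       file.path(dir, "chosen_k.json"), auto_unbox = TRUE)
}

stage_assign <- function(config, gen, dir) {
  chosen <- jsonlite::read_json(file.path(dir, "chosen_k.json"))$chosen_K
  if (is.null(chosen) || is.na(chosen)) abort("no admissible K was selected")
  model <- read_gbmtm(file.path(dir, sprintf("model_K%d.json", chosen)))
  panel <- read_panel(dir)
  mse <- assign_by_mse(model, panel)
  letters_map <- if (chosen == 4) {
    match_template_classes(model, gen, panel$stats)
  } else paste0("class", seq_len(chosen))
  labels <- tibble::tibble(patient_id = mse$patient_id,
                           class = mse$assigned,
                           phenotype = letters_map[mse$assigned])
  wcsv(labels, dir, "labels.csv")
  wcsv(dplyr::select(tibble::as_tibble(mse), -dplyr::any_of("excluded")),
       dir, "mse_table.csv")
  wcsv(agreement_by_hours(model, panel), dir, "agreement.csv")
}

stage_outcomes <- function(dir) {
  labels <- rcsv(dir, "labels.csv")
  surv <- rcsv(dir, "survival.csv") |>
    dplyr::select(-dplyr::any_of("phenotype")) |>
    dplyr::inner_join(dplyr::select(labels, "patient_id", "phenotype"),
                      by = "patient_id")
  base <- rcsv(dir, "baseline.csv")
  ref <- if ("B" %in% surv$phenotype) "B" else sort(unique(surv$phenotype))[1]
  desc_vars <- setdiff(names(base), c("patient_id", "stay_number"))
  wcsv(describe_by_phenotype(base, labels, desc_vars), dir, "table1.csv")
  wcsv(compare_groups(base, labels, desc_vars), dir, "group_tests.csv")
  cm <- correlation_matrix(base, labels)
  wcsv(tibble::as_tibble(cm, rownames = "variable"), dir, "correlations.csv")
  wcsv(fit_cox(surv, reference = ref), dir, "cox_crude.csv")
  wcsv(fit_cox(surv, covariates = c("age", "gender", "race"),
               reference = ref), dir, "cox_adjusted.csv")
  wcsv(adjusted_km(surv, reference = ref), dir, "adjusted_km.csv")
  comorb <- intersect(names(surv <- dplyr::left_join(
    surv, dplyr::select(base, -dplyr::any_of(c("age", "gender", "race"))),
    by = "patient_id")),
    c("congestive_heart_failure", "chronic_pulmonary_disease", "diabetes",
      "liver_disease", "renal_disease", "malignant_tumor"))
  wcsv(comorbidity_cox(surv, comorb), dir, "comorbidity_cox.csv")
}

stage_treatment <- function(config, dir, seed) {
  labels <- rcsv(dir, "labels.csv")
  fluids <- rcsv(dir, "fluids.csv") |>
    dplyr::select(-dplyr::any_of("phenotype")) |>
    dplyr::inner_join(dplyr::select(labels, "patient_id", "phenotype"),
                      by = "patient_id")
  base <- rcsv(dir, "baseline.csv") |>
    dplyr::select(-dplyr::any_of(c("stay_number", "icu_los_hours", "race")))
  wcsv(missing_report(base), dir, "missing_report.csv")
  imp <- impute_ensemble(drop_high_missing(base), seed = seed)
  wcsv(imp, dir, "baseline_imputed.csv")
  feats <- dplyr::inner_join(imp,
                             dplyr::select(fluids, "patient_id",
                                           "day1_ml", "day2_ml"),
                             by = "patient_id")
  rf <- fit_rf_per_phenotype(feats, fluids$icu_death, fluids$phenotype,
                             seed = seed)
  wcsv(glance(rf), dir, "rf_auroc.csv")
  ranges <- purrr::map_dfr(names(rf$models), function(p) {
    surf <- pdp_2d(rf$models[[p]],
                   feats[fluids$phenotype == p, , drop = FALSE],
                   background = 300, seed = seed) |>
      risk_strata()
    wcsv(tidy(surf), dir, sprintf("pd_surface_%s.csv", p))
    if (surf$n_strata < 2) {
      return(tibble::tibble(phenotype = p, day1_lo = NA_real_,
                            day1_hi = NA_real_, day2_lo = NA_real_,
                            day2_hi = NA_real_, n_cells = NA_integer_))
    }
    dplyr::mutate(lowest_risk_range(surf), phenotype = p, .before = 1)
  })
  wcsv(ranges, dir, "fluid_ranges.csv")
  surv <- rcsv(dir, "survival.csv") |>
    dplyr::select(-dplyr::any_of("phenotype")) |>
    dplyr::inner_join(dplyr::select(labels, "patient_id", "phenotype"),
                      by = "patient_id") |>
    dplyr::inner_join(dplyr::select(fluids, "patient_id", "ringer"),
                      by = "patient_id")
  wcsv(ringer_cox(surv), dir, "ringer_cox.csv")
}

build_manifest <- function(config, seeds, dir, t_start) {
  files <- list.files(dir, pattern = "\\.(csv|json)$")
  files <- setdiff(files, "run_manifest.json")
  sums <- tools::md5sum(file.path(dir, files))
  cfg_file <- tempfile(fileext = ".yaml")
  yaml::write_yaml(config[!vapply(config, is.null, logical(1))], cfg_file)
  on.exit(unlink(cfg_file))
  list(
    config_hash = unname(tools::md5sum(cfg_file)),
    seeds = as.list(seeds),
    versions = list(trajphen = as.character(utils::packageVersion("trajphen")),
                    R = paste(R.version$major, R.version$minor, sep = ".")),
    checksums = as.list(setNames(unname(sums), files)),
    started = format(t_start, "%Y-%m-%dT%H:%M:%S%z"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
}
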