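test_that("generator config validates its inputs", {
  expect_error(generator_config(n_patients = 0), "positive count")
  expect_error(generator_config(class_proportions = c(0.5, 0.5, 0, 0)),
               "positive")
  expect_error(generator_config(noise_sd = -1), "non-negative")
  expect_error(generator_config(ar1_rho = 1), "ar1_rho")
  expect_error(generator_config(missing_rate = 1), "missing_rate")
  expect_error(generator_config(ringer_hr_classC = 0), "positive")
  expect_error(generator_config(fluid_risk_curvature = -1), "curvature")
  # printed class shares (99.9% total) are normalised to sum exactly 1
  cfg <- generator_config()
  expect_equal(sum(cfg$class_proportions), 1, tolerance = 1e-14)
  expect_equal(unname(cfg$class_proportions["D"]), 0.412 / 0.999,
               tolerance = 1e-12)
})

test_that("cohorts are byte-identical given the same config and seed", {
  cfg <- generator_config(n_patients = 60, seed = 7)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$raw_vitals, b$raw_vitals)
  expect_identical(a$survival, b$survival)
  expect_identical(a$fluids, b$fluids)
  expect_identical(a$baseline, b$baseline)
})

test_that("every patient appears once in each component table", {
  co <- generate_cohort(generator_config(n_patients = 80, seed = 2))
  ids <- co$truth_labels$patient_id
  expect_false(any(duplicated(ids)))
  for (tbl in list(co$baseline, co$survival, co$fluids)) {
    expect_setequal(tbl$patient_id, ids)
    expect_false(any(duplicated(tbl$patient_id)))
  }
  expect_true(all(co$raw_vitals$patient_id %in% ids))
  expect_true(all(co$truth_labels$phenotype %in% c("A", "B", "C", "D")))
})

test_that("zero-noise trajectories equal the class templates exactly", {
  cfg <- generator_config(n_patients = 12, noise_sd = 0, missing_rate = 0,
                          seed = 4)
  co <- generate_cohort(cfg)
  loc <- c(SBP = 120, DBP = 70, HR = 85, RR = 18, TEMP = 36.8)
  scl <- c(SBP = 20, DBP = 12, HR = 15, RR = 4, TEMP = 0.7)
  tb <- vapply(0:2, function(j) (0:11 / 11)^j, numeric(12))
  for (i in seq_len(4)) {
    id <- co$truth_labels$patient_id[i]
    k <- match(co$truth_labels$phenotype[i], c("A", "B", "C", "D"))
    for (ci in 1:5) {
      obs <- co$raw_vitals |>
        dplyr::filter(patient_id == id, channel == CH[ci]) |>
        dplyr::arrange(time_from_admission)
      mu <- loc[ci] + scl[ci] * drop(tb %*% cfg$class_templates[k, ci, ])
      expect_equal(obs$value, unname(mu), tolerance = 1e-12)
    }
  }
})

test_that("empirical class shares converge to the configured proportions", {
  cfg <- generator_config(n_patients = 30000, seed = 11)
  co <- generate_cohort(cfg)
  shares <- prop.table(table(factor(co$truth_labels$phenotype,
                                    c("A", "B", "C", "D"))))
  for (k in c("A", "B", "C", "D")) {
    p <- cfg$class_proportions[[k]]
    se <- sqrt(p * (1 - p) / 30000)
    expect_lt(abs(shares[[k]] - p), 3 * se + 1e-9)
  }
  # class D within one percentage point of the printed 41.2%
  expect_lt(abs(shares[["D"]] - 0.412), 0.01)
})

test_that("survival generation matches its closed-form calibration", {
  cfg <- generator_config(seed = 5)
  set.seed(5)
  # null case: equal hazards -> HR ~ 1
  cfg_null <- generator_config(survival_hazards = c(A = 0.002, B = 0.002,
                                                    C = 0.002, D = 0.002),
                               seed = 5)
  labs <- rep(c("A", "B"), each = 4000)
  s <- generate_survival(labs, cfg_null)
  hr <- fit_cox(s)$HR[1]
  expect_lt(abs(log(hr)), 0.25)
  # all-zero hazards -> everyone administratively censored at 30 days
  cfg0 <- generator_config(survival_hazards = c(A = 0, B = 0, C = 0, D = 0),
                           seed = 5)
  s0 <- generate_survival(rep(c("A", "B", "C", "D"), 50), cfg0)
  expect_false(any(s0$event))
  expect_true(all(s0$time == 30))
  expect_error(generate_survival("E", cfg), "labels")
})

test_that("the configured A-vs-B hazard ratio is recovered by Cox at large n", {
  cfg <- generator_config(seed = 21)
  set.seed(21)
  labs <- rep(c("A", "B"), each = 10000)
  s <- generate_survival(labs, cfg)
  hr <- fit_cox(s)$HR[1]
  true_hr <- unname(cfg$survival_hazards["A"] / cfg$survival_hazards["B"])
  expect_equal(true_hr, 3.38, tolerance = 1e-12)
  expect_gt(hr, 3.0)
  expect_lt(hr, 3.8)
})

test_that("fluid-risk surface behaves per its generating formula", {
  # flat curvature: death independent of volumes
  cfg_flat <- generator_config(fluid_risk_curvature = 0, seed = 6)
  set.seed(6)
  fl <- generate_fluids_and_icu_death(rep("A", 20000), cfg_flat)
  hi <- fl$day1_ml > stats::median(fl$day1_ml)
  expect_lt(abs(mean(fl$icu_death[hi]) - mean(fl$icu_death[!hi])), 0.02)
  # at the exact optimum the death probability equals the class baseline
  cfg_opt <- generator_config(fluid_sd = 0, fluid_offset = 0, seed = 6)
  set.seed(6)
  fl2 <- generate_fluids_and_icu_death(rep("B", 20000), cfg_opt)
  expect_equal(unique(fl2$day1_ml), 4050)
  p <- unname(cfg_opt$baseline_icu_death["B"])
  expect_lt(abs(mean(fl2$icu_death) - p), 3 * sqrt(p * (1 - p) / 20000))
})

test_that("the empirical lowest-risk cell abuts the class-A optimum", {
  # brute-force empirical risk over 200-mL cells, against the generating
  # formula's own argmin as oracle
  cfg <- generator_config(seed = 8)
  set.seed(8)
  n <- 300000
  fl <- generate_fluids_and_icu_death(rep("A", n), cfg)
  b1 <- findInterval(fl$day1_ml, seq(0, 6000, 200))
  b2 <- findInterval(fl$day2_ml, seq(0, 6000, 200))
  agg <- stats::aggregate(icu_death ~ b1 + b2, data.frame(b1, b2,
                          icu_death = fl$icu_death), mean)
  counts <- stats::aggregate(icu_death ~ b1 + b2, data.frame(b1, b2,
                             icu_death = fl$icu_death), length)
  agg <- agg[counts$icu_death >= 500, ]
  emp <- agg[which.min(agg$icu_death), ]
  # oracle: expected risk per cell from the generating formula
  mids <- seq(100, 5900, 200)
  cv <- cfg$fluid_risk_curvature
  oracle <- outer(mids, mids, function(x1, x2) {
    e1 <- (x1 - 4200) / 1000; e2 <- (x2 - 3500) / 1000
    plogis(qlogis(0.125) + ifelse(e1 < 0, cv[["day1_below"]],
                                  cv[["day1_above"]]) * e1^2 +
             cv[["day2"]] * e2^2)
  })
  om <- which(oracle == min(oracle), arr.ind = TRUE)[1, ]
  expect_lte(abs(emp$b1 - om[1]), 1)
  expect_lte(abs(emp$b2 - om[2]), 1)
  # and the oracle minimum lies within the published day-1 low-risk zone
  expect_true(mids[om[1]] >= 4100 && mids[om[1]] <= 4300)
})

test_that("missingness injection is MCAR, seeded, and validated", {
  cfg <- generator_config(n_patients = 50, missing_rate = 0, seed = 3)
  co <- generate_cohort(cfg)
  expect_identical(inject_missingness(co$raw_vitals, 0), co$raw_vitals)
  thin1 <- inject_missingness(co$raw_vitals, 0.5, seed = 42)
  thin2 <- inject_missingness(co$raw_vitals, 0.5, seed = 42)
  expect_identical(thin1, thin2)
  # binomial 99% bounds on the number of dropped cells
  n_cells <- nrow(co$raw_vitals)
  dropped <- n_cells - nrow(thin1)
  bounds <- qbinom(c(0.005, 0.995), n_cells, 0.5)
  expect_gte(dropped, bounds[1])
  expect_lte(dropped, bounds[2])
  expect_error(inject_missingness(co$raw_vitals, 1), "missing_rate")
})
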