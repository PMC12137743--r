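tiny_grid <- expand.grid(num_trees = 100, max_depth = 0, min_node = 5)

test_that("CV AUROC is near chance for permuted labels and high for a rule", {
  set.seed(2)
  n <- 600
  feats <- tibble::tibble(age = rnorm(n, 50, 10),
                          day1_ml = runif(n, 0, 6000),
                          day2_ml = runif(n, 0, 6000))
  y_rule <- feats$day1_ml > 4000
  rf_rule <- fit_rf_per_phenotype(feats, y_rule, rep("A", n),
                                  grid = tiny_grid, seed = 1)
  expect_gte(rf_rule$models$A$cv_auroc, 0.98)
  y_perm <- sample(y_rule)
  rf_perm <- fit_rf_per_phenotype(feats, y_perm, rep("A", n),
                                  grid = tiny_grid, seed = 1)
  expect_lt(abs(rf_perm$models$A$cv_auroc - 0.5), 0.08)
})

test_that("few-death phenotypes are fit but flagged unreliable", {
  set.seed(3)
  n <- 80
  feats <- tibble::tibble(day1_ml = runif(n, 0, 6000),
                          day2_ml = runif(n, 0, 6000))
  y <- c(rep(TRUE, 5), rep(FALSE, n - 5))
  expect_warning(
    rf <- fit_rf_per_phenotype(feats, y, rep("A", n), grid = tiny_grid,
                               seed = 2),
    "unreliable")
  expect_false(rf$models$A$reliable)
})

test_that("partial dependence matches brute-force averaging", {
  feats <- tibble::tibble(age = c(40, 50, 60),
                          day1_ml = c(1000, 2000, 3000),
                          day2_ml = c(500, 1500, 2500))
  clf <- mock_clf(function(d) plogis(-2 + d$day1_ml / 3000 +
                                       d$day2_ml / 6000 - d$age / 100))
  surf <- pdp_2d(clf, feats, grid1 = seq(0, 300, 100),
                 grid2 = seq(0, 200, 100))
  for (i in 1:3) for (j in 1:2) {
    manual <- mean(plogis(-2 + surf$mid1[i] / 3000 + surf$mid2[j] / 6000 -
                            feats$age / 100))
    expect_equal(surf$pd[i, j], manual, tolerance = 1e-12)
  }
})

test_that("a fluid-blind model yields a flat PD surface", {
  set.seed(4)
  n <- 300
  feats <- tibble::tibble(age = rnorm(n, 50, 10),
                          wbc = rnorm(n, 12, 3),
                          day1_ml = runif(n, 0, 6000),
                          day2_ml = runif(n, 0, 6000))
  y <- factor(as.integer(feats$age + rnorm(n, 0, 5) > 50), c(0, 1))
  blind <- ranger::ranger(x = as.data.frame(feats[c("age", "wbc")]), y = y,
                          num.trees = 50, probability = TRUE, seed = 1,
                          num.threads = 1)
  surf <- pdp_2d(blind, feats[c("age", "wbc", "day1_ml", "day2_ml")],
                 grid1 = seq(0, 6000, 1000), grid2 = seq(0, 6000, 1000))
  expect_lt(diff(range(surf$pd)), 1e-12)
  expect_message(s2 <- risk_strata(surf), "single risk stratum")
  expect_error(lowest_risk_range(s2), "degenerate")
})

test_that("PD inherits monotonicity from a monotone single-feature model", {
  feats <- tibble::tibble(day1_ml = runif(50, 0, 6000),
                          day2_ml = runif(50, 0, 6000))
  clf <- mock_clf(function(d) plogis(d$day1_ml / 2000 - 1.5))
  surf <- pdp_2d(clf, feats)
  expect_true(all(diff(surf$pd[, 1]) > 0))
  expect_true(all(abs(surf$pd[1, ] - surf$pd[1, 1]) < 1e-12))
})

test_that("risk strata are decile cuts of the PD values", {
  surf <- structure(list(grid1 = seq(0, 1000, 100), grid2 = seq(0, 1000, 100),
                         mid1 = seq(50, 950, 100), mid2 = seq(50, 950, 100),
                         pd = matrix(seq(0.01, 1, 0.01), 10, 10),
                         strata = NULL, n_strata = NULL),
                    class = "pdp_surface")
  s <- risk_strata(surf, 10)
  expect_equal(as.integer(table(s$strata)), rep(10L, 10))
  expect_equal(s$strata[1, 1], 1L)
  expect_equal(s$strata[10, 10], 10L)
  # hand 3x3 grid, 3 strata
  surf3 <- structure(list(grid1 = 0:3 * 100, grid2 = 0:3 * 100,
                          mid1 = 1:3 * 100 - 50, mid2 = 1:3 * 100 - 50,
                          pd = matrix(c(.1, .2, .3, .4, .5, .6, .7, .8, .9),
                                      3, 3),
                          strata = NULL, n_strata = NULL),
                     class = "pdp_surface")
  s3 <- risk_strata(surf3, 3)
  expect_equal(as.vector(s3$strata), rep(1:3, each = 3))
})

test_that("lowest-risk range is the connected bottom component's box", {
  pd <- matrix(0.5, 5, 5)
  pd[2, 2] <- 0.01          # global minimum, singleton in stratum 1
  pd[4, 4] <- 0.02          # second low cell, not connected to the min
  pd[5, 1] <- 0.03
  surf <- structure(list(grid1 = 0:5 * 100, grid2 = 0:5 * 100,
                         mid1 = 1:5 * 100 - 50, mid2 = 1:5 * 100 - 50,
                         pd = pd, strata = NULL, n_strata = NULL),
                    class = "pdp_surface")
  rng <- lowest_risk_range(risk_strata(surf, 5))
  expect_equal(rng$day1_lo, 100)
  expect_equal(rng$day1_hi, 200)
  expect_equal(rng$day2_lo, 100)
  expect_equal(rng$day2_hi, 200)
  expect_equal(rng$n_cells, 1L)
})

test_that("recovered fluid ranges track the generating optimum", {
  # class-D bowl at (3300, 2000): the recovered day-1 box must cover it
  cfg <- generator_config(seed = 19)
  set.seed(19)
  n <- 1500
  fl <- generate_fluids_and_icu_death(rep("D", n), cfg)
  feats <- tibble::tibble(age = rnorm(n, 47, 12),
                          day1_ml = fl$day1_ml, day2_ml = fl$day2_ml)
  rf <- fit_rf_per_phenotype(feats, fl$icu_death, rep("D", n),
                             grid = expand.grid(num_trees = 200,
                                                max_depth = 0,
                                                min_node = 10),
                             seed = 5)
  surf <- risk_strata(pdp_2d(rf$models$D, feats, background = 100, seed = 5))
  rng <- lowest_risk_range(surf)
  expect_lte(rng$day1_lo, 3300)
  expect_gte(rng$day1_hi, 3300)
  expect_gt(rng$day1_lo, 2000)    # box sits near the optimum, not at 0
})

test_that("AUROC is invariant to monotone transforms and matches pROC", {
  set.seed(6)
  y <- rbinom(200, 1, 0.3)
  p <- runif(200)
  a1 <- trajphen:::auroc(y, p)
  expect_equal(trajphen:::auroc(y, qlogis(p)), a1, tolerance = 1e-12)
  expect_equal(trajphen:::auroc(y, p^3), a1, tolerance = 1e-12)
  expect_equal(roc_auc(y, p), a1, tolerance = 1e-12)
})

test_that("Ringer's contrast is null when assigned independently", {
  cfg <- generator_config(seed = 23)
  set.seed(23)
  labs <- rep(c("B", "C"), each = 3000)
  fl <- generate_fluids_and_icu_death(labs, cfg)
  # survival WITHOUT the Ringer effect: independent of receipt
  s <- generate_survival(labs, cfg)
  s$ringer <- fl$ringer
  rep <- ringer_cox(s, covariates = c("age", "gender"))
  expect_true(all(rep$conf_low <= 1 & 1 <= rep$conf_high))
  # with the effect switched on in class C only, B's CI still covers 1
  set.seed(23)
  s2 <- generate_survival(labs, cfg, ringer = fl$ringer)
  s2$ringer <- fl$ringer
  rep2 <- ringer_cox(s2, covariates = c("age", "gender"))
  b <- rep2[rep2$phenotype == "B", ]
  expect_true(b$conf_low <= 1 & 1 <= b$conf_high)
  expect_lt(rep2$HR[rep2$phenotype == "C"], 1)
})
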