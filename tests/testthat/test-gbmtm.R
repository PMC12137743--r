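test_that("K = 1 degenerates to pooled per-channel least squares", {
  set.seed(2)
  df <- complete_vitals(8, value_fn = function(i, h, c)
    c + 0.3 * h + rnorm(1, sd = 0.2))
  panel <- filter_complete_hours(hourly_aggregate(df))
  panel$standardized <- TRUE   # treat as already scaled for this check
  fit <- fit_gbmtm(panel, K = 1, order = 1, seed = 1)
  expect_equal(fit$mixing, 1)
  # oracle: ordinary least squares on the pooled long data per channel
  long <- tidy(panel)
  for (ci in 1:5) {
    sub <- long[long$channel == CH[ci], ]
    ols <- coef(lm(value ~ I(hour / 11), data = sub))
    expect_equal(unname(fit$coeffs[1, ci, ]), unname(ols),
                 tolerance = 1e-8)
  }
})

test_that("the E-step matches a brute-force Bayes computation", {
  df <- complete_vitals(1, hours = 0:1, value_fn = function(i, h, c) 0.5)
  panel <- filter_complete_hours(hourly_aggregate(df))
  panel$standardized <- TRUE
  model <- list(K = 2, order = 0,
                coeffs = array(rep(c(0, 1), 5), c(2, 5, 1)),  # mu 0 vs 1
                resid_var = matrix(c(1, 0.5), 2, 5),
                mixing = c(0.3, 0.7))
  tau <- e_step(model, panel)
  # oracle: direct product of normal densities over the 10 observed cells
  lik <- function(mu, s2) prod(dnorm(0.5, mu, sqrt(s2))^10)
  w <- c(0.3 * lik(0, 1), 0.7 * lik(1, 0.5))
  expect_equal(unname(tau[1, ]), w / sum(w), tolerance = 1e-12)
  # degenerate mixing puts all posterior on the supported class
  model$mixing <- c(1, 0)
  expect_equal(unname(e_step(model, panel)[1, ]), c(1, 0))
  # two identical classes split the posterior evenly
  model$mixing <- c(0.5, 0.5)
  model$coeffs[2, , 1] <- 0
  model$resid_var[2, ] <- 1
  expect_equal(unname(e_step(model, panel)[1, ]), c(0.5, 0.5))
})

test_that("the M-step solves tau-weighted least squares", {
  # three exact-line points per channel: closed-form fit, order 1
  df <- complete_vitals(1, hours = 0:2, value_fn = function(i, h, c)
    2 + 3 * (h / 11))
  panel <- filter_complete_hours(hourly_aggregate(df))
  panel$standardized <- TRUE
  par1 <- m_step(panel, matrix(1, 1, 1), order = 1)
  expect_equal(unname(par1$coeffs[1, 1, ]), c(2, 3), tolerance = 1e-10)
  # uniform posteriors with K = 2 give two identical classes
  par2 <- m_step(panel, matrix(0.5, 1, 2), order = 1)
  expect_equal(par2$coeffs[1, , ], par2$coeffs[2, , ])
  expect_equal(par2$mixing, c(0.5, 0.5))
})

test_that("zero-noise four-template cohorts are recovered exactly", {
  panel <- template_panel(8, noise_sd = 0)
  fit <- fit_gbmtm(panel, K = 4, order = 2, n_restarts = 3, seed = 1)
  lab <- assign_modal(fit$posterior, quiet = TRUE)
  expect_equal(ari(lab, template_truth(panel)), 1)
  # recovered coefficients match the generating templates up to class order
  tpl <- default_class_templates()
  for (k in 1:4) {
    truth_k <- template_truth(panel)[which(lab == k)[1]]
    expect_equal(fit$coeffs[k, , ], unname(tpl[truth_k, , ]),
                 tolerance = 1e-6)
  }
})

test_that("EM log-likelihood trace is non-decreasing", {
  panel <- template_panel(10, noise_sd = 0.8, seed = 3)
  fit <- fit_gbmtm(panel, K = 3, order = 2, n_restarts = 2, seed = 5)
  expect_true(all(diff(fit$loglik_trace) > -1e-8 * abs(fit$loglik)))
  expect_true(all(abs(rowSums(fit$posterior) - 1) < 1e-10))
  expect_true(all(fit$resid_var > 0))
  expect_equal(sum(fit$mixing), 1, tolerance = 1e-10)
})

test_that("parameters are recovered under realistic noise", {
  cfg <- generator_config(n_patients = 2000, seed = 12)
  co <- generate_cohort(cfg)
  prep <- prepare_trajectories(co$raw_vitals, co$baseline)
  fit <- fit_gbmtm(prep$panel, K = 4, n_restarts = 10, seed = 2)
  lab <- assign_modal(fit$posterior, quiet = TRUE)
  truth <- co$truth_labels$phenotype[match(prep$panel$patient_id,
                                           co$truth_labels$patient_id)]
  expect_gte(ari(lab, truth), 0.95)
  # mixing proportions within 0.03 elementwise, after matching classes
  map <- match_template_classes(fit, cfg, prep$panel$stats)
  pi_hat <- setNames(fit$mixing, map)[c("A", "B", "C", "D")]
  expect_true(all(abs(pi_hat - cfg$class_proportions) <= 0.03))
})

test_that("information criteria follow their definitions", {
  panel <- template_panel(4, noise_sd = 0.1, seed = 9)
  fit <- fit_gbmtm(panel, K = 2, order = 1, n_restarts = 2, seed = 3)
  N <- n_patients(panel)
  ic <- information_criteria(fit)
  expect_equal(ic$AIC, -2 * fit$loglik + 2 * fit$n_params)
  expect_equal(ic$BIC, -2 * fit$loglik + fit$n_params * log(N))
  # hard posteriors: zero entropy, ICL = BIC, normalised entropy 1
  hard <- matrix(0, N, 2); hard[, 1] <- 1
  ich <- information_criteria(fit, tau = hard)
  expect_equal(ich$ICL, ich$BIC)
  expect_equal(ich$entropy, 1)
  # uniform posteriors: normalised entropy 0
  unif <- matrix(0.5, N, 2)
  expect_equal(information_criteria(fit, tau = unif)$entropy, 0)
})

test_that("modal assignment breaks ties toward the lowest class index", {
  tau <- rbind(c(0.7, 0.1, 0.1, 0.1), c(0.25, 0.25, 0.25, 0.25))
  expect_message(lab <- assign_modal(tau), "tie")
  expect_equal(lab, c(1L, 1L))
  # permutation equivariance: relabeling classes permutes assignments
  tau2 <- matrix(runif(40), 10, 4)
  tau2 <- tau2 / rowSums(tau2)
  perm <- c(3, 1, 4, 2)
  a <- assign_modal(tau2, quiet = TRUE)
  b <- assign_modal(tau2[, perm], quiet = TRUE)
  expect_equal(perm[b], a)
})

test_that("class mean curves evaluate the fitted polynomial", {
  panel <- template_panel(4, noise_sd = 0.2, seed = 4)
  fit <- fit_gbmtm(panel, K = 2, order = 3, n_restarts = 2, seed = 6)
  hours <- c(0, 2.5, 7, 11)
  cur <- class_mean_curve(fit, 1, "HR", hours)
  naive <- vapply(hours, function(h)
    sum(fit$coeffs[1, 3, ] * (h / 11)^(0:3)), numeric(1))
  expect_equal(cur$value, naive, tolerance = 1e-12)
  expect_warning(class_mean_curve(fit, 1, "HR", 13), "outside")
  expect_error(class_mean_curve(fit, 5, "HR"), "exceeds")
  # serialisation round trip preserves curves
  path <- withr::local_tempfile(fileext = ".json")
  write_gbmtm(fit, path)
  fit2 <- read_gbmtm(path)
  expect_equal(class_mean_curve(fit2, 1, "HR", hours)$value, cur$value,
               tolerance = 1e-12)
})
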