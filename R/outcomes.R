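# Descriptive and prognostic comparison of subphenotypes: "Table 1"-style
# summaries, Kruskal-Wallis / chi-square group tests, Pearson correlation
# with one-hot phenotype indicators, crude/adjusted Cox contrasts with a
# chosen reference class, direct-adjusted Kaplan-Meier curves, and
# per-phenotype comorbidity Cox models.

fmt1 <- function(x) sprintf("%.1f", x)

#' Describe baseline variables by phenotype
#'
#' Continuous variables are summarised as `median (Q1, Q3)`; categorical
#' (character, factor or logical) variables as `n (%)` with the phenotype
#' size as denominator.
#'
#' @param baseline Data frame with `patient_id` and baseline variables.
#' @param labels Data frame with `patient_id` and `phenotype`, or a
#'   vector aligned with `baseline`.
#' @param variables Variables to summarise (default: all except
#'   `patient_id`).
#' @return A tibble with `variable`, `level` (for categorical), one
#'   formatted column per phenotype, and `n_missing`.
#' @export
describe_by_phenotype <- function(baseline, labels,
                                  variables = NULL) {
  df <- join_labels(baseline, labels)
  variables <- variables %||%
    setdiff(names(baseline), c("patient_id", "phenotype"))
  phen <- sort(unique(df$phenotype))
  rows <- purrr::map_dfr(variables, function(v) {
    x <- df[[v]]
    if (all(is.na(x))) {
      return(tibble::tibble(variable = v, level = NA_character_,
                            !!!setNames(as.list(rep(NA_character_,
                                                    length(phen))), phen),
                            n_missing = sum(is.na(x))))
    }
    if (is.numeric(x)) {
      vals <- vapply(phen, function(p) {
        xi <- x[df$phenotype == p & !is.na(x)]
        q <- quantile(xi, c(0.25, 0.5, 0.75), names = FALSE)
        sprintf("%s (%s, %s)", fmt1(q[2]), fmt1(q[1]), fmt1(q[3]))
      }, character(1))
      tibble::tibble(variable = v, level = NA_character_,
                     !!!setNames(as.list(vals), phen),
                     n_missing = sum(is.na(x)))
    } else {
      x <- as.factor(x)
      purrr::map_dfr(levels(x), function(lv) {
        vals <- vapply(phen, function(p) {
          in_p <- df$phenotype == p
          n <- sum(x[in_p] == lv, na.rm = TRUE)
          sprintf("%d (%s)", n, fmt1(100 * n / sum(in_p & !is.na(x))))
        }, character(1))
        tibble::tibble(variable = v, level = lv,
                       !!!setNames(as.list(vals), phen),
                       n_missing = sum(is.na(x)))
      })
    }
  })
  rows
}

#' Compare baseline variables across phenotypes
#'
#' Kruskal-Wallis tests for continuous variables; Pearson chi-square
#' tests without continuity correction for categorical variables.
#' Low-expected-count warnings are captured into the `note` column.
#'
#' @inheritParams describe_by_phenotype
#' @return A tibble with `variable`, `test`, `statistic`, `p_value`,
#'   `note`.
#' @export
compare_groups <- function(baseline, labels, variables = NULL) {
  df <- join_labels(baseline, labels)
  variables <- variables %||%
    setdiff(names(baseline), c("patient_id", "phenotype"))
  purrr::map_dfr(variables, function(v) {
    x <- df[[v]]
    ok <- !is.na(x) & !is.na(df$phenotype)
    g <- factor(df$phenotype[ok])
    if (nlevels(droplevels(g)) < 2 || !sum(ok)) {
      return(tibble::tibble(variable = v, test = NA_character_,
                            statistic = NA_real_, p_value = NA_real_,
                            note = "fewer than 2 non-empty groups"))
    }
    if (is.numeric(x)) {
      kt <- kruskal.test(x[ok], g)
      tibble::tibble(variable = v, test = "kruskal-wallis",
                     statistic = unname(kt$statistic),
                     p_value = kt$p.value, note = NA_character_)
    } else {
      note <- NA_character_
      ct <- withCallingHandlers(
        chisq.test(table(x[ok], g), correct = FALSE),
        warning = function(w) {
          note <<- conditionMessage(w)
          invokeRestart("muffleWarning")
        })
      tibble::tibble(variable = v, test = "chi-square",
                     statistic = unname(ct$statistic),
                     p_value = ct$p.value, note = note)
    }
  })
}

#' Pearson correlations between variables and phenotype indicators
#'
#' Continuous baseline variables plus one-hot phenotype indicator columns
#' are correlated pairwise on complete pairs. Zero-variance columns give
#' `NA` correlations.
#'
#' @inheritParams describe_by_phenotype
#' @return A correlation matrix (variables + `phenotype_X` indicators).
#' @export
correlation_matrix <- function(baseline, labels, variables = NULL) {
  df <- join_labels(baseline, labels)
  variables <- variables %||%
    setdiff(names(baseline), c("patient_id", "phenotype"))
  num_vars <- variables[vapply(df[variables], is.numeric, logical(1))]
  mat <- as.matrix(df[num_vars])
  for (p in sort(unique(df$phenotype))) {
    mat <- cbind(mat, as.numeric(df$phenotype == p))
    colnames(mat)[ncol(mat)] <- paste0("phenotype_", p)
  }
  suppressWarnings(cor(mat, use = "pairwise.complete.obs"))
}

#' Cox proportional-hazards contrasts between subphenotypes
#'
#' Fits a partial-likelihood Cox model (Efron tie handling) of 30-day
#' mortality on phenotype, with class `reference` as the baseline level.
#' When `covariates` are supplied the model is adjusted; constant
#' covariates (e.g. a single-race cohort) are dropped with a message.
#'
#' @param records Data frame with `time`, `event`, `phenotype` and any
#'   covariate columns.
#' @param covariates Character vector of adjustment covariates (empty for
#'   a crude model).
#' @param reference Reference phenotype (default `"B"`).
#' @return A `cox_report` tibble: one row per contrast with `term`,
#'   `HR`, `conf_low`, `conf_high`, `p_value`, `model`.
#' @export
fit_cox <- function(records, covariates = character(0), reference = "B") {
  records <- tibble::as_tibble(records)
  if (!any(records$event)) abort("no events: Cox model cannot be fit")
  records$phenotype <- stats::relevel(factor(records$phenotype),
                                      ref = reference)
  covariates <- drop_constant_covariates(records, covariates)
  fml <- stats::reformulate(c("phenotype", covariates),
                            response = "survival::Surv(time, event)")
  fit <- survival::coxph(fml, data = records, ties = "efron")
  model_type <- if (length(covariates)) "adjusted" else "crude"
  cox_report(fit, model = model_type, reference = reference)
}

drop_constant_covariates <- function(df, covariates) {
  keep <- vapply(covariates, function(v) {
    length(unique(df[[v]][!is.na(df[[v]])])) > 1
  }, logical(1))
  if (any(!keep)) {
    inform(paste("dropping constant covariate(s):",
                 paste(covariates[!keep], collapse = ", ")))
  }
  covariates[keep]
}

# tidy a coxph fit into the package's report shape
cox_report <- function(fit, model, reference = NA_character_) {
  s <- summary(fit)
  co <- s$coefficients
  ci <- s$conf.int
  unstable <- any(abs(co[, "coef"]) > 10)
  if (unstable) warn("possible separation: extreme Cox coefficients")
  tibble::tibble(
    term = rownames(co),
    HR = unname(co[, "exp(coef)"]),
    conf_low = unname(ci[, "lower .95"]),
    conf_high = unname(ci[, "upper .95"]),
    p_value = unname(co[, ncol(co)]),
    model = model,
    reference = reference)
}

#' Direct-adjusted (corrected group prognosis) survival curves
#'
#' Fits a Cox model of survival on phenotype plus covariates, then
#' averages each patient's predicted survival curve over the pooled
#' covariate distribution with phenotype set to each class in turn:
#' `S_adj_k(t) = mean_i exp(-H0(t) * exp(lp(x_i, phenotype = k)))`.
#'
#' @inheritParams fit_cox
#' @param covariates Adjustment covariates (default age, gender, race).
#' @return An object of class `adjusted_km`: a tibble of step functions
#'   with `phenotype`, `time`, `surv`.
#' @export
adjusted_km <- function(records,
                        covariates = c("age", "gender", "race"),
                        reference = "B") {
  records <- tibble::as_tibble(records)
  if (!any(records$event)) abort("no events: Cox model cannot be fit")
  records$phenotype <- stats::relevel(factor(records$phenotype),
                                      ref = reference)
  covariates <- drop_constant_covariates(records, covariates)
  fml <- stats::reformulate(c("phenotype", covariates),
                            response = "survival::Surv(time, event)")
  fit <- survival::coxph(fml, data = records, ties = "efron")
  bh <- survival::basehaz(fit, centered = FALSE)
  phen <- levels(records$phenotype)
  curves <- purrr::map_dfr(phen, function(p) {
    nd <- records
    nd$phenotype <- factor(p, levels = phen)
    lp <- predict(fit, newdata = nd, type = "lp", reference = "zero")
    surv <- vapply(bh$hazard, function(h0) mean(exp(-h0 * exp(lp))),
                   numeric(1))
    tibble::tibble(phenotype = p,
                   time = c(0, bh$time), surv = c(1, surv))
  })
  structure(curves, class = c("adjusted_km", class(curves)))
}

#' Plot adjusted survival curves
#' @param object An `adjusted_km`.
#' @param ... Unused.
#' @return A ggplot of step survival curves per phenotype.
#' @export
autoplot.adjusted_km <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$time, .data$surv,
                                       colour = .data$phenotype)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Days since ICU admission",
                  y = "Adjusted survival", colour = "Phenotype")
}

#' Per-phenotype multivariate Cox models of comorbidity burden
#'
#' Comorbidities with prevalence strictly above `prevalence_min` in the
#' analysis cohort enter one multivariate Cox model per phenotype
#' stratum; strata without events are skipped with a note.
#'
#' @param records Survival records with `phenotype` and logical/0-1
#'   comorbidity columns.
#' @param comorbidities Character vector of comorbidity column names.
#' @param prevalence_min Inclusion threshold (default 0.05, strict).
#' @return A tibble of per-phenotype `cox_report` rows plus a `phenotype`
#'   column; skipped strata appear with `note`.
#' @export
comorbidity_cox <- function(records, comorbidities, prevalence_min = 0.05) {
  records <- tibble::as_tibble(records)
  prev <- vapply(comorbidities,
                 function(v) mean(as.numeric(records[[v]]), na.rm = TRUE),
                 numeric(1))
  keep <- comorbidities[prev > prevalence_min]
  if (!length(keep)) abort("no comorbidity exceeds the prevalence threshold")
  purrr::map_dfr(sort(unique(records$phenotype)), function(p) {
    sub <- records[records$phenotype == p, ]
    if (!any(sub$event)) {
      return(tibble::tibble(phenotype = p, term = NA_character_,
                            HR = NA_real_, conf_low = NA_real_,
                            conf_high = NA_real_, p_value = NA_real_,
                            model = "multivariate",
                            note = "no events in stratum"))
    }
    fml <- stats::reformulate(keep,
                              response = "survival::Surv(time, event)")
    fit <- survival::coxph(fml, data = sub, ties = "efron")
    dplyr::mutate(cox_report(fit, model = "multivariate"),
                  phenotype = p, note = NA_character_,
                  .before = 1)
  })
}

# join a labels table (patient_id, phenotype) or aligned vector onto a
# baseline data frame
join_labels <- function(baseline, labels) {
  baseline <- tibble::as_tibble(baseline)
  if (is.data.frame(labels)) {
    dplyr::inner_join(baseline,
                      dplyr::select(tibble::as_tibble(labels),
                                    "patient_id", "phenotype"),
                      by = "patient_id")
  } else {
    stopifnot(length(labels) == nrow(baseline))
    dplyr::mutate(baseline, phenotype = as.character(labels))
  }
}
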