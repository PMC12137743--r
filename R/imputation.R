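# Missing-data policy for the feature table: report per-variable missing
# rates, drop variables with rates strictly above 20%, then impute with a
# four-method ensemble (mean substitution and chained-equations passes of
# CART, random forest and lasso regression) averaged into one completed
# dataset.

#' Per-variable missingness report
#'
#' @param table A data frame (a `patient_id` column, if present, is
#'   reported but never dropped).
#' @param max_rate Retention threshold: variables are retained when the
#'   missing rate is less than or equal to `max_rate` (the exclusion rule
#'   "over 20%" is strict; default 0.20).
#' @return A tibble with `variable`, `n_missing`, `missing_rate`,
#'   `retained`.
#' @export
missing_report <- function(table, max_rate = 0.20) {
  table <- tibble::as_tibble(table)
  purrr::map_dfr(names(table), function(v) {
    nm <- sum(is.na(table[[v]]))
    rate <- nm / nrow(table)
    tibble::tibble(variable = v, n_missing = nm, missing_rate = rate,
                   retained = v == "patient_id" || rate <= max_rate)
  })
}

#' Drop variables above the missing-rate threshold
#' @inheritParams missing_report
#' @return The table restricted to retained variables.
#' @export
drop_high_missing <- function(table, max_rate = 0.20) {
  rep <- missing_report(table, max_rate)
  tibble::as_tibble(table)[, rep$variable[rep$retained], drop = FALSE]
}

#' Four-method ensemble imputation
#'
#' Each method produces one completed dataset: `mean` substitutes the
#' column mean (mode for categorical variables); `cart`, `rf` and
#' `lasso_norm` run single-imputation chained equations (variable by
#' variable, `n_iter` sweeps, mean/mode initialisation) with a regression
#' tree, a random forest, or a lasso-regularised linear model as the
#' per-variable learner. The completed datasets are combined cell-wise:
#' continuous cells by arithmetic mean, categorical cells by majority
#' vote with ties broken by method order as listed. Observed cells are
#' never modified.
#'
#' @param table A data frame with missing values (high-missing variables
#'   already dropped; a variable that is entirely missing is an error).
#' @param methods Subset of `c("mean", "cart", "rf", "lasso_norm")`.
#' @param n_iter Chained-equation sweeps (default 5).
#' @param seed Integer seed (stochastic methods are deterministic given
#'   it).
#' @return The completed tibble, with the per-method completions in the
#'   `completions` attribute.
#' @export
impute_ensemble <- function(table,
                            methods = c("mean", "cart", "rf", "lasso_norm"),
                            n_iter = 5, seed = 11L) {
  methods <- match.arg(methods, several.ok = TRUE)
  table <- tibble::as_tibble(table)
  id <- table[["patient_id"]]
  work <- table[setdiff(names(table), "patient_id")]
  all_na <- names(work)[vapply(work, function(x) all(is.na(x)), logical(1))]
  if (length(all_na)) {
    abort(paste("variable(s) entirely missing (should have been dropped):",
                paste(all_na, collapse = ", ")))
  }
  chr <- names(work)[vapply(work, is.character, logical(1))]
  for (v in chr) work[[v]] <- factor(work[[v]])

  completions <- purrr::map(methods, function(m) {
    set.seed(as.integer(seed))
    switch(m,
           mean = impute_mean(work),
           cart = impute_chained(work, n_iter, learner = "cart"),
           rf = impute_chained(work, n_iter, learner = "rf"),
           lasso_norm = impute_chained(work, n_iter, learner = "lasso"))
  })
  names(completions) <- methods

  out <- work
  for (v in names(work)) {
    miss <- is.na(work[[v]])
    if (!any(miss)) next
    vals <- lapply(completions, function(d) d[[v]][miss])
    if (is.numeric(work[[v]])) {
      out[[v]][miss] <- Reduce(`+`, vals) / length(vals)
    } else {
      out[[v]][miss] <- majority_vote(vals)
    }
  }
  for (v in chr) out[[v]] <- as.character(out[[v]])
  if (!is.null(id)) out <- dplyr::bind_cols(tibble::tibble(patient_id = id), out)
  completions <- purrr::map(completions, function(d) {
    for (v in chr) d[[v]] <- as.character(d[[v]])
    d
  })
  attr(out, "completions") <- completions
  out
}

# cell-wise majority vote across per-method factor imputations; ties go
# to the method listed first among the tied values
majority_vote <- function(vals) {
  m <- do.call(cbind, lapply(vals, as.character))
  apply(m, 1, function(row) {
    tab <- table(row)
    winners <- names(tab)[tab == max(tab)]
    row[row %in% winners][1]
  })
}

impute_mean <- function(df) {
  for (v in names(df)) {
    miss <- is.na(df[[v]])
    if (!any(miss)) next
    if (is.numeric(df[[v]])) {
      df[[v]][miss] <- mean(df[[v]][!miss])
    } else {
      tab <- table(df[[v]][!miss])
      df[[v]][miss] <- names(tab)[which.max(tab)]
    }
  }
  df
}

impute_chained <- function(df, n_iter, learner) {
  miss <- lapply(df, is.na)
  filled <- impute_mean(df)
  targets <- names(df)[vapply(miss, any, logical(1))]
  if (!length(targets)) return(df)
  for (it in seq_len(n_iter)) {
    for (v in targets) {
      others <- setdiff(names(df), v)
      train <- !miss[[v]]
      pred <- switch(
        learner,
        cart = fit_predict_cart(filled, v, others, train, miss[[v]]),
        rf = fit_predict_rf(filled, v, others, train, miss[[v]]),
        lasso = fit_predict_lasso(filled, v, others, train, miss[[v]]))
      filled[[v]][miss[[v]]] <- pred
    }
  }
  filled
}

fit_predict_cart <- function(df, v, others, train, need) {
  fml <- stats::reformulate(others, response = v)
  method <- if (is.numeric(df[[v]])) "anova" else "class"
  fit <- rpart::rpart(fml, data = df[train, ], method = method,
                      control = rpart::rpart.control(cp = 0.001,
                                                     minsplit = 10))
  p <- predict(fit, newdata = df[need, , drop = FALSE])
  if (method == "class") {
    factor(colnames(p)[max.col(p)], levels = levels(df[[v]]))
  } else as.numeric(p)
}

fit_predict_rf <- function(df, v, others, train, need) {
  x <- as.data.frame(df[train, others, drop = FALSE])
  fit <- ranger::ranger(x = x, y = df[[v]][train], num.trees = 100,
                        seed = sample.int(2^30, 1), num.threads = 1)
  predict(fit, data = as.data.frame(df[need, others, drop = FALSE]),
          num.threads = 1)$predictions
}

fit_predict_lasso <- function(df, v, others, train, need) {
  mm <- stats::model.matrix(~ . - 1, data = df[others])
  y <- df[[v]]
  if (is.numeric(y)) {
    fit <- glmnet::cv.glmnet(mm[train, , drop = FALSE], y[train],
                             family = "gaussian", nfolds = 5)
    as.numeric(predict(fit, newx = mm[need, , drop = FALSE],
                       s = "lambda.min"))
  } else {
    if (nlevels(droplevels(y[train])) < 2) {
      return(rep(levels(y)[which.max(table(y[train]))], sum(need)))
    }
    fit <- glmnet::cv.glmnet(mm[train, , drop = FALSE],
                             droplevels(y[train]),
                             family = if (nlevels(droplevels(y[train])) == 2)
                               "binomial" else "multinomial",
                             nfolds = 5)
    cls <- as.character(predict(fit, newx = mm[need, , drop = FALSE],
                                s = "lambda.min", type = "class"))
    factor(cls, levels = levels(y))
  }
}
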