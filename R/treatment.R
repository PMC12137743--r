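# Phenotype-specific fluid-resuscitation response: per-phenotype random
# forest ICU-death classifiers (5-fold CV over a small hyperparameter
# grid, AUROC metric), two-predictor partial dependence over the day-1 x
# day-2 fluid grid, decile risk stratification, and the lowest-risk fluid
# range as the connected bottom-stratum region around the global minimum.

default_rf_grid <- function() {
  expand.grid(num_trees = c(200, 500), max_depth = c(0, 6, 10),
              min_node = c(1, 5, 20))
}

#' Fit per-phenotype random-forest ICU-death classifiers
#'
#' For each phenotype, selects random-forest hyperparameters by
#' stratified 5-fold cross-validation maximising mean AUROC, then refits
#' on the phenotype's full data. Phenotypes with fewer than 10 deaths
#' are still fit but flagged unreliable.
#'
#' @param features Data frame of predictors including `day1_ml` and
#'   `day2_ml` plus clinical characteristics (and `patient_id`, ignored
#'   as a predictor).
#' @param icu_death Logical/0-1 outcome vector aligned with `features`.
#' @param labels Phenotype vector aligned with `features`.
#' @param cv_folds Number of CV folds (default 5).
#' @param grid Hyperparameter grid (columns `num_trees`, `max_depth`
#'   with 0 meaning unlimited, `min_node`); defaults to a small grid of
#'   2 x 3 x 3 settings.
#' @param seed Integer seed.
#' @return An object of class `rf_phenotype_models`: per-phenotype list
#'   with `model` (a `ranger` probability forest), `cv_auroc`,
#'   `hyperparameters`, `reliable`, plus the feature names.
#' @export
fit_rf_per_phenotype <- function(features, icu_death, labels,
                                 cv_folds = 5, grid = default_rf_grid(),
                                 seed = 3L) {
  features <- tibble::as_tibble(features)
  stopifnot(nrow(features) == length(icu_death),
            nrow(features) == length(labels))
  if (!all(c("day1_ml", "day2_ml") %in% names(features))) {
    abort("features must include day1_ml and day2_ml")
  }
  pred_cols <- setdiff(names(features), "patient_id")
  y <- as.integer(icu_death)
  set.seed(as.integer(seed))
  phen <- sort(unique(as.character(labels)))
  models <- purrr::map(phen, function(p) {
    idx <- which(labels == p)
    xf <- as.data.frame(features[idx, pred_cols])
    yp <- y[idx]
    reliable <- sum(yp) >= 10
    if (!reliable) {
      warn(sprintf("phenotype %s: fewer than 10 deaths; model flagged unreliable", p))
    }
    folds <- stratified_folds(yp, cv_folds)
    cv <- purrr::map_dbl(seq_len(nrow(grid)), function(g) {
      mean(purrr::map_dbl(seq_len(cv_folds), function(f) {
        tr <- folds != f
        if (length(unique(yp[tr])) < 2 || length(unique(yp[!tr])) < 2) {
          return(NA_real_)
        }
        fit <- ranger_fit(xf[tr, , drop = FALSE], yp[tr], grid[g, ],
                          seed = sample.int(2^30, 1))
        pr <- predict(fit, data = xf[!tr, , drop = FALSE],
                      num.threads = 1)$predictions[, "1"]
        auroc(yp[!tr], pr)
      }), na.rm = TRUE)
    })
    best <- which.max(cv)
    final <- ranger_fit(xf, yp, grid[best, ], seed = sample.int(2^30, 1))
    list(phenotype = p, model = final, cv_auroc = cv[best],
         hyperparameters = grid[best, ], reliable = reliable,
         n = length(idx), n_deaths = sum(yp))
  })
  structure(list(models = setNames(models, phen), features = pred_cols),
            class = "rf_phenotype_models")
}

ranger_fit <- function(x, y, hp, seed) {
  ranger::ranger(
    x = x, y = factor(y, levels = c(0, 1)),
    num.trees = hp$num_trees,
    max.depth = if (hp$max_depth == 0) NULL else hp$max_depth,
    min.node.size = hp$min_node,
    probability = TRUE, seed = seed, num.threads = 1)
}

stratified_folds <- function(y, k) {
  folds <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    folds[idx] <- sample(rep(seq_len(k), length.out = length(idx)))
  }
  folds
}

# AUROC via the rank statistic (pROC used for the reported metric in
# summaries; this internal version avoids per-fold object overhead)
auroc <- function(y, score) {
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(score)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' CV performance summary for per-phenotype classifiers
#' @param x An `rf_phenotype_models`.
#' @param ... Unused.
#' @return A tibble with one row per phenotype.
#' @export
glance.rf_phenotype_models <- function(x, ...) {
  purrr::map_dfr(x$models, function(m) {
    tibble::tibble(phenotype = m$phenotype, n = m$n, n_deaths = m$n_deaths,
                   cv_auroc = m$cv_auroc, reliable = m$reliable,
                   num_trees = m$hyperparameters$num_trees,
                   max_depth = m$hyperparameters$max_depth,
                   min_node = m$hyperparameters$min_node)
  })
}

#' Two-predictor partial dependence over the fluid grid
#'
#' `PD(x1, x2)` is the mean predicted ICU-death probability over cohort
#' members when `day1_ml` is set to `x1` and `day2_ml` to `x2`, all other
#' features kept at their jointly observed values (true partial
#' dependence). Grid cells are 100 mL wide by default (0-6000 mL) and PD
#' is evaluated at cell midpoints.
#'
#' @param classifier A `ranger` probability forest or one element of
#'   [fit_rf_per_phenotype()] output (`$model` is used).
#' @param features Cohort feature data frame (background distribution).
#' @param grid1,grid2 Cell edges in mL (default `seq(0, 6000, 100)`).
#' @param background Number of cohort rows used for PD averaging; the
#'   default `Inf` uses all rows.
#' @param seed Seed for background subsampling.
#' @return An object of class `pdp_surface`: `grid1`, `grid2` (edges),
#'   `pd` matrix (`length(grid1) - 1` x `length(grid2) - 1`) and the
#'   midpoints.
#' @export
pdp_2d <- function(classifier, features, grid1 = seq(0, 6000, 100),
                   grid2 = seq(0, 6000, 100), background = Inf,
                   seed = 1L) {
  if (is.list(classifier) && !inherits(classifier, "ranger") &&
      !is.null(classifier$model)) {
    classifier <- classifier$model
  }
  features <- as.data.frame(features)
  features$patient_id <- NULL
  if (!nrow(features)) abort("empty cohort")
  if (is.finite(background) && background < nrow(features)) {
    set.seed(as.integer(seed))
    features <- features[sample.int(nrow(features), background), ,
                         drop = FALSE]
  }
  mid1 <- (head(grid1, -1) + grid1[-1]) / 2
  mid2 <- (head(grid2, -1) + grid2[-1]) / 2
  nb <- nrow(features)
  pd <- matrix(NA_real_, length(mid1), length(mid2))
  # evaluate one day-2 column at a time: nb * length(mid1) rows per batch
  for (j in seq_along(mid2)) {
    batch <- features[rep(seq_len(nb), times = length(mid1)), , drop = FALSE]
    batch$day1_ml <- rep(mid1, each = nb)
    batch$day2_ml <- mid2[j]
    pr <- predict(classifier, data = batch,
                  num.threads = 1)$predictions[, "1"]
    pd[, j] <- colMeans(matrix(pr, nb, length(mid1)))
  }
  structure(list(grid1 = grid1, grid2 = grid2, mid1 = mid1, mid2 = mid2,
                 pd = pd, strata = NULL, n_strata = NULL),
            class = "pdp_surface")
}

#' Stratify a partial-dependence surface by risk gradient
#'
#' Cells are ranked by PD and cut into `n_strata` quantile strata;
#' stratum 1 carries the lowest risk. A constant surface degenerates to
#' a single stratum.
#'
#' @param surface A `pdp_surface`.
#' @param n_strata Number of strata (default 10, i.e. deciles).
#' @return The surface with a `strata` matrix added.
#' @export
risk_strata <- function(surface, n_strata = 10) {
  pd <- surface$pd
  if (diff(range(pd)) <= 1e-10) {
    surface$strata <- matrix(1L, nrow(pd), ncol(pd))
    surface$n_strata <- 1L
    inform("constant PD surface: single risk stratum")
    return(surface)
  }
  r <- rank(as.vector(pd), ties.method = "average")
  strata <- as.integer(ceiling(r * n_strata / length(r)))
  surface$strata <- matrix(strata, nrow(pd), ncol(pd))
  surface$n_strata <- as.integer(length(unique(strata)))
  surface
}

#' Lowest-risk fluid range from a stratified PD surface
#'
#' Takes the 4-connected component of stratum-1 cells containing the
#' global PD minimum and reports its bounding box on the cell edges.
#'
#' @param surface A `pdp_surface` with strata computed.
#' @return A one-row tibble with `day1_lo`, `day1_hi`, `day2_lo`,
#'   `day2_hi` (mL) and `n_cells` in the component.
#' @export
lowest_risk_range <- function(surface) {
  if (is.null(surface$strata)) abort("call risk_strata() first")
  if (surface$n_strata < 2) abort("no range: degenerate single stratum")
  s1 <- surface$strata == min(surface$strata)
  minpos <- which(surface$pd == min(surface$pd), arr.ind = TRUE)[1, ]
  comp <- connected_component(s1, minpos[1], minpos[2])
  idx <- which(comp, arr.ind = TRUE)
  tibble::tibble(
    day1_lo = surface$grid1[min(idx[, 1])],
    day1_hi = surface$grid1[max(idx[, 1]) + 1],
    day2_lo = surface$grid2[min(idx[, 2])],
    day2_hi = surface$grid2[max(idx[, 2]) + 1],
    n_cells = nrow(idx))
}

# flood fill of the 4-connected TRUE component containing (r0, c0)
connected_component <- function(mask, r0, c0) {
  comp <- matrix(FALSE, nrow(mask), ncol(mask))
  if (!mask[r0, c0]) {
    comp[r0, c0] <- TRUE       # the minimum itself always belongs
    return(comp)
  }
  stack <- list(c(r0, c0))
  comp[r0, c0] <- TRUE
  while (length(stack)) {
    cur <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      r <- cur[1] + d[1]; cc <- cur[2] + d[2]
      if (r >= 1 && r <= nrow(mask) && cc >= 1 && cc <= ncol(mask) &&
          mask[r, cc] && !comp[r, cc]) {
        comp[r, cc] <- TRUE
        stack[[length(stack) + 1]] <- c(r, cc)
      }
    }
  }
  comp
}

#' Tidy a PD surface into a long grid tibble
#' @param x A `pdp_surface`.
#' @param ... Unused.
#' @return A tibble with `day1_ml`, `day2_ml` (cell midpoints), `pd` and
#'   `stratum` (if computed).
#' @export
tidy.pdp_surface <- function(x, ...) {
  out <- tidyr::expand_grid(day1_ml = x$mid1, day2_ml = x$mid2)
  out$pd <- as.vector(t(x$pd))
  if (!is.null(x$strata)) out$stratum <- as.vector(t(x$strata))
  out
}

#' Heat-map of a PD surface with the lowest-risk range outlined
#' @param object A `pdp_surface`.
#' @param ... Unused.
#' @return A ggplot heat map.
#' @export
autoplot.pdp_surface <- function(object, ...) {
  df <- tidy(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$day1_ml, .data$day2_ml,
                                        fill = .data$pd)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(direction = -1) +
    ggplot2::labs(x = "Day-1 fluid intake (mL)",
                  y = "Day-2 fluid intake (mL)",
                  fill = "Predicted\nICU death")
  if (!is.null(object$strata) && object$n_strata >= 2) {
    rng <- lowest_risk_range(object)
    p <- p + ggplot2::annotate(
      "rect", xmin = rng$day1_lo, xmax = rng$day1_hi,
      ymin = rng$day2_lo, ymax = rng$day2_hi,
      colour = "red", fill = NA)
  }
  p
}

#' Adjusted Cox contrast for lactated Ringer's receipt per phenotype
#'
#' Within each phenotype stratum, fits a Cox model of 30-day mortality on
#' Ringer's receipt adjusted for the given covariates and reports the
#' hazard ratio of receipt versus non-receipt.
#'
#' @param records Survival records with `phenotype` plus covariates.
#' @param ringer Logical vector aligned with `records` (or a column name
#'   present in `records`).
#' @param covariates Adjustment covariates (default age, gender, race).
#' @return A tibble of per-phenotype Ringer hazard ratios.
#' @export
ringer_cox <- function(records, ringer = "ringer",
                       covariates = c("age", "gender", "race")) {
  records <- tibble::as_tibble(records)
  if (is.character(ringer) && length(ringer) == 1) {
    ringer <- records[[ringer]]
  }
  records$.ringer <- as.logical(ringer)
  purrr::map_dfr(sort(unique(records$phenotype)), function(p) {
    sub <- records[records$phenotype == p, ]
    if (!any(sub$event) || length(unique(sub$.ringer)) < 2) {
      return(tibble::tibble(phenotype = p, term = ".ringerTRUE",
                            HR = NA_real_, conf_low = NA_real_,
                            conf_high = NA_real_, p_value = NA_real_,
                            model = "adjusted",
                            note = "no events or no treatment contrast"))
    }
    covs <- drop_constant_covariates(sub, covariates)
    fml <- stats::reformulate(c(".ringer", covs),
                              response = "survival::Surv(time, event)")
    fit <- survival::coxph(fml, data = sub, ties = "efron")
    rep <- cox_report(fit, model = "adjusted")
    dplyr::mutate(dplyr::filter(rep, grepl("^\\.ringer", .data$term)),
                  phenotype = p, note = NA_character_, .before = 1)
  })
}

#' AUROC of predicted probabilities against outcomes
#'
#' Thin wrapper over `pROC::auc` used for reported metrics.
#'
#' @param truth 0/1 or logical outcomes.
#' @param prob Predicted probabilities.
#' @return The AUROC as a number.
#' @export
roc_auc <- function(truth, prob) {
  as.numeric(pROC::auc(pROC::roc(as.integer(truth), prob, quiet = TRUE,
                                 direction = "<", levels = c(0, 1))))
}
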