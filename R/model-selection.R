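# Consensus clustering over refitted trajectory mixtures: the number of
# subphenotypes K is chosen by the stability of co-assignment under
# patient subsampling, summarised by the CDF of consensus values, its
# area, and the relative delta area between successive K.

#' Longitudinal consensus clustering over a K range
#'
#' For each K and each resample: subsample patients without replacement,
#' fit the trajectory mixture, and record modal co-assignments. The
#' consensus matrix entry `M[i, j]` is the number of co-assignments
#' divided by the number of co-samplings of the pair; pairs never
#' co-sampled are undefined (`NaN`) and excluded from CDF summaries.
#'
#' @param panel A standardised `trajectory_panel`.
#' @param K_range Integer vector of candidate class counts (default 2:6).
#' @param n_resamples Subsampling replicates per K (default 100).
#' @param subsample_frac Fraction of patients per resample (default 0.8).
#' @param fit_opts List of arguments passed to [fit_gbmtm()] for resample
#'   fits (default `list(order = 3, n_restarts = 3)`).
#' @param seed Integer seed.
#' @param max_retries Redraws allowed per failed resample fit.
#' @return An object of class `consensus_result`: per-K consensus
#'   matrices, CDF areas `A`, delta areas `delta`, and per-cluster mean
#'   consensus scores.
#' @export
consensus_cluster <- function(panel, K_range = 2:6, n_resamples = 100,
                              subsample_frac = 0.8,
                              fit_opts = list(order = 3, n_restarts = 3),
                              seed = 1L, max_retries = 5L) {
  if (n_resamples < 2) abort("n_resamples must be >= 2")
  if (subsample_frac <= 0 || subsample_frac >= 1) {
    abort("subsample_frac must be in (0, 1)")
  }
  n <- n_patients(panel)
  m <- max(2L, floor(subsample_frac * n))
  set.seed(as.integer(seed))
  matrices <- list()
  for (K in K_range) {
    co_assign <- matrix(0, n, n)
    co_sample <- matrix(0, n, n)
    r <- 0L
    while (r < n_resamples) {
      idx <- sort(sample.int(n, m))
      fit <- NULL
      for (try in seq_len(max_retries)) {
        fit <- tryCatch(
          do.call(fit_gbmtm, c(list(panel = panel_subset(panel, idx), K = K,
                                    seed = sample.int(2^30, 1)),
                               fit_opts)),
          error = function(e) NULL)
        if (!is.null(fit)) break
        idx <- sort(sample.int(n, m))
      }
      if (is.null(fit)) abort(sprintf("resample fits failed repeatedly at K=%d", K))
      lab <- assign_modal(fit$posterior, quiet = TRUE)
      same <- outer(lab, lab, "==") * 1
      co_assign[idx, idx] <- co_assign[idx, idx] + same
      co_sample[idx, idx] <- co_sample[idx, idx] + 1
      r <- r + 1L
    }
    M <- co_assign / co_sample            # NaN where never co-sampled
    diag(M) <- 1
    matrices[[as.character(K)]] <- M
  }
  areas <- vapply(matrices, consensus_cdf_area, numeric(1))
  delta <- areas
  for (i in seq_along(K_range)) {
    delta[i] <- if (i == 1) areas[1] else {
      (areas[i] - areas[i - 1]) / areas[i - 1]
    }
  }
  cluster_consensus <- purrr::map2(matrices, K_range, per_cluster_consensus)
  structure(
    list(K_range = K_range, matrices = matrices,
         area = setNames(areas, K_range), delta = setNames(delta, K_range),
         cluster_consensus = cluster_consensus,
         n_resamples = n_resamples, subsample_frac = subsample_frac,
         seed = as.integer(seed)),
    class = "consensus_result")
}

# cluster the consensus matrix itself (average-linkage hierarchical
# clustering on 1 - M) and return the mean within-cluster consensus
per_cluster_consensus <- function(M, K) {
  D <- 1 - M
  D[!is.finite(D)] <- 1
  hc <- hclust(as.dist(D), method = "average")
  cl <- cutree(hc, k = K)
  vapply(seq_len(K), function(k) {
    idx <- which(cl == k)
    if (length(idx) < 2) return(1)
    vals <- M[idx, idx][upper.tri(M[idx, idx])]
    mean(vals[is.finite(vals)])
  }, numeric(1))
}

#' Area under the consensus CDF
#'
#' Empirical CDF of the defined off-diagonal upper-triangle consensus
#' values, integrated over `[0, 1]` as a Riemann sum on the standard
#' 100-bin grid: `A = sum_b F(b/100) / 100`.
#'
#' @param M A consensus matrix (entries in `[0, 1]`, `NaN` where
#'   undefined).
#' @return The area `A` in `[0, 1]`.
#' @export
consensus_cdf_area <- function(M) {
  vals <- M[upper.tri(M)]
  vals <- vals[is.finite(vals)]
  if (!length(vals)) abort("no defined consensus entries")
  edges <- seq_len(100) / 100
  cdf <- vapply(edges, function(e) mean(vals <= e), numeric(1))
  sum(cdf) / 100
}

#' Select the number of subphenotypes
#'
#' A candidate K is admissible when every per-cluster mean consensus
#' exceeds 0.8 and the smallest mixture class share meets the share
#' constraint (by default, a minimum of 10% of the cohort; the literal
#' "maximum 10%" reading is available via `class_share_mode = "max"`).
#' Among admissible K the choice is the delta-area elbow: the largest K
#' whose relative delta area is at least `elbow_threshold`; when no
#' admissible K clears the threshold, the admissible K with the largest
#' delta area is chosen.
#'
#' @param consensus A `consensus_result`.
#' @param ic_table Sensitivity table from [sensitivity_table()] (attached
#'   as evidence; must contain `K` and `min_share`).
#' @param min_share Class-share constraint (default 0.10).
#' @param elbow_threshold Relative delta-area threshold (default 0.1).
#' @param consensus_min Per-cluster mean consensus requirement (default
#'   0.8).
#' @param class_share_mode `"min"` (default) or `"max"` for the literal
#'   reading of the share constraint.
#' @return An object of class `selection_report`: `chosen_K` (`NA` if no
#'   admissible K) and a per-K `criteria` tibble.
#' @export
select_k <- function(consensus, ic_table, min_share = 0.10,
                     elbow_threshold = 0.1, consensus_min = 0.8,
                     class_share_mode = c("min", "max")) {
  class_share_mode <- match.arg(class_share_mode)
  Ks <- consensus$K_range
  ic <- tibble::as_tibble(ic_table)
  crit <- tibble::tibble(
    K = Ks,
    area = unname(consensus$area),
    delta = unname(consensus$delta),
    min_cluster_consensus = vapply(consensus$cluster_consensus, min,
                                   numeric(1)),
    min_class_share = ic$min_share[match(Ks, ic$K)]
  ) |>
    dplyr::left_join(dplyr::select(ic, "K", dplyr::any_of(c(
      "AIC", "BIC", "ICL", "entropy"))), by = "K") |>
    dplyr::mutate(
      consensus_ok = .data$min_cluster_consensus > consensus_min,
      share_ok = if (class_share_mode == "min") {
        .data$min_class_share >= min_share
      } else {
        .data$min_class_share <= min_share
      },
      admissible = .data$consensus_ok & .data$share_ok)

  adm <- crit$K[crit$admissible]
  chosen <- NA_integer_
  if (length(adm)) {
    elbow <- adm[crit$delta[match(adm, crit$K)] >= elbow_threshold]
    chosen <- if (length(elbow)) max(elbow) else {
      adm[which.max(crit$delta[match(adm, crit$K)])]
    }
  }
  structure(list(chosen_K = chosen, criteria = crit,
                 no_admissible = !length(adm)),
            class = "selection_report")
}

#' @export
print.selection_report <- function(x, ...) {
  if (is.na(x$chosen_K)) {
    cat("<selection_report> no admissible K\n")
  } else {
    cat(sprintf("<selection_report> chosen K = %d\n", x$chosen_K))
  }
  print(x$criteria)
  invisible(x)
}

#' Information-criterion sensitivity table across K
#'
#' Fits the full-data trajectory mixture for each K and tabulates AIC,
#' BIC, ICL, normalised entropy and the minimum class share.
#'
#' @param panel A standardised `trajectory_panel`.
#' @param K_range Candidate class counts (may include 1).
#' @param fit_opts Arguments passed to [fit_gbmtm()].
#' @param seed Integer seed.
#' @param keep_models Return fitted models as an attribute.
#' @return A tibble with one row per K (rows for failed fits carry an
#'   `error` note).
#' @export
sensitivity_table <- function(panel, K_range = 1:6,
                              fit_opts = list(order = 3, n_restarts = 5),
                              seed = 1L, keep_models = FALSE) {
  models <- list()
  rows <- purrr::map(K_range, function(K) {
    fit <- tryCatch(
      do.call(fit_gbmtm, c(list(panel = panel, K = K, seed = seed),
                           fit_opts)),
      error = function(e) e)
    if (inherits(fit, "error")) {
      return(tibble::tibble(K = K, loglik = NA_real_, AIC = NA_real_,
                            BIC = NA_real_, ICL = NA_real_,
                            entropy = NA_real_, min_share = NA_real_,
                            error = conditionMessage(fit)))
    }
    if (keep_models) models[[as.character(K)]] <<- fit
    dplyr::mutate(information_criteria(fit),
                  min_share = min(fit$mixing), error = NA_character_)
  })
  out <- dplyr::bind_rows(rows)
  if (keep_models) attr(out, "models") <- models
  out
}

#' Plot consensus CDFs and delta areas
#' @param object A `consensus_result`.
#' @param ... Unused.
#' @return A ggplot of per-K consensus CDFs.
#' @export
autoplot.consensus_result <- function(object, ...) {
  df <- purrr::map2_dfr(object$matrices, object$K_range, function(M, K) {
    vals <- M[upper.tri(M)]
    vals <- sort(vals[is.finite(vals)])
    tibble::tibble(K = factor(K), consensus = vals,
                   cdf = seq_along(vals) / length(vals))
  })
  ggplot2::ggplot(df, ggplot2::aes(.data$consensus, .data$cdf,
                                   colour = .data$K)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "Consensus value", y = "CDF")
}
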