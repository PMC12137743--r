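# Shared fixtures, all generated in code.

CH <- c("SBP", "DBP", "HR", "RR", "TEMP")

# long-format vitals for a hand-specified set of observations
long_vitals <- function(...) {
  rows <- list(...)
  tibble::tibble(
    patient_id = vapply(rows, `[[`, "", 1),
    time_from_admission = as.numeric(vapply(rows, `[[`, "", 2)),
    channel = vapply(rows, `[[`, "", 3),
    value = as.numeric(vapply(rows, `[[`, "", 4)))
}

# complete long table: every hour in `hours` fully observed for each patient,
# values given by `value_fn(patient_index, hour, channel_index)`
complete_vitals <- function(n, hours = 0:11,
                            value_fn = function(i, h, c) 10 * c + h) {
  do.call(rbind, lapply(seq_len(n), function(i) {
    do.call(rbind, lapply(hours, function(h) {
      data.frame(patient_id = sprintf("P%03d", i),
                 time_from_admission = h, channel = CH,
                 value = vapply(1:5, function(c) value_fn(i, h, c),
                                numeric(1)))
    }))
  }))
}

eligible_baseline <- function(ids) {
  tibble::tibble(patient_id = unique(ids), age = 50, gender = "Male",
                 race = "Asia", stay_number = 1L, icu_los_hours = 48)
}

# standardised panel built directly from class templates + optional noise,
# bypassing the natural-unit round trip (values already on the z scale)
template_panel <- function(n_per_class, noise_sd = 0, seed = 1,
                           templates = default_class_templates()) {
  set.seed(seed)
  tb <- vapply(0:2, function(j) (0:11 / 11)^j, numeric(12))
  rows <- list()
  for (k in 1:4) {
    for (i in seq_len(n_per_class)) {
      id <- sprintf("K%d_%03d", k, i)
      for (ci in 1:5) {
        mu <- drop(tb %*% templates[k, ci, ])
        rows[[length(rows) + 1]] <- data.frame(
          patient_id = id, hour = 0:11, channel = CH[ci],
          value = mu + rnorm(12, sd = noise_sd))
      }
    }
  }
  df <- do.call(rbind, rows)
  panel_from_long(df, standardized = TRUE)
}

template_truth <- function(panel) {
  as.integer(substr(panel$patient_id, 2, 2))
}

# mock classifier: any object with a predict method returning class
# probabilities, used as a transparent stand-in for a fitted forest
predict.mock_clf <- function(object, data, ...) {
  p <- object$f(data)
  list(predictions = cbind("0" = 1 - p, "1" = p))
}
mock_clf <- function(f) structure(list(f = f), class = "mock_clf")
registerS3method("predict", "mock_clf", predict.mock_clf,
                 envir = asNamespace("stats"))

# adjusted Rand index between two labelings (independent of the package's
# code paths; mclust is the oracle when available, else a direct formula)
ari <- function(a, b) {
  if (requireNamespace("mclust", quietly = TRUE)) {
    return(mclust::adjustedRandIndex(a, b))
  }
  tab <- table(a, b)
  ch2 <- function(x) sum(choose(x, 2))
  sij <- ch2(tab); si <- ch2(rowSums(tab)); sj <- ch2(colSums(tab))
  n2 <- choose(sum(tab), 2)
  (sij - si * sj / n2) / ((si + sj) / 2 - si * sj / n2)
}
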