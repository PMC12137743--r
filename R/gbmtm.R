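# Group-based multi-trajectory model: a finite mixture over patients in
# which each latent class defines one polynomial mean curve per vital-sign
# channel with class- and channel-specific Gaussian residual variance.
# Fitted by EM on the observed (complete-hour) cells only.

# channel indicator matrix mapping the 60 flat columns to 5 channels
channel_indicator <- function() {
  ind <- matrix(0, 60, 5)
  ind[cbind(1:60, rep(1:5, each = 12))] <- 1
  ind
}

# per-patient per-class log density matrix [n, K]
class_logdens <- function(flat, nobs, coeffs, resid_var, X) {
  K <- dim(coeffs)[1]
  n <- nrow(flat$y)
  Cmat <- channel_indicator()
  out <- matrix(0, n, K)
  for (k in seq_len(K)) {
    mu <- as.vector(X %*% t(coeffs[k, , ]))            # 60, channel-major
    d <- (flat$y - rep(mu, each = n)) * flat$m
    ss <- (d * d) %*% Cmat                              # n x 5
    inv <- 1 / resid_var[k, ]
    const <- sum(log(2 * pi * resid_var[k, ]))
    out[, k] <- -0.5 * (nobs * const + drop(ss %*% inv))
  }
  out
}

#' E-step: posterior class-membership probabilities
#'
#' Computes `tau[i, k]` proportional to `pi[k] * exp(logdens[i, k])`,
#' normalised per patient with log-sum-exp stabilisation.
#'
#' @param model A `gbmtm_fit` (or a bare parameter list with `mixing`,
#'   `coeffs`, `resid_var`, `order`).
#' @param panel A standardised `trajectory_panel`.
#' @return An `[n, K]` posterior matrix; rows sum to 1.
#' @export
e_step <- function(model, panel) {
  flat <- panel_flat(panel)
  nobs <- observed_hours(panel)
  X <- time_basis(0:11, model$order)
  ld <- class_logdens(flat, nobs, model$coeffs, model$resid_var, X)
  logw <- sweep(ld, 2, log(model$mixing), "+")
  bad <- !is.finite(apply(logw, 1, max))
  if (any(bad)) {
    abort(paste0("non-finite class densities for patient(s): ",
                 paste(panel$patient_id[bad], collapse = ", ")))
  }
  tau <- exp(logw - row_logsumexp(logw))
  rownames(tau) <- panel$patient_id
  tau
}

#' M-step: weighted-least-squares parameter updates
#'
#' Mixing proportions become the mean posterior weight; class/channel
#' coefficients solve the tau-weighted least squares of observed values on
#' the polynomial time basis; residual variances are tau-weighted mean
#' squared residuals (floored at 1e-6). A class whose weighted design is
#' singular (fewer distinct observed hours than coefficients) has its
#' polynomial order reduced for that fit, with a warning.
#'
#' @param panel A standardised `trajectory_panel`.
#' @param tau `[n, K]` posterior matrix.
#' @param order Polynomial degree.
#' @return A list with `mixing`, `coeffs` (`[K, 5, order + 1]`),
#'   `resid_var` (`[K, 5]`).
#' @export
m_step <- function(panel, tau, order = 3) {
  n <- n_patients(panel)
  K <- ncol(tau)
  X <- time_basis(0:11, order)
  flat <- panel_flat(panel)
  Cmat <- channel_indicator()
  mask <- panel$mask * 1
  coeffs <- array(0, dim = c(K, 5, order + 1))
  resid_var <- matrix(0, K, 5)
  for (k in seq_len(K)) {
    w_h <- drop(crossprod(tau[, k], mask))            # 12: total weight per hour
    if (sum(w_h) < 1e-8) {
      # class with no posterior mass: reinitialise neutrally
      coeffs[k, , ] <- 0
      resid_var[k, ] <- 1
      next
    }
    XtWX <- crossprod(X, X * w_h)
    use <- seq_len(order + 1)
    while (length(use) > 1 &&
           rcond_safe(XtWX[use, use, drop = FALSE]) < 1e-12) {
      use <- use[-length(use)]
    }
    if (length(use) < order + 1) {
      warn(sprintf("class %d: singular design, order reduced to %d",
                   k, length(use) - 1L))
    }
    for (ci in 1:5) {
      yc <- matrix(flat$y[, (ci - 1) * 12 + 1:12], n, 12)
      mc <- matrix(flat$m[, (ci - 1) * 12 + 1:12], n, 12)
      s <- drop(crossprod(X[, use, drop = FALSE],
                          drop(crossprod(yc * mc, tau[, k]))))
      b <- rep(0, order + 1)
      b[use] <- solve(XtWX[use, use, drop = FALSE], s)
      coeffs[k, ci, ] <- b
      mu <- drop(X %*% b)
      r2 <- (yc - rep(mu, each = n))^2 * mc
      wtot <- sum(w_h)
      resid_var[k, ci] <- max(sum(drop(crossprod(tau[, k], r2))) /
                                max(wtot, 1e-12), 1e-6)
    }
  }
  list(mixing = colMeans(tau), coeffs = coeffs, resid_var = resid_var)
}

rcond_safe <- function(m) {
  tryCatch(rcond(m), error = function(e) 0)
}

#' Fit a group-based multi-trajectory model by EM
#'
#' Fits a `K`-class finite mixture of per-channel polynomial regressions
#' to a standardised trajectory panel, taking the best log-likelihood
#' over `n_restarts` initialisations: the first uses k-means on
#' per-patient observed channel means, the rest use random posteriors.
#' The per-patient class log density sums Normal log densities over
#' observed (hour, channel) cells; the time covariate is scaled to
#' `h/11` in `[0, 1]`.
#'
#' @param panel A standardised `trajectory_panel` in which every patient
#'   has at least 2 observed hours.
#' @param K Number of latent classes (>= 1).
#' @param order Polynomial degree (0-5; default 3).
#' @param n_restarts Number of EM initialisations (default 10).
#' @param tol Relative log-likelihood convergence tolerance.
#' @param max_iter Maximum EM iterations per restart.
#' @param seed Integer seed controlling initialisation.
#' @return An object of class `gbmtm_fit`: mixing proportions, `coeffs`
#'   array `[K, 5 channels, order + 1]`, residual variances `[K, 5]`,
#'   log-likelihood and its trace, parameter count, convergence info,
#'   the posterior matrix (`$posterior`) and the panel's standardisation
#'   stats.
#' @export
fit_gbmtm <- function(panel, K, order = 3, n_restarts = 10,
                      tol = 1e-6, max_iter = 500, seed = 1L) {
  stopifnot(inherits(panel, "trajectory_panel"))
  if (!is_count(K)) abort("K must be a positive count")
  if (order < 0 || order > 5) abort("order must be in 0..5")
  if (any(observed_hours(panel) < 2)) {
    abort("every patient must have >= 2 observed hours")
  }
  n <- n_patients(panel)
  set.seed(as.integer(seed))
  if (K == 1) n_restarts <- 1L

  best <- NULL
  n_collapsed <- 0L
  for (r in seq_len(n_restarts)) {
    tau0 <- init_tau(panel, K, kmeans_init = (r == 1))
    fit <- tryCatch(
      em_run(panel, tau0, K, order, tol, max_iter),
      trajphen_collapse = function(c) NULL)
    if (is.null(fit)) { n_collapsed <- n_collapsed + 1L; next }
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  if (is.null(best)) {
    abort(sprintf("all %d restarts collapsed; try fewer classes", n_restarts))
  }
  structure(
    c(best,
      list(K = K, order = order, n = n,
           n_params = (K - 1) + K * 5 * (order + 1) + K * 5,
           n_restarts = n_restarts, n_collapsed = n_collapsed,
           seed = as.integer(seed), stats = panel$stats)),
    class = "gbmtm_fit")
}

init_tau <- function(panel, K, kmeans_init = TRUE) {
  n <- n_patients(panel)
  if (K == 1) return(matrix(1, n, 1))
  if (kmeans_init) {
    feat <- vapply(1:5, function(ci) {
      v <- panel$values[, , ci]
      rowSums(v * panel$mask, na.rm = TRUE) / pmax(rowSums(panel$mask), 1)
    }, numeric(n))
    km <- tryCatch(kmeans(feat, centers = K, nstart = 5),
                   error = function(e) NULL)
    if (!is.null(km)) {
      tau <- matrix(1e-3, n, K)
      tau[cbind(seq_len(n), km$cluster)] <- 1
      return(tau / rowSums(tau))
    }
  }
  tau <- matrix(rexp(n * K), n, K)
  tau / rowSums(tau)
}

em_run <- function(panel, tau, K, order, tol, max_iter) {
  flat <- panel_flat(panel)
  nobs <- observed_hours(panel)
  X <- time_basis(0:11, order)
  trace <- numeric(0)
  ll_prev <- -Inf
  params <- NULL
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    if (any(colSums(tau) < order + 2)) {
      rlang::cnd_signal(rlang::cnd("trajphen_collapse",
                                   message = "class collapsed"))
    }
    params <- m_step(panel, tau, order)
    ld <- class_logdens(flat, nobs, params$coeffs, params$resid_var, X)
    logw <- sweep(ld, 2, log(pmax(params$mixing, 1e-300)), "+")
    lse <- row_logsumexp(logw)
    ll <- sum(lse)
    trace <- c(trace, ll)
    tau <- exp(logw - lse)
    if (is.finite(ll_prev) &&
        abs(ll - ll_prev) < tol * (abs(ll_prev) + 1e-3)) {
      converged <- TRUE
      break
    }
    ll_prev <- ll
  }
  rownames(tau) <- panel$patient_id
  c(params, list(loglik = ll, loglik_trace = trace, converged = converged,
                 n_iter = length(trace), posterior = tau))
}

#' Information criteria and entropy for a fitted trajectory mixture
#'
#' `AIC = -2 loglik + 2 p`; `BIC = -2 loglik + p log N`;
#' `E = -sum tau log tau` (with `0 log 0 = 0`); `ICL = BIC + 2 E`;
#' normalised entropy `1 - E / (N log K)` for `K >= 2` (reported as 1
#' when `K = 1`).
#'
#' @param model A `gbmtm_fit`.
#' @param tau Optional posterior matrix; defaults to `model$posterior`.
#' @return A one-row tibble with `K`, `loglik`, `AIC`, `BIC`, `ICL`,
#'   `entropy` (normalised).
#' @export
information_criteria <- function(model, tau = NULL) {
  tau <- tau %||% model$posterior
  N <- nrow(tau)
  p <- model$n_params
  aic <- -2 * model$loglik + 2 * p
  bic <- -2 * model$loglik + p * log(N)
  tl <- tau * log(tau)
  tl[!is.finite(tl)] <- 0
  E <- -sum(tl)
  icl <- bic + 2 * E
  entropy <- if (model$K >= 2) 1 - E / (N * log(model$K)) else 1
  tibble::tibble(K = model$K, loglik = model$loglik, AIC = aic,
                 BIC = bic, ICL = icl, entropy = entropy)
}

#' Modal class assignment from a posterior matrix
#'
#' @param tau `[n, K]` posterior matrix.
#' @param quiet Suppress the tie message.
#' @return Integer class labels; ties broken by the lowest class index
#'   (a message reports how many ties occurred).
#' @export
assign_modal <- function(tau, quiet = FALSE) {
  lab <- apply(tau, 1, which.max)           # which.max takes the first max
  n_tie <- sum(apply(tau, 1, function(r) sum(r == max(r)) > 1))
  if (n_tie > 0 && !quiet) {
    inform(sprintf("%d posterior tie(s) broken by lowest class index", n_tie))
  }
  as.integer(lab)
}

#' Evaluate a fitted class mean curve
#'
#' @param model A `gbmtm_fit`.
#' @param k Class index.
#' @param channel Channel name (`"SBP"`, `"DBP"`, `"HR"`, `"RR"`,
#'   `"TEMP"`).
#' @param hours Hours at which to evaluate (warning outside 0-11).
#' @return A tibble with `hour` and `value` (z-score scale).
#' @export
class_mean_curve <- function(model, k, channel, hours = 0:11) {
  if (k > model$K) abort("class index exceeds K")
  ci <- match(channel, VITAL_CHANNELS)
  if (is.na(ci)) abort("unknown channel")
  if (any(hours < 0 | hours > 11)) {
    warn("evaluating mean curve outside the fitted 0-11 hour range")
  }
  tibble::tibble(hour = hours,
                 value = poly_eval(model$coeffs[k, ci, ], hours))
}

#' @export
print.gbmtm_fit <- function(x, ...) {
  cat(sprintf(
    "<gbmtm_fit> K = %d, order = %d, n = %d\n  loglik = %.2f (%s, %d iter)\n  mixing: %s\n",
    x$K, x$order, x$n, x$loglik,
    if (x$converged) "converged" else "not converged", x$n_iter,
    paste(sprintf("%.3f", x$mixing), collapse = ", ")))
  invisible(x)
}

#' Tidy method for fitted trajectory mixtures
#'
#' @param x A `gbmtm_fit`.
#' @param ... Unused.
#' @return A long tibble of class/channel polynomial coefficients and
#'   residual variances.
#' @export
tidy.gbmtm_fit <- function(x, ...) {
  grid <- expand.grid(class = seq_len(x$K), channel = VITAL_CHANNELS,
                      power = 0:x$order, stringsAsFactors = FALSE)
  grid$estimate <- mapply(function(k, c, j) {
    x$coeffs[k, match(c, VITAL_CHANNELS), j + 1]
  }, grid$class, grid$channel, grid$power)
  grid$resid_var <- mapply(function(k, c) {
    x$resid_var[k, match(c, VITAL_CHANNELS)]
  }, grid$class, grid$channel)
  tibble::as_tibble(grid) |>
    dplyr::arrange(.data$class, .data$channel, .data$power)
}

#' Glance method for fitted trajectory mixtures
#' @param x A `gbmtm_fit`.
#' @param ... Unused.
#' @return One-row tibble of fit diagnostics.
#' @export
glance.gbmtm_fit <- function(x, ...) {
  dplyr::bind_cols(
    information_criteria(x),
    tibble::tibble(n = x$n, order = x$order, converged = x$converged,
                   n_iter = x$n_iter, min_share = min(x$mixing)))
}

#' Plot fitted class mean curves
#' @param object A `gbmtm_fit`.
#' @param ... Unused.
#' @return A ggplot faceted by channel.
#' @export
autoplot.gbmtm_fit <- function(object, ...) {
  df <- purrr::map_dfr(seq_len(object$K), function(k) {
    purrr::map_dfr(VITAL_CHANNELS, function(ch) {
      dplyr::mutate(class_mean_curve(object, k, ch),
                    class = factor(k), channel = ch)
    })
  })
  ggplot2::ggplot(df, ggplot2::aes(.data$hour, .data$value,
                                   colour = .data$class)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~channel, scales = "free_y") +
    ggplot2::labs(x = "Hour after ICU admission",
                  y = "Standardised value", colour = "Class")
}

#' Serialize a fitted model to structured text (JSON)
#' @param model A `gbmtm_fit`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gbmtm <- function(model, path) {
  obj <- list(K = model$K, order = model$order, n = model$n,
              mixing = model$mixing, coeffs = model$coeffs,
              resid_var = model$resid_var, loglik = model$loglik,
              n_params = model$n_params, converged = model$converged,
              n_iter = model$n_iter, seed = model$seed,
              stats = model$stats)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a serialized model
#' @param path File written by [write_gbmtm()].
#' @return A `gbmtm_fit` (without posterior matrix).
#' @export
read_gbmtm <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$coeffs <- array(obj$coeffs, dim = c(obj$K, 5, obj$order + 1))
  obj$resid_var <- matrix(obj$resid_var, obj$K, 5)
  if (!is.null(obj$stats)) obj$stats <- tibble::as_tibble(obj$stats)
  structure(obj, class = "gbmtm_fit")
}
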