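# Internal helpers shared across modules.

VITAL_CHANNELS <- c("SBP", "DBP", "HR", "RR", "TEMP")
PHENOTYPE_LEVELS <- c("A", "B", "C", "D")

#' Derive a stream of per-stage seeds from one global seed
#'
#' Deterministically expands a single integer seed into named per-stage
#' seeds so that partial pipeline reruns reproduce identical stage output.
#' All derived seeds stay below `.Machine$integer.max`.
#'
#' @param seed Integer global seed.
#' @param stages Character vector of stage names.
#' @return Named integer vector of seeds.
#' @export
derive_seeds <- function(seed, stages) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(stages))
  base <- as.integer(seed) %% 1000003L
  out <- vapply(seq_along(stages), function(i) {
    (base * 7919L + i * 104729L) %% 2147483629L
  }, integer(1))
  setNames(out, stages)
}

# polynomial time basis on the scaled covariate h_s = hour / 11
time_basis <- function(hours, order) {
  hs <- hours / 11
  vapply(0:order, function(j) hs^j, numeric(length(hours)))
}

# evaluate polynomial coefficients (ascending powers) on scaled hours
poly_eval <- function(coefs, hours) {
  drop(time_basis(hours, length(coefs) - 1L) %*% coefs)
}

# log-sum-exp over rows of a matrix
row_logsumexp <- function(m) {
  mx <- apply(m, 1, max)
  mx + log(rowSums(exp(m - mx)))
}

is_count <- function(x) is.numeric(x) && length(x) == 1 && !is.na(x) && x >= 1 && x == floor(x)
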