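# Internal helpers shared across modules.

#' Derive a reproducible sub-stream seed from a master seed and a key
#'
#' All randomness in the package flows from a single master seed. Independent
#' simulation streams (one per SNP, one per allergen, one per power
#' configuration) are derived by a stable polynomial hash of the master seed
#' and a string key, so results do not depend on the order in which SNPs
#' appear in a catalog or cohort.
#'
#' @param seed Integer master seed.
#' @param key Character scalar identifying the stream (e.g. an rsID).
#' @return An integer in [0, 2^31 - 2] suitable for `set.seed()`.
#' @keywords internal
stream_seed <- function(seed, key) {
  stopifnot(length(seed) == 1L, is.finite(seed), length(key) == 1L)
  codes <- utf8ToInt(paste0(format(seed, scientific = FALSE), ":", key))
  h <- 0
  # h stays < 2^31 * 131 + 255 < 2^53, so double arithmetic is exact
  for (cc in codes) h <- (h * 131 + cc) %% 2147483647
  as.integer(h)
}

#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; printed tables in this field
#' conventionally round half up (2.45 -> 2.5). A tiny epsilon absorbs
#' binary-representation error in products like 45 * 0.05.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @keywords internal
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  floor(x * scale + 0.5 + 1e-9) / scale
}

# Stop with a classed condition so callers/tests can distinguish validation
# failures from I/O failures.
abort_validation <- function(msg) {
  stop(errorCondition(msg, class = c("snpreplicate_validation_error", "error")))
}

abort_io <- function(msg) {
  stop(errorCondition(msg, class = c("snpreplicate_io_error", "error")))
}

is_count <- function(x) {
  length(x) == 1L && is.finite(x) && x >= 0 && x == trunc(x)
}
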