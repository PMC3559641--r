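#' @title Cross-study concordance of odds ratios
#'
#' @description
#' If published effects are real but inflated (winner's curse), the
#' replication study may lack power for individual significance yet still
#' show correlated effect directions. These operations quantify that:
#' Spearman rank correlation of paired odds ratios, the count of
#' sign-concordant pairs (both ORs on the same side of 1), and an exact
#' binomial test of the concordant/discordant split against equal
#' proportions.
#'
#' @name cross_study
NULL

#' Spearman rank correlation of paired odds ratios
#'
#' Average ranks for ties; pairs with a missing value in either study are
#' dropped. The two-sided P-value uses the exact permutation distribution
#' when n <= 9 and there are no ties, and the t-approximation otherwise.
#' Because ranks are invariant under strictly monotone transforms, the
#' correlation is identical on the OR and log-OR scales.
#'
#' @param or_a,or_b Paired numeric vectors of odds ratios.
#' @return A list with `rho`, `p`, `n_pairs`.
#' @export
#' @examples
#' spearman_or(c(1, 2, 3, 4, 5), c(1, 3, 2, 5, 4))  # rho = 0.8
spearman_or <- function(or_a, or_b) {
  if (length(or_a) != length(or_b)) {
    abort_validation("or_a and or_b must have equal length")
  }
  keep <- !is.na(or_a) & !is.na(or_b)
  a <- or_a[keep]
  b <- or_b[keep]
  n <- length(a)
  if (n < 3L) abort_validation("need at least 3 complete pairs")
  has_ties <- anyDuplicated(a) > 0 || anyDuplicated(b) > 0
  use_exact <- n <= 9L && !has_ties
  ct <- suppressWarnings(
    stats::cor.test(a, b, method = "spearman", exact = use_exact))
  list(rho = unname(ct$estimate), p = unname(ct$p.value), n_pairs = n)
}

#' Sign concordance of paired odds ratios
#'
#' A pair is concordant when both ORs are above 1 or both below 1
#' (`(a - 1) * (b - 1) > 0`), discordant when they fall on opposite sides,
#' and excluded when either value is missing or exactly 1 (no direction).
#'
#' @param or_a,or_b Paired numeric vectors of odds ratios.
#' @return A list with `n_concordant`, `n_discordant`, `n_excluded`;
#'   the three sum to the number of pairs.
#' @export
#' @examples
#' sign_concordance(c(1.5, 0.8, 1.0), c(2.0, 1.3, 1.4))
sign_concordance <- function(or_a, or_b) {
  if (length(or_a) != length(or_b)) {
    abort_validation("or_a and or_b must have equal length")
  }
  prod_sign <- (or_a - 1) * (or_b - 1)
  excluded <- is.na(prod_sign) | prod_sign == 0
  list(n_concordant = sum(prod_sign > 0, na.rm = TRUE),
       n_discordant = sum(prod_sign < 0, na.rm = TRUE),
       n_excluded = sum(excluded))
}

#' Exact two-sided binomial sign test against equal proportions
#'
#' P-value is the sum of the probabilities of all outcomes no more likely
#' than the observed count under Binomial(n, 1/2).
#'
#' @param k Number of successes (e.g. concordant pairs).
#' @param n Number of trials (concordant + discordant).
#' @return Two-sided P-value.
#' @export
#' @examples
#' binomial_sign_test(23, 43)  # ~0.76: no departure from 50:50
binomial_sign_test <- function(k, n) {
  if (!is_count(n) || n < 1) abort_validation("n must be a positive integer")
  if (!is_count(k) || k > n) abort_validation("k must satisfy 0 <= k <= n")
  stats::binom.test(k, n, p = 0.5)$p.value
}

#' Full concordance report for two sets of odds ratios
#'
#' Combines [spearman_or()], [sign_concordance()] and
#' [binomial_sign_test()] on the concordant/discordant split.
#'
#' @param or_a,or_b Paired numeric vectors of odds ratios (e.g. the
#'   `or_minor` columns of two [run_association()] tables matched on
#'   `snp_id`).
#' @return A list of class `concordance_report` with `n_concordant`,
#'   `n_discordant`, `n_excluded`, `spearman_rho`, `spearman_p`,
#'   `binomial_p`.
#' @export
concordance_report <- function(or_a, or_b) {
  sc <- sign_concordance(or_a, or_b)
  sp <- spearman_or(or_a, or_b)
  n_trials <- sc$n_concordant + sc$n_discordant
  structure(list(n_concordant = sc$n_concordant,
                 n_discordant = sc$n_discordant,
                 n_excluded = sc$n_excluded,
                 spearman_rho = sp$rho, spearman_p = sp$p,
                 binomial_p = if (n_trials > 0) {
                   binomial_sign_test(sc$n_concordant, n_trials)
                 } else NA_real_),
            class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat(sprintf(
    "concordance: %d concordant, %d discordant, %d excluded\n",
    x$n_concordant, x$n_discordant, x$n_excluded))
  cat(sprintf("Spearman R = %.2f (P = %.2f); binomial P = %.2f\n",
              x$spearman_rho, x$spearman_p, x$binomial_p))
  invisible(x)
}
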