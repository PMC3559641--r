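#' @title Simulation-based power for the allele test
#'
#' @description
#' Monte-Carlo power of the allele-based (2x2) chi-square homogeneity test
#' at given case/control sizes, control minor-allele frequency and allelic
#' odds ratio. Each replicate draws allele counts binomially (cases at the
#' odds-shifted frequency, controls at `p0`), computes the uncorrected
#' chi-square statistic and scores whether it exceeds the critical value
#' at each significance level; power is the rejection fraction. Also
#' provides the expected-significant-count statistic: the number of
#' significant tests expected if every published odds ratio were true,
#' `E = sum(power_i)` with `SD = sqrt(sum(power_i * (1 - power_i)))`.
#'
#' @name power_engine
NULL

# Vectorized uncorrected 2x2 chi-square statistic on tables
# [[a, b], [c, d]] given as parallel vectors. Tables with a zero margin are
# Haldane-corrected (0.5 added to every cell) rather than dropped, so the
# rejection denominator stays at n_reps.
chisq_stat_2x2 <- function(a, b, c_, d) {
  # double arithmetic: margin products overflow 32-bit integers
  a <- as.numeric(a); b <- as.numeric(b)
  c_ <- as.numeric(c_); d <- as.numeric(d)
  zero_margin <- (a + b == 0) | (c_ + d == 0) | (a + c_ == 0) | (b + d == 0)
  if (any(zero_margin)) {
    a[zero_margin] <- a[zero_margin] + 0.5
    b[zero_margin] <- b[zero_margin] + 0.5
    c_[zero_margin] <- c_[zero_margin] + 0.5
    d[zero_margin] <- d[zero_margin] + 0.5
  }
  n <- a + b + c_ + d
  n * (a * d - b * c_)^2 / ((a + b) * (c_ + d) * (a + c_) * (b + d))
}

#' Monte-Carlo power of the allele-based chi-square test
#'
#' @param n_case,n_control Cohort sizes (individuals; allele denominators
#'   are twice these).
#' @param p0 Control minor-allele frequency, strictly inside (0, 1).
#' @param or Allelic odds ratio, > 0.
#' @param alphas Significance levels; default `c(0.05, 0.001)`.
#' @param n_reps Number of simulation replicates; default 10000.
#' @param seed Integer seed; identical seeds give identical estimates.
#' @return A data frame of class `power_estimate` with one row per alpha:
#'   `n_case`, `n_control`, `p0`, `or`, `alpha`, `n_reps`, `power`, `seed`.
#' @export
#' @examples
#' simulate_power(352, 709, p0 = 0.25, or = 2.0, alphas = 0.05,
#'                n_reps = 2000, seed = 7)
simulate_power <- function(n_case, n_control, p0, or,
                           alphas = c(0.05, 0.001), n_reps = 10000L,
                           seed = 1L) {
  if (!is_count(n_reps) || n_reps < 1) {
    abort_validation("n_reps must be a positive integer")
  }
  if (!is.finite(p0) || p0 <= 0 || p0 >= 1) {
    abort_validation("p0 must lie strictly inside (0, 1)")
  }
  if (!is.finite(or) || or <= 0) abort_validation("or must be > 0")
  if (any(alphas <= 0 | alphas >= 1)) {
    abort_validation("alphas must lie strictly inside (0, 1)")
  }
  p1 <- case_allele_freq(p0, or)
  n1 <- 2L * n_case
  n0 <- 2L * n_control
  set.seed(seed)
  a <- stats::rbinom(n_reps, n1, p1)   # case minor-allele counts
  c_ <- stats::rbinom(n_reps, n0, p0)  # control minor-allele counts
  stat <- chisq_stat_2x2(a, n1 - a, c_, n0 - c_)
  crit <- stats::qchisq(1 - alphas, df = 1)
  power <- vapply(crit, function(cv) mean(stat > cv), numeric(1))
  out <- data.frame(n_case = n_case, n_control = n_control, p0 = p0,
                    or = or, alpha = alphas, n_reps = n_reps,
                    power = power, seed = seed)
  class(out) <- c("power_estimate", class(out))
  out
}

#' Closed-form power of the pooled two-proportion z-test
#'
#' Normal-approximation power for comparing the case and control
#' minor-allele proportions with allele denominators `2 * n_case` and
#' `2 * n_control` (the squared z equals the uncorrected 2x2 chi-square).
#' Used as an independent check of [simulate_power()].
#'
#' @inheritParams simulate_power
#' @param alpha Single two-sided significance level.
#' @return Scalar power in \[0, 1\].
#' @export
analytic_power <- function(n_case, n_control, p0, or, alpha = 0.05) {
  p1 <- case_allele_freq(p0, or)
  n1 <- 2 * n_case
  n0 <- 2 * n_control
  pbar <- (n1 * p1 + n0 * p0) / (n1 + n0)
  se0 <- sqrt(pbar * (1 - pbar) * (1 / n1 + 1 / n0))
  se1 <- sqrt(p1 * (1 - p1) / n1 + p0 * (1 - p0) / n0)
  z <- stats::qnorm(1 - alpha / 2)
  delta <- p1 - p0
  stats::pnorm((-z * se0 - delta) / se1) +
    stats::pnorm((delta - z * se0) / se1)
}

#' Power table for a catalog of published odds ratios
#'
#' One row per catalog entry and study population, giving the Monte-Carlo
#' power of the allele test to detect the published odds ratio at the
#' configured study's case/control sizes, for each significance level.
#' The control minor-allele frequency comes from `maf_source` when
#' provided (a data frame `snp_id`, `population_label`, `maf`; `maf = 0`
#' or NA marks the SNP monomorphic in that population and its power is
#' reported NA, printed "-"); otherwise `default_p0` is used for every SNP
#' with a one-time message. Per-row simulation streams are derived from
#' the master seed, the rsID, the population label and the catalog row, so
#' the table is reproducible and independent of row order.
#'
#' @param catalog A `snp_catalog` (e.g. [packaged_catalog()]).
#' @param populations Named list of `c(n_case, n_control)` vectors, one
#'   per study population.
#' @param maf_source Optional data frame with columns `snp_id`,
#'   `population_label`, `maf`.
#' @param alphas Significance levels; default `c(0.05, 0.001)`.
#' @param n_reps Replicates per cell; default 10000.
#' @param seed Master seed.
#' @param default_p0 Fallback control MAF; default 0.25.
#' @return A data frame with columns `gene`, `snp_id`, `population_label`,
#'   `n_case`, `n_control`, `p0`, `or` and one `power_<alpha>` column per
#'   significance level.
#' @export
power_table <- function(catalog,
                        populations = list(SP = c(352, 709),
                                           CP = c(948, 580)),
                        maf_source = NULL, alphas = c(0.05, 0.001),
                        n_reps = 10000L, seed = 1L, default_p0 = 0.25) {
  if (nrow(catalog) == 0L) abort_validation("catalog must be non-empty")
  if (is.null(names(populations)) || any(names(populations) == "")) {
    abort_validation("populations must be a named list")
  }
  lookup_maf <- function(sid, pop) {
    if (is.null(maf_source)) return(default_p0)
    hit <- maf_source$maf[maf_source$snp_id == sid &
                          maf_source$population_label == pop]
    if (length(hit) == 0L) {
      message(sprintf("no MAF for %s in %s; using default p0 = %g",
                      sid, pop, default_p0))
      return(default_p0)
    }
    hit[1L]
  }
  rows <- list()
  for (pop in names(populations)) {
    sizes <- populations[[pop]]
    for (i in seq_len(nrow(catalog))) {
      sid <- catalog$snp_id[i]
      p0 <- lookup_maf(sid, pop)
      row <- list(gene = catalog$gene[i], snp_id = sid,
                  population_label = pop,
                  n_case = sizes[[1L]], n_control = sizes[[2L]],
                  p0 = if (is.na(p0)) NA_real_ else p0,
                  or = catalog$or[i])
      if (is.na(p0) || p0 == 0 || p0 == 1) {
        # monomorphic in this population: untestable, Table prints "-"
        for (al in alphas) row[[sprintf("power_%g", al)]] <- NA_real_
      } else {
        pw <- simulate_power(sizes[[1L]], sizes[[2L]], p0, catalog$or[i],
                             alphas, n_reps,
                             seed = stream_seed(seed,
                                                paste(sid, pop, i, sep = "|")))
        for (j in seq_along(alphas)) {
          row[[sprintf("power_%g", alphas[j])]] <- pw$power[j]
        }
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, lapply(rows, as.data.frame))
  rownames(out) <- NULL
  out
}

#' Expected number of significant tests given per-SNP power
#'
#' If every published odds ratio were true, the number of significant
#' P-values would be a sum of independent Bernoulli trials with success
#' probabilities the per-SNP powers: expectation `sum(power_i)`, standard
#' deviation `sqrt(sum(power_i * (1 - power_i)))`. Comparing this
#' expectation with the observed count measures how far the replication
#' falls short of what the published effects predict.
#'
#' @param powers Numeric vector of per-SNP power values in \[0, 1\].
#' @param observed_count Optional observed number of significant tests.
#' @param alpha Optional significance level, carried through for labeling.
#' @return A list of class `expected_significance` with `alpha`,
#'   `expected_count`, `sd`, `observed_count`.
#' @export
#' @examples
#' expected_significant(c(1, 1, 0.5), observed_count = 0)
expected_significant <- function(powers, observed_count = NA_integer_,
                                 alpha = NA_real_) {
  if (length(powers) == 0L) abort_validation("powers must be non-empty")
  if (any(is.na(powers)) || any(powers < 0 | powers > 1)) {
    abort_validation("powers must lie in [0, 1]")
  }
  structure(list(alpha = alpha,
                 expected_count = sum(powers),
                 sd = sqrt(sum(powers * (1 - powers))),
                 observed_count = observed_count),
            class = "expected_significance")
}

#' @export
print.expected_significance <- function(x, ...) {
  cat(sprintf("expected significant: %.1f (SD %.1f), observed: %s\n",
              x$expected_count, x$sd,
              if (is.na(x$observed_count)) "-" else x$observed_count))
  invisible(x)
}
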