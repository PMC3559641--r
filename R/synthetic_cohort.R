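#' @title Synthetic case-control cohort generator
#'
#' @description
#' Generates case-control genotype data with the statistical structure the
#' downstream analysis assumes: control genotypes in Hardy-Weinberg
#' proportions at a stated control minor-allele frequency `p0`, case
#' genotypes in Hardy-Weinberg proportions at the case frequency implied by
#' a multiplicative allelic odds ratio, and optional log-normal
#' skin-prick-test-like scores with an additive per-dosage effect on the
#' log scale. All randomness flows from a single master seed; per-SNP and
#' per-allergen streams are derived by a stable hash so results do not
#' depend on SNP ordering.
#'
#' @name synthetic_cohort
NULL

#' Case minor-allele frequency implied by an allelic odds ratio
#'
#' Under a multiplicative allelic model the case allele odds are the
#' control odds times the odds ratio, giving
#' `p1 = or * p0 / (1 - p0 + or * p0)`.
#'
#' @param p0 Control minor-allele frequency in \[0, 1\].
#' @param or Allelic odds ratio, > 0.
#' @return The case minor-allele frequency `p1`.
#' @export
#' @examples
#' case_allele_freq(0.25, 3)   # 0.5
#' case_allele_freq(0.25, 1)   # no effect: 0.25
case_allele_freq <- function(p0, or) {
  if (any(!is.finite(or)) || any(or <= 0)) {
    abort_validation("odds ratio must be a positive finite number")
  }
  if (any(p0 < 0) || any(p0 > 1)) {
    abort_validation("allele frequency must lie in [0, 1]")
  }
  or * p0 / (1 - p0 + or * p0)
}

#' Simulate a 2x2 allele count table for one SNP
#'
#' Draws the case minor-allele count from Binomial(2 * n_case, p1) with
#' `p1 = case_allele_freq(p0, or)` and the control minor-allele count from
#' Binomial(2 * n_control, p0); major-allele counts are the complements.
#' This is the allele-level sampling model used by the power engine.
#'
#' @param n_case,n_control Numbers of cases and controls (>= 1).
#' @param p0 Control minor-allele frequency, strictly inside (0, 1).
#' @param or Allelic odds ratio, > 0.
#' @param seed Integer seed; identical seeds give identical tables.
#' @return A 2x2 integer matrix with rows `case`/`control` and columns
#'   `minor`/`major`.
#' @export
simulate_allele_counts <- function(n_case, n_control, p0, or, seed) {
  if (!is_count(n_case) || n_case < 1 || !is_count(n_control) || n_control < 1) {
    abort_validation("n_case and n_control must be positive integers")
  }
  if (!is.finite(p0) || p0 <= 0 || p0 >= 1) {
    abort_validation("p0 must lie strictly inside (0, 1)")
  }
  p1 <- case_allele_freq(p0, or)
  set.seed(seed)
  a <- stats::rbinom(1L, 2L * n_case, p1)
  c_ <- stats::rbinom(1L, 2L * n_control, p0)
  matrix(c(a, c_, 2L * n_case - a, 2L * n_control - c_), nrow = 2,
         dimnames = list(c("case", "control"), c("minor", "major")))
}

#' Construct a simulation specification
#'
#' @param n_case,n_control Cohort sizes (>= 1).
#' @param snps Data frame with columns `snp_id`, `p0` (control minor-allele
#'   frequency in (0, 1)) and `or` (allelic odds ratio > 0).
#' @param spt_effects Optional data frame with columns `allergen`,
#'   `baseline_log_mean`, `per_dosage_log_shift`, `log_sd` (> 0) and
#'   optionally `snp_id` naming the SNP whose dosage drives the shift
#'   (defaults to the first SNP in `snps`).
#' @param seed Integer master seed.
#' @return A list of class `simulation_spec`.
#' @export
simulation_spec <- function(n_case, n_control, snps, spt_effects = NULL,
                            seed = 1L) {
  if (!is_count(n_case) || n_case < 1 || !is_count(n_control) || n_control < 1) {
    abort_validation("n_case and n_control must be positive integers")
  }
  snps <- as.data.frame(snps)
  if (nrow(snps) == 0L) abort_validation("at least one SNP must be specified")
  needed <- c("snp_id", "p0", "or")
  if (!all(needed %in% names(snps))) {
    abort_validation("snps must have columns snp_id, p0, or")
  }
  if (any(snps$p0 <= 0 | snps$p0 >= 1)) {
    abort_validation("each p0 must lie strictly inside (0, 1)")
  }
  if (any(snps$or <= 0)) abort_validation("each or must be > 0")
  if (anyDuplicated(snps$snp_id)) abort_validation("duplicate snp_id in spec")
  if (!is.null(spt_effects)) {
    spt_effects <- as.data.frame(spt_effects)
    needed <- c("allergen", "baseline_log_mean", "per_dosage_log_shift",
                "log_sd")
    if (!all(needed %in% names(spt_effects))) {
      abort_validation(paste("spt_effects must have columns",
                             paste(needed, collapse = ", ")))
    }
    if (any(spt_effects$log_sd <= 0)) abort_validation("log_sd must be > 0")
    if (is.null(spt_effects$snp_id)) spt_effects$snp_id <- snps$snp_id[1L]
    if (!all(spt_effects$snp_id %in% snps$snp_id)) {
      abort_validation("spt_effects reference unknown snp_id")
    }
  }
  structure(list(n_case = as.integer(n_case),
                 n_control = as.integer(n_control),
                 snps = snps, spt_effects = spt_effects,
                 seed = as.integer(seed)),
            class = "simulation_spec")
}

#' Read a simulation specification from a YAML config file
#'
#' The config holds flat keys `n_case`, `n_control`, `seed`, a `snps` list
#' with one block per SNP (`snp_id`, `p0`, `or`) and an optional
#' `spt_effects` list (`allergen`, `baseline_log_mean`,
#' `per_dosage_log_shift`, `log_sd`, optional `snp_id`).
#'
#' @param path Path to the YAML file.
#' @return A `simulation_spec`.
#' @export
read_simulation_spec <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("config file not found: %s", path))
  cfg <- yaml::read_yaml(path)
  for (k in c("n_case", "n_control", "snps")) {
    if (is.null(cfg[[k]])) {
      abort_validation(sprintf("config is missing required key: %s", k))
    }
  }
  snps <- do.call(rbind, lapply(cfg$snps, function(s) {
    data.frame(snp_id = s$snp_id, p0 = as.numeric(s$p0),
               or = as.numeric(s$or), stringsAsFactors = FALSE)
  }))
  spt <- NULL
  if (!is.null(cfg$spt_effects)) {
    spt <- do.call(rbind, lapply(cfg$spt_effects, function(s) {
      data.frame(allergen = s$allergen,
                 baseline_log_mean = as.numeric(s$baseline_log_mean),
                 per_dosage_log_shift = as.numeric(s$per_dosage_log_shift),
                 log_sd = as.numeric(s$log_sd),
                 snp_id = if (is.null(s$snp_id)) NA_character_ else s$snp_id,
                 stringsAsFactors = FALSE)
    }))
    if (all(is.na(spt$snp_id))) spt$snp_id <- NULL
  }
  simulation_spec(cfg$n_case, cfg$n_control, snps, spt,
                  seed = if (is.null(cfg$seed)) 1L else as.integer(cfg$seed))
}

# Draw n genotypes (minor-allele dosage 0/1/2) in HWE proportions at
# minor-allele frequency p.
draw_hwe_genotypes <- function(n, p) {
  probs <- c((1 - p)^2, 2 * p * (1 - p), p^2)  # dosage 0, 1, 2
  sample(0:2, n, replace = TRUE, prob = probs)
}

#' Simulate an individual-level case-control cohort
#'
#' Control genotypes are drawn from Hardy-Weinberg proportions at `p0`;
#' case genotypes from Hardy-Weinberg proportions at the case frequency
#' `p1` implied by the allelic odds ratio ([case_allele_freq()]). For each
#' configured allergen, cases receive a skin-prick-test-like score drawn as
#' `exp(Normal(baseline_log_mean + per_dosage_log_shift * dosage, log_sd))`,
#' rounded to three decimals (the precision of a wheal-size ratio);
#' controls, being non-atopic by definition, carry no score.
#'
#' @param spec A [simulation_spec()].
#' @return A `cohort_dataset` (see [read_cohort()]).
#' @export
#' @examples
#' spec <- simulation_spec(
#'   n_case = 50, n_control = 80,
#'   snps = data.frame(snp_id = "rs0001", p0 = 0.25, or = 2.0),
#'   seed = 42)
#' cohort <- simulate_cohort(spec)
#' cohort_sizes(cohort)
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  n_case <- spec$n_case
  n_control <- spec$n_control
  ids <- c(sprintf("case_%04d", seq_len(n_case)),
           sprintf("control_%04d", seq_len(n_control)))
  status <- rep(c("case", "control"), c(n_case, n_control))
  df <- data.frame(individual_id = ids, status = status,
                   stringsAsFactors = FALSE)

  for (i in seq_len(nrow(spec$snps))) {
    sid <- spec$snps$snp_id[i]
    p0 <- spec$snps$p0[i]
    p1 <- case_allele_freq(p0, spec$snps$or[i])
    set.seed(stream_seed(spec$seed, sid))
    df[[sid]] <- as.integer(c(draw_hwe_genotypes(n_case, p1),
                              draw_hwe_genotypes(n_control, p0)))
  }

  allergens <- character()
  if (!is.null(spec$spt_effects)) {
    for (i in seq_len(nrow(spec$spt_effects))) {
      eff <- spec$spt_effects[i, ]
      dosage <- df[[eff$snp_id]][seq_len(n_case)]
      set.seed(stream_seed(spec$seed, paste0("spt:", eff$allergen)))
      mu <- eff$baseline_log_mean + eff$per_dosage_log_shift * dosage
      score <- round(exp(stats::rnorm(n_case, mu, eff$log_sd)), 3)
      df[[paste0("spt:", eff$allergen)]] <-
        c(score, rep(NA_real_, n_control))
      allergens <- c(allergens, eff$allergen)
    }
  }

  new_cohort(df, spec$snps$snp_id, allergens)
}
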