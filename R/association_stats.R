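#' @title Per-SNP association statistics
#'
#' @description
#' The per-SNP battery applied to a case-control cohort: allele-based
#' (2x2) and genotype-based (2x3) chi-square homogeneity tests,
#' Hardy-Weinberg equilibrium chi-square within cases and controls,
#' minor-allele odds ratio with a Woolf log-scale confidence interval, and
#' Kruskal-Wallis rank-sum tests of quantitative skin-prick-test scores by
#' genotype.
#'
#' @name association_stats
NULL

new_test_result <- function(statistic, df, p_value, method) {
  structure(list(statistic = statistic, df = df, p_value = p_value,
                 method = method),
            class = "snp_test_result")
}

#' @export
print.snp_test_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, df = %s, p = %.4g\n",
              x$method, x$statistic,
              if (is.na(x$df)) "-" else x$df, x$p_value))
  invisible(x)
}

#' Genotype counts for one group
#'
#' @param n_major_hom,n_het,n_minor_hom Non-negative genotype counts
#'   (major-allele homozygotes, heterozygotes, minor-allele homozygotes).
#' @return Named integer vector of length 3.
#' @export
genotype_counts <- function(n_major_hom, n_het, n_minor_hom) {
  counts <- c(n_major_hom = n_major_hom, n_het = n_het,
              n_minor_hom = n_minor_hom)
  if (any(counts < 0) || any(counts != trunc(counts))) {
    abort_validation("genotype counts must be non-negative integers")
  }
  counts
}

#' Collapse genotype counts into a 2x2 allele count table
#'
#' Each heterozygote contributes one minor allele, each minor-allele
#' homozygote two; totals are twice the genotype totals.
#'
#' @param case_counts,control_counts Genotype count vectors as returned by
#'   [genotype_counts()].
#' @return A 2x2 matrix with rows `case`/`control` and columns
#'   `minor`/`major`.
#' @export
allele_table <- function(case_counts, control_counts) {
  for (g in list(case_counts, control_counts)) {
    if (sum(g) <= 0) abort_validation("each group must have a positive total")
  }
  minor <- function(g) 2 * g[["n_minor_hom"]] + g[["n_het"]]
  tot <- function(g) 2 * sum(g)
  m <- matrix(c(minor(case_counts), minor(control_counts),
                tot(case_counts) - minor(case_counts),
                tot(control_counts) - minor(control_counts)),
              nrow = 2,
              dimnames = list(c("case", "control"), c("minor", "major")))
  storage.mode(m) <- "integer"
  m
}

#' Chi-square homogeneity test on a count table
#'
#' Pearson chi-square test that the row distributions are homogeneous.
#' All-zero rows and columns are dropped before testing (rare genotype
#' classes can be empty at realistic sample sizes) and the degrees of
#' freedom adjust accordingly. The Yates continuity correction is applied
#' only when `continuity_correction = TRUE` and the retained table is 2x2;
#' the correction term is capped at |O - E| so cells never overshoot.
#'
#' @param table Matrix of non-negative counts (r x c).
#' @param continuity_correction Logical; default FALSE.
#' @return A `snp_test_result` with fields `statistic`, `df`, `p_value`,
#'   `method`.
#' @export
#' @examples
#' chisq_homogeneity(matrix(c(30, 10, 70, 90), nrow = 2))
chisq_homogeneity <- function(table, continuity_correction = FALSE) {
  m <- as.matrix(table)
  if (any(m < 0) || any(!is.finite(m))) {
    abort_validation("counts must be finite and non-negative")
  }
  m <- m[rowSums(m) > 0, , drop = FALSE]
  m <- m[, colSums(m) > 0, drop = FALSE]
  if (nrow(m) < 2L || ncol(m) < 2L) {
    abort_validation(
      "degenerate table: fewer than 2 non-empty rows or columns")
  }
  ht <- suppressWarnings(
    stats::chisq.test(m, correct = continuity_correction))
  new_test_result(unname(ht$statistic), unname(ht$parameter),
                  unname(ht$p.value),
                  if (continuity_correction && all(dim(m) == 2L))
                    "chisq_homogeneity_yates" else "chisq_homogeneity")
}

#' Hardy-Weinberg equilibrium chi-square test
#'
#' One-degree-of-freedom goodness-of-fit chi-square comparing observed
#' genotype counts with the Hardy-Weinberg expectations `n*(1-p)^2`,
#' `2n*p*(1-p)`, `n*p^2` at the sample minor-allele frequency `p`.
#' A monomorphic sample cannot depart from equilibrium; it returns
#' statistic 0, p = 1, flagged `"monomorphic"`.
#'
#' @param counts Genotype counts as from [genotype_counts()].
#' @return A `snp_test_result`.
#' @export
#' @examples
#' hwe_chisq(genotype_counts(30, 40, 30))
hwe_chisq <- function(counts) {
  n <- sum(counts)
  if (n <= 0) abort_validation("total genotype count must be positive")
  p_hat <- (2 * counts[["n_minor_hom"]] + counts[["n_het"]]) / (2 * n)
  if (p_hat == 0 || p_hat == 1) {
    return(new_test_result(0, 1L, 1, "hwe_chisq (monomorphic)"))
  }
  expected <- n * c((1 - p_hat)^2, 2 * p_hat * (1 - p_hat), p_hat^2)
  observed <- c(counts[["n_major_hom"]], counts[["n_het"]],
                counts[["n_minor_hom"]])
  stat <- sum((observed - expected)^2 / expected)
  new_test_result(stat, 1L, stats::pchisq(stat, 1, lower.tail = FALSE),
                  "hwe_chisq")
}

#' Minor-allele odds ratio with Woolf confidence interval
#'
#' Cross-product odds ratio for the minor allele with the major allele as
#' referent, with the log-scale (Woolf) confidence interval
#' `exp(log(or) +/- z * sqrt(1/a + 1/b + 1/c + 1/d))`. When any cell is
#' zero, 0.5 is added to every cell first (Haldane-Anscombe) and the result
#' is flagged `haldane`. When a whole row or column is zero the odds ratio
#' is undefined and NA is returned with flag `undefined`.
#'
#' @param table 2x2 allele count matrix, rows `case`/`control`, columns
#'   `minor`/`major`.
#' @param level Confidence level, default 0.95.
#' @return A list with `or`, `ci_low`, `ci_high`, `level`, `flag`
#'   (`"none"`, `"haldane"` or `"undefined"`).
#' @export
#' @examples
#' odds_ratio_ci(matrix(c(20, 10, 80, 90), nrow = 2))
odds_ratio_ci <- function(table, level = 0.95) {
  m <- as.matrix(table)
  if (!all(dim(m) == 2L)) abort_validation("allele table must be 2x2")
  if (any(m < 0)) abort_validation("counts must be non-negative")
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    return(list(or = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                level = level, flag = "undefined"))
  }
  flag <- "none"
  if (any(m == 0)) {
    m <- m + 0.5
    flag <- "haldane"
  }
  a <- m[1, 1]; b <- m[1, 2]; c_ <- m[2, 1]; d <- m[2, 2]
  or <- (a * d) / (b * c_)
  z <- stats::qnorm(1 - (1 - level) / 2)
  se <- sqrt(1 / a + 1 / b + 1 / c_ + 1 / d)
  list(or = or, ci_low = exp(log(or) - z * se),
       ci_high = exp(log(or) + z * se), level = level, flag = flag)
}

#' Kruskal-Wallis test of scores across genotype groups
#'
#' Rank-sum test with tie correction and a chi-square approximation for the
#' P-value; degrees of freedom are the number of non-empty groups minus
#' one. The degenerate all-tied input (every observation equal) returns
#' statistic 0, p = 1 instead of a 0/0 in the tie correction.
#'
#' @param scores_by_genotype List of numeric vectors, one per genotype
#'   group (dosage 0, 1, 2); empty groups are dropped.
#' @return A `snp_test_result`.
#' @export
#' @examples
#' kruskal_wallis(list(c(1, 2), c(3, 4), c(5, 6)))
kruskal_wallis <- function(scores_by_genotype) {
  groups <- Filter(function(v) length(v) > 0,
                   lapply(scores_by_genotype, function(v) v[!is.na(v)]))
  if (length(groups) < 2L) {
    abort_validation("need at least 2 non-empty genotype groups")
  }
  values <- unlist(groups, use.names = FALSE)
  if (length(values) < 3L) {
    abort_validation("need at least 3 observations in total")
  }
  df <- length(groups) - 1L
  if (length(unique(values)) == 1L) {
    return(new_test_result(0, df, 1, "kruskal_wallis (all tied)"))
  }
  g <- factor(rep(seq_along(groups), lengths(groups)))
  kt <- stats::kruskal.test(values, g)
  new_test_result(unname(kt$statistic), unname(kt$parameter),
                  unname(kt$p.value), "kruskal_wallis")
}

# Genotype counts (major hom, het, minor hom) from a dosage vector,
# NA dropped.
dosage_to_counts <- function(dosage) {
  d <- dosage[!is.na(dosage)]
  genotype_counts(sum(d == 0), sum(d == 1), sum(d == 2))
}

#' Run the full association battery on a cohort
#'
#' For each SNP, individuals missing that SNP's dosage are dropped for that
#' SNP only (per-SNP complete case). The minor allele is re-oriented in the
#' combined case+control sample: if the dosage-coded allele has combined
#' frequency above 0.5 the dosage is flipped (2 - dosage) so reported MAFs,
#' odds ratios and tests always refer to the combined-sample minor allele;
#' an exact 0.5 tie keeps the file's coding. SNPs monomorphic in the
#' combined sample are flagged and their tests skipped. Skin-prick-test
#' columns, where present, are tested by Kruskal-Wallis across the three
#' dosage groups among individuals with a score.
#'
#' @param cohort A `cohort_dataset`.
#' @param continuity_correction Logical, passed to [chisq_homogeneity()];
#'   default FALSE.
#' @param level Confidence level for odds-ratio intervals, default 0.95.
#' @return A data frame with one row per SNP: `snp_id`, `n_used`,
#'   `maf_case`, `maf_control`, `p_allele`, `p_genotype`, `or_minor`,
#'   `ci_low`, `ci_high`, `hwe_p_case`, `hwe_p_control`, `monomorphic`,
#'   plus one `spt_<allergen>` P-value column per allergen.
#' @export
run_association <- function(cohort, continuity_correction = FALSE,
                            level = 0.95) {
  stopifnot(inherits(cohort, "cohort_dataset"))
  snp_ids <- attr(cohort, "snp_ids")
  allergens <- attr(cohort, "allergens")
  if (sum(cohort$status == "case") < 1L ||
      sum(cohort$status == "control") < 1L) {
    abort_validation("cohort must contain at least one case and one control")
  }

  rows <- lapply(snp_ids, function(sid) {
    dosage <- cohort[[sid]]
    keep <- !is.na(dosage)
    d <- dosage[keep]
    status <- cohort$status[keep]
    row <- list(snp_id = sid, n_used = sum(keep),
                maf_case = NA_real_, maf_control = NA_real_,
                p_allele = NA_real_, p_genotype = NA_real_,
                or_minor = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                hwe_p_case = NA_real_, hwe_p_control = NA_real_,
                monomorphic = FALSE)
    for (al in allergens) row[[paste0("spt_", al)]] <- NA_real_

    combined_freq <- mean(d) / 2
    if (combined_freq == 0 || combined_freq == 1) {
      row$monomorphic <- TRUE
      return(row)
    }
    if (combined_freq > 0.5) d <- 2L - d  # re-orient to combined-sample minor

    cc <- dosage_to_counts(d[status == "case"])
    ct <- dosage_to_counts(d[status == "control"])
    row$maf_case <- (2 * cc[["n_minor_hom"]] + cc[["n_het"]]) / (2 * sum(cc))
    row$maf_control <- (2 * ct[["n_minor_hom"]] + ct[["n_het"]]) / (2 * sum(ct))

    at <- allele_table(cc, ct)
    row$p_allele <- tryCatch(
      chisq_homogeneity(at, continuity_correction)$p_value,
      snpreplicate_validation_error = function(e) NA_real_)
    gt <- rbind(case = cc, control = ct)
    row$p_genotype <- tryCatch(
      chisq_homogeneity(gt, continuity_correction)$p_value,
      snpreplicate_validation_error = function(e) NA_real_)
    orci <- odds_ratio_ci(at, level)
    row$or_minor <- orci$or
    row$ci_low <- orci$ci_low
    row$ci_high <- orci$ci_high
    row$hwe_p_case <- hwe_chisq(cc)$p_value
    row$hwe_p_control <- hwe_chisq(ct)$p_value

    for (al in allergens) {
      sc <- cohort[[paste0("spt:", al)]][keep]
      groups <- split(sc[!is.na(sc)], d[!is.na(sc)])
      row[[paste0("spt_", al)]] <- tryCatch(
        kruskal_wallis(groups)$p_value,
        snpreplicate_validation_error = function(e) NA_real_)
    }
    row
  })

  out <- do.call(rbind, lapply(rows, function(r) as.data.frame(r)))
  rownames(out) <- NULL
  out
}
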