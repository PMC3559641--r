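test_that("allele_table collapses genotype counts to allele counts", {
  at <- allele_table(genotype_counts(10, 20, 10), genotype_counts(100, 0, 0))
  expect_equal(at["case", "minor"], 40L)
  expect_equal(sum(at["case", ]), 80L)
  expect_equal(at["control", "minor"], 0L)
  expect_equal(sum(at["control", ]), 200L)

  sym <- allele_table(genotype_counts(25, 50, 25), genotype_counts(25, 50, 25))
  expect_equal(sym["case", ], sym["control", ])
})

test_that("chisq_homogeneity matches hand-derived values and drops empty categories", {
  same <- chisq_homogeneity(matrix(c(30, 30, 70, 70), 2))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  t <- chisq_homogeneity(matrix(c(30, 10, 70, 90), 2))
  expect_equal(t$statistic, 12.5)
  expect_equal(t$p_value, 0.000407, tolerance = 1e-3)
  expect_equal(t$df, 1L)

  # all-zero genotype column dropped, df adjusts to 1
  m <- matrix(c(30, 25, 20, 25, 0, 0), nrow = 2)
  expect_equal(chisq_homogeneity(m)$df, 1L)

  expect_error(chisq_homogeneity(matrix(c(5, 0, 7, 0), 2)),
               class = "snpreplicate_validation_error")
})

test_that("chi-square equals the brute-force oracle on an exhaustive small sweep", {
  # every 2x2 table with cells 0..12 and no zero margins, vectorized oracle
  grid <- expand.grid(a = 0:12, b = 0:12, c = 0:12, d = 0:12)
  keep <- with(grid, (a + b) > 0 & (c + d) > 0 & (a + c) > 0 & (b + d) > 0)
  grid <- grid[keep, ]
  n <- with(grid, a + b + c + d)
  oracle <- with(grid,
                 n * (a * d - b * c)^2 /
                   ((a + b) * (c + d) * (a + c) * (b + d)))
  idx <- seq_len(nrow(grid))
  impl <- vapply(idx, function(i) {
    chisq_homogeneity(matrix(as.numeric(grid[i, ]), 2, byrow = TRUE))$statistic
  }, numeric(1))
  expect_equal(impl, oracle, tolerance = 1e-12)
})

test_that("chi-square equals the cell-sum oracle on random 2x3 tables", {
  set.seed(101)
  for (r in 1:100) {
    m <- matrix(rpois(6, lambda = sample(3:25, 1)), nrow = 2)
    if (any(rowSums(m) == 0) || sum(colSums(m) > 0) < 2) next
    mm <- m[, colSums(m) > 0, drop = FALSE]
    expect_equal(chisq_homogeneity(m)$statistic, oracle_chisq(mm),
                 tolerance = 1e-12)
  }
})

test_that("Yates correction applies only to 2x2 tables and is capped", {
  m <- matrix(c(30, 10, 70, 90), 2)
  expect_lt(chisq_homogeneity(m, continuity_correction = TRUE)$statistic,
            chisq_homogeneity(m)$statistic)
  # correction never drives |O - E| below zero
  near <- matrix(c(10, 10, 10, 11), 2)
  expect_gte(chisq_homogeneity(near, continuity_correction = TRUE)$statistic, 0)
  # 2x3: correction flag is a no-op
  m3 <- matrix(c(10, 12, 8, 9, 5, 6), nrow = 2)
  expect_equal(chisq_homogeneity(m3, continuity_correction = TRUE)$statistic,
               chisq_homogeneity(m3)$statistic)
})

test_that("HWE chi-square matches hand computation and flags monomorphs", {
  exact <- hwe_chisq(genotype_counts(25, 50, 25))
  expect_equal(exact$statistic, 0)
  expect_equal(exact$p_value, 1)

  dep <- hwe_chisq(genotype_counts(30, 40, 30))
  expect_equal(dep$statistic, 4.0)
  expect_equal(dep$p_value, 0.0455, tolerance = 1e-3)

  mono <- hwe_chisq(genotype_counts(100, 0, 0))
  expect_match(mono$method, "monomorphic")
  expect_equal(mono$p_value, 1)
})

test_that("odds ratio, Haldane correction and antisymmetry behave", {
  o <- odds_ratio_ci(matrix(c(20, 10, 80, 90), 2))
  expect_equal(o$or, 2.25)
  expect_equal(o$flag, "none")
  expect_true(o$ci_low <= 2.25 && 2.25 <= o$ci_high)

  null <- odds_ratio_ci(matrix(c(50, 50, 50, 50), 2))
  expect_equal(null$or, 1)
  expect_true(null$ci_low < 1 && 1 < null$ci_high)

  hald <- odds_ratio_ci(matrix(c(0, 10, 100, 90), 2))
  expect_equal(hald$flag, "haldane")
  expect_equal(hald$or, (0.5 * 90.5) / (100.5 * 10.5))

  undef <- odds_ratio_ci(matrix(c(0, 10, 0, 90), 2))
  expect_equal(undef$flag, "undefined")
  expect_true(is.na(undef$or))

  # swapping case/control rows inverts the OR and reflects the CI
  m <- matrix(c(23, 11, 77, 89), 2)
  fwd <- odds_ratio_ci(m)
  rev_ <- odds_ratio_ci(m[2:1, ])
  expect_equal(rev_$or, 1 / fwd$or)
  expect_equal(rev_$ci_low, 1 / fwd$ci_high)
  expect_equal(rev_$ci_high, 1 / fwd$ci_low)
})

test_that("Kruskal-Wallis matches the rank formula and handles degeneracy", {
  kw <- kruskal_wallis(list(c(1, 2), c(3, 4), c(5, 6)))
  # H = 12/(n(n+1)) * sum(Rj^2/nj) - 3(n+1) with ranks 1..6: 32/7
  expect_equal(kw$statistic, 12 / 42 * (9 / 2 + 49 / 2 + 121 / 2) - 21)
  expect_equal(kw$p_value, 0.1017, tolerance = 1e-3)
  expect_equal(kw$df, 2L)

  tied <- kruskal_wallis(list(c(2, 2), c(2, 2), c(2, 2)))
  expect_equal(tied$statistic, 0)
  expect_equal(tied$p_value, 1)

  two <- kruskal_wallis(list(c(1, 2), numeric(0), c(5, 6)))
  expect_equal(two$df, 1L)

  expect_error(kruskal_wallis(list(1:5, numeric(0))),
               class = "snpreplicate_validation_error")

  # invariance under strictly monotone transforms of the scores
  set.seed(7)
  groups <- list(runif(8), runif(5), runif(7))
  base <- kruskal_wallis(groups)$statistic
  expect_equal(kruskal_wallis(lapply(groups, exp))$statistic, base)
  expect_equal(kruskal_wallis(lapply(groups, function(x) x^3))$statistic, base)
})

test_that("run_association assembles the per-SNP battery", {
  cohort <- read_cohort(write_toy_cohort())
  res <- run_association(cohort)
  expect_equal(nrow(res), 1L)
  expect_true(all(c("p_allele", "p_genotype", "or_minor", "hwe_p_case",
                    "spt_birch") %in% names(res)))

  # strong effect at realistic sizes is overwhelmingly significant
  strong <- simulate_cohort(toy_spec(or = 7.75, seed = 31L))
  expect_lt(run_association(strong)$p_allele, 0.001)

  # monomorphic SNP flagged, others tested
  spec <- simulation_spec(
    30, 30, data.frame(snp_id = c("rsA", "rsB"), p0 = c(0.3, 0.3),
                       or = c(1, 1)), seed = 2L)
  co <- simulate_cohort(spec)
  co$rsB <- 0L  # force monomorphic
  res2 <- run_association(co)
  expect_equal(res2$monomorphic, c(FALSE, TRUE))
  expect_true(is.na(res2$p_allele[2]))

  # dosage re-orientation: flipping the coded allele leaves results invariant
  flipped <- co
  flipped$rsA <- 2L - flipped$rsA
  res3 <- run_association(flipped)
  expect_equal(res3$p_allele[1], res2$p_allele[1])
  expect_equal(res3$maf_case[1], res2$maf_case[1])
})

test_that("allele-test type-I error is nominal on null cohorts", {
  n_rep <- 1000L
  rej <- 0L
  for (r in seq_len(n_rep)) {
    co <- simulate_cohort(toy_spec(or = 1.0, n_case = 120L, n_control = 120L,
                                   seed = 40000L + r))
    rej <- rej + (run_association(co)$p_allele < 0.05)
  }
  expect_lt(abs(rej / n_rep - 0.05), 3 * sqrt(0.05 * 0.95 / n_rep))
})
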