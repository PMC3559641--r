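test_that("case_allele_freq follows the multiplicative odds model", {
  expect_equal(case_allele_freq(0.25, 3.0), 0.5)
  expect_equal(case_allele_freq(0.0, 7.75), 0.0)
  for (p0 in c(0.05, 0.25, 0.4, 0.9)) {
    expect_equal(case_allele_freq(p0, 1.0), p0)
  }
  expect_error(case_allele_freq(0.25, 0), class = "snpreplicate_validation_error")
  expect_error(case_allele_freq(0.25, -1), class = "snpreplicate_validation_error")

  # monotone increasing in or for fixed p0
  for (p0 in c(0.1, 0.25, 0.4)) {
    ors <- c(0.2, 0.5, 1, 2, 5, 10)
    expect_true(all(diff(case_allele_freq(p0, ors)) > 0))
  }
})

test_that("simulate_allele_counts is a seeded binomial allele model", {
  t1 <- simulate_allele_counts(352, 709, 0.25, 2.0, seed = 5)
  t2 <- simulate_allele_counts(352, 709, 0.25, 2.0, seed = 5)
  expect_identical(t1, t2)
  expect_equal(rowSums(t1), c(case = 2 * 352, control = 2 * 709))

  # null model: case and control minor fractions agree within 4 binomial SE
  t0 <- simulate_allele_counts(5000, 5000, 0.25, 1.0, seed = 17)
  se <- sqrt(2 * 0.25 * 0.75 / 10000)
  expect_lt(abs(t0["case", "minor"] / 10000 - t0["control", "minor"] / 10000),
            4 * se)

  expect_error(simulate_allele_counts(100, 100, 0, 2, 1),
               class = "snpreplicate_validation_error")
  expect_error(simulate_allele_counts(100, 100, 1, 2, 1),
               class = "snpreplicate_validation_error")
})

test_that("a strong effect orders case and control frequencies in nearly all seeds", {
  # OR 7.75 at the Swedish sizes is ~20 SE; brute force over 10,000 seeds
  n_seeds <- 10000L
  hits <- 0L
  for (s in seq_len(n_seeds)) {
    tab <- simulate_allele_counts(352, 709, 0.25, 7.75, seed = s)
    hits <- hits + (tab["case", "minor"] / 704 > tab["control", "minor"] / 1418)
  }
  expect_gte(hits, 9990L)
})

test_that("simulated genotypes sit at the target frequencies and in HWE", {
  # control MAF concentrates on p0 at large n
  spec <- toy_spec(or = 1.0, n_case = 100L, n_control = 10000L, seed = 3L)
  cohort <- simulate_cohort(spec)
  ctrl <- cohort$rs0001[cohort$status == "control"]
  expect_lt(abs(mean(ctrl) / 2 - 0.25), 0.02)

  # under or = 1 the pooled sample passes the HWE test ~95% of the time
  n_rep <- 1000L
  pass <- 0L
  for (r in seq_len(n_rep)) {
    co <- simulate_cohort(toy_spec(or = 1.0, n_case = 150L, n_control = 150L,
                                   seed = 1000L + r))
    counts <- genotype_counts(sum(co$rs0001 == 0), sum(co$rs0001 == 1),
                              sum(co$rs0001 == 2))
    pass <- pass + (hwe_chisq(counts)$p_value >= 0.05)
  }
  expect_gte(pass / n_rep, 0.93)
})

test_that("null SPT effects give a calibrated Kruskal-Wallis test", {
  n_rep <- 400L
  rej <- 0L
  for (r in seq_len(n_rep)) {
    co <- simulate_cohort(toy_spec(or = 1.0, n_case = 200L, n_control = 50L,
                                   seed = 5000L + r, spt = TRUE))
    cases <- co$status == "case"
    groups <- split(co$`spt:birch`[cases], co$rs0001[cases])
    rej <- rej + (kruskal_wallis(groups)$p_value < 0.05)
  }
  # binomial 3 SE band around 0.05 at 400 replicates: +/- 0.033
  expect_lt(abs(rej / n_rep - 0.05), 3 * sqrt(0.05 * 0.95 / n_rep))
})

test_that("all randomness flows from the master seed, independent of SNP order", {
  snps <- data.frame(snp_id = c("rsA", "rsB"), p0 = c(0.2, 0.4),
                     or = c(1.5, 0.7))
  s1 <- simulation_spec(50, 50, snps, seed = 9L)
  s2 <- simulation_spec(50, 50, snps[2:1, ], seed = 9L)
  c1 <- simulate_cohort(s1)
  c2 <- simulate_cohort(s2)
  expect_identical(c1$rsA, c2$rsA)
  expect_identical(c1$rsB, c2$rsB)
  expect_identical(as.data.frame(simulate_cohort(s1)), as.data.frame(c1))
})

test_that("simulation spec round-trips through the YAML config format", {
  path <- tempfile(fileext = ".yaml")
  writeLines(c(
    "n_case: 30",
    "n_control: 40",
    "seed: 7",
    "snps:",
    "  - snp_id: rs123",
    "    p0: 0.3",
    "    or: 1.8",
    "spt_effects:",
    "  - allergen: timothy",
    "    baseline_log_mean: 0.1",
    "    per_dosage_log_shift: 0.2",
    "    log_sd: 0.5"), path)
  spec <- read_simulation_spec(path)
  expect_equal(spec$n_case, 30L)
  expect_equal(spec$snps$or, 1.8)
  expect_equal(spec$spt_effects$snp_id, "rs123")  # defaults to first SNP
  cohort <- simulate_cohort(spec)
  expect_equal(nrow(cohort), 70L)
  expect_error(simulation_spec(10, 10, data.frame()),
               class = "snpreplicate_validation_error")
})

test_that("association on simulated cohorts recovers the generating OR", {
  # 95% CI coverage of or = 2.0 across 500 cohorts at the Swedish sizes
  n_rep <- 500L
  covered <- 0L
  for (r in seq_len(n_rep)) {
    co <- simulate_cohort(toy_spec(or = 2.0, seed = 20000L + r))
    res <- run_association(co)
    covered <- covered + (res$ci_low <= 2.0 && 2.0 <= res$ci_high)
  }
  expect_gte(covered / n_rep, 0.93)
  expect_lte(covered / n_rep, 0.97)
})
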