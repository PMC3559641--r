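# Shared fixtures built in code at test time.

# A tiny hand-written cohort TSV: 2 cases, 2 controls, one SNP, one
# skin-prick score column.
write_toy_cohort <- function(path = tempfile(fileext = ".tsv")) {
  writeLines(c(
    "individual_id\tstatus\trs0001\tspt:birch",
    "c1\tcase\t2\t1.5",
    "c2\tcase\t1\t0.8",
    "k1\tcontrol\t0\tNA",
    "k2\tcontrol\t1\tNA"), path)
  path
}

# Simulation spec used across tests: one moderately associated SNP at the
# Swedish cohort sizes.
toy_spec <- function(or = 2.0, p0 = 0.25, n_case = 352L, n_control = 709L,
                     seed = 11L, spt = FALSE) {
  simulation_spec(
    n_case = n_case, n_control = n_control,
    snps = data.frame(snp_id = "rs0001", p0 = p0, or = or),
    spt_effects = if (spt) {
      data.frame(allergen = "birch", baseline_log_mean = 0,
                 per_dosage_log_shift = 0, log_sd = 0.5)
    } else NULL,
    seed = seed)
}

# Independent brute-force Pearson chi-square oracle (no dropping, no
# correction): straight sum((O - E)^2 / E) from margins.
oracle_chisq <- function(m) {
  e <- outer(rowSums(m), colSums(m)) / sum(m)
  sum((m - e)^2 / e)
}

# Exact two-sided binomial sign-test oracle by direct enumeration.
oracle_binom_two_sided <- function(k, n) {
  probs <- stats::dbinom(0:n, n, 0.5)
  min(1, sum(probs[probs <= probs[k + 1L] * (1 + 1e-7)]))
}
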