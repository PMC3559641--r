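---
title: "Assessing replication of candidate-gene SNP associations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing replication of candidate-gene SNP associations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snpreplicate)
```

## The problem

Candidate-gene case-control studies of allergic rhinitis (AR) have reported
more than a hundred SNP associations, mostly from small samples, and few
have been replicated. When an independent study genotypes those same SNPs
and finds nothing, three explanations compete: the original reports were
false positives, the published odds ratios were inflated by the winner's
curse, or the replication study lacked power. `snpreplicate` implements the
analyses needed to separate these explanations:

1. **Per-SNP association statistics** on the replication cohort(s):
   allele-based (2x2) and genotype-based (2x3) chi-square homogeneity
   tests, Hardy-Weinberg equilibrium (HWE) checks within cases and
   controls, minor-allele odds ratios (OR) with confidence intervals, and
   Kruskal-Wallis tests of quantitative skin-prick-test (SPT) scores by
   genotype.
2. **P-value distribution diagnostics**: if no SNP has an effect, the
   P-values are uniform on [0, 1]; an observed-versus-expected bin table
   with finer bins at small P, plus Storey q-values, shows whether the
   family of tests deviates from that null in aggregate.
3. **Simulation-based power**: for each published OR, the probability that
   the replication study's allele test would have rejected had that OR
   been true, and from the per-SNP powers the expected number of
   significant results with its standard deviation.
4. **Cross-study concordance**: Spearman correlation of per-SNP ORs
   between studies and the concordant/discordant sign split around OR = 1,
   which retains sensitivity to real-but-inflated effects even when
   individual tests are underpowered.

A synthetic cohort generator provides individual-level data with exactly
the statistical structure these analyses assume, so the whole pipeline is
testable without access to the original genotypes (which were never
deposited).

## Models and assumptions

### The allelic odds model

A SNP is coded as minor-allele dosage 0/1/2, the minor allele defined by
frequency in the combined case+control sample (an exact 0.5 tie keeps the
file's coding; the combined-sample rule keeps case and control ORs on a
common referent). With control minor-allele frequency $p_0$ and allelic
odds ratio $\psi$, the case allele frequency follows from multiplying the
allele odds:

$$p_1 = \frac{\psi\, p_0}{1 - p_0 + \psi\, p_0}.$$

`case_allele_freq()` is exactly this map; it is increasing in $\psi$ and
fixes $p_0$ at $\psi = 1$.

### Power simulation

`simulate_power()` works at the allele level: each replicate draws the
case minor-allele count from $\mathrm{Bin}(2n_\text{case}, p_1)$ and the
control count from $\mathrm{Bin}(2n_\text{control}, p_0)$, forms the 2x2
allele table, computes the *uncorrected* Pearson chi-square and compares
it with the upper-tail critical value (3.841 at $\alpha = 0.05$, 10.828 at
$\alpha = 0.001$, df 1). Power is the rejection fraction over `n_reps`
replicates (default 10,000). Replicates with a zero table margin are
Haldane-corrected (0.5 added to each cell) rather than redrawn: redrawing
would condition on polymorphism and bias power upward at rare-allele
configurations, and correction keeps the denominator at `n_reps`.

Allele-level sampling (rather than drawing genotypes and collapsing) is
the minimal model for an allele-based test; the individual-level generator
exists separately for cohort emulation. The analytic two-proportion
z-test power (`analytic_power()`, with allele denominators $2n$) is kept
solely as an independent cross-check: the squared pooled z statistic *is*
the uncorrected chi-square, so in the mid-power regime the two must agree
up to Monte-Carlo and normal-approximation error (the test suite requires
0.03).

The expected number of significant tests, if every published OR were
true, treats the tests as independent Bernoulli trials:
$E = \sum_i \text{power}_i$, $SD = (\sum_i \text{power}_i(1 -
\text{power}_i))^{1/2}$ (`expected_significant()`). Comparing $E$ with
the observed count expresses the replication shortfall in standard
deviations.

### Multiple testing

`qvalues()` implements the direct FDR recipe: with P-values sorted
ascending, $q_{(i)} = \min_{j \ge i}\, \hat\pi_0\, m\, p_{(j)} / j$. With
$\hat\pi_0 = 1$ this reduces exactly to Benjamini-Hochberg, which the test
suite verifies pointwise on random vectors. $\hat\pi_0$ comes from
$\hat\pi_0(\lambda) = \#\{p > \lambda\}/(m(1 - \lambda))$, either at a
fixed $\lambda$ (default 0.5) or, by default, from a cubic smoothing
spline over $\lambda = 0.05, 0.10, \ldots, 0.90$ evaluated at the largest
$\lambda$ — the original recipe's defaults, since the settings actually
used upstream of the published q-values are not recorded. The estimate is
clipped to $(0, 1]$, with a floor of $1/m$ when the raw estimate is 0
(otherwise heavily non-null toy inputs would return all-zero q-values).

The bin table (`pvalue_bin_table()`) uses bins
$(0.1, 1], (0.05, 0.1], (0.01, 0.05], (0.001, 0.01], [0, 0.001]$:
lower-open/upper-closed with the lowest bin closed at zero, the one
convention under which the five bins tile $[0, 1]$ exactly (published
range labels such as "1.0–0.1" do not state the edge rule; a boundary
value like $p = 0.05$ falls in the lower bin). Expected counts are
$m \times$ bin width, kept unrounded internally; `render_expected()`
applies the display rule — round half away from zero, to the nearest
integer at $\ge 10$, one decimal in $[1, 10)$, two decimals below 1 —
which reproduces every printed expected value for $m = 49$
(44, 2.5, 2.0, 0.44, 0.05). For $m = 45$ the same rule gives 0.05 in the
lowest bin where the published table prints 0.040; that printed value is
inconsistent with $m = 45$ (which yields 0.045) and is treated as a typo,
not reproduced.

### Concordance

`sign_concordance()` classifies a pair of ORs as concordant when
$(\psi_A - 1)(\psi_B - 1) > 0$, discordant when negative, and excluded
when either is missing or exactly 1 — the published definition covers only
the "> 1" and "< 1" classes, so ties are excluded rather than assigned.
The concordant/discordant split is tested against 50:50 with the exact
two-sided binomial test. `spearman_or()` uses average ranks for ties and
a t-approximation P-value, switching to the exact permutation distribution
for $n \le 9$ without ties; because ranks are monotone-invariant, OR and
log-OR give identical results.

## The synthetic cohort generator

`simulate_cohort()` draws control genotypes from Hardy-Weinberg
proportions $((1-p_0)^2,\, 2p_0(1-p_0),\, p_0^2)$ at dosage (0, 1, 2) and
case genotypes from HWE at $p_1$. SPT-like scores are log-normal:
$\exp(\mathcal{N}(\mu_0 + \beta d, \sigma))$ for a case with dosage $d$ —
any positive right-skewed family would be defensible for a wheal-size
ratio; log-normal is the tractable choice, and scores are rounded to three
decimals (measurement-scale precision, and it makes cohort files
round-trip exactly). Controls carry no score, matching cohorts whose
controls are non-atopic by definition. Each SPT effect block names the SNP
whose dosage drives it (defaulting to the first SNP in the spec).

One master seed drives everything; per-SNP and per-allergen streams are
derived by a stable hash of (seed, key), so adding, removing or reordering
SNPs leaves other columns' draws unchanged and identical seeds give
byte-identical files.

What the generator deliberately does **not** model: linkage
disequilibrium between SNPs, covariates (age, sex), population
stratification, genotyping error and per-SNP missingness patterns.
Passing tests on synthetic cohorts therefore demonstrate the statistical
machinery is correct under the stated model — not that real cohorts
satisfy that model.

Default parameter choices where no observed value exists: control MAF
$p_0 = 0.25$ (a mid-range common-variant frequency — the observed MAFs
behind the published power table live in supplementary files that are not
available; the extreme-OR power values reproduced in the tests are
insensitive to this choice), and cohort sizes 352/709 and 948/580, the
two replication studies' sizes.

## Numerical and design choices

* **Continuity correction OFF by default** everywhere. The power
  simulation's critical-value comparison explicitly uses the uncorrected
  statistic; whether the published per-SNP P-values used R's default 2x2
  Yates correction is unknown, so the correction is exposed as a flag
  (`continuity_correction`) but never silently applied. When applied, the
  correction term is capped at $|O - E|$.
* **Zero genotype categories are dropped** before the 2x3 test, with df
  adjusting, rather than erroring: rare-allele homozygotes routinely
  vanish at these sample sizes. A genotype-level test on 2x3 homogeneity
  (not a trend test) is used; the upstream choice is unstated and 2x3 is
  the plain reading of "genotype frequencies investigated for
  association".
* **HWE is the 1-df chi-square**, not the exact test, matching the era's
  standard toolkit; monomorphic samples return statistic 0 / p = 1 with a
  flag instead of 0/0.
* **All-tied Kruskal-Wallis input** returns statistic 0 / p = 1 (the tie
  correction would otherwise divide by zero; the input is degenerate but
  reachable on synthetic data).
* **Haldane-Anscombe 0.5** is added to all four cells of an OR table with
  any zero cell (flagged); a fully zero row or column makes the OR
  undefined and returns NA with a flag.
* **Per-SNP complete case**: an individual missing one SNP's dosage is
  dropped for that SNP only, consistent with per-SNP genotyping rates
  just under 100%.
* **Monomorphic SNPs** (combined sample) are flagged and skipped, the way
  a replication panel loses SNPs that are not polymorphic in a new
  population; power-table cells for a population where the SNP is
  monomorphic render as "-".
* Result tables render floats to 4 significant figures, with scientific
  notation below 1e-4, matching the reporting granularity of the
  association tables this format mirrors.

## Problem sizes in the test suite

The suite verifies calibration at the sizes the methods are meant for:
CI coverage of a generating OR of 2.0 over 500 synthetic cohorts of
352/709; type-I error of the allele test over 1,000 null cohorts; HWE
test size over 1,000 replicates; power simulations at 10,000 replicates;
the chi-square implementation against a brute-force $\sum (O-E)^2/E$
oracle over every 2x2 table with cells up to 20 and exhaustive small 2x3
tables; and q-values against Benjamini-Hochberg over 200 random vectors.

## Known limitations

* Power is computed for the allele-based test only (no 2x3 or
  Kruskal-Wallis power), and there is no inverse (sample-size) solver.
* No meta-analytic pooling, heterogeneity statistics or shrinkage in the
  cross-study module; it measures concordance, not combined effect size.
* The q-value implementation targets the direct-FDR estimator with the
  defaults above; local FDR and permutation nulls are out of scope.
* The packaged catalog records published ORs and source sizes; the
  original studies' observed MAFs are unavailable, so catalog-driven power
  uses observed cohort MAFs when a cohort is supplied and the 0.25
  default otherwise.

## A worked example

```{r example, eval = FALSE}
library(snpreplicate)

# simulate two replication cohorts sharing a 45-SNP null panel
snps <- data.frame(snp_id = sprintf("rs%03d", 1:45), p0 = 0.25, or = 1.0)
sp <- tempfile(fileext = ".tsv")
cp <- tempfile(fileext = ".tsv")
cmd_simulate(simulation_spec(352, 709, snps, seed = 1), sp)
cmd_simulate(simulation_spec(948, 580, snps, seed = 2), cp)

# full report: association, q-values, bin tables, power, concordance
out <- cmd_report(c(SP = sp, CP = cp), catalog_path = NULL,
                  out_dir = tempfile("report"), seed = 1, n_reps = 10000)
out$concordance
```
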