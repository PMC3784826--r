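---
title: "Combining family-based and case-control association tests with independent screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Combining family-based and case-control association tests with independent screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Genome-wide association studies sometimes recruit two kinds of subjects at
once: unrelated cases and controls ("singletons"), and mother-father-offspring
trios ascertained through an affected or unaffected proband.  Analyzed
separately, each subset pays the full genome-wide multiple-testing penalty
(`alpha / M` over `M` markers) with only part of the sample.  Pooling the trio
offspring into the case-control set uses everyone but discards parental
information and inherits the case-control design's sensitivity to population
stratification.

`trioscreen` implements a two-step alternative.  Each subset first *screens*
markers using information that is statistically independent of its own
association test; the two screening rankings are aggregated; and only the
top `K` markers (default 10) are tested, each at level `alpha / K` - with
`K = 10` and `alpha = 0.05`, a per-marker threshold of `0.005` instead of,
say, `1.3e-7` at `M = 384,094`.  Because the screening information never
touches what the tests use, no further multiple-testing correction for the
screening step is needed.

## The test statistics

**Cochran-Armitage trend test** (unrelated subset).  For genotype classes
`j = 0, 1, 2` (minor-allele count) with `a_j` affected and `u_j` unaffected
subjects, `n_j = a_j + u_j`, `A = sum(a_j)`, `N = sum(n_j)` and additive
scores `s_j = j`:

$$U = \sum_j s_j\!\left(a_j - n_j \frac{A}{N}\right),\qquad
  V = \frac{A(N-A)}{N^2}\left(\sum_j s_j^2 n_j -
      \frac{(\sum_j s_j n_j)^2}{N}\right),\qquad Z = U/\sqrt V .$$

The unconditional (binomial, `N^2`) variance is the default; the
hypergeometric `N/(N-1)` correction is available via an argument.  The
difference is `O(1/N)` and irrelevant at GWAS sample sizes.  Strata (we use
the cartesian product of the recruitment-centre label and sex, which adjusts
for sex and stratifies by centre in one pass) are combined
Cochran-Mantel-Haenszel style: `Z = sum(U_k) / sqrt(sum(V_k))`, degenerate
strata contributing nothing.

**Offset FBAT** (trio subset).  Conditional on the parental genotypes `S`,
the offspring minor-allele count `X` is the sum of two independent
Bernoulli(`score/2`) transmissions, giving exact conditional moments
`E(X|S)` and `Var(X|S)`.  With phenotype `Y` in {0, 1} and offset `mu`:

$$U = \sum_i (Y_i - \mu)\,(X_i - E(X_i|S_i)),\qquad
  V = \sum_i (Y_i - \mu)^2\, \mathrm{Var}(X_i|S_i),\qquad Z = U/\sqrt V .$$

The offset is the trait prevalence - 0.3 here, the prevalence of diabetic
nephropathy among type 1 diabetics - which maximizes power when
ascertainment is not conditioned on the trait.  Unaffected offspring enter
with weight `-mu`; at `mu = 0` the statistic reduces to the traditional
affecteds-only TDT.  We use the conditional (Mendel-model) variance, not an
empirical one: in complete trios the sufficient statistics are fully
observed.  Results with fewer than 10 informative trios are flagged
`low_info` rather than suppressed.

## The screening statistics

**Conditional power (trios).**  The joint likelihood factorizes as
`P(Y, X, S) = P(X | Y, S) P(Y, S)`; screening uses only `P(Y, S)` - parental
genotypes and offspring phenotypes - so the FBAT, built from `P(X | Y, S)`,
is independent of the ranking.  Per SNP we (1) form the proxy genotype
`g_i = E(X_i | S_i)`, (2) regress `Y` on `g` by least squares for a slope
`b` and residual variance `s^2`, (3) approximate the FBAT noncentrality by
`delta = b sqrt(V) / s^2` with `V = sum((Y_i - mu)^2 Var(X_i | S_i))`, and
(4) score the SNP by the two-sided power
`Phi(delta - z_{alpha/2}) + Phi(-delta - z_{alpha/2})`.  The derivation is
first-order: under a small additive effect `b`, `E[U] ~ (b/s^2) V` and
`Var_0[U] = V`.  Power is strictly increasing in `|delta|`, so the *ranking*
is insensitive both to the choice of `alpha` and to the roughness of the
approximation.  Using `Y` rather than `Y - mu` as the regression response
changes only the intercept, not the slope, hence not the ranks.  The
function's interface only ever reads parental genotype columns; a test
verifies that scrambling every offspring column leaves the output
byte-identical.

**C2BAT partitioning (cases/controls).**  The margins of the
affection-by-genotype table are the sufficient statistics of its cells.  Per
SNP, a simple random sample of each genotype class - defaults 75% of minor
homozygotes, 50% of heterozygotes, 25% of major homozygotes, drawn ignoring
phenotype - forms a *testing table*; the remainder is the *screening table*.
For ranking, the testing cells are *imputed under the null* given the
testing margins (sequential hypergeometric draws, so every margin holds
exactly), added to the screening table, and the absolute trend `Z` of the
sum is the screening score.  The association p-value comes from the trend
test on the real testing table alone.  The score depends on disjoint
subjects plus margins only, so it is independent of the test.  Selection by
genotype class alone (not genotype-by-phenotype cell) is what preserves
this independence.  Each SNP uses an RNG stream derived from the master
seed and its own index, so results are reproducible and unaffected by which
other SNPs are in the run.

## Aggregation and decision

Subset rankings (1 = most promising; ties broken by smaller genomic
position, then marker id) are combined by the mean of log-ranks, whose
ordering is identical to the rank product's.  The implementation sorts on
the exact integer rank product: the mathematically equivalent log-scale sum
can split exact product ties inconsistently by one floating-point ulp.
Rank-product ties are broken by the better family rank, then marker id.
Markers unranked in one subset receive that subset's worst rank and are
flagged; the eligible universe is the intersection of markers passing QC in
both subsets.

The top `K` markers by aggregate rank are tested with Fisher's combined
probability, `X = -2 (ln p_fam + ln p_cc) ~ chi^2_4`, declaring
significance at `p < alpha / K`.  `p_fam` is the full-data FBAT p-value
(legitimate: the family screen never saw offspring genotypes) and `p_cc` is
the C2BAT *testing-table* p-value (legitimate: the case-control screen saw
only disjoint subjects plus margins).  Substituting the full-sample trend p
here would silently break the independence Fisher's method needs, so the
pipeline does not offer it.  A sample-size weighted-Z combination
(`Z_i = Phi^{-1}(1 - p_i/2)`, weights `sqrt(N_i)`) is provided for the
single-step meta-analysis comparison.  P-values are floored at `1e-300`
before logs.

## Quality control

Markers are removed for: Mendelian errors in 3 or more trios (default
`max_mendel_trios = 2`); call rate below 0.95; minor-allele frequency below
0.01; or monomorphism.  At retained markers, a trio showing a Mendelian
error is set missing at that marker only (PLINK-like per-SNP zeroing).
Whether error trios at retained markers should be zeroed or kept is a
convention with no single standard; zeroing is our choice, and the raw
matrix is left untouched for callers who want the alternative.  QC runs separately per subset
(population subset: unrelated subjects; family subset: trio members plus
the Mendelian filter), mirroring the with/without-offspring QC duality of
mixed designs.

## The synthetic cohort generator

`simulate_cohort()` emulates the mixed design: parents and singletons in
Hardy-Weinberg equilibrium at a per-SNP MAF drawn uniformly from
`maf_range` (default 0.05-0.5), offspring by Mendelian transmission,
disease by `logit P(Y=1|X) = b0 + sum(log OR_c X_c)` with `b0` calibrated
by root-finding (tolerance 1e-8) against the enumerated causal-genotype
distribution so the marginal prevalence equals 0.3 by default.  Singletons
and probands are ascertained by phenotype via rejection sampling (capped at
1e6 draws) to hit the requested case/control counts; `trio_case_fraction`
(default 0.5) splits the trio quota between affected and unaffected
probands.  Optional stratification draws each family or singleton from one
of two subpopulations shifting MAF by `±maf_delta/2` and prevalence by
`±prevalence_delta/2`.  Parent phenotypes are missing, as under
proband-based recruitment.

What the generator does *not* emulate: linkage disequilibrium (SNPs are
independent), genotyping error, duo families, sibships, cryptic
relatedness, more than two subpopulations.  A green calibration or power
test therefore establishes correctness of the statistics under the stated
sampling model - not robustness to LD-induced correlation between tests,
nor realistic genome structure.

## Numerical and design choices

* Two-sided p-values from the normal approximation throughout (standard
  GWAS practice); a label-permutation oracle backs the approximation in the
  tests.  No continuity corrections.
* Degenerate inputs (zero variance) yield `untestable` flags with missing
  p-values, never exceptions; degenerate strata or trios contribute zero.
* Offspring with exactly one recorded parent are excluded from both the
  trio set and the singleton set: one-parent conditioning rules are a
  different method, and silently treating such subjects as unrelated would
  bias both subsets.  When several offspring share parents, the lowest
  individual id is kept.
* Fraction rounding in C2BAT is half-away-from-zero; marker order is MAP
  order and subject order is PED order everywhere.
* Missing allele code is `"0"`; PED phenotype 1/2 maps to 0/1 internally.

## Validation design

The test suite pairs every statistic with an independent oracle: the trend
test against `stats::prop.trend.test`, against the subject-level identity
`chi^2 = N r^2` over *all* 2x3 tables with `N <= 12`, and against a 100,000
label-permutation null; the FBAT against full enumeration of all `3^n`
offspring configurations for up to 6 trios; Fisher's and the weighted-Z
combination against hand-evaluated closed forms.  Property tests cover
type-I calibration of all four tests (within 3 binomial standard errors at
2,000 null SNPs, 500 trios, 500/500 singletons), screen/test independence
(|Spearman rho| < 3/sqrt(M)), familywise error of the two-step rule at
`K = 10` over 400 null replicates (200 SNPs, 150 trios, 150/150 singletons
per replicate - the replicate world is ours, chosen once), the
rank-product/log-rank ordering equivalence over 1,000 random permutations,
and the power comparison at the stated world (one causal SNP, OR 2, MAF
0.3, M = 5,000, 500 trios + 500/500 singletons, 200 paired replicates)
against all-marker Bonferroni on the same Fisher p-values.  The
stratification property - confounding inflates the pooled trend test while
the FBAT stays calibrated - is asserted as a simulation property of the
generator and tests, not as a biological claim.

## Worked example

```{r, eval = FALSE}
library(trioscreen)

st <- simulate_cohort(simulation_config(
  n_snps = 2000, n_trios = 500, n_cases = 500, n_controls = 500,
  causal = data.frame(index = 1000, or = 2, maf = 0.3), seed = 42))

res <- run_all(run_config(seed = 42, out_dir = "example_out"), study = st)
subset(res$two_step, selected_top_k,
       select = c(snp_id, aggregate_rank, p_family, p_cc, p_fisher,
                  significant))
```

## Known limitations

Only complete trios are analyzed (no duos, no larger sibships); only
biallelic autosomal-style markers (no X-chromosome dosage handling); no
covariate-adjusted (logistic regression) tests; no LD-aware multiple
testing; the conditional-power formula is a first-order approximation whose
absolute value should not be interpreted as an achieved power, only as a
ranking score.
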