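---
title: "Methods: rare-variant carrier prevalence and gene constraint from aggregate counts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rare-variant carrier prevalence and gene constraint from aggregate counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(RareCarrier)
```

# The data model

RareCarrier works entirely on *aggregate* allele-count data of the kind
exported by large exome databases: per variant and per ancestry group, the
alternate-allele count `AC`, the total number of called alleles `AN`, the
number of homozygous-alternate individuals `nhomalt`, and sex-split allele
counts, alongside functional annotations (VEP-style consequence, SIFT,
PolyPhen-2, ClinVar assertion, a QC flag). The ancestry composition lives
in a `PopulationPanel`; a designated catch-all group ("other" ancestries)
is kept in the data model but excluded from every analysis, because it
mixes ancestries and supports no population-specific inference.

Validation enforces the count algebra on load: `0 ≤ 2·nhomalt ≤ AC ≤ AN ≤
2n` per group, `AC_male + AC_female = AC`, and a protein change for every
missense/synonymous record. Violations raise errors naming the offending
variants; rows are never silently dropped. The VCF and TSV dialects load to
identical tables, with multi-allelic sites decomposed one record per
alternate allele and the site-level `AN` duplicated per alt.

# Pathogenicity classification

`classifyVariants()` applies a fixed-order cascade; the order matters and
is part of the contract:

1. QC-flagged records are excluded.
2. Rarity: the alt-allele frequency must be **strictly** below
   `mafThreshold` (default 0.01) in **every** analysed group. The strict
   inequality follows the usual "lower than 1%" phrasing of carrier
   screens; a variant at exactly 1% anywhere is not rare. No folding to
   the minor allele is applied — below 1% the alt allele is the minor
   allele.
3. Records annotated against a non-canonical isoform are excluded.
4. Records whose carriers are confined to the catch-all group are excluded.
5. Synonymous variants are called non-pathogenic (they are a real verdict,
   not a removal); in-frame indels and other unscored classes (start/stop
   loss, "other") are excluded — the in-silico tools consumed here do not
   score them.
6. Nonsense, essential-splice and frameshift alleles (`lofClasses`) are
   pathogenic.
7. Missense: a ClinVar pathogenic/likely-pathogenic assertion is decisive
   when `clinvarOverride = TRUE` (a "conflicting" assertion never is);
   otherwise the in-silico rule applies. The default rule,
   `both_damaging`, requires SIFT *deleterious* **and** PolyPhen-2
   *probably/possibly damaging*: published analyses of this kind rarely
   state their combination rule, and requiring concordance is the
   conservative convention. The rule is a policy field
   (`either_damaging`, `sift_only`, `polyphen_only`) precisely because it
   is not recoverable from the literature. A missense record with no SIFT,
   no PolyPhen and no ClinVar evidence is non-pathogenic with a distinct
   `unscorable` reason code, never an error.

Every call carries machine-readable reason codes, the statuses partition
the input, and classification is per-record, hence order-independent and
idempotent. `start_lost` sits in `excludedClasses` by default — consistent
with census conventions that count only the four LOF classes — but can be
moved into `lofClasses` by policy.

# Carrier prevalence

Counts are *allele-derived*: per variant and group, heterozygous carriers
= `AC − 2·nhomalt`, homozygous carriers = `nhomalt`, mutated alleles =
`AC`. Aggregate data cannot identify compound heterozygotes, so an
individual carrying two different pathogenic variants is counted once per
variant; carrier frequencies are therefore upper bounds at the individual
level. Frequencies are stored at full precision; display rounding (2-dp
percentages, 2-significant-digit homozygote frequencies, 1-dp fold
changes) lives only in the report layer.

When `nhomalt` sex splits are absent, homozygote alleles are attributed
greedily to males first (`min(nhomalt, AC_male %/% 2)`), remainder to
females — a documented, deterministic tie-break; supply
`nhomalt_<group>_male/_female` columns to override it.

The headline max/min fold difference is computed on percentages rounded to
2 decimals (the display convention under which such figures are quoted)
with the unrounded ratio always reported alongside.

`chiSquareTest()` is the plain Pearson statistic with marginal-based
expected cells, `df = (r−1)(k−1)`, and an upper-tail p-value — two-sided
in the usual sense for chi-square. No continuity correction by default
(Yates is a flag, 2×2 only), expected cells below 5 set a `low_expected`
flag, an expected cell of zero is an error, and a p-value underflowing
double precision is labelled `"< 2.2e-308"` rather than printed as 0.
The statistic is evaluated in-package (three lines of marginal algebra) so
these reporting contracts are controlled; `stats::chisq.test()` serves as
an independent oracle in the test suite.

# Protein-domain burden

Only missense alleles are placed on the domain model: a truncating allele
affects every downstream domain, so positioning it in one domain would be
misleading. Two length-normalised statistics are reported per domain:
`pct_mutant_aa` = 100 · distinct mutated residues / domain length, and
`pct_individuals` = 100 · carrier-individuals / domain length. The second
is a burden *density*, not a proportion — it exceeds 100% when a short
domain carries more carrier-individuals than residues. Residues covered by
no domain form a `linker` bin and the sterol-sensing block is additionally
aggregated as `SSD`, so the per-domain mutation counts partition the input
(excluding the aggregate row).

The packaged NPC1 domain model is **synthetic**: exact published boundary
coordinates exist only in graphical form, so the fixture reconstructs the
27-domain alternating topology (luminal/transmembrane/cytoplasmic, SSD =
TD3–TD7) and fixes exactly those domain lengths that published
length-normalised percentages pin down (LDC 248, CDJ 14, CDL 29, CDN 30,
TD4 20, TD7 20). Other boundaries are plausible approximations and are
labelled as such in the file. Analyses of real data should supply measured
boundaries via `readDomainModel()`.

# Gene constraint

Per mutation class, `oeRatio()` reports obs/exp with the exact
gamma-quantile (Garwood) 90% interval on the Poisson rate:
`qgamma(0.05, obs)/exp` to `qgamma(0.95, obs + 1)/exp`, lower bound 0 at
`obs = 0`. Constraint browsers build this interval by likelihood-grid
search instead; the two agree except occasionally in the last rounded
digit. `zScore()` is the raw signed depletion score `(exp − obs)/√exp`
(positive = depletion). Browser-published Z values additionally divide by
per-class empirical constants that are not public; the divisor is exposed
as configuration and defaults to 1, so raw scores are what this package
reports and tests.

pLI comes from a three-class Poisson mixture: a gene's observed LOF count
is Poisson with mean `expected × f_k`, `f = (1, 0.463, 0.089)` for the
null / recessive / haploinsufficient classes (the ExAC calibration,
carried as `EMConfig` defaults; re-estimating the factors is out of
scope). With several genes the mixture weights are fitted by EM — E-step
responsibilities in log space with log-sum-exp (no underflow at large
counts), M-step = mean responsibilities, iterating until the
log-likelihood increment falls below `tol = 1e-8` (cap 1000 iterations;
non-convergence returns the best iterate with a warning). The
log-likelihood is asserted non-decreasing at every step. With a single
gene or `estimatePriors = FALSE` the posteriors are a single Bayes update
under the configured priors (uniform by default); for a strongly LOF-
tolerant gene the posterior is insensitive to any non-degenerate prior
choice. Labels follow the standard thresholds: LOF tolerant at
`pLI ≤ 0.1`, intolerant at `pLI ≥ 0.9`, |Z| > 3.71 (synonymous) and
> 3.09 (missense) for significance, and a 90% o/e upper bound < 0.35 for
strong intolerance. The published threshold sentence for *elevated*
counts carries an obvious sign typo; the implementation reads the
thresholds two-sided with the sign giving direction.

# The synthetic cohort generator

`simulateCohort()` emulates the aggregate structure the pipeline consumes:
six ancestry groups with realistic sizes (67,709 / 17,296 / 15,308 /
9,197 / 8,128 / 5,040) plus a 3,070-strong catch-all to exercise the
exclusion path; a heavy-tailed alt-copy spectrum (P(k) ∝ k^−1.5 on 1–30
copies — rare by construction against groups of thousands); 82% of
variants confined to a single group (drawn size-weighted); homozygotes by
Hardy–Weinberg (`Binomial(n, q²)` per group, capped by `AC %/% 2`); sex
splits binomial with the group's male fraction; annotations generated
from the truth label with configurable contradiction noise and a ClinVar
rescue fraction (truth-pathogenic missense labelled benign in silico but
pathogenic in ClinVar). One master seed drives everything through
per-variant sub-streams derived from the variant index, so extending a
configuration never perturbs earlier records, and the caller's RNG state
is restored on exit.

What the generator does *not* emulate — and what passing tests therefore
do not establish about real data: linkage between variants, realistic
site-frequency spectra beyond the stated zipf form, sequence-context
mutation rates, call-rate variation (`AN` is always `2n`), relatedness,
and annotation error structure beyond symmetric verdict flips.

`simulateConstraintGenes()` draws gene classes from given priors, expected
counts from a lognormal (defaults `meanlog = log(30)`, `sdlog = 1` — a
median of 30 expected LOF variants per gene, typical of exome-scale gene
sets), and observed counts from the class-scaled Poisson — exactly the
generating model of the pLI mixture, enabling parameter-recovery tests.

# Problem sizes and numerical choices in the test suite

The suite exercises: cohorts of ~300 variants over the full six-group
panel (classification truth recovery, prevalence conservation); 1,000
random contingency tables against a cell-by-cell oracle at 1e-9 relative
tolerance; 1,000 null replicates of the heterogeneity test (size within
3–7%); EM recovery on 2,000 genes × 5 seeds (priors within ±0.03,
class-assignment accuracy > 0.9 for genes with expected ≥ 20); and 400
common variants in one group for the Hardy–Weinberg homozygote check
(summed homozygotes within 3 Poisson-scale standard errors of Σ n q²).
These sizes give stable statistical assertions at interactive runtimes.

# Known limitations

* Carrier counts are allele-derived; compound heterozygotes inflate
  heterozygous-carrier counts and cannot be resolved from aggregate data.
* The classification consumes SIFT/PolyPhen/ClinVar verdicts as given; it
  recomputes nothing and implements no further ACMG criteria.
* Printed Z-scores from constraint browsers are not reproducible without
  their unpublished per-class scaling constants; raw Z is reported.
* The packaged NPC1 domain model is approximate away from the
  length-pinned domains; per-domain results on it are illustrative.
* Expected variant counts are inputs; no sequence-context mutation-rate
  model is included.
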