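# RareCarrier

Rare pathogenic variant classification, carrier prevalence by ancestry, and
gene-constraint selection metrics from aggregate allele-count data.

Large exome aggregation databases publish, for every variant, per-population
alternate-allele counts (`AC`), total called alleles (`AN`) and homozygote
counts (`nhomalt`), together with functional annotations (VEP consequence,
SIFT, PolyPhen-2, ClinVar). For an autosomal recessive disease gene this is
enough to ask three questions without any individual-level genotypes:

1. **Which coding variants are pathogenic?** A deterministic rule cascade:
   keep variants with alt-allele frequency < 1% in *every* ancestry group,
   on the canonical isoform, unflagged by QC, and observed outside the
   catch-all ancestry bin; call nonsense, essential-splice and frameshift
   alleles loss-of-function (LOF) pathogenic; call missense alleles
   pathogenic when SIFT and PolyPhen-2 concur on damage, or when ClinVar
   asserts pathogenic/likely pathogenic; synonymous and in-frame changes are
   never pathogenic.
2. **How common are carriers, and does prevalence differ by ancestry or
   sex?** Per group: mutated alleles = Σ AC, homozygous carriers =
   Σ nhomalt, heterozygous carriers = Σ (AC − 2·nhomalt); heterogeneity is
   tested with Pearson chi-square on (mutated, non-mutated) × groups and
   (carrier, non-carrier) × sex tables. The package also partitions variants
   into group-specific vs shared, and maps pathogenic missense alleles onto
   a protein-domain model to compute per-domain burden (% mutant residues
   and carrier-individuals per domain length).
3. **Is the gene under selective constraint?** Per mutation class,
   o/e = observed/expected with an exact gamma-quantile 90% Poisson
   interval; the raw depletion Z-score (exp − obs)/√exp; and pLI — the
   posterior probability of the haploinsufficient class in a three-class
   Poisson mixture (class means = expected × 1 / 0.463 / 0.089) fitted by
   expectation–maximization, with `pLI ≤ 0.1` labelling a LOF-tolerant gene
   and `pLI ≥ 0.9` a LOF-intolerant one.

A synthetic cohort generator (`simulateCohort()`) emulates the database's
per-population count structure with known truth labels, so every stage is
testable without network access; `simulateConstraintGenes()` does the same
for the pLI mixture. The packaged worked example is the *NPC1* gene
(Niemann–Pick type C1 disease; heterozygous carriers are of interest for
obesity risk), whose published per-group carrier counts and
observed/expected variant counts ship as plain-text fixtures.

## Worked example

```r
library(RareCarrier)

panel <- npc1Panel()          # six ancestry groups, 122,678 exomes
cc <- npc1CarrierCounts()     # published per-group carrier counts
tbl <- carrierTableFromCounts(panel,
                              het = setNames(cc$het, cc$group),
                              hom = setNames(cc$hom, cc$group))
round(100 * tbl$het_frequency[tbl$group == "afr"], 2)
#> [1] 3.26                      # African/African American carrier %
round(100 * tbl$het_frequency[tbl$group == "global"], 2)
#> [1] 1.28                      # 1,566 heterozygous carriers / 122,678
foldDifference(tbl, "het_frequency")$rounded
#> [1] 5.8                       # highest vs lowest group prevalence

gc <- geneConstraint(npc1GeneCounts())
round(c(oe_lof = gc$oe_lof, pli = gc$pLI), 2)
#> oe_lof    pli
#>   0.34   0.00                 # LOF depleted in count, yet LOF-tolerant
gc$lof_tolerant
#> [1] TRUE
```

A full synthetic run — simulate, classify, prevalence, domain burden,
constraint, with a JSON manifest — is one call:

```r
runPipeline("out/", panel = npc1Panel(),
            simConfig = cohortSimConfig(seed = 1L),
            domainModel = npc1DomainModel(),
            geneCounts = npc1GeneCounts(), seed = 1L)
```

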