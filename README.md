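# RAFcompare

Do men of one ancestry carry a heavier burden of disease **risk alleles**
than men of another? Opposite incidence gradients between populations — for
example a disease that is more common in people of African ancestry while a
second disease is more common in people of European ancestry — could have a
genetic component that is visible directly in the frequencies of the
GWAS-reported risk alleles. `RAFcompare` implements, as a tested and
reusable pipeline, the comparison of curated risk-allele catalogs between
two ancestral populations:

1. **Catalog I/O and harmonization.** SNP catalogs arrive as plain TSV (one
   row per rsID: alleles, odds ratio, CI, gene, cytoband, and per-population
   per-database allele frequencies from the public references 1000 Genomes,
   ALFA, and gnomAD). Records with OR < 1 are re-coded so that the *risk*
   allele is the one with OR ≥ 1 (alleles swapped, OR inverted, frequencies
   complemented).
2. **Frequency aggregation.** Per SNP and population, the databases are
   pooled into one frequency *F* by an allele-count-weighted mean
   (w<sub>d</sub> = 2·n<sub>d</sub>), and scaled into an OR-weighted
   frequency

   > F<sub>w</sub> = F · OR / OR<sub>max</sub>

   so that alleles with stronger association contribute proportionally more
   to the population's attributable-risk burden.
3. **LD collapsing.** Same-chromosome SNPs with pairwise r² > 0.8 form
   groups (connected components) that are collapsed to one
   frequency-averaged unit — *unless* the members lie in different coding
   genes, lie in a functional region (e.g. 3′-UTR), or disagree about which
   population has the higher frequency.
4. **Inference.** A one-tailed t-test (Student, Welch, or paired) compares
   the per-unit frequencies between populations, and **Deming
   errors-in-variables regression** fits the frequency scatter of one
   population against the other, testing the slope against the identity
   line (slope = 1, equal frequencies everywhere) with a jackknife slope
   standard error.
5. **Sensitivity analyses.** Locus removal (e.g. everything on cytoband
   8q24), named-outlier removal, and LD-collapsed re-analysis with or
   without the location rules, each re-running the inference stage.
6. **Synthetic catalogs.** A generator with known ground truth (true
   frequency shift δ, lognormal ORs, per-database binomial sampling,
   optional LD groups) so the *whole* pipeline can be calibrated for
   type-I error, power, and parameter recovery without downloading
   anything.

## Worked example

A 12-SNP synthetic demo catalog ships with the package:

```r
library(RAFcompare)

path <- system.file("extdata", "synthetic_demo_catalog.tsv",
                    package = "RAFcompare")
cat <- harmonizeRiskAlleles(readSnpCatalog(path, cancerLabel = "demo"))
agg <- aggregateCatalog(cat)
agg
#> AggregatedCatalog 'demo': 12 unit(s), ORmax = 1.593
#>   afr: mean F = 0.5807, mean Fw = 0.4657
#>   eur: mean F = 0.5599, mean Fw = 0.4483

comparePopulations(agg, "afr", "eur", useWeighted = TRUE,
                   direction = "greater", variant = "paired")
#> Population comparison on Fw (12 units): afr vs eur
#>   mean afr = 0.4657, mean eur = 0.4483
#>   paired t-test, greater: p = 0.01029

u <- aggregatedUnits(agg)
demingRegression(u$eur_F, u$afr_F)
#> DemingFit (lambda = 1, n = 12)
#>   y = 1.0499 * x + -0.0071
#>   slope SE (jackknife) = 0.05783; p(slope != 1) = 0.4081, p(slope != 0) = 5.513e-09
```

The weighted mean frequency is higher in the `afr` population
(0.466 vs 0.448) and the one-tailed paired test calls that difference
significant (p ≈ 0.01) — as it should, since the demo catalog was simulated
with a true shift of +0.04. The Deming slope (1.05) is not distinguishable
from the identity line with only 12 SNPs (p ≈ 0.41).

LD-aware re-analysis through the sensitivity suite:

```r
ld <- readLdPairs(system.file("extdata", "synthetic_demo_ld_pairs.tsv",
                              package = "RAFcompare"), cat)
runSensitivitySuite(cat, ld,
                    list(sensitivitySpec("primary"),
                         sensitivitySpec("ld_collapsed", ldMode = "full_rules")),
                    popA = "afr", popB = "eur",
                    direction = "greater", variant = "paired")
#>           name n_units mean_a mean_b   t df      p slope intercept slope_se p_slope_vs_one
#> 1      primary      12  0.466  0.448 2.7 11 0.0103  1.05  -0.00712   0.0578          0.408
#> 2 ld_collapsed      10  0.471  0.453 2.3  9 0.0233  1.05  -0.00683   0.0589          0.420
```

The three linked SNPs on chromosome 5 collapse to one averaged unit
(12 → 10 units); the population difference survives.

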