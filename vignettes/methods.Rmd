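---
title: "Comparing risk-allele frequency burden between populations: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing risk-allele frequency burden between populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(RAFcompare)
```

## The question and the data model

Two diseases can show opposite incidence gradients between ancestral
populations. If genetics contributes, the GWAS-reported risk alleles of the
higher-incidence population's disease should, on average, be *more common*
in that population. `RAFcompare` tests exactly this on a curated catalog:
one row per risk SNP with its risk/reference alleles, odds ratio (OR), and
allele-frequency observations per population from up to three public
reference databases (a 1000-Genomes-scale sequencing panel, the very large
ALFA array aggregate, and the gnomAD sequencing aggregate).

Three modelling ideas do the work:

1. **Pooling.** Database estimates of the same underlying frequency differ
   by sampling noise. Under binomial sampling of $2n_d$ alleles per
   database, the maximum-likelihood pooled estimate is the
   allele-count-weighted mean
   $$F=\frac{\sum_d 2 n_d f_d}{\sum_d 2 n_d},$$
   which is what `pooledFrequency()` computes (the factor 2 cancels but
   keeps the unit — individuals in the files, alleles in the weights —
   explicit). An unweighted mean is available (`pooling = "unweighted"`)
   because pooling recipes in the literature are not always explicit about
   weighting; the weighted mean is the default on likelihood grounds.
2. **OR weighting.** Counting a weakly associated allele as heavily as a
   strongly associated one misstates the burden. The weighted frequency
   $$F_w = F\cdot\frac{\mathrm{OR}}{\mathrm{OR}_{\max}}$$
   down-weights each allele by its association strength relative to the
   strongest allele in the catalog, so $0 \le F_w \le F$ with equality only
   at the maximal OR.
3. **Harmonization.** A reported OR below 1 means the *other* allele is the
   risk allele: `harmonizeRiskAlleles()` swaps alleles, inverts the OR and
   its CI, and complements every frequency ($f \to 1-f$), making the
   operation idempotent and the invariant OR ≥ 1 catalog-wide.

## Linkage disequilibrium

SNPs in strong LD are partially redundant measurements of one signal;
keeping them all would double-count loci with dense coverage.
`buildLdGroups()` links same-chromosome SNPs with pairwise $r^2 > 0.8$ (the
conventional threshold for "the same signal") and takes **connected
components** rather than cliques: pairwise LD exports do not guarantee
clique structure, and transitive closure is the conservative reading.
A component is collapsed to a single unit whose per-population frequency is
the unweighted mean of member pooled frequencies — *except* when any of
three exclusion rules fires, in which case the members stay separate:

1. members lie in **different coding genes** (≥ 2 distinct non-empty gene
   symbols): plausibly distinct biology;
2. any member lies in a **functional region** (e.g. 3′-UTR): a potentially
   causal variant should not be averaged away;
3. members show **opposite frequency directions** — the risk allele is
   commoner in one population for some members and in the other population
   for the rest — so averaging would cancel real signal. The direction is
   the sign of the pooled-frequency difference between the two compared
   populations; a zero difference is compatible with either sign.

The rules are checked in that fixed order purely so that the recorded
`reason` is deterministic; any rule prevents collapsing. A location-blind
variant (`ignoreLocations = TRUE`, or `ldMode = "ignore_locations"` in the
sensitivity suite) disables rules 1–2 and keeps only the direction rule,
which quantifies how much the location annotations matter. The collapsed
unit's OR is the member maximum by default (`orRule = "mean"` is the
alternative): collapsing is defined on frequencies, and the maximum keeps
the unit's weight from being diluted by its weakest member. Whether rule 3
should use pooled frequencies or each database separately is genuinely
open; pooled frequencies are used because the collapse itself operates on
pooled values.

## Inference

**Mean comparison.** The hypotheses are directional by construction (the
higher-incidence population is tested for the *higher* burden), so
`oneTailedTTest()` reports one-tailed p-values. Three variants are exposed:

* `student` — classical two-sample pooled-variance t-test (the default:
  the plainest reading of comparing "two groups");
* `welch` — unequal variances;
* `paired` — on per-unit differences. Because both populations are
  measured on the *same* catalog units, pairing is the statistically
  natural choice, and it is what the calibration runs use; the default
  stays `student` only because the choice between them is a judgement
  call, and all three are computed by `stats::t.test()` internally.

**Deming regression.** Plotting the per-unit frequency of population A
against population B, equal burdens mean the identity line. Ordinary least
squares is biased here because *both* axes are noisy estimates; Deming
errors-in-variables regression minimises
$$\sum_i \frac{(y_i - a - b x_i)^2}{1 + \lambda b^2},$$
where $\lambda$ is the assumed ratio of x-error variance to y-error
variance. The slope has the closed form (with $\delta = 1/\lambda$)
$$\hat b = \frac{s_{yy} - \delta s_{xx} +
  \sqrt{(s_{yy} - \delta s_{xx})^2 + 4\delta s_{xy}^2}}{2 s_{xy}},$$
and the line passes through the centroid. This parameterisation makes the
three sanity limits come out right: $\lambda = 1$ is orthogonal regression,
$\lambda \to 0$ (error-free x) recovers OLS of y on x, and at $\lambda = 1$
swapping the axes exactly inverts the slope. Both populations' frequencies
are pooled from the same databases with comparable sample sizes, so
$\lambda = 1$ is the default. When $s_{xy} = 0$ exactly, the positive root
$\sqrt{\delta s_{yy}/s_{xx}}$ is returned by convention.

No exact finite-sample slope SE exists for this estimator, so
`demingSlopeSE()` uses the delete-one jackknife,
$\mathrm{SE}^2 = \frac{n-1}{n}\sum_i (b_i - \bar b)^2$, and `testSlope()`
refers $(\hat b - b_0)/\mathrm{SE}$ to a t distribution with $n - 2$
degrees of freedom. The slope-vs-1 test is two-sided (no direction is
privileged for a slope), while the means test is one-tailed as stated
above. The jackknife was verified against a parametric bootstrap in the
test suite.

## Sensitivity analyses

`runSensitivitySuite()` re-runs aggregation + inference after:

* **region removal** (`removeByRegion()`): cytoband *prefix* match (so
  `"8q24"` catches `"8q24.21"`) or a chromosome + position interval — the
  package ships no genome annotation, the catalog's own cytoband column is
  the authority;
* **rsID-list removal** (`removeByRsids()`), for hand-identified outliers;
* **LD collapsing** in full-rules or location-blind mode.

By default $\mathrm{OR}_{\max}$ — hence the $F_w$ scale — is *not*
recomputed inside a subset (`recomputeOrMax = FALSE`), so weighted
frequencies stay comparable across re-analyses even when the subset drops
the strongest allele; recomputation is a switch, not a silent behaviour.
The suite never mutates its input, and the all-defaults spec reproduces the
primary analysis bit for bit.

## The synthetic generator and what the calibration shows

`simulateCatalog()` draws, per SNP $i$: a population-B truth
$p_{B,i} \sim \mathrm{Uniform}(0.05, 0.95)$ (a flat, wide spectrum typical
of common GWAS variants; a Beta option exists); a population-A truth
$p_{A,i} = \mathrm{clip}(p_{B,i} + \delta + u_i,\ 0.01, 0.99)$ with
$u_i \sim N(0, 0.02^2)$ — the per-SNP heterogeneity is essential, because a
purely constant shift would make the paired t-test degenerate and is
biologically implausible anyway; an OR
$\max(1, \mathrm{Lognormal}(\log 1.2, 0.2))$, matching the modest effect
sizes of post-GWAS-era risk alleles; and per-database observations
$\mathrm{Bin}(2 n_d, p)/(2 n_d)$ with default individual counts
$\{1\mathrm{kg}: 661,\ \mathrm{gnomAD}: 8000,\ \mathrm{ALFA}: 50000\}$,
reflecting the real ordering of ancestry-specific sample sizes in those
resources. LD groups share their latent frequencies (including $u_i$) and
declare $r^2 \sim \mathrm{Uniform}(0.85, 0.99)$; $r^2$ is declared, not
derived from genotypes — no haplotype simulation is attempted. Replicate
$r$ reuses the configuration with seed $\texttt{seed} + r$, so every
replicate is independently reproducible.

The calibration runs (in `tests/testthat/test-acceptance.R` and
`scripts/acceptance.R`) use catalog sizes of 200–226 SNPs — the scale of a
well-powered cancer catalog — with 200–1000 Monte-Carlo replicates:
type-I error of the full pipeline at $\alpha = 0.05$, power at
$\delta = 0.3$, recovery of $\delta = 0.03$ to within 0.005, and a mean
null Deming slope within 0.02 of 1.

What passing these checks does **not** show: real catalogs violate the
generator's exchangeability in known ways — frequencies are correlated
along chromosomes beyond the declared LD groups, ORs and frequencies are
dependent (selection and winner's curse), database panels overlap subjects,
and ascertainment of SNPs is biased toward the populations in which they
were discovered. The calibration validates the *statistical machinery*, not
the representativeness of any particular curated catalog.

## Numerical and edge-case conventions

* Duplicate rsIDs are a hard error (curation to one row per SNP is a
  manual, upstream decision); validation reports row numbers and never
  silently drops.
* An observation is a frequency *and* its sample size; one without the
  other is a format error. 1–3 databases per record are fine — pooling
  uses what is present.
* Catalog TSVs print doubles with 17 significant digits so that
  write → read is the exact identity.
* Constant paired differences, zero pooled variance, constant x in the
  regression, and a zero jackknife SE with slope ≠ reference are all
  reported as degenerate, never as a quiet p-value (the one exception:
  zero SE at slope = reference gives p = 1, and slope ≠ reference gives
  p = 0 with a warning, the two defensible limits).
* Collapsed units store their averaged frequency as a single
  pseudo-observation under database label `"pooled"` with the summed
  member individual counts, so collapsed catalogs remain valid, writable,
  and re-readable in the same dialect.

## Limitations

Frequencies arrive pre-extracted: there is no VCF parsing, no live
database or LD-server queries, and no rsID liftover. No multiple-testing
correction is applied across the analyses — the suite reports raw
p-values, mirroring how such comparisons are usually presented, and
leaving any correction to the caller. Automated outlier *detection* is out
of scope: `removeByRsids()` implements outlier *removal* for externally
chosen lists.
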