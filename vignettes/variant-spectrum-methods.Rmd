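---
title: "Comparing variant spectra between a re-sequenced case cohort and population references"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing variant spectra between a re-sequenced case cohort and population references}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(varspectrum)
```

## The problem

Candidate-gene re-sequencing studies ask whether a disease cohort carries an
excess of rare variation in a panel of genes. The design varspectrum supports
is a case cohort of a few hundred re-sequenced individuals (available as
per-site alternate-allele counts, or genotypes where Sanger data exist),
compared against two kinds of background: a genotype-level control population
of similar size (a 1000Genomes-style subset), and a much larger aggregate
reference known only through per-site allele counts (an ExAC/gnomAD-style
extract of tens of thousands of chromosomes). The default geometry mirrors a
ten-gene Toll-like receptor panel: 288 cases (140 female, 148 male), 379
controls, and two X-linked genes, where males are hemizygous, so the
chromosome count at an X-linked site is `2 * n_female + n_male` (428 for the
cases) instead of `2 * n` (576).

Counts, not individual genotypes, are the primitive: every frequency is
`alt_count / chrom_count` with the same reference allele used in all
populations, and the minor-allele frequency (MAF) folds it to
`min(f, 1 - f)`. Missing data reduce `chrom_count` per site rather than being
imputed, which matches the count-based model and the aggregate reference's
per-site call rates.

## Spectrum statistics

Three integer statistics summarise a gene's spectrum of detected variation:

* **rare** — sites detected in the cohort with within-cohort MAF $\le$ 1%;
* **specific** — sites detected in one cohort and absent from the other;
* **damaging** — detected sites whose missense annotation is called damaging
  by *both* SIFT and PolyPhen-2.

Two conventions matter and are applied everywhere:

* a site with `alt_count` 0 has MAF 0 but is **not** rare — rarity is a
  property of detected variants, so rare counts are subsets of the totals;
* the 1% boundary is evaluated on integer counts
  (`minor_count <= threshold * chrom_count` with a relative slack of 1e-12),
  so 5 copies in 576 chromosomes (MAF 0.0087) is rare while 6 copies
  (MAF 0.0104) is not, deterministically, with no floating-point edge cases.

The damaging statistic is a site count under concordant categorical calls,
not a score sum: the per-gene summary tables report concordant counts, and a
count keeps the permutation null identical in form to the other two
statistics. Sites lacking either predictor's call are excluded with a
message.

For the case-versus-control contrast we test the case-side count of each
statistic (does the randomized case cohort exceed the observed case cohort?).
A case-minus-control difference statistic would order the same replicates
almost identically for specificity, and the case-side count is the direct
reading of a one-sided "accumulation in cases" hypothesis, so it is the
default and the only mode exposed.

## The per-site allele-randomization permutation test

Under the null hypothesis that case and control chromosomes are exchangeable,
the alleles observed at a site are an arbitrary labelling of the pooled
chromosomes. Each permutation replicate therefore deals, independently at
every variable site, the site's pooled alternate alleles onto the case's
`n_case` chromosomes without replacement — the permuted case count is
hypergeometric — and recomputes the spectrum statistic on the permuted case
side, re-classifying rarity and specificity from the permuted counts. With
100,000 replicates (the default), the one-sided P-value is the proportion of
replicates whose permuted value exceeds the observed value.

Numerical and design choices:

* **Tie handling.** `mode = "strict"` counts only strictly greater
  replicates (`p = n_gt / n_perm`); `mode = "ge"` counts ties and applies the
  add-one correction (`p = (n_ge + 1) / (n_perm + 1)`), which can never be
  anti-conservative at p = 0. Both proportions are always returned. Strict is
  the default because it is the literal reading of "proportion of replicates
  with a higher value"; every calibration check in this package uses the
  `ge` form because only it is a valid p-value at finite replicate counts.
* **Independence across sites.** Sites are permuted independently; linkage
  disequilibrium between sites is deliberately ignored, because the null is
  defined per variable site. Consequence: the global test treats per-site
  contributions as independent, which is anti-conservative if strong LD
  couples rare sites. This is a property of the method, documented rather
  than patched.
* **RNG discipline.** Each gene's sites are permuted under a substream seed
  derived from the master seed and the gene name, so per-gene results do not
  depend on the order genes are supplied; the panel-wide ("ALL") statistic
  sums the same per-gene replicate streams, so per-gene and global results
  are mutually consistent. Results are bit-reproducible given
  `(seed, n_perm)`.
* **Degenerate scopes.** An empty scope, a damaging scope with no
  concordantly damaging site, or a scope in which every site is fixed in the
  pooled sample (all-reference or all-alternate) has no permutation null;
  such results are flagged `degenerate = TRUE` and reported with p = 1.
* **Multiplicity.** `bonferroni_adjust(p, m)` takes the family size from the
  caller, because overlapping statistics on the same genes (rare and specific
  counts share most of their sites) make the nominal family deliberately
  conservative.

## The reference-simulation test

The aggregate reference has no genotypes, so exchangeability cannot be
invoked. Instead, the test asks directly: if a cohort of the case's size were
drawn from the reference population, how often would it contain more rare
variants than the case actually does? Each replicate simulates, at every site
of the case-reference union, an alternate count `Binomial(n_chrom, AC/AN)`
(default) or hypergeometric from the finite reference pool, and recomputes
the rare count with rarity judged *inside* the simulated cohort — the same
rule applied to the observed case, keeping the two sides of the comparison
symmetric (judging rarity at the fixed reference frequencies is available via
`rarity = "reference"`). The binomial and hypergeometric models agree
whenever the reference is much deeper than the cohort (the package checks
this empirically at a 100-fold depth ratio); binomial is the default because
an ExAC-style extract is a frequency estimate, not a closed pool.

Sites detected in the case but absent from the reference enter with frequency
0 and can never appear in a simulated cohort. That is the point of the test:
observed case-private rare sites are exactly the excess the simulation can
never match, and each one pushes the one-sided P-value down (a property the
test suite checks monotonically).

## The common-variant layer

Sites where at least one of the two cohorts has MAF $\ge$ 5% (inclusive) are
tested individually with the classical two-proportion normal-approximation
z-test on allele frequencies, two-sided and without continuity correction by
default (a corrected variant is a flag). Two-sided is the right default
because a frequency difference in either direction is reportable at this
layer. A pooled frequency of exactly 0 or 1 leaves z undefined; such sites
are flagged degenerate with p = 1.

Hardy-Weinberg screening applies to the same MAF $\ge$ 5% sites where
genotype tallies exist, as the 1-degree-of-freedom chi-square against the
$p^2 : 2pq : q^2$ expectation; at n = 288 and MAF $\ge$ 5% the expected cell
counts are all comfortably large, so the asymptotic test is adequate, and an
exact conditional test (enumeration of heterozygote counts given the minor
allele count) is available by flag for smaller cells. X-linked sites carry
female-only diploid tallies by construction — hemizygous males never enter
the HWE comparison, and a heterozygous hemizygote is a validation error, not
data.

## What the synthetic-data generator emulates

`sim_config()` + `sim_cohort_pair()` generate the study geometry end to end:
the ten-gene panel with its published coding lengths and two X-linked genes,
a 288/379 case-control pair with the stated sex splits (the control sex split
is not part of the published geometry; an even 190/189 split is assumed), and
a 33,000-individual aggregate reference. Variable sites come in two layers:

* a **common layer** (default 3 candidate sites/kb) with population
  frequencies from a neutral-like site-frequency spectrum — allele-count
  class $i$ drawn with probability $\propto 1/i$ over a 758-chromosome pool,
  giving the familiar rare-heavy spectrum with a realistic common tail — and
* a **rare layer** (default 1.2 candidate sites/kb) with frequencies from
  Beta(0.5, 400) (mean $\approx 0.00125$, so detected sites are mostly
  singletons and doubletons).

Both cohorts draw every site binomially from its population frequency, and
sites detected in neither cohort are dropped, mirroring what re-sequencing
can observe. Because the two cohorts sample the *same* frequency at every
site, case and control are exchangeable given the per-site allele totals at
enrichment factor $\rho = 1$ — exactly the null the permutation test
conditions on, which is what makes the calibration checks meaningful rather
than approximate.

Enrichment ($\rho > 1$ in designated genes) adds case-only rare sites at rate
$(\rho - 1) \times$ the base rare rate, so the case cohort's rare-site
occurrence rate is $\rho$ times the base rate while every site stays rare.
Modelling enrichment as a multiplied per-site *frequency* was rejected: at
$\rho = 8$ it pushes sites across the 1% MAF boundary, so the "rare-variant
enrichment" would leak out of the statistic being tested. Enriched sites have
background frequency 0 in the manifest, so a reference generated from the
manifest treats them as case-private — the direction the reference test is
designed to detect.

What the generator does **not** emulate: linkage disequilibrium and haplotype
structure (the analysis permutes sites independently, so correlated sites
would stress exactly the documented independence assumption), sequencing
error and coverage variation, population stratification between case and
control, and indels (excluded from the data model entirely). Passing
calibration and power checks therefore show that the machinery is correct
under the stated sampling model, not that real cohorts satisfy that model.

## Problem sizes used by the checks

The package's own verification runs at sizes chosen to make Monte-Carlo error
negligible relative to the properties asserted: exhaustive-enumeration
comparisons on panels of $\le$ 3 sites and $\le$ 12 pooled chromosomes at
100,000 permutation replicates; null calibration on 1,000 single-gene panels
with 400 replicates per panel and add-one corrected non-strict p-values
(valid at any replicate count); power curves over $\rho \in \{1, 2, 4, 8\}$
with 150 panels per level and ~10 rare candidate sites per gene; 5,000
replicates for the z-test type-I error and the HWE uniformity check. The
`scripts/acceptance.R` runner recomputes all of these from scratch at the
same sizes.

## Known limitations

* Independent-site permutation ignores LD (above).
* The strict tie mode can report p = 0; use `p_ge` for inference at small
  replicate counts.
* The reference-simulation test inherits any ascertainment difference between
  the case pipeline and the reference extract (coverage, calling
  sensitivity); it tests sampling variation only.
* The exact HWE test enumerates heterozygote counts and is quadratic in the
  minor-allele count; it is intended for the promoter-scale genotype data it
  serves, not genome-wide use.
* Genomic coordinates in the bundled panel are schematic single-exon
  intervals anchored near each gene's GRCh37 locus; only gene membership,
  interval lengths and X-linkage enter the analysis.
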