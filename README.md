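# varspectrum

Rare-variant spectrum comparison for candidate-gene re-sequencing studies:
does a case cohort carry an excess of rare, population-specific, or damaging
variants relative to a control population and a large aggregate reference?

A re-sequenced case cohort (per-site alternate-allele counts for N diploid
individuals, e.g. 288 cases split 140 F / 148 M) is compared against two
backgrounds: a genotype-level control population of similar size (a
1000Genomes-style subset) and an ExAC/gnomAD-style aggregate reference known
only through per-site `AC/AN` counts. All frequencies are `alt_count /
chrom_count` with a shared reference allele; the minor-allele frequency is
the folded `min(f, 1 − f)`; X-linked genes use `2·n_female + n_male`
chromosomes (males hemizygous).

Three per-gene spectrum statistics are computed for each cohort:

* **rare** — sites with within-cohort MAF ≤ 1% (boundary inclusive, on
  integer counts);
* **specific** — sites detected in one cohort and absent from the other;
* **damaging** — sites called damaging concordantly by SIFT and PolyPhen-2.

and tested with:

* a **one-sided per-site allele-randomization permutation test**: at every
  variable site the pooled alternate alleles are dealt back onto the case
  chromosomes without replacement (hypergeometric), independently across
  sites; the statistic is recomputed on each of `n_perm = 100 000` permuted
  case cohorts, per gene and summed over genes, and
  `P = #{permuted > observed} / n_perm` (a tie-counting add-one variant
  `(n_ge + 1)/(n_perm + 1)` is always reported alongside);
* a **one-sided reference-simulation test**: replicates draw a case-sized
  cohort from the reference frequencies (`Binomial(n_chrom, AC/AN)` per site,
  hypergeometric optional) and recompute the rare count with rarity judged
  within the simulated cohort; case-private sites have reference frequency 0
  and can never be matched, which is exactly the excess being tested;
* a **common-variant layer**: two-proportion normal-approximation z-test
  (two-sided, no continuity correction) at sites where either cohort has
  MAF ≥ 5%, plus Hardy-Weinberg chi-square screening of genotype-level data;
* **per-gene summary tables** (totals / rare / specific / new-to-dbSNP /
  missense / nonsense / synonymous / damaging per cohort) with a Pearson
  correlation of per-gene totals between cohorts.

A synthetic-data generator reproduces the whole study geometry (ten-gene
TLR panel with published coding lengths, two X-linked genes, neutral-like
site-frequency spectrum, shared common variants plus private rare variants,
tunable case rare-variant enrichment factor ρ, aggregate reference of 33 000
individuals), so every pipeline stage is testable without downloads.

## Worked example

Simulate a four-gene panel with an 8-fold rare-variant enrichment planted in
TLR1, then test it:

```r
library(varspectrum)

cfg <- sim_config(n_genes = 4, rho = 8, enriched_genes = "TLR1")
d   <- sim_cohort_pair(cfg, seed = 42)

gene_summary(d$case, d$control, d$sites, panel = d$panel)
#>   gene  case_total case_rare case_specific case_new case_missense ...
#> 1 TLR1          20        13             7        7            11
#> 2 TLR2           3         1             0        0             2
#> 3 TLR3          10         5             0        3             7
#> 4 TLR4          12         5             0        2             5
#> 5 Total         45        24             7       12            25

perm_test(d$case, d$control, d$sites, "rare", n_perm = 1e5, seed = 42)
#> One-sided allele-permutation test (rare statistic, 100000 replicates, mode=strict)
#>   scope observed p_strict   p_ge
#> 1 TLR1        13  0.00107 0.0121
#> 2 TLR2         1  0.637   0.981
#> 3 TLR3         5  0.639   0.899
#> 4 TLR4         5  0.429   0.761
#> 5 ALL         24  0.103   0.212

ref <- sim_reference(d$manifest, n_individuals = 33000, seed = 43)
ref_sim_test(d$case, ref, d$sites, n_sim = 2e4, seed = 44)
#> One-sided reference-simulation test (binomial sampling, 20000 replicates)
#>   scope observed p_strict      p_ge
#> 1 TLR1        13    0     0.0000500
#> 2 TLR2         1    0.692 0.971
#> 3 TLR3         5    0.231 0.567
#> 4 TLR4         5    0.268 0.564
#> 5 ALL         24    0     0.000700
```

The planted enrichment surfaces only in TLR1: 13 rare case variants, with
permutation `p ≈ 0.001` against the control cohort and `p ≈ 5e-5` against
the deep reference; the unenriched genes stay null. `p_strict` counts
strictly-exceeding replicates (and can reach 0); `p_ge` counts ties with an
add-one correction and is the calibrated choice at small replicate counts.

A shell entry point wrapping the same functions ships in
`inst/scripts/varspectrum.R` with subcommands `simulate`, `summarize`,
`perm-test`, `sim-test`, `snp-test`, `hwe`.

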