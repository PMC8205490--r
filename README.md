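# gslchemo

Glucosinolate (GSL) chemotype analysis for *Arabidopsis thaliana*
accession panels — from replicated seed metabolite measurements to
enzyme-state calls, chemotype classification, heritability, geography ×
environment association models, haplotype trees and
epistasis-conditioned loss-of-function (LOF) allele frequencies.

## The problem and who this is for

Aliphatic GSL structure in Arabidopsis is controlled by three
epistatically interacting loci. *GS-Elong* sets the side-chain length
(MAM2 → C3, MAM1 → C4 compounds), *GS-AOP* the side-chain modification
(AOP2 → alkenyl, AOP3 → hydroxyalkyl, null → methylsulfinyl), and
*GS-OH* hydroxylates 3-Butenyl GSL — visibly only in C4-alkenyl
backgrounds that make its substrate. For anyone surveying seed GSL
profiles across natural accessions, this package turns a long table of
per-compound amounts into:

* per-compound **broad-sense heritability**, from the fixed-effects
  model `amount ~ accession + replicate + plate` by ANOVA
  variance-component partitioning, `H² = σ²_accession / σ²_total`;
* per-accession **adjusted means** (estimated marginal means) and a
  **PCA** of the accession × compound matrix;
* a seven-way **chemotype call** per accession from majority rules on
  compound-class ratios: C3 vs C4 totals decide the MAM state; the
  alkenyl : alkyl : MSO ratios (over the full short-chain total) decide
  the AOP state; the 2-OH-3-Butenyl share of the butenyls decides GS-OH
  where it is observable:

  | MAM | AOP | GS-OH | chemotype |
  |-----|-----|-------|-----------|
  | MAM2 | null | — | 3MSO |
  | MAM1 | null | — | 4MSO |
  | MAM2 | AOP3 | — | 3OHP |
  | MAM1 | AOP3 | — | 4OHB |
  | MAM2 | AOP2 | — | Allyl |
  | MAM1 | AOP2 | nonfunctional | 3-Butenyl |
  | MAM1 | AOP2 | functional | 2-OH-3-Butenyl |

* **environment-association linear models** per northern/southern
  collection (split at a configurable Pyrenees–Alps–Carpathians
  boundary) with geography × covariate interactions and Type-II
  partial-F p-values;
* **neighbor-joining haplotype trees** (p-distance, outgroup rooting,
  column-resampling bootstrap, clade extraction, clade ↔ chemotype
  concordance);
* the **epistasis-conditioned LOF table**: carrier fractions among
  phenotypically informative (C4-alkenyl) accessions vs observed
  frequencies among masked accessions, with one-sided Fisher exact
  enrichment tests.

A seed-deterministic synthetic cohort generator (`simulate_cohort()`)
with known ground truth makes the entire pipeline testable offline.

## Worked example

```r
library(gslchemo)

cfg <- sim_config(n_accessions = 120, seed = 42)
cohort <- simulate_cohort(cfg)

herit <- estimate_heritability(cohort$measurements)
sprintf("median H2 = %.2f", attr(herit, "median_h2"))
#> "median H2 = 0.83"

emm <- compute_emmeans(cohort$measurements)
calls <- classify_all(emm)
calls
#> Chemotype calls for 120 accessions ( 0 undetermined )
#>       chemotype count percent
#>            3MSO     7    5.83
#>            4MSO    11    9.17
#>            3OHP     6    5.00
#>            4OHB     7    5.83
#>           Allyl    50   41.67
#>       3-Butenyl     2    1.67
#>  2-OH-3-Butenyl    37   30.83
```

The median heritability matches the generator's target (0.83), and the
chemotype frequencies recover the configured mixture (47% Allyl, 27%
2-OH-3-Butenyl in expectation); every call agrees with the simulated
ground truth at these noise levels.

The LOF analysis runs from the curated GS-OH carrier counts shipped
with the package (`inst/extdata/gsoh_lof_carriers.tsv`):

```r
counts <- gsoh_lof_counts()
lof <- compute_lof_frequencies(counts$carriers, counts$n_expressed,
                               counts$n_masked)
lof[, c("class", "fraction_display", "observed_frequency_display")]
#>                 class fraction_display observed_frequency_display
#>    premature_stop_snp            0.009                      0.067
#>  active_site_mutation            0.004                      0.025
#>         gene_deletion            0.009                      0.055
#>   unidentified_lesion            0.027                         NA

test_enrichment(lof)
#>                 class odds_ratio  p_value note
#>    premature_stop_snp       8.08 1.50e-04
#>  active_site_mutation       5.72 4.33e-02
#>         gene_deletion       6.50 1.23e-03
#>                pooled       7.62 1.57e-08
```

Fractions are carriers / 226 C4-alkenyl accessions; observed
frequencies are carriers / 564 masked accessions. The pooled Fisher
test shows LOF alleles are strongly enriched where GS-OH is hidden by
epistasis — the signature of ongoing pseudogenization of a cryptic
gene.

Haplotype trees close the loop between genotype and chemotype:

```r
tree <- root_by_outgroup(
  neighbor_joining(p_distance_matrix(cohort$sequences)),
  cfg$outgroup_id)
clades <- cut_clades(tree, 8)
conc <- clade_chemotype_concordance(
  clades, setNames(cohort$truth$chemotype_true, cohort$truth$accession_id))
sprintf("overall clade purity = %.2f", conc$overall)
#> "overall clade purity = 0.72"
```

The eight extracted clades match the simulated haplotype clades exactly
(adjusted Rand index 1); purity against the seven chemotype labels is
below 1 because each MAM clade legitimately hosts several AOP/GS-OH
states.

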