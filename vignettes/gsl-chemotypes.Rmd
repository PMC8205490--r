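---
title: "Seed glucosinolate chemotypes: models, classification and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Seed glucosinolate chemotypes: models, classification and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gslchemo)
```

## The biological problem

Aliphatic glucosinolates (GSLs) are methionine-derived defense
metabolites of *Arabidopsis thaliana* whose side-chain structure is
controlled by three epistatically interacting loci. *GS-Elong* (the MAM
enzymes) sets the side-chain length: MAM2 produces three-carbon (C3),
MAM1 four-carbon (C4) GSLs. *GS-AOP* modifies the methylsulfinyl (MSO)
core: an expressed AOP2 yields alkenyl, an expressed AOP3 yields
hydroxyalkyl side chains, and a null locus leaves MSO compounds.
*GS-OH* finally hydroxylates 3-Butenyl to 2-OH-3-Butenyl GSL — but only
C4-alkenyl backgrounds make its substrate, so its functional state is
observable only there (functional epistasis). The combination of the
three states defines seven discrete chemotypes (3MSO, 4MSO, 3OHP, 4OHB,
Allyl, 3-Butenyl, 2-OH-3-Butenyl), each dominated by the eponymous
compound in the seed profile.

`gslchemo` implements the full analysis chain from replicated seed
measurements to chemotype calls, heritability, ordination, geography ×
environment association models, haplotype trees and the
epistasis-conditioned loss-of-function (LOF) frequency analysis, plus a
synthetic cohort generator that makes every stage testable without any
external data.

## The per-compound linear model and heritability

Each compound is modelled as
`amount ~ accession + replicate + plate` with all terms categorical
fixed effects, fitted by OLS and decomposed by sequential ANOVA
(accession first). Variance components are extracted by the method of
moments: for a factor with mean squares `MS_f` and an average of `m`
observations per level, `sigma2_f = max(0, (MS_f - MS_res) / m)`.
Broad-sense heritability is the accession share of the component total.

Why variance components and not the raw sum-of-squares share: with two
replicates per accession the accession term owns roughly half of all
degrees of freedom, so the SS share of a pure-noise compound sits near
0.5 rather than 0 — it cannot represent low heritabilities at all. The
method-of-moments ratio is consistent across the whole [0, 1) range and
reduces to the SS share as replication grows. The SS share is still
reported (`eta2_accession`) as a diagnostic. The truncation at zero
leaves a small positive bias under the null (a few percent), visible in
the null test.

Adjusted per-accession means come from the same model via the emmeans
package: predictions averaged uniformly over the observed replicate and
plate levels. In a balanced design they equal arithmetic means; in
unbalanced designs they correct for plate and replicate bias (the test
suite checks this against explicit normal equations).

PCA of the accession × compound matrix of adjusted means centres
columns and by default scales them to unit variance (`scale = TRUE`,
recorded as a switch because either convention is defensible for
metabolite panels); component signs are fixed so the largest-magnitude
loading is positive.

## The chemotype classifier

All calls are ratios of the nine canonical short-chain compounds
(C3: 3MT, 3MSO, 3OHP, Allyl; C4: 4MT, 4MSO, 4OHB, 3-Butenyl,
2-OH-3-Butenyl), so they are invariant to overall profile scaling.

* **MAM**: C3 total vs C4 total; the strict majority wins (MAM2 for C3,
  MAM1 for C4). A tie, or a short-chain total below the configurable
  detection floor (default 0), is `undetermined`. "Majority" is taken
  as a strict maximum throughout: refusing to guess on ties is
  auditable, and ties have measure zero on real data.
* **AOP**: alkenyl (Allyl + 3-Butenyl + 2-OH-3-Butenyl), alkyl
  (3OHP + 4OHB) and MSO (3MSO + 4MSO) ratios, all over the *full*
  short-chain total including the MT compounds. The MT compounds sit in
  the denominator only, so the three ratios can sum to less than one;
  profiles that are mostly MT still get the argmax call but carry an
  `MT-dominated` warning, since the call then rests on a small
  remainder.
* **GS-OH**: only evaluated in MAM1 + AOP2 accessions (`masked`
  elsewhere); functional when 2-OH-3-Butenyl exceeds the configurable
  proportion threshold (default 0.5, mirroring the majority logic) of
  the two butenyl GSLs.

The state-to-chemotype lookup is exhaustive: every profile maps to
exactly one of the seven chemotypes or `undetermined`, and any
undetermined enzyme state propagates.

## The synthetic cohort generator

`sim_config()` defaults encode the survey this package is designed for:
797 accessions × 2 independent replicates, measurements randomized over
8 plate positions, 23 compounds (the 9 canonical short-chain compounds
plus 14 long-chain aliphatic, indolic and aromatic fillers), chemotype
mixture 47% Allyl / 27% 2-OH-3-Butenyl with the remainder spread evenly
over the other five chemotypes, and a heritability target of 0.83 (the
survey's median). Geography mimics the continental pattern: roughly
half the cohort sits south of the Pyrenees–Alps–Carpathians line with a
sharp longitudinal C4(west)/C3(east) partition, while the north mixes
all chemotypes.

Amounts are log-normal with additive effects on the log scale:
genetic expected values `G` are the chemotype-determined means (the
dominant compound carries the `dominance` fraction, default 0.85, of a
20 µmol/g short-chain total; the remainder is split evenly) times a
log-normal accession deviate (log-variance 0.04), and measurements are
`G × exp(replicate + plate + residual)`. The residual log-variance per
compound solves

```
h2 = Var(G) / (Var(G) + E[G^2] * (exp(V) - 1))
```

using the realized `Var(G)` of the cohort, which makes the
variance-component heritability estimator consistent with the
configured target on the measurement scale. The replicate and plate
effects are *not* part of this budget — the ANOVA removes their main
effects — so they enter as small proportional shifts (5% of `V` each).
With `heritability_target = 1` all noise vanishes and replicates are
identical.

Latent GS-OH alleles are drawn for every accession (15% nonfunctional
in masked backgrounds, matching the aggregate carrier frequency of the
known lesion classes), so the epistatic masking analysis has ground
truth everywhere. Marker-gene alignments are generated as eight clade
ancestors mutated from a common root (0.02 substitutions/site), tips
mutated from their ancestor (0.002), and an outgroup at four times the
clade rate — a star-like radiation with long stems, short backbone and
tight clades, plus a clearly external root. Environmental covariates
are smooth latitude/longitude fields with independent noise; their
drivers are deliberately distinct (temperature mostly latitude,
continentality mostly longitude, precipitation noise-heavy) so that
injected covariate effects are statistically identifiable rather than
aliased. When effect sizes are configured, accessions of the
Allyl / 2-OH-3-Butenyl pair are re-drawn with probabilities shifted by
the standardized covariates (optionally with different southern
coefficients, producing geography × environment interactions), and all
genotype fields are updated consistently.

What the generator does *not* model — and hence what passing tests do
not show about real data: compositional covariance among the 14 filler
compounds (real long-chain GSLs are strongly correlated through shared
precursor flux, which is why the survey's PC1+PC2 captured about a
third of total variance while the synthetic analogue sits near 13%),
linkage and recombination (clades and AOP structures are independent
categorical draws), spatial autocorrelation beyond the smooth covariate
fields, and measurement censoring at the detection limit.

## Environment-association models

`assign_region()` splits accessions at a piecewise-constant
mountain-chain boundary (42.5°N west of 2°E, 45.5°N to 18°E, 46.5°N
beyond; fully configurable); points exactly on the boundary are north.
`fit_region_model()` fits the linear probability model
`chemotype ~ genomic_group + bio5 + bio6 + bio13 + bio14 +
coast_distance` (OLS on a 0/1 response, deliberately a linear model
rather than logistic regression, matching the analysis the package
reproduces), per region or pooled with a geography main effect and all
geography × covariate interactions. Per-term p-values are Type-II
partial F-tests: with no interactions in the regional models Type II
equals the obvious drop-one test, and it does not depend on term order.
Factor levels with fewer than two observations are merged into
`"other"`; aliased coefficients are reported, never silently dropped.

## Haplotype trees

Distances are raw p-distances with pairwise deletion of gaps and `N` —
the minimal assumption at within-species divergence levels, where
multiple-hit corrections are negligible. Neighbor joining follows
Saitou–Nei with the Studier–Keppler criterion; taxa are processed in
lexicographic order and Q ties break at the smallest index pair, so
results are reproducible to the bit. Negative branch lengths are
clamped to zero with the deficit moved to the sibling branch,
preserving the joined pair's distance. Rooting places the root at the
midpoint of the outgroup's pendant edge and is idempotent. Bootstrap
supports resample alignment columns, rebuild the NJ tree and count
matching bipartitions.

Clade extraction (`cut_clades`) deletes edges in priority order until
the requested number of ingroup tip groups exists, where a deletion
only counts if it increases the group count. The default priority is
longest-edge-first: under the stem-and-backbone geometry of haplotype
groups diverged from a common ancestor, the clade stems are the longest
internal edges, and this rule recovers the generating clades exactly
(adjusted Rand index 1 in the tests). A root-proximity ordering
(`method = "depth"`) is also provided; it is appropriate when the
backbone is resolved and deep, but on star-like radiations the backbone
collapses to near-zero edges in arbitrary order and depth-based cutting
can split shallow clades first, which is why it is not the default.

## LOF frequencies under epistasis

`partition_by_epistasis()` separates C4-alkenyl accessions (3-Butenyl,
2-OH-3-Butenyl), where GS-OH function is phenotypically visible, from
all other classified accessions, where it is masked.
`compute_lof_frequencies()` keeps exact ratios alongside 3-decimal
display values rounded half away from zero. Enrichment of LOF alleles
in the masked set is tested one-sided by Fisher's exact test (exact at
these counts; the test suite pins the p-values to a direct
hypergeometric enumeration to 1e-12), per lesion class and pooled, with
the conditional-MLE odds ratio. Classes whose masked carrier count is
unknown are reported as unknown, never imputed.

## Numerical and scale choices

Problem sizes used by the tests and the acceptance script: the
survey-scale cohort is the full 797 accessions; statistical guarantees
(chemotype round-trip, heritability recovery at targets 0.3 and 0.8)
use 200 accessions; tree workflows use 80–150 tips with 100 bootstrap
replicates; the environment-model null calibration and power checks use
200 simulation replicates at 160–250 accessions. All simulation is
seed-deterministic; each generator stage derives its own stream from
the configured seed, so stages can be re-run independently.

Known limitations: heritability components use the balanced-design
method-of-moments formula with average level sizes, which is
approximate for strongly unbalanced tables; adjusted means for
accessions never measured on a compound are set to 0 (below detection)
with a warning; the clade count `k` must be chosen by the analyst, as
with any tree-cutting method; and the linear probability model can
predict outside [0, 1] — it is used for fidelity, not as the best
possible binary regression.
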