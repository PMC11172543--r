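---
title: "Predicted mutation burden in genebank germplasm: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicted mutation burden in genebank germplasm: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(burdenscan)
```

## The problem

Genebanks conserve millions of crop accessions for decades. Deleterious
mutations — amino-acid changes predicted to damage protein function —
accumulate in conserved germplasm through mutation, drift and
regeneration bottlenecks, and their extent is a direct measure of the
genetic risk carried by a collection. `burdenscan` implements a
genotype-panel workflow for quantifying that risk: identify predicted
deleterious SNPs (dSNPs) from functional and evolutionary-constraint
annotations, estimate a per-sample mutation burden, and characterize how
burden varies across germplasm groups and relates to genetic
distinctness.

The workflow targets highly inbred, predominantly selfing crops (the
motivating case is domesticated barley genotyped by GBS), where almost
all deleterious genotypes are homozygous.

## dSNP identification

A biallelic SNP is called deleterious when three predicates all hold for
at least one of its transcript annotations:

1. the annotation is a **missense** change on a **canonical transcript**
   (`canonical_only = TRUE`);
2. its **SIFT score is at most 0.05** — SIFT scores in [0, 1] measure
   tolerance of an amino-acid substitution, and 0.05 or less is the
   conventional deleterious call. The threshold is inclusive by default
   because that is how the deleterious class is defined; a strict `<`
   mode (`sift_strict`) is available;
3. the position's **GERP rejected-substitution (RS) score is strictly
   positive**. RS measures evolutionary constraint from a multi-species
   alignment; positive values mark conserved positions where
   substitutions are rejected, so a damaging change at such a position
   is predicted deleterious. Positions absent from the constraint track
   fail this criterion: constraint tracks distributed as
   "positive-scores-only" files encode non-qualifying positions by
   omission.

The deleterious allele is taken to be the alternate allele of the
annotated variant. Polarizing by ancestral state would require an
outgroup-informed derived-allele call that the input tables do not
carry, so no repolarization is attempted; with strongly skewed, rare
alternate alleles the two readings rarely disagree.

Annotations are keyed to genotyped loci by `(chrom, pos, alt)`. The
alternate allele is part of the key so that a position carrying several
annotated substitutions cannot be joined to the wrong one. Consequence
tallies are available both per annotation row and per SNP
(`per_snp = TRUE`, which keeps each SNP's most severe consequence under
the standard annotator severity ranking), since published tallies do not
always state which convention they use.

## Burden model

For a sample with $h$ homozygous and $e$ heterozygous deleterious
genotypes over $L$ dSNP loci, the per-deleterious-locus burdens are

$$B_{hom} = \frac{2h}{2L}, \qquad B_{het} = \frac{e}{2L}, \qquad
  B_{tot} = \frac{2h + e}{2L} = B_{hom} + B_{het},$$

i.e. the number of deleterious alleles carried, out of the $2L$
genotyped allele slots. $B_{tot}$ is computed as $B_{hom} + B_{het}$ so
the additivity identity is exact in floating point, not just
mathematically.

Missing genotype calls at dSNP loci contribute zero deleterious alleles
and, under the default `missing_policy = "zero"`, the denominator stays
$2L$ for every sample. This matches panels that were imputed upstream,
where residual missingness is small (around 3%) and treating a missing
call as non-carrier biases burdens down only negligibly. For sparser
data, `missing_policy = "per_sample"` divides by twice each sample's
count of non-missing dSNP genotypes instead.

**Carrier frequency.** Rarity statements are made on the *carrier
fraction* $f = \text{carriers}/N$ (samples with dosage $\ge 1$), not the
allele frequency over $2N$ chromosomes: in a selfing crop almost every
carrier is homozygous, and the carrier fraction is the quantity a
curator acts on ("this allele is present in 20 accessions"). The
spectrum reports counts at the 1-, 5- and 20-carrier thresholds plus a
binned histogram.

## Genetic distinctness (APD)

A sample's average pairwise difference is its mean genetic distance to
every other sample; low APD flags redundant (near-duplicate) accessions,
high APD distinct ones. The default distance is the allele-sharing
mismatch $d(a, b) = \overline{|a_m - b_m|}/2$ over loci where both
samples are called (pairwise deletion), which is 0 for identical
genotypes and 1 for opposite homozygotes; a simple-matching alternative
(proportion of unequal dosages) is provided because published
distinctness analyses do not always state their metric.

The $N \times N$ computation is done blockwise with dosage indicator
matrix products, so memory stays at $O(N \cdot \text{block})$ and the
result is exactly the naive double loop (this equivalence is a tested
invariant, not an approximation).

## Group characterization

Group summaries report n, mean, SD (sample SD, $n-1$ denominator; `NA`
for singleton groups), min and max of total burden per passport category
(panel, material type, growth habit, row type, country, region,
core/non-core). One-way fixed-effects ANOVA tests mean differences;
`"Unknown"` labels are excluded from the test by default but retained in
summary tables, since an unknown origin is a catalogue fact worth
reporting but not a biological group. Degenerate inputs resolve
explicitly: no between-group variation gives $F = 0$, $p = 1$; zero
within-group variance with distinct means gives $p = 0$ with a warning.

The burden–APD association is summarized by Pearson's r with the
two-sided t-transform p-value. At genebank cohort sizes any $|r| >
0.02$ is formally significant, so the report emphasizes r itself.

The **selection target zone** operationalizes the germplasm-choice
trade-off: breeders want distinct but low-burden material, so the zone
is the rectangle `apd >= apd_min & total_burden <= burden_max`. When
thresholds are not supplied, the pipeline defaults to the upper-quartile
APD and lower-quartile burden — a deliberately conservative corner
rather than a tuned cutoff.

## The synthetic cohort generator

`generate_bundle()` produces complete, internally consistent input
bundles (VCF, annotation TSV, constraint TSV, passport CSV) with truth
tables, so every stage is testable without external data. It emulates
the marginal structure the pipeline consumes:

- **Inbred genotypes**: carriers are homozygous with probability
  `selfing_rate = 0.99`, the value implied by cohorts averaging ~4.7
  homozygous but only ~0.05 heterozygous deleterious genotypes per
  sample.
- **Rarity skew**: per-locus carrier counts follow a Zipf-like law
  (`s = 1.5`, capped at carrier fraction 0.2), giving the strongly
  skewed spectrum in which most deleterious alleles are carried by a
  handful of samples. A target rare fraction (e.g. 82% of dSNPs at
  carrier fraction ≤ 0.001) can be requested; it is infeasible below
  N = 1000 because a single carrier already exceeds that fraction, and
  the generator says so rather than silently missing the target.
- **Missingness**: calls are masked at `missing_rate = 0.029`
  (the ~2.9% per-marker missing rate typical of imputed GBS panels).
- **Group structure**: passport groups receive positive carrier
  weights; a sample's chance of being drawn as a carrier scales with
  its weight, so expected group-mean burdens are ordered by the planted
  effects. Defaults are a 60/30/10 landrace/cultivar/breeding split
  with weights 1.3/1.0/0.85, reproducing the landrace > cultivar >
  breeding-material ordering reported for real genebank panels.
  Ordering recovery is a large-group property (reliable from roughly
  200 samples per group); the 10%-group default is below that size at
  N = 500, which is faithful to real passport imbalance but means its
  rank is noisy.
- **Redundancy**: a few exact-duplicate pairs are planted so the APD
  distribution has the redundant tail real collections show.

Genotypes are placed per locus by drawing the exact planted number of
carriers without replacement, not per sample from frequencies, so
locus-level truth is exact; truth tables are computed from the final
matrix (after masking and duplication), making planted-recovery tests
exact identities under the missing-as-noncarrier convention. Identical
seed and configuration give byte-identical files (all floating-point
output uses fixed decimal formats).

What the generator does **not** emulate: linkage disequilibrium,
demography, selection, genotyping error, or within-accession
heterogeneity. Passing tests therefore demonstrate correctness of the
estimators on data with the assumed marginal structure, not robustness
to the correlated noise of real GBS panels.

## Numerical and design choices

- Coordinates are 1-based throughout (VCF convention); the constraint
  track must share the assembly and convention.
- Dosage codes are `{0, 1, 2, NA}`; phased and unphased GT separators
  are equivalent; multi-allelic or indel records are a hard error by
  default (`skip_nonbiallelic = TRUE` downgrades to skip-with-warning),
  because the intended input is a biallelic SNP panel.
- Report rounding: burdens print at 5 decimals in per-country tables,
  carrier frequencies at 6, APDs at 6; R's round-half-even is used.
  Full precision is kept internally — rounding is formatting only.
- When several transcript annotations of one locus qualify, the lowest
  SIFT score is kept; output order is (chrom, pos), deterministic.
- Pipeline outputs are written atomically (temp file, then rename), so
  an aborted run leaves no truncated tables.

## Problem sizes used in the test suite

The reference synthetic conditions are 500 samples × 2000 loci with 50
planted dSNPs — large enough for stable group contrasts and spectrum
shape, small enough that the full suite (including 200 null-calibration
replicates at 150 × 200 and an exhaustive APD cross-check at N = 50)
runs in well under a minute. The ANOVA null calibration uses bundles
without duplicate clusters, since planted duplicates violate the
independence the F-test assumes.

## Known limitations

- Burden is predictive: SIFT/RS-based calls carry no fitness
  validation, and paralogous genes can inflate deleterious predictions.
- A reduced-representation panel samples a fixed sliver of the genome;
  zero estimated burden means "no deleterious alleles at the genotyped
  loci", not "no genetic load".
- Sample-wise estimates ignore within-accession variation (one
  genotype stands for a whole accession).
- No ancestral-state polarization; the alternate allele is assumed
  deleterious where the filters fire.
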