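# burdenscan

Deleterious-SNP identification and mutation-burden estimation for
genebank germplasm collections.

Genebanks conserve crop accessions for decades, and deleterious
mutations accumulating in conserved germplasm are a largely unmeasured
genetic risk. `burdenscan` quantifies that risk from a biallelic SNP
genotype panel plus standard per-variant annotation tables. It is aimed
at curators and population geneticists working with highly inbred,
predominantly selfing crops (the motivating case is domesticated barley
genotyped by GBS).

## What it computes

**dSNP identification.** A SNP is called a predicted deleterious SNP
(dSNP) when it has a missense annotation on a canonical transcript with
SIFT score ≤ 0.05 *and* its position has a GERP rejected-substitution
constraint score RS > 0. SIFT measures tolerance of an amino-acid
substitution (low = damaging); positive RS marks evolutionarily
conserved positions where substitutions are rejected. Positions absent
from the constraint track fail the RS criterion.

**Mutation burden.** For a sample carrying *h* homozygous and *e*
heterozygous deleterious genotypes over *L* dSNP loci,

    B_hom = 2h / (2L)    B_het = e / (2L)    B_tot = B_hom + B_het

i.e. the fraction of the sample's 2L genotyped allele slots occupied by
deleterious alleles.

**Carrier spectrum.** Per dSNP, the carrier fraction f = carriers / N
(samples with dosage ≥ 1), with rarity counts at the 1-, 5- and
20-carrier thresholds.

**Distinctness and characterization.** Per-sample average pairwise
difference (APD; allele-sharing distance, pairwise-complete loci),
group-wise burden summaries and one-way ANOVA over passport categories,
Pearson correlation between burden and APD, and the selection target
zone (high APD, low burden) for choosing distinct but low-load
germplasm.

A planted-truth synthetic data generator (`generate_bundle()`) emulates
the inbred-crop input structure (99% homozygous carriers, Zipf-skewed
carrier counts, 2.9% missing calls, group-level burden effects,
duplicate accessions), so the whole pipeline is testable end to end
without external downloads.

## Worked example

```r
library(burdenscan)

# a complete synthetic study: VCF + annotations + constraint + passport
cfg <- synthetic_config(seed = 101)          # 500 samples x 2000 loci
bundle <- generate_bundle(cfg, "demo-bundle")

gm    <- read_genotypes("demo-bundle/genotypes.vcf")
ann   <- read_annotations("demo-bundle/annotations.tsv")
track <- read_constraint("demo-bundle/constraint.tsv")
dset  <- identify_dsnps(ann, track, loci = gm$loci)

est  <- burden_estimates(gm, dset)
spec <- carrier_spectrum(gm, dset)
apd  <- apd_vector(gm)
```

```
> gm
genotype_matrix: 500 samples x 2000 loci
  missing calls: 28831 (2.88%)
> per_chromosome_counts(dset)
1H 2H 3H 4H 5H 6H 7H
12  7  5  4  5  7 10
> spec
carrier spectrum of 50 dSNPs in 500 samples
  <= 1 carrier(s) (f <= 0.002000): 19 dSNPs (38.0%)
  <= 5 carrier(s) (f <= 0.010000): 34 dSNPs (68.0%)
  <= 20 carrier(s) (f <= 0.040000): 44 dSNPs (88.0%)
> correlate_burden_apd(est$total_burden, apd$apd)
burden-APD Pearson r = 0.1605 (n = 500, p = 0.000315)
```

All 50 planted dSNPs are recovered (L = 50), spread over the seven
chromosomes. The cohort mean total burden is 0.01366 (range 0–0.08),
with 255 samples showing zero burden at the genotyped loci — a zero
means "no deleterious alleles observed at these loci", not "no load".
Most deleterious alleles are rare (38% singletons), and burden
correlates positively with genetic distinctness (r = 0.16): distinct
accessions tend to carry more predicted load, which is why the
selection zone filters on both axes.

Group characterization uses the passport:

```r
pp <- align_passport(read_passport("demo-bundle/passport.csv"), gm$samples)
format_group_summary(group_summary(est$total_burden, pp$material_type))
#>               group   n    mean      sd     min     max
#> 1 Breeding_material  50 0.00700 0.01282 0.00000 0.06000
#> 2          Cultivar 150 0.01147 0.01453 0.00000 0.04000
#> 3          Landrace 300 0.01587 0.01687 0.00000 0.08000
anova_oneway(est$total_burden, pp$material_type)
#> one-way ANOVA: F(2, 497) = 8.776, p = 0.0001797 (k = 3, n = 500)
```

The realized group means follow the planted landrace > cultivar >
breeding-material ordering.

The whole analysis can also be driven from one config:

```r
run_pipeline(run_config(
  vcf = "demo-bundle/genotypes.vcf",
  annotations = "demo-bundle/annotations.tsv",
  constraint = "demo-bundle/constraint.tsv",
  passport = "demo-bundle/passport.csv",
  outdir = "demo-out"))
```

which writes `dsnps.tsv`, `burdens.tsv`, `spectrum.tsv`, `apd.tsv`,
per-grouping summary tables, `anova.tsv`, `zone.tsv` and a JSON run
report with parameters, input checksums and headline numbers. A thin
shell wrapper lives at `inst/cli/burdenscan`
(`burdenscan run --config run.yaml`, `burdenscan simulate ...`).

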