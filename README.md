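# mhcdepth

Genotype reliability across sequencing depths, and diversity of multicopy
immune gene families.

## The problem

Conservation genomics increasingly relies on whole-genome resequencing
(WGS), but the most disease-relevant regions of a genome — the major
histocompatibility complex (MHC) above all — are polymorphic, duplicated
and hard to genotype. Before committing a population-scale survey to a
sequencing depth, two questions must be answered:

1. **How deep is deep enough?** At what target depth do genotype calls in
   complex multicopy genes become concordant with a trusted high-depth call
   set (e.g. target-enrichment data at hundreds-fold coverage), and when
   does copy-number variation (CNV) become detectable from read depth?
2. **What diversity is there?** Given a depth that works, how are SNPs,
   alleles, copy number and functional supertypes distributed across a
   species' range?

`mhcdepth` implements the full analysis workflow for both questions as a
tested R package, driven end-to-end by a synthetic diploid population
simulator, so every stage is verifiable without access to the original
sequencing data. The motivating system is the koala (*Phascolarctos
cinereus*) MHC — class I and class II genes profiled against ten
single-copy toll-like receptor (TLR) genes — but every component is
organism-agnostic.

## The methods at its core

**Concordance.** For each variant site shared between a reference call set
(TE, target enrichment) and a test call set (WGS), every individual's
genotype pair is classified onto a 4 × 4 grid — rows the WGS state, columns
the TE state, both ordered (hom-ref, het, hom-alt, missing) — labelled
`A`..`P` row-major. Four metrics partition the pairs:

```
concordance      = (A + F + K + P) / total
missing WGS      = (M + N + O) / total
missing TE       = (D + H + L) / total
non-concordance  = (B + C + E + G + I + J) / total
```

**Filtering.** Sites pass a hard-filter cascade before analysis: only
biallelic exonic SNPs; QUAL ≥ 80; MQ ≥ 40; (MHC profile only) MQRankSum in
(−12.5, 12.5), ReadPosRankSum in (−8, 8) and mean heterozygote
allelic-balance difference |ref − alt| / (ref + alt) ≤ 0.9; and mean site
depth at least min(target/3, 10).

**Copy number.** Reads per kilobase (RPK = reads / gene kb) for each gene
are normalised by the mean RPK of the single-copy reference genes and
doubled, giving an allelic copy number (ACN) where 2 means a normal diploid
single-copy gene. ACN in [1.5, 2.5] is single copy; classes 0–6 bin at
n ± 0.5.

**Diversity.** Phased haplotypes per gene become alleles (`H1`, `H2`, … by
descending count); alleles below frequency 0.005 are removed; per-gene
statistics are the number of sequences N, segregating SNPs, non-synonymous
SNPs (from the genetic code), nucleotide diversity π (mean pairwise
difference per site) and allelic diversity h = n/(n−1)(1 − Σp²). Population
differentiation is Weir–Cockerham F_ST (1984 variance components,
mean-weighted Σa / Σ(a+b+c)); structure is explored with principal
coordinates analysis and a permutation Mantel test of isolation by
distance.

**Supertypes.** Class I alleles are translated, reduced to their
peptide-binding residues, encoded with the five Sandberg z-descriptors per
residue, clustered by k-means with k selected by modal minimum BIC
(BIC = n·ln(WSS/n) + k·ln n over replicated searches), and refined by
discriminant analysis of principal components (DAPC) with the PC count
tuned by the a-score.

## Worked example

The depth-comparison pipeline simulates one population of ten individuals,
genotypes it with a 264× reference call set and WGS call sets down-sampled
over the 0.5–30× ladder, filters each, and reports concordance and CNV
recovery per depth:

```r
library(mhcdepth)
res <- runDepthComparison(depthComparisonConfig(seed = 1))
subset(res$concordance, family == "MHC",
       select = c(depth, n_shared_sites, concordance, missing_wgs, non_concordance))
#>  depth n_shared_sites concordance missing_wgs non_concordance
#>    0.5             40       0.165    0.802500         0.03250
#>    1.0             87       0.256    0.694253         0.04943
#>    2.0            127       0.520    0.403937         0.07638
#>    5.0            131       0.896    0.044275         0.05954
#>   10.0            122       0.980    0.004098         0.01639
#>   15.0            131       0.994    0.000000         0.00611
#>   20.0            124       0.996    0.000806         0.00323
#>   30.0            119       0.999    0.000000         0.00084
```

Concordance between the WGS and reference call sets rises with depth and
plateaus around 15×; at 0.5× most shared sites simply lack a WGS genotype
(`missing_wgs` ≈ 0.80). CNV recovery behaves the same way — complete
deletions are caught from 1× (`deletion_detection` = 1 at every depth ≥ 1
in `res$cnv`), hemizygotes need ≥ 10×, and copy classes are essentially
exact at 30×.

The package also ships the published per-gene diversity summary for the 24
polymorphic koala MHC genes as a worked input:

```r
agg <- aggregateGeneTable(koalaGeneStats())
agg$overall[, c("n", "snps", "snps_ns", "n_alleles")]
#>             n   snps snps_ns n_alleles
#> sum  19183.00 269.00  164.00     180.0
#> mean   799.29  11.21    6.83       7.5
#> min    363.00   1.00    0.00       2.0
#> max    876.00  53.00   36.00      27.0
```

180 alleles in total (75 class I + 105 class II), a mean of 7.5 alleles and
6.8 non-synonymous SNPs per gene, and a maximum of 27 alleles at one gene.
The range-wide survey pipeline (`runDiversitySurvey()`) produces this table
shape, pairwise F_ST between regions, ordinations, a Mantel test and
supertype assignments from simulated (or user-supplied) data.

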