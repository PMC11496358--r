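Package: mhcdepth
Title: Genotype Reliability Across Sequencing Depths and Diversity of
    Multicopy Immune Gene Families
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to assess how reliably diploid genotypes and gene copy
    number can be recovered from whole-genome resequencing at different
    target depths, and to characterise diversity in polymorphic multicopy
    immune gene families (MHC class I and II) relative to conserved
    single-copy reference genes (TLR). Implements the 16-category
    genotype-pair concordance classification between a high-depth
    reference call set and a test call set, hard-filter cascades for
    variant sites (quality, mapping quality, rank sums, mean depth,
    allelic balance), read-depth allelic copy-number estimation with
    single-copy normalisation, allele assignment from phased haplotypes
    with rare-allele removal, nucleotide and allelic diversity,
    Weir-Cockerham F_ST, principal coordinates analysis, Mantel tests of
    isolation by distance, and physiochemical supertype clustering of
    class I alleles (z-descriptor encoding, BIC model selection over
    k-means, discriminant analysis of principal components). A synthetic
    diploid population simulator with region-structured allele
    frequencies, copy-number genotypes and depth-dependent genotype
    missingness makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    Biostrings,
    VariantAnnotation,
    MASS,
    geosphere,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan,
    ape,
    mclust
biocViews: Genetics, PopulationGenetics, SNP, CopyNumberVariation,
    Sequencing, Coverage
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
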