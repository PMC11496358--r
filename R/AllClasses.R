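#' @import methods
#' @importFrom S4Vectors DataFrame SimpleList metadata metadata<- mcols mcols<-
#' @importFrom GenomicRanges GRanges seqnames start end strand granges
#' @importFrom IRanges IRanges findOverlaps
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowRanges
#'   rowRanges<- colData colData<-
#' @importFrom Biostrings DNAStringSet AAStringSet width translate
#'   reverseComplement subseq GENETIC_CODE
NULL

## Genotype call codes used throughout: 0 = homozygous reference,
## 1 = heterozygous, 2 = homozygous alternate, NA = missing call.

#' Matrix of genotype calls with depths and site annotations
#'
#' `GenotypeExperiment` extends
#' [SummarizedExperiment::RangedSummarizedExperiment] to hold a sites x
#' individuals genotype matrix together with the per-genotype total depth and
#' allele depths, the per-site annotations used by hard filters (QUAL, MQ,
#' MQRankSum, ReadPosRankSum), and the gene each site falls in. Rows are
#' biallelic SNP sites (1-based positions, VCF convention), columns are
#' individuals with a `region` label.
#'
#' Assays:
#' \describe{
#'   \item{calls}{integer; 0 hom-ref, 1 het, 2 hom-alt, NA missing}
#'   \item{depth}{integer; total reads covering the genotype (may be 0 for
#'     missing calls)}
#'   \item{refDepth, altDepth}{integer; reads supporting each allele.
#'     Wherever both are present, `depth == refDepth + altDepth`.}
#' }
#'
#' @export
setClass("GenotypeExperiment", contains = "RangedSummarizedExperiment")

setValidity("GenotypeExperiment", function(object) {
    a <- assays(object)
    need <- c("calls", "depth", "refDepth", "altDepth")
    if (!all(need %in% names(a)))
        return(paste("assays must include", paste(need, collapse = ", ")))
    cl <- a$calls
    if (!all(cl[!is.na(cl)] %in% 0:2))
        return("calls must be 0 (hom-ref), 1 (het), 2 (hom-alt) or NA")
    dp <- a$depth; rd <- a$refDepth; ad <- a$altDepth
    ok <- !is.na(dp) & !is.na(rd) & !is.na(ad)
    if (any(dp[ok] != rd[ok] + ad[ok]))
        return("depth must equal refDepth + altDepth where allele depths are present")
    if (any(dp[!is.na(dp)] < 0))
        return("depths must be non-negative")
    needed <- c("ref", "alt", "gene_id")
    if (nrow(object) > 0L && !all(needed %in% names(mcols(rowRanges(object)))))
        return("rowRanges must carry ref, alt and gene_id")
    if (ncol(object) > 0L && !"region" %in% names(colData(object)))
        return("colData must carry a region label per individual")
    TRUE
})

#' Phased haplotype sequences for one gene
#'
#' Holds up to two phased coding sequences per individual for a single gene.
#' Sequences containing any non-ACGT character are flagged `unresolved`
#' (ambiguity codes mean phasing failed to resolve the allele) and are
#' excluded before allele assignment.
#'
#' @slot geneId single gene identifier.
#' @slot sequences [Biostrings::DNAStringSet], all the same width.
#' @slot individual,hapIndex character/integer vectors parallel to
#'   `sequences`; `hapIndex` is 1 or 2.
#' @slot unresolved logical, `TRUE` where the sequence contains a non-ACGT
#'   character.
#' @export
setClass("HaplotypeSet",
    representation(geneId = "character", sequences = "DNAStringSet",
                   individual = "character", hapIndex = "integer",
                   unresolved = "logical"))

setValidity("HaplotypeSet", function(object) {
    n <- length(object@sequences)
    if (length(object@individual) != n || length(object@hapIndex) != n ||
        length(object@unresolved) != n)
        return("individual, hapIndex and unresolved must parallel sequences")
    if (n > 0 && length(unique(width(object@sequences))) != 1L)
        return("all haplotype sequences of a gene must have equal length")
    if (length(object@geneId) != 1L)
        return("geneId must be a single string")
    if (n > 0 && !all(object@hapIndex %in% 1:2))
        return("hapIndex must be 1 or 2")
    tab <- table(object@individual)
    if (any(tab > 2))
        return("at most two haplotypes per individual per gene")
    TRUE
})

#' Allele table for one gene
#'
#' Distinct haplotype sequences become alleles, labelled `H1`, `H2`, ... by
#' descending count (ties broken by sequence lexicographic order). Counts are
#' kept per region so regional allele frequencies and frequency heatmaps can
#' be derived directly.
#'
#' @slot geneId gene identifier.
#' @slot sequences [Biostrings::DNAStringSet] named by allele label.
#' @slot counts integer matrix, alleles x regions; `rowSums(counts)` are the
#'   total allele counts and sum to `nSequences`.
#' @slot assignments [S4Vectors::DataFrame] with one row per input sequence:
#'   `individual`, `hapIndex`, `allele`.
#' @export
setClass("AlleleTable",
    representation(geneId = "character", sequences = "DNAStringSet",
                   counts = "matrix", assignments = "DataFrame"))

setValidity("AlleleTable", function(object) {
    if (length(object@sequences) != nrow(object@counts))
        return("counts must have one row per allele")
    if (!identical(names(object@sequences), rownames(object@counts)))
        return("counts rownames must match allele labels")
    if (anyDuplicated(names(object@sequences)))
        return("allele labels must be unique")
    if (any(object@counts < 0))
        return("counts must be non-negative")
    TRUE
})

#' Hard-filter profile for variant sites
#'
#' Thresholds of the site-level filter cascade. The `MHC` profile applies
#' quality, mapping-quality, rank-sum and allelic-balance rules; the `TLR`
#' profile applies only the quality and mapping-quality rules (rank-sum
#' bounds and the allelic-balance cut-off are `NA`). All comparisons are
#' strict: a site is removed when QUAL < `minQual`, MQ < `minMQ`, a rank sum
#' falls strictly outside its bounds, or the mean heterozygote allelic-balance
#' difference exceeds `maxAlleleBalanceDiff`.
#'
#' @export
setClass("FilterProfile",
    representation(name = "character", minQual = "numeric", minMQ = "numeric",
                   mqRankSumBounds = "numeric",
                   readPosRankSumBounds = "numeric",
                   maxAlleleBalanceDiff = "numeric"))

setValidity("FilterProfile", function(object) {
    if (object@minQual <= 0 || object@minMQ <= 0)
        return("thresholds must be strictly positive")
    for (b in list(object@mqRankSumBounds, object@readPosRankSumBounds)) {
        if (length(b) != 2L) return("rank-sum bounds must have length 2")
        if (!all(is.na(b)) && !isTRUE(all.equal(b[1], -b[2])))
            return("rank-sum bounds must be symmetric about zero")
    }
    TRUE
})

#' Sixteen-category genotype-pair concordance table
#'
#' Counts of genotype pairs between a high-depth reference call set
#' (\dQuote{TE}, target enrichment) and a test call set (\dQuote{WGS}),
#' classified into letters A..P on a 4 x 4 grid: rows are the WGS state,
#' columns the TE state, both ordered (hom-ref, het, hom-alt, missing), and
#' letters run row-major. The diagonal (A, F, K, P) are concordant pairs;
#' column 4 (D, H, L) are TE-missing; row 4 (M, N, O) are WGS-missing; the
#' remaining six letters are discordant calls.
#'
#' @slot counts named integer vector over `LETTERS[1:16]`.
#' @export
setClass("ConcordanceTable", representation(counts = "integer"))

setValidity("ConcordanceTable", function(object) {
    if (!identical(names(object@counts), LETTERS[1:16]))
        return("counts must be named A..P")
    if (any(object@counts < 0)) return("counts must be non-negative")
    TRUE
})

#' Configuration of the synthetic population simulator
#'
#' Defines the diploid populations the simulator generates: regions with
#' Dirichlet-structured allele frequencies, per-gene copy-number genotype
#' distributions (0-6 copies; single-copy reference genes are pinned at 2),
#' a depth ladder, and the two-parameter genotype-caller emulation (minimum
#' reads to call and per-read error).
#'
#' @slot nRegions,nIndividuals number of regions and individuals per region.
#' @slot genes exon-level [GenomicRanges::GRanges] as built by
#'   [geneRegions()].
#' @slot allelePoolSize alleles in each gene's regional pool.
#' @slot mutationDensity expected polymorphic sites per bp of coding
#'   sequence.
#' @slot differentiation in `[0, 1)`: approximate expected F_ST between
#'   neighbouring regions (0 = panmixia). Regional allele frequencies follow
#'   a Dirichlet chain along the region order, so differentiation accumulates
#'   with distance (isolation by distance) unless `isolationByDistance` is
#'   `FALSE`, in which case regions are exchangeable draws around the global
#'   frequencies.
#' @slot copyNumberProbs named list: gene id to a `nRegions` x 7 matrix of
#'   probabilities over 0..6 copies (rows sum to 1). Genes absent from the
#'   list are single copy.
#' @slot targetDepths depth ladder for down-sampled call sets.
#' @slot enrichmentDepth depth of the reference (target-enrichment) call set.
#' @slot readLength read length in bp used to convert depth to read counts.
#' @slot minReads minimum reads to emit a genotype call.
#' @slot perReadError probability a read reports the wrong allele.
#' @slot annotationParams rates/scales for simulated site annotations
#'   (QUAL, MQ, rank sums) so the filter cascade has failing sites to remove.
#' @slot pbrPositions codon positions (1-based, within the translated CDS)
#'   treated as the peptide-binding region for supertype clustering.
#' @slot seed base RNG seed; all generators derive their streams from it.
#' @export
setClass("SimConfig",
    representation(nRegions = "integer", nIndividuals = "integer",
                   genes = "GRanges", allelePoolSize = "integer",
                   mutationDensity = "numeric", differentiation = "numeric",
                   isolationByDistance = "logical",
                   copyNumberProbs = "list", targetDepths = "numeric",
                   enrichmentDepth = "numeric", readLength = "numeric",
                   minReads = "integer", perReadError = "numeric",
                   annotationParams = "list", pbrPositions = "integer",
                   seed = "integer"))

setValidity("SimConfig", function(object) {
    if (object@nRegions < 1L || object@nIndividuals < 1L)
        return("need at least one region and one individual per region")
    if (object@differentiation < 0 || object@differentiation >= 1)
        return("differentiation must be in [0, 1)")
    if (object@mutationDensity <= 0)
        return("mutationDensity must be positive")
    if (any(object@targetDepths <= 0))
        return("target depths must be positive")
    if (object@minReads < 1L) return("minReads must be >= 1")
    if (object@perReadError < 0 || object@perReadError >= 0.5)
        return("perReadError must be in [0, 0.5)")
    for (g in names(object@copyNumberProbs)) {
        p <- object@copyNumberProbs[[g]]
        if (!is.matrix(p) || ncol(p) != 7L || nrow(p) != object@nRegions)
            return("copyNumberProbs matrices must be nRegions x 7 (copies 0..6)")
        if (any(abs(rowSums(p) - 1) > 1e-8) || any(p < 0))
            return("copy-number probabilities must be non-negative and sum to 1")
    }
    TRUE
})

#' Ground truth of a simulated population
#'
#' Everything downstream stages are asked to recover: region labels and
#' geographic coordinates per individual, the per-gene allele pools and
#' regional frequencies, true copy numbers, the two phased haplotypes per
#' individual per gene, and the true genotypes at every polymorphic site.
#'
#' @slot config the [SimConfig-class] that produced it.
#' @slot individuals [S4Vectors::DataFrame]: `id`, `region`, `lon`, `lat`.
#' @slot alleleSeqs [S4Vectors::SimpleList] of per-gene
#'   [Biostrings::DNAStringSet] allele pools.
#' @slot alleleFreqs list of per-gene alleles x regions frequency matrices.
#' @slot copyNumber integer matrix genes x individuals.
#' @slot haplotypes list of per-gene 2 x individuals matrices of allele
#'   indices (`NA` where the individual carries fewer copies).
#' @slot sites [GenomicRanges::GRanges] of true polymorphic sites with
#'   `ref`, `alt`, `gene_id` and `cdsPos` (position within the gene CDS).
#' @slot trueGenotypes integer matrix sites x individuals (0/1/2, `NA` for
#'   whole-gene deletions).
#' @export
setClass("PopulationTruth",
    representation(config = "SimConfig", individuals = "DataFrame",
                   alleleSeqs = "SimpleList", alleleFreqs = "list",
                   copyNumber = "matrix", haplotypes = "list",
                   sites = "GRanges", trueGenotypes = "matrix"))

setValidity("PopulationTruth", function(object) {
    n <- nrow(object@individuals)
    if (ncol(object@copyNumber) != n)
        return("copyNumber must have one column per individual")
    if (ncol(object@trueGenotypes) != n)
        return("trueGenotypes must have one column per individual")
    if (nrow(object@trueGenotypes) != length(object@sites))
        return("trueGenotypes must have one row per site")
    cn <- object@copyNumber
    if (any(cn[!is.na(cn)] < 0 | cn[!is.na(cn)] > 6))
        return("copy numbers must be in 0..6")
    TRUE
})

#' Supertype clustering model
#'
#' Result of BIC-guided k selection and discriminant analysis of principal
#' components (DAPC) on z-descriptor-encoded peptide-binding residues.
#'
#' @slot k selected number of clusters.
#' @slot assignments factor of cluster memberships, named by allele.
#' @slot bicTrace numeric matrix, replicates x k, of BIC values.
#' @slot nPca number of principal components retained for the discriminant
#'   step.
#' @slot posterior numeric matrix alleles x clusters; rows sum to 1.
#' @slot pca,lda fitted components kept so the model can re-project.
#' @export
setClass("SupertypeModel",
    representation(k = "integer", assignments = "factor",
                   bicTrace = "matrix", nPca = "integer",
                   posterior = "matrix", pca = "ANY", lda = "ANY"))

setValidity("SupertypeModel", function(object) {
    if (object@k < 1L) return("k must be >= 1")
    if (nrow(object@posterior) > 0 &&
        any(abs(rowSums(object@posterior) - 1) > 1e-6))
        return("posterior rows must sum to 1")
    TRUE
})
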