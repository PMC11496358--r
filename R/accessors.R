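#' Accessors for GenotypeExperiment
#'
#' `genotypeCalls()` returns the sites x individuals integer call matrix
#' (0 hom-ref, 1 het, 2 hom-alt, NA missing); `genotypeDepth()`,
#' `refDepth()` and `altDepth()` the matching depth matrices; `siteInfo()`
#' the per-site annotations as a `DataFrame`; `regionLabels()` the region
#' label of each individual.
#'
#' @param x a [GenotypeExperiment-class].
#' @return matrices, a `DataFrame`, or a character vector (see above).
#' @aliases genotypeCalls genotypeDepth refDepth altDepth siteInfo
#'   regionLabels
#' @name GenotypeExperiment-accessors
#' @examples
#' ge <- exampleGenotypes()
#' genotypeCalls(ge)[1:3, 1:3]
#' table(regionLabels(ge))
NULL

#' @rdname GenotypeExperiment-accessors
#' @export
genotypeCalls <- function(x) assay(x, "calls")

#' @rdname GenotypeExperiment-accessors
#' @export
genotypeDepth <- function(x) assay(x, "depth")

#' @rdname GenotypeExperiment-accessors
#' @export
refDepth <- function(x) assay(x, "refDepth")

#' @rdname GenotypeExperiment-accessors
#' @export
altDepth <- function(x) assay(x, "altDepth")

#' @rdname GenotypeExperiment-accessors
#' @export
siteInfo <- function(x) {
    df <- mcols(rowRanges(x))
    df$chrom <- as.character(seqnames(rowRanges(x)))
    df$pos <- start(rowRanges(x))
    df
}

#' @rdname GenotypeExperiment-accessors
#' @export
regionLabels <- function(x) as.character(colData(x)$region)

#' Construct a GenotypeExperiment
#'
#' @param calls integer matrix sites x individuals, values 0/1/2/NA.
#' @param depth,refDepth,altDepth integer matrices of the same shape; any
#'   may be omitted (`depth` defaults to `refDepth + altDepth` when both are
#'   given, otherwise NA).
#' @param rowRanges a [GenomicRanges::GRanges] with metadata columns `ref`,
#'   `alt`, `gene_id` and optionally `qual`, `mq`, `mqRankSum`,
#'   `readPosRankSum`.
#' @param individuals character vector of individual ids (defaults to
#'   `colnames(calls)`).
#' @param region character vector of region labels per individual.
#' @return a [GenotypeExperiment-class].
#' @export
GenotypeExperiment <- function(calls, depth = NULL, refDepth = NULL,
                               altDepth = NULL, rowRanges,
                               individuals = colnames(calls),
                               region = rep("R1", ncol(calls))) {
    storage.mode(calls) <- "integer"
    blank <- function() matrix(NA_integer_, nrow(calls), ncol(calls))
    if (is.null(refDepth)) refDepth <- blank()
    if (is.null(altDepth)) altDepth <- blank()
    if (is.null(depth)) {
        depth <- refDepth + altDepth
    }
    storage.mode(depth) <- "integer"
    storage.mode(refDepth) <- "integer"
    storage.mode(altDepth) <- "integer"
    if (is.null(individuals))
        individuals <- paste0("ind", seq_len(ncol(calls)))
    dn <- list(NULL, individuals)
    dimnames(calls) <- dimnames(depth) <- dn
    dimnames(refDepth) <- dimnames(altDepth) <- dn
    se <- SummarizedExperiment(
        assays = list(calls = calls, depth = depth,
                      refDepth = refDepth, altDepth = altDepth),
        rowRanges = rowRanges,
        colData = DataFrame(region = region, row.names = individuals))
    new("GenotypeExperiment", se)
}

setMethod("show", "GenotypeExperiment", function(object) {
    cat("GenotypeExperiment:", nrow(object), "biallelic sites x",
        ncol(object), "individuals\n")
    cl <- genotypeCalls(object)
    if (length(cl)) {
        miss <- mean(is.na(cl))
        cat(sprintf("  missing calls: %.1f%%; genes: %d; regions: %d\n",
                    100 * miss,
                    length(unique(mcols(rowRanges(object))$gene_id)),
                    length(unique(regionLabels(object)))))
    }
    log <- metadata(object)$filterLog
    if (!is.null(log))
        cat("  filters applied:", paste(names(log), collapse = ", "), "\n")
})

#' Accessors for HaplotypeSet and AlleleTable
#'
#' @param x a [HaplotypeSet-class] or [AlleleTable-class].
#' @return `haplotypeSequences()` and `alleleSequences()` return a
#'   `DNAStringSet`; `unresolvedFlags()` a logical vector;
#'   `incompleteIndividuals()` the ids with fewer than two resolved
#'   haplotypes; `alleleCountMatrix()` the alleles x regions count matrix;
#'   `alleleAssignments()` the per-sequence allele labels.
#' @name haplotype-accessors
#' @aliases haplotypeSequences unresolvedFlags incompleteIndividuals
#'   alleleSequences alleleCountMatrix alleleAssignments
NULL

#' @rdname haplotype-accessors
#' @export
haplotypeSequences <- function(x) x@sequences

#' @rdname haplotype-accessors
#' @export
unresolvedFlags <- function(x) x@unresolved

#' @rdname haplotype-accessors
#' @export
incompleteIndividuals <- function(x) {
    ok <- !x@unresolved
    tab <- table(x@individual[ok])
    sort(unique(c(names(tab)[tab < 2], setdiff(x@individual, names(tab)))))
}

#' @rdname haplotype-accessors
#' @export
alleleSequences <- function(x) x@sequences

#' @rdname haplotype-accessors
#' @export
alleleCountMatrix <- function(x) x@counts

#' @rdname haplotype-accessors
#' @export
alleleAssignments <- function(x) x@assignments

setMethod("show", "HaplotypeSet", function(object) {
    cat("HaplotypeSet for gene", object@geneId, "-",
        length(object@sequences), "sequences from",
        length(unique(object@individual)), "individuals\n")
    if (any(object@unresolved))
        cat("  unresolved:", sum(object@unresolved), "\n")
})

setMethod("show", "AlleleTable", function(object) {
    cat("AlleleTable for gene", object@geneId, "-",
        length(object@sequences), "alleles over",
        sum(object@counts), "sequences\n")
})

setMethod("show", "ConcordanceTable", function(object) {
    cat("ConcordanceTable (", sum(object@counts), "genotype pairs )\n")
    print(matrix(object@counts, 4, 4, byrow = TRUE,
                 dimnames = list(WGS = c("hom_ref", "het", "hom_alt", "missing"),
                                 TE = c("hom_ref", "het", "hom_alt", "missing"))))
})

setMethod("show", "SimConfig", function(object) {
    cat("SimConfig:", object@nRegions, "regions x", object@nIndividuals,
        "individuals;", length(unique(mcols(object@genes)$gene_id)),
        "genes; differentiation", object@differentiation, "\n")
    cat("  depth ladder:", paste(object@targetDepths, collapse = ", "),
        "x; reference depth:", object@enrichmentDepth, "x\n")
})

setMethod("show", "PopulationTruth", function(object) {
    cat("PopulationTruth:", nrow(object@individuals), "individuals,",
        length(object@sites), "polymorphic sites,",
        nrow(object@copyNumber), "genes\n")
})

setMethod("show", "SupertypeModel", function(object) {
    cat("SupertypeModel: k =", object@k, "clusters over",
        length(object@assignments), "alleles (", object@nPca,
        "PCs retained )\n")
})
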