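#' Ready-made configurations for the two study designs
#'
#' `depthComparisonConfig()` mirrors the depth-comparison design: one
#' population of ten individuals genotyped by a 264x reference
#' (target-enrichment) call set and whole-genome call sets down-sampled
#' over the 0.5-30x ladder. `diversitySurveyConfig()` mirrors the
#' range-wide survey: seven regions along a geographic gradient genotyped
#' at 30x.
#'
#' @param seed base RNG seed.
#' @param nIndividuals individuals per region.
#' @param differentiation expected neighbouring-region F_ST.
#' @return a [SimConfig-class].
#' @export
depthComparisonConfig <- function(seed = 1L, nIndividuals = 10L) {
    simConfig(nRegions = 1L, nIndividuals = nIndividuals,
              differentiation = 0, seed = seed)
}

#' @rdname depthComparisonConfig
#' @export
diversitySurveyConfig <- function(seed = 1L, nIndividuals = 10L,
                                  differentiation = 0.15) {
    simConfig(nRegions = 7L, nIndividuals = nIndividuals,
              differentiation = differentiation, seed = seed)
}

familyGenes <- function(regions, families) {
    unique(mcols(regions)$gene_id[mcols(regions)$family %in% families])
}

subsetGenes <- function(x, genes) {
    x[mcols(rowRanges(x))$gene_id %in% genes, ]
}

#' Depth-comparison pipeline
#'
#' Simulates a population, genotypes it with a high-depth reference
#' (target-enrichment) call set and whole-genome call sets at each rung of
#' the depth ladder, pushes every call set through the family-appropriate
#' filter cascade, and reports per-depth concordance metrics (MHC and TLR
#' separately) together with per-depth copy-number recovery.
#'
#' @param config a [SimConfig-class]; defaults to
#'   [depthComparisonConfig()].
#' @return list with `concordance` (depth x family metrics table), `cnv`
#'   (per-depth copy-class accuracy and deletion detection) and `manifest`.
#' @export
runDepthComparison <- function(config = depthComparisonConfig()) {
    truth <- simulateTruth(config)
    regions <- config@genes
    mhcGenes <- familyGenes(regions, c("MHC_I", "MHC_II_A", "MHC_II_B"))
    tlrGenes <- familyGenes(regions, "TLR")
    te <- simulateCalls(truth, platform = "enrichment",
                        seed = config@seed + 1000L)
    teSets <- list(
        MHC = filterCascade(subsetGenes(te, mhcGenes), "MHC"),
        TLR = filterCascade(subsetGenes(te, tlrGenes), "TLR"))
    rows <- list(); cnvRows <- list()
    for (i in seq_along(config@targetDepths)) {
        d <- config@targetDepths[i]
        wgs <- simulateCalls(truth, depth = d, platform = "wgs",
                             seed = config@seed + 2000L + i)
        for (fam in c("MHC", "TLR")) {
            genes <- if (fam == "MHC") mhcGenes else tlrGenes
            wgsF <- filterCascade(subsetGenes(wgs, genes), fam,
                                  targetDepth = d)
            pair <- suppressWarnings(alignSites(teSets[[fam]], wgsF))
            if (nrow(pair$te) == 0L) next
            met <- concordanceMetrics(concordanceTable(pair))
            rows[[length(rows) + 1L]] <- data.frame(
                depth = d, family = fam, n_shared_sites = nrow(pair$te),
                t(met))
        }
        cov <- simulateCoverage(truth, d, seed = config@seed + 3000L + i)
        calls <- copyNumberCalls(cov, regions)
        trueCp <- truth@copyNumber[cbind(calls$gene_id, calls$individual)]
        del <- trueCp == 0
        cnvRows[[length(cnvRows) + 1L]] <- data.frame(
            depth = d,
            copy_class_accuracy = mean(calls$copy_class == trueCp),
            hemizygote_accuracy = if (any(trueCp == 1))
                mean(calls$copy_class[trueCp == 1] == 1) else NA_real_,
            deletion_detection = if (any(del))
                mean(calls$copy_class[del] == 0) else NA_real_)
    }
    conc <- do.call(rbind, rows)
    cnv <- do.call(rbind, cnvRows)
    list(concordance = conc, cnv = cnv,
         manifest = runManifest(config, list(concordance = conc, cnv = cnv)))
}

#' Range-wide diversity pipeline
#'
#' Simulates a structured population, genotypes it at the survey depth
#' (30x), filters the MHC call set, and derives the survey outputs: a
#' per-gene diversity table, pairwise Weir-Cockerham F_ST between regions,
#' ordinations (separately for single-copy and CNV genes), a Mantel test of
#' isolation by distance, copy-number calls, and supertype clustering of
#' the class I alleles.
#'
#' @param config a [SimConfig-class]; defaults to
#'   [diversitySurveyConfig()].
#' @param depth survey sequencing depth.
#' @param supertypeReplicates BIC replicates for the supertype k selection.
#' @return list with `geneTable`, `aggregate`, `fst`, `pcoa`, `mantel`,
#'   `cnv`, `supertypes` and `manifest`.
#' @export
runDiversitySurvey <- function(config = diversitySurveyConfig(),
                               depth = 30, supertypeReplicates = 20) {
    truth <- simulateTruth(config)
    regions <- config@genes
    regionOf <- stats::setNames(truth@individuals$region,
                                truth@individuals$id)
    mhcGenes <- familyGenes(regions, c("MHC_I", "MHC_II_A", "MHC_II_B"))
    calls <- simulateCalls(truth, depth = depth, platform = "wgs",
                           seed = config@seed + 1L)
    filtered <- filterCascade(subsetGenes(calls, mhcGenes), "MHC",
                              targetDepth = depth)
    # per-gene diversity from the simulator's phased haplotypes
    famOf <- stats::setNames(mcols(regions)$family, mcols(regions)$gene_id)
    tables <- list(); statRows <- list()
    for (g in mhcGenes) {
        haps <- truthHaplotypes(truth, g)
        if (length(haps@sequences) == 0L) next
        stat <- geneDiversityStats(haps, regionOf)
        stat$class <- if (famOf[[g]] == "MHC_I") "I" else "II"
        statRows[[g]] <- stat
        tables[[g]] <- filterRareAlleles(assignAlleles(haps, regionOf))
    }
    geneTable <- do.call(rbind, statRows)
    rownames(geneTable) <- NULL
    fst <- pairwiseFst(filtered)
    # ordinations: single-copy vs CNV gene partitions
    cnvGenes <- names(config@copyNumberProbs)
    singleGenes <- setdiff(mhcGenes, cnvGenes)
    pcoaOf <- function(genes) {
        dos <- snpDosage(filtered, genes)
        if (ncol(dos) < 2L) return(NULL)
        runPCoA(geneticDistance(dos), k = 2)
    }
    pcoa <- list(single_copy = pcoaOf(singleGenes), cnv = pcoaOf(cnvGenes))
    mant <- mantelTest(geneticDistance(snpDosage(filtered)),
                       geographicDistance(truth), nPerm = 499,
                       seed = config@seed + 2L)
    cov <- simulateCoverage(truth, depth, seed = config@seed + 3L)
    cnvCalls <- copyNumberCalls(cov, regions)
    cnvFlag <- callCnvGenes(cnvCalls)
    # supertype clustering of pooled class I alleles
    classI <- intersect(familyGenes(regions, "MHC_I"), names(tables))
    prot <- list()
    for (g in classI) {
        aa <- suppressWarnings(Biostrings::translate(
            tables[[g]]@sequences, if.fuzzy.codon = "solve"))
        prot[[g]] <- stats::setNames(
            as.character(aa),
            paste(g, names(tables[[g]]@sequences), sep = ":"))
    }
    prot <- unlist(prot, use.names = TRUE)
    names(prot) <- sub("^[^.]*\\.", "", names(prot))
    model <- clusterSupertypes(prot, config@pbrPositions,
                               nReplicates = supertypeReplicates,
                               seed = config@seed + 4L)
    supertypes <- suppressWarnings(
        assignSupertypes(model, tables[classI], skipMissing = TRUE))
    out <- list(geneTable = geneTable,
                aggregate = aggregateGeneTable(geneTable),
                fst = fst, pcoa = pcoa, mantel = mant,
                cnv = list(calls = cnvCalls, genes = cnvFlag),
                supertypes = c(supertypes, list(model = model)))
    out$manifest <- runManifest(config, out)
    out
}

## lightweight run manifest: seed plus row counts per stage output
runManifest <- function(config, outputs) {
    count <- function(x) {
        if (is.data.frame(x)) nrow(x)
        else if (is.matrix(x)) nrow(x)
        else if (is.list(x)) sum(vapply(x, count, numeric(1)))
        else length(x)
    }
    list(seed = config@seed,
         n_individuals = config@nRegions * config@nIndividuals,
         stages = vapply(outputs, count, numeric(1)))
}

#' Simulate allele encodings from latent supertype centroids
#'
#' Draws `k` cluster centroids in z-descriptor space and scatters alleles
#' around them, giving a ground-truth clustering for supertype-recovery
#' checks.
#'
#' @param k number of latent supertypes.
#' @param nPerCluster alleles per supertype.
#' @param nPositions peptide-binding positions (5 descriptors each).
#' @param spread centroid scale (between-cluster).
#' @param noise within-cluster standard deviation.
#' @param seed RNG seed.
#' @return list with `z` (matrix alleles x features) and `labels`.
#' @export
simulateZAlleles <- function(k, nPerCluster = 10, nPositions = 10,
                             spread = 4, noise = 0.3, seed = 1L) {
    set.seed(seed)
    p <- nPositions * 5L
    centroids <- matrix(stats::rnorm(k * p, 0, spread), k, p)
    z <- do.call(rbind, lapply(seq_len(k), function(i)
        sweep(matrix(stats::rnorm(nPerCluster * p, 0, noise),
                     nPerCluster, p), 2, centroids[i, ], "+")))
    rownames(z) <- paste0("allele", seq_len(nrow(z)))
    list(z = z, labels = rep(seq_len(k), each = nPerCluster))
}
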