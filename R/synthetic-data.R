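#' Synthetic exon-level gene set
#'
#' Builds a default gene panel emulating a multicopy immune gene family
#' profiled against conserved single-copy references: six MHC class I, four
#' class II and eight single-copy TLR genes laid out along one contig. MHC
#' genes are split into two exons (with the codon phase of the second exon
#' recorded in `frame`); one class I gene sits on the minus strand to
#' exercise strand handling. Coding lengths (810-2100 bp) are in the range
#' of real immune-gene coding sequences and are multiples of 3 so
#' haplotypes translate cleanly.
#'
#' @return exon `GRanges` as from [geneRegions()].
#' @export
syntheticGeneRegions <- function() {
    mhc1 <- c("UA", "UB", "UC", "UE", "UG", "UH")
    mhc2 <- c("DAB2", "DBA2", "DCA", "DMA")
    tlr <- paste0("TLR", 1:8)
    rows <- list()
    base <- 10000L
    for (i in seq_along(mhc1)) {
        g <- mhc1[i]
        st <- as.character(ifelse(g == "UE", "-", "+"))
        s1 <- base + (i - 1L) * 10000L
        if (g == "UE") {  # single exon, minus strand
            rows[[length(rows) + 1L]] <- data.frame(
                chrom = "chr1", start = s1, end = s1 + 1079L, gene_id = g,
                family = "MHC_I", single_copy = FALSE, strand = st, frame = 0L)
        } else {          # 540 + 540 bp exons; exon 2 starts in phase 0
            rows[[length(rows) + 1L]] <- data.frame(
                chrom = "chr1", start = s1, end = s1 + 539L, gene_id = g,
                family = "MHC_I", single_copy = FALSE, strand = st, frame = 0L)
            rows[[length(rows) + 1L]] <- data.frame(
                chrom = "chr1", start = s1 + 2000L, end = s1 + 2539L,
                gene_id = g, family = "MHC_I", single_copy = FALSE,
                strand = st, frame = 0L)
        }
    }
    for (i in seq_along(mhc2)) {
        g <- mhc2[i]
        s1 <- base + 80000L + (i - 1L) * 10000L
        rows[[length(rows) + 1L]] <- data.frame(
            chrom = "chr1", start = s1, end = s1 + 809L, gene_id = g,
            family = ifelse(grepl("^D.A", g), "MHC_II_A", "MHC_II_B"),
            single_copy = FALSE, strand = "+", frame = 0L)
    }
    for (i in seq_along(tlr)) {
        s1 <- base + 160000L + (i - 1L) * 10000L
        rows[[length(rows) + 1L]] <- data.frame(
            chrom = "chr1", start = s1, end = s1 + 2099L, gene_id = tlr[i],
            family = "TLR", single_copy = TRUE, strand = "+", frame = 0L)
    }
    geneRegions(do.call(rbind, rows))
}

## Default copy-number genotype distributions per region (rows) over 0..6
## copies (columns): a duplicating gene (UA, up to 6 copies), a gene deleted
## in the two trailing regions (UB), a hemizygous-everywhere gene (UG), a
## full-spectrum CNV gene (DBA2, complete deletion through duplication) and
## a mildly duplicating class II gene (DAB2).
defaultCopyNumberProbs <- function(nRegions) {
    row <- function(p) matrix(rep(p, nRegions), nRegions, 7, byrow = TRUE)
    ua <- row(c(0, 0, .5, .25, .15, .07, .03))
    ub <- row(c(0, .05, .95, 0, 0, 0, 0))
    if (nRegions >= 2) {
        tail <- max(1L, nRegions - 1L):nRegions
        ub[tail, ] <- matrix(rep(c(.4, .4, .2, 0, 0, 0, 0), length(tail)),
                             length(tail), 7, byrow = TRUE)
    }
    ug <- row(c(0, .3, .7, 0, 0, 0, 0))
    dba2 <- row(c(.15, .2, .55, .1, 0, 0, 0))
    dab2 <- row(c(0, 0, .7, .2, .1, 0, 0))
    list(UA = ua, UB = ub, UG = ug, DBA2 = dba2, DAB2 = dab2)
}

#' Build a simulator configuration
#'
#' Defaults reflect the study design the package emulates: a depth ladder of
#' 0.5, 1, 2, 5, 10, 15, 20 and 30x against a 264x reference (target
#' enrichment) call set, 2 x 150 bp style reads, a two-parameter genotype
#' caller (two reads minimum, 1% per-read error), and seven regions along a
#' geographic gradient.
#'
#' @param nRegions,nIndividuals regions and individuals per region.
#' @param genes exon `GRanges`; defaults to [syntheticGeneRegions()].
#' @param allelePoolSize alleles per gene pool.
#' @param mutationDensity expected polymorphic sites per CDS bp.
#' @param differentiation approximate expected F_ST between neighbouring
#'   regions, in `[0, 1)`.
#' @param isolationByDistance if `TRUE` regional allele frequencies follow a
#'   Dirichlet chain along the region order (differentiation accumulates
#'   with distance); if `FALSE` regions are exchangeable.
#' @param copyNumberProbs named list of per-gene `nRegions` x 7 copy-number
#'   probability matrices; defaults to [defaultCopyNumberProbs] applied to
#'   the CNV-capable genes of the default panel. Use `list()` for an
#'   all-single-copy panel.
#' @param targetDepths,enrichmentDepth,readLength,minReads,perReadError see
#'   [SimConfig-class].
#' @param annotationParams list with `qualFailRate`, `mqFailRate`,
#'   `rankSumOutlierRate`: the fraction of simulated sites drawn beyond each
#'   hard-filter threshold.
#' @param pbrPositions codon positions treated as peptide-binding residues
#'   for supertype clustering (default: 24 positions spread over the first
#'   180 codons).
#' @param seed base RNG seed.
#' @return a [SimConfig-class].
#' @export
simConfig <- function(nRegions = 7L, nIndividuals = 10L,
                      genes = syntheticGeneRegions(),
                      allelePoolSize = 8L, mutationDensity = 0.02,
                      differentiation = 0.1, isolationByDistance = TRUE,
                      copyNumberProbs = NULL,
                      targetDepths = c(0.5, 1, 2, 5, 10, 15, 20, 30),
                      enrichmentDepth = 264, readLength = 150,
                      minReads = 2L, perReadError = 0.01,
                      annotationParams = list(qualFailRate = 0.05,
                                              mqFailRate = 0.05,
                                              rankSumOutlierRate = 0.03),
                      pbrPositions = as.integer(round(seq(3, 178, length.out = 24))),
                      seed = 1L) {
    if (is.null(copyNumberProbs)) {
        pool <- defaultCopyNumberProbs(nRegions)
        copyNumberProbs <- pool[intersect(names(pool),
                                          unique(mcols(genes)$gene_id))]
    }
    new("SimConfig", nRegions = as.integer(nRegions),
        nIndividuals = as.integer(nIndividuals), genes = genes,
        allelePoolSize = as.integer(allelePoolSize),
        mutationDensity = mutationDensity,
        differentiation = differentiation,
        isolationByDistance = isolationByDistance,
        copyNumberProbs = copyNumberProbs, targetDepths = targetDepths,
        enrichmentDepth = enrichmentDepth, readLength = readLength,
        minReads = as.integer(minReads), perReadError = perReadError,
        annotationParams = annotationParams,
        pbrPositions = as.integer(pbrPositions), seed = as.integer(seed))
}

rdirichlet1 <- function(alpha) {
    x <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
    if (sum(x) == 0) x[which.max(alpha)] <- 1
    x / sum(x)
}

## genomic positions of a gene's CDS bases in CDS order (5'->3')
cdsGenomicPositions <- function(exons) {
    pos <- unlist(lapply(seq_along(exons),
                         function(i) seq(start(exons)[i], end(exons)[i])))
    if (as.character(strand(exons)[1]) == "-") pos <- rev(pos)
    pos
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' Simulate the ground truth of a structured diploid population
#'
#' Draws, per gene, an ancestral coding sequence, Poisson-placed polymorphic
#' sites and an allele pool; regional allele frequencies from a Dirichlet
#' model whose concentration is set by the configuration's `differentiation`
#' parameter; per-individual copy numbers from the configured distributions
#' (single-copy reference genes are always two copies); and two phased
#' haplotypes per individual (one when hemizygous, none for complete
#' deletions), from which the true genotype at every site follows.
#' Synonymous/non-synonymous status of sites is not assigned: it emerges
#' from the genetic code when allele sequences are translated.
#'
#' @param config a [SimConfig-class].
#' @return a [PopulationTruth-class]. Reproducible: the same config (same
#'   seed) gives an identical truth set.
#' @export
simulateTruth <- function(config) {
    stopifnot(is(config, "SimConfig"))
    validObject(config)
    set.seed(config@seed)
    genes <- unique(mcols(config@genes)$gene_id)
    nR <- config@nRegions; nI <- config@nIndividuals
    n <- nR * nI
    regions <- paste0("R", rep(seq_len(nR), each = nI))
    ids <- sprintf("%s_I%02d", regions, rep(seq_len(nI), nR))
    # regions strung along a geographic gradient (north-east to south-west)
    rlon <- 153 - 1.1 * (seq_len(nR) - 1)
    rlat <- -19 - 2.3 * (seq_len(nR) - 1)
    individuals <- DataFrame(
        id = ids, region = regions,
        lon = rlon[rep(seq_len(nR), each = nI)] + stats::rnorm(n, 0, 0.15),
        lat = rlat[rep(seq_len(nR), each = nI)] + stats::rnorm(n, 0, 0.15),
        row.names = ids)

    d <- config@differentiation
    kappa <- if (d > 0) (1 - d) / d else Inf
    alleleSeqs <- list(); alleleFreqs <- list(); haplotypes <- list()
    copyNumber <- matrix(2L, length(genes), n,
                         dimnames = list(genes, ids))
    siteRows <- list(); gtRows <- list()
    for (g in genes) {
        ex <- config@genes[mcols(config@genes)$gene_id == g]
        L <- sum(width(ex))
        # ancestral CDS drawn codon-wise from the 61 sense codons, so the
        # reading frame is open; point mutations may still create stops
        sense <- names(GENETIC_CODE)[GENETIC_CODE != "*"]
        anc <- unlist(strsplit(sample(sense, L / 3, replace = TRUE), ""))
        m <- stats::rpois(1, L * config@mutationDensity)
        sitePos <- sort(sample.int(L, min(m, L)))
        altBase <- vapply(sitePos, function(p)
            sample(setdiff(c("A", "C", "G", "T"), anc[p]), 1), character(1))
        A <- config@allelePoolSize
        hapMat <- matrix(FALSE, A, length(sitePos))  # allele x site: carries alt?
        if (length(sitePos) && A > 1) {
            for (a in 2:A) {
                for (tries in 1:50) {
                    cand <- stats::runif(length(sitePos)) < 0.35
                    dup <- any(vapply(seq_len(a - 1), function(b)
                        all(hapMat[b, ] == cand), logical(1)))
                    if (!dup || tries == 50) { hapMat[a, ] <- cand; break }
                }
            }
        }
        seqs <- apply(hapMat, 1, function(carry) {
            s <- anc; s[sitePos[carry]] <- altBase[carry]
            paste(s, collapse = "")
        })
        pool <- DNAStringSet(seqs)
        names(pool) <- paste0("A", seq_len(A))
        alleleSeqs[[g]] <- pool
        # regional frequencies: Dirichlet chain (or exchangeable draws)
        p0 <- rdirichlet1(rep(1.5, A))
        fr <- matrix(0, A, nR, dimnames = list(names(pool),
                                               paste0("R", seq_len(nR))))
        prev <- p0
        for (r in seq_len(nR)) {
            fr[, r] <- if (!is.finite(kappa)) p0
                       else rdirichlet1(kappa * pmax(prev, 1e-6))
            if (config@isolationByDistance) prev <- fr[, r]
        }
        alleleFreqs[[g]] <- fr
        # copy numbers
        single <- mcols(ex)$single_copy[1]
        if (!single && g %in% names(config@copyNumberProbs)) {
            pm <- config@copyNumberProbs[[g]]
            copyNumber[g, ] <- vapply(seq_len(n), function(i) {
                r <- as.integer(sub("R", "", regions[i]))
                sample(0:6, 1, prob = pm[r, ])
            }, integer(1))
        }
        # phased haplotypes: allele indices per individual
        hm <- matrix(NA_integer_, 2, n, dimnames = list(NULL, ids))
        for (i in seq_len(n)) {
            cp <- copyNumber[g, i]
            if (cp >= 1)
                hm[1, i] <- sample.int(A, 1, prob = fr[, regions[i] ==
                                                paste0("R", seq_len(nR))])
            if (cp >= 2)
                hm[2, i] <- sample.int(A, 1, prob = fr[, regions[i] ==
                                                paste0("R", seq_len(nR))])
        }
        haplotypes[[g]] <- hm
        # true genotypes per site
        if (length(sitePos)) {
            gpos <- cdsGenomicPositions(ex)
            minus <- as.character(strand(ex)[1]) == "-"
            gt <- matrix(NA_integer_, length(sitePos), n)
            for (s in seq_along(sitePos)) {
                carry <- hapMat[, s]
                a1 <- carry[hm[1, ]]; a2 <- carry[hm[2, ]]
                gt[s, ] <- ifelse(is.na(a1), NA_integer_,
                           ifelse(is.na(a2), 2L * a1, a1 + a2))
            }
            refG <- anc[sitePos]; altG <- altBase
            if (minus) { refG <- COMPLEMENT[refG]; altG <- COMPLEMENT[altG] }
            sr <- GRanges("chr1", IRanges(gpos[sitePos], width = 1L))
            mcols(sr)$ref <- unname(refG)
            mcols(sr)$alt <- unname(altG)
            mcols(sr)$gene_id <- g
            mcols(sr)$cdsPos <- sitePos
            siteRows[[g]] <- sr
            gtRows[[g]] <- gt
        }
    }
    sites <- if (length(siteRows)) do.call(c, unname(siteRows))
             else GRanges()
    trueGenotypes <- if (length(gtRows)) do.call(rbind, gtRows)
                     else matrix(NA_integer_, 0, n)
    ord <- order(start(sites))
    sites <- sites[ord]
    trueGenotypes <- trueGenotypes[ord, , drop = FALSE]
    colnames(trueGenotypes) <- ids
    new("PopulationTruth", config = config, individuals = individuals,
        alleleSeqs = SimpleList(alleleSeqs), alleleFreqs = alleleFreqs,
        copyNumber = copyNumber, haplotypes = haplotypes, sites = sites,
        trueGenotypes = trueGenotypes)
}

#' Simulate per-gene coverage summaries at a target depth
#'
#' Read counts are Poisson with mean `depth x (copies / 2) x gene length /
#' read length`, so coverage scales linearly with true copy number and
#' single-copy reference genes sit at the nominal depth. Bases covered
#' follow the usual Poisson-coverage approximation.
#'
#' @param truth a [PopulationTruth-class].
#' @param depth target sequencing depth (x).
#' @param seed RNG seed.
#' @param mismapRate additional Poisson reads per kb assigned to deleted
#'   genes (default 0: complete deletions get zero reads).
#' @return a coverage summary data.frame (`gene_id`, `individual`,
#'   `read_count`, `bases_covered`, `gene_length_bp`).
#' @export
simulateCoverage <- function(truth, depth, seed = truth@config@seed,
                             mismapRate = 0) {
    stopifnot(depth > 0)
    set.seed(seed)
    cfg <- truth@config
    lens <- geneLengths(cfg@genes)
    genes <- rownames(truth@copyNumber)
    ids <- truth@individuals$id
    grid <- expand.grid(gene_id = genes, individual = ids,
                        stringsAsFactors = FALSE)
    cp <- truth@copyNumber[cbind(grid$gene_id, grid$individual)]
    len <- lens[grid$gene_id]
    lambda <- depth * (cp / 2) * len / cfg@readLength +
        mismapRate * len / 1000
    reads <- stats::rpois(nrow(grid), lambda)
    covered <- round(len * (1 - exp(-reads * cfg@readLength / len)))
    data.frame(gene_id = grid$gene_id, individual = grid$individual,
               read_count = reads, bases_covered = pmin(covered, len),
               gene_length_bp = unname(len))
}

#' Simulate a multi-sample call set at a target depth
#'
#' Emulates the output of an external joint-genotyping pipeline with a
#' two-parameter caller: per-site per-individual depth is Poisson at the
#' target (scaled by the individual's copy number at the gene), each read
#' reports the wrong allele with probability `perReadError`, genotypes are
#' only emitted when at least `minReads` reads are present, and a
#' heterozygote is called whenever both alleles are observed (so a true het
#' is miscalled homozygous with probability `2 * 0.5^d` at depth `d`,
#' error-free). Site annotations (QUAL, MQ, MQRankSum, ReadPosRankSum) are
#' drawn from the configured distributions so the hard-filter cascade has
#' failing sites to remove. Only sites at which some individual carries an
#' alternate allele call are retained (a site must be discovered to appear
#' in a call set).
#'
#' @param truth a [PopulationTruth-class].
#' @param depth target depth; defaults to the configured enrichment depth
#'   when `platform = "enrichment"`.
#' @param platform `"wgs"` or `"enrichment"` (recorded in metadata).
#' @param seed RNG seed.
#' @return a [GenotypeExperiment-class] with `metadata()` fields `platform`
#'   and `targetDepth`.
#' @export
simulateCalls <- function(truth, depth = NULL,
                          platform = c("wgs", "enrichment"),
                          seed = truth@config@seed) {
    platform <- match.arg(platform)
    cfg <- truth@config
    if (is.null(depth))
        depth <- if (platform == "enrichment") cfg@enrichmentDepth
                 else stop("depth required for platform 'wgs'")
    stopifnot(depth > 0)
    set.seed(seed)
    sites <- truth@sites
    nS <- length(sites); nInd <- nrow(truth@individuals)
    ids <- truth@individuals$id
    gt <- truth@trueGenotypes
    cp <- truth@copyNumber[mcols(sites)$gene_id, , drop = FALSE]
    lambda <- depth * cp / 2
    d <- matrix(stats::rpois(nS * nInd, lambda), nS, nInd)
    q <- gt / 2  # true alt-allele fraction; NA for deleted genes
    q[is.na(q)] <- 0
    altTrue <- matrix(stats::rbinom(nS * nInd, d, q), nS, nInd)
    e <- cfg@perReadError
    altObs <- matrix(stats::rbinom(nS * nInd, altTrue, 1 - e), nS, nInd) +
        matrix(stats::rbinom(nS * nInd, d - altTrue, e), nS, nInd)
    refObs <- d - altObs
    # maximum-likelihood genotype under the binomial read model with
    # alt-read fraction e (hom-ref), 0.5 (het) or 1 - e (hom-alt); with all
    # reads on one allele the homozygote wins, so an error-free true het is
    # miscalled homozygous with probability 2 * 0.5^d
    eML <- max(e, 1e-12)
    l0 <- altObs * log(eML) + refObs * log(1 - eML)
    l1 <- d * log(0.5)
    l2 <- altObs * log(1 - eML) + refObs * log(eML)
    best <- pmax(l0, l1, l2)
    calls <- matrix(NA_integer_, nS, nInd)
    called <- d >= cfg@minReads & !is.na(truth@trueGenotypes)
    calls[called & l2 >= best] <- 2L
    calls[called & l1 >= best] <- 1L
    calls[called & l0 >= best] <- 0L
    # site annotations: mostly passing, a configured fraction failing
    ap <- cfg@annotationParams
    qual <- ifelse(stats::runif(nS) < ap$qualFailRate,
                   stats::runif(nS, 5, 79.9),
                   80 + stats::rgamma(nS, shape = 4, scale = 80))
    mq <- ifelse(stats::runif(nS) < ap$mqFailRate,
                 stats::runif(nS, 10, 39.9), stats::runif(nS, 40, 60))
    rankSum <- function(bound) {
        x <- pmin(pmax(stats::rnorm(nS, 0, bound / 4), -bound + 0.01),
                  bound - 0.01)
        out <- stats::runif(nS) < ap$rankSumOutlierRate
        x[out] <- sample(c(-1, 1), sum(out), TRUE) *
            stats::runif(sum(out), bound + 0.01, bound + 8)
        x
    }
    rr <- granges(sites)
    mcols(rr)$ref <- mcols(sites)$ref
    mcols(rr)$alt <- mcols(sites)$alt
    mcols(rr)$qual <- qual
    mcols(rr)$mq <- mq
    mcols(rr)$mqRankSum <- rankSum(12.5)
    mcols(rr)$readPosRankSum <- rankSum(8)
    mcols(rr)$gene_id <- mcols(sites)$gene_id
    mcols(rr)$cdsPos <- mcols(sites)$cdsPos
    ge <- GenotypeExperiment(calls, depth = d, refDepth = refObs,
                             altDepth = altObs, rowRanges = rr,
                             individuals = ids,
                             region = truth@individuals$region)
    discovered <- rowSums(genotypeCalls(ge) > 0, na.rm = TRUE) > 0
    ge <- ge[discovered, ]
    metadata(ge)$platform <- platform
    metadata(ge)$targetDepth <- depth
    ge
}

#' Phased haplotypes implied by the simulation truth
#'
#' The simulator stands in for statistical phasing: individuals with two or
#' more gene copies contribute their two phased sequences, hemizygous
#' individuals one, and complete deletions none.
#'
#' @param truth a [PopulationTruth-class].
#' @param gene gene id.
#' @return a [HaplotypeSet-class].
#' @export
truthHaplotypes <- function(truth, gene) {
    hm <- truth@haplotypes[[gene]]
    if (is.null(hm)) stop("unknown gene: ", gene)
    pool <- truth@alleleSeqs[[gene]]
    ids <- truth@individuals$id
    keep1 <- !is.na(hm[1, ]); keep2 <- !is.na(hm[2, ])
    seqs <- c(pool[hm[1, keep1]], pool[hm[2, keep2]])
    HaplotypeSet(gene, seqs,
                 individual = c(ids[keep1], ids[keep2]),
                 hapIndex = c(rep(1L, sum(keep1)), rep(2L, sum(keep2))))
}

#' Great-circle distances between simulated individuals
#'
#' @param truth a [PopulationTruth-class].
#' @return a `dist` of pairwise haversine distances in km.
#' @export
geographicDistance <- function(truth) {
    xy <- as.matrix(as.data.frame(truth@individuals[, c("lon", "lat")]))
    m <- geosphere::distm(xy, fun = geosphere::distHaversine) / 1000
    rownames(m) <- colnames(m) <- truth@individuals$id
    stats::as.dist(m)
}
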