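#' Read genotypes from a multi-sample VCF restricted to gene exons
#'
#' Parses a VCF 4.x file with [VariantAnnotation::readVcf], keeps only
#' biallelic SNPs whose position falls inside an exon of `regions`, and
#' returns a [GenotypeExperiment-class]. GT is mapped to 0/1/2/NA; DP and AD
#' populate the depth assays when present. Records on contigs absent from
#' `regions` trigger a warning and are skipped.
#'
#' @param path VCF file (plain text or bgzipped).
#' @param regions exon `GRanges` from [geneRegions()].
#' @param region character vector of region labels per sample, or a named
#'   vector/`NULL` (all samples labelled `"R1"`).
#' @return a [GenotypeExperiment-class].
#' @export
readVcfGenotypes <- function(path, regions, region = NULL) {
    vcf <- tryCatch(
        VariantAnnotation::readVcf(path, genome = "unknown"),
        error = function(e) stop("malformed VCF '", path, "': ",
                                 conditionMessage(e), call. = FALSE))
    rr <- rowRanges(vcf)
    known <- unique(as.character(seqnames(regions)))
    bad <- !(as.character(seqnames(rr)) %in% known)
    if (any(bad))
        warning(sum(bad), " record(s) on contigs absent from the region ",
                "table were skipped")
    alt <- VariantAnnotation::alt(vcf)
    ref <- VariantAnnotation::ref(vcf)
    biallelic <- S4Vectors::elementNROWS(alt) == 1L
    snp <- biallelic & width(ref) == 1L &
        vapply(as.list(alt), function(a)
            length(a) == 1L && nchar(as.character(a[[1]])) == 1L, logical(1))
    ov <- findOverlaps(rr, regions, ignore.strand = TRUE)
    exonic <- seq_along(rr) %in% S4Vectors::queryHits(ov)
    keep <- which(!bad & snp & exonic)
    vcf <- vcf[keep]
    rr <- rowRanges(vcf)
    alt <- VariantAnnotation::alt(vcf)
    ref <- VariantAnnotation::ref(vcf)
    ov <- findOverlaps(rr, regions, ignore.strand = TRUE)
    gene <- rep(NA_character_, length(rr))
    gene[S4Vectors::queryHits(ov)] <-
        mcols(regions)$gene_id[S4Vectors::subjectHits(ov)]

    gt <- VariantAnnotation::geno(vcf)$GT
    calls <- matrix(NA_integer_, nrow(gt), ncol(gt))
    calls[gt %in% c("0/0", "0|0")] <- 0L
    calls[gt %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
    calls[gt %in% c("1/1", "1|1")] <- 2L
    gn <- VariantAnnotation::geno(vcf)
    dp <- if ("DP" %in% names(gn)) {
        m <- gn$DP; storage.mode(m) <- "integer"; m
    } else NULL
    refd <- altd <- NULL
    if ("AD" %in% names(gn)) {
        ad <- gn$AD
        pick <- function(i) {
            m <- apply(ad, c(1, 2), function(v) {
                v <- v[[1]]
                if (length(v) >= i && !is.na(v[i])) as.integer(v[i])
                else NA_integer_
            })
            matrix(as.integer(m), nrow(gt), ncol(gt))
        }
        refd <- pick(1); altd <- pick(2)
    }
    info <- VariantAnnotation::info(vcf)
    site <- GRanges(seqnames(rr), IRanges(start(rr), width = 1L))
    mcols(site)$ref <- as.character(ref)
    mcols(site)$alt <- vapply(as.list(alt), function(a)
        as.character(a[[1]]), character(1))
    mcols(site)$qual <- VariantAnnotation::fixed(vcf)$QUAL
    for (key in c("MQ", "MQRankSum", "ReadPosRankSum")) {
        slot <- c(MQ = "mq", MQRankSum = "mqRankSum",
                  ReadPosRankSum = "readPosRankSum")[[key]]
        mcols(site)[[slot]] <- if (key %in% names(info))
            as.numeric(info[[key]]) else NA_real_
    }
    mcols(site)$gene_id <- gene
    samples <- colnames(gt)
    if (is.null(region)) region <- rep("R1", length(samples))
    if (!is.null(names(region))) region <- unname(region[samples])
    GenotypeExperiment(calls, depth = dp, refDepth = refd, altDepth = altd,
                       rowRanges = site, individuals = samples,
                       region = region)
}

#' Write a GenotypeExperiment as VCF 4.2
#'
#' Emits GT/DP/AD per sample and the site annotations (QUAL and the INFO
#' keys MQ, MQRankSum, ReadPosRankSum) so that
#' `readVcfGenotypes(writeVcfGenotypes(x))` round-trips genotype states,
#' positions and annotations.
#'
#' @param x a [GenotypeExperiment-class].
#' @param path output path (`.vcf`).
#' @return `path`, invisibly.
#' @export
writeVcfGenotypes <- function(x, path) {
    n <- nrow(x); m <- ncol(x)
    si <- mcols(rowRanges(x))
    rr <- GRanges(seqnames(rowRanges(x)),
                  IRanges(start(rowRanges(x)), width = 1L))
    names(rr) <- paste0("site", seq_len(max(n, 0L)))
    gtmap <- c("0/0", "0/1", "1/1")
    cl <- genotypeCalls(x)
    gt <- matrix("./.", n, m, dimnames = list(names(rr), colnames(x)))
    gt[!is.na(cl)] <- gtmap[cl[!is.na(cl)] + 1L]
    dp <- genotypeDepth(x); dp[is.na(dp)] <- 0L
    rd <- refDepth(x); ad <- altDepth(x)
    rd[is.na(rd)] <- 0L; ad[is.na(ad)] <- 0L
    adl <- matrix(mapply(function(r, a) c(r, a), rd, ad, SIMPLIFY = FALSE),
                  n, m, dimnames = dimnames(gt))
    dimnames(dp) <- dimnames(gt)
    hdr <- VariantAnnotation::VCFHeader(samples = colnames(x))
    VariantAnnotation::meta(hdr) <- IRanges::DataFrameList(
        fileformat = DataFrame(Value = "VCFv4.2", row.names = "fileformat"))
    VariantAnnotation::geno(hdr) <- DataFrame(
        Number = c("1", "1", "R"), Type = c("String", "Integer", "Integer"),
        Description = c("Genotype", "Read depth", "Allele depths"),
        row.names = c("GT", "DP", "AD"))
    VariantAnnotation::info(hdr) <- DataFrame(
        Number = rep("1", 3), Type = rep("Float", 3),
        Description = c("Mapping quality", "Mapping-quality rank sum",
                        "Read-position rank sum"),
        row.names = c("MQ", "MQRankSum", "ReadPosRankSum"))
    num_or_na <- function(v) if (is.null(v)) rep(NA_real_, n) else as.numeric(v)
    fx <- DataFrame(
        REF = DNAStringSet(si$ref),
        ALT = Biostrings::DNAStringSetList(as.list(si$alt)),
        QUAL = num_or_na(si$qual), FILTER = rep(".", n))
    info <- DataFrame(MQ = num_or_na(si$mq),
                      MQRankSum = num_or_na(si$mqRankSum),
                      ReadPosRankSum = num_or_na(si$readPosRankSum))
    vcf <- VariantAnnotation::VCF(
        rowRanges = rr,
        colData = DataFrame(Samples = seq_len(m), row.names = colnames(x)),
        exptData = list(header = hdr), fixed = fx, info = info,
        geno = SimpleList(GT = gt, DP = dp, AD = adl))
    VariantAnnotation::writeVcf(vcf, path)
    invisible(path)
}

#' Read a per-gene per-individual coverage table
#'
#' Tab-separated with header `gene_id, individual, read_count,
#' bases_covered, gene_length_bp` (the columns a `samtools coverage` style
#' summary provides). Duplicate (gene, individual) rows and negative counts
#' are rejected; `bases_covered` may not exceed `gene_length_bp`.
#'
#' @param path file path.
#' @return a data.frame (\dQuote{coverage summary}) with the five columns.
#' @export
readCoverageTable <- function(path) {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("gene_id", "individual", "read_count", "bases_covered",
              "gene_length_bp")
    miss <- setdiff(need, names(tab))
    if (length(miss))
        stop("coverage table missing columns: ", paste(miss, collapse = ", "))
    if (nrow(tab) == 0L) {
        warning("empty coverage table: ", path)
        return(tab)
    }
    validateCoverage(tab)
    tab
}

validateCoverage <- function(tab) {
    if (any(tab$read_count < 0) || any(tab$bases_covered < 0))
        stop("coverage counts must be non-negative")
    if (any(tab$bases_covered > tab$gene_length_bp))
        stop("bases_covered cannot exceed gene_length_bp")
    if (anyDuplicated(tab[c("gene_id", "individual")]))
        stop("duplicate (gene_id, individual) rows in coverage table")
    invisible(tab)
}

#' Write a coverage summary table
#'
#' @param coverage data.frame as returned by [readCoverageTable()] or
#'   [simulateCoverage()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeCoverageTable <- function(coverage, path) {
    utils::write.table(coverage, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Construct a HaplotypeSet
#'
#' @param geneId gene identifier.
#' @param sequences a `DNAStringSet` (or character vector) of phased coding
#'   sequences, all the same length.
#' @param individual,hapIndex vectors parallel to `sequences`.
#' @return a [HaplotypeSet-class]; sequences containing non-ACGT characters
#'   are flagged unresolved.
#' @export
HaplotypeSet <- function(geneId, sequences, individual, hapIndex) {
    if (!is(sequences, "DNAStringSet")) sequences <- DNAStringSet(sequences)
    unresolved <- grepl("[^ACGT]", as.character(sequences))
    new("HaplotypeSet", geneId = as.character(geneId), sequences = sequences,
        individual = as.character(individual),
        hapIndex = as.integer(hapIndex), unresolved = unresolved)
}

#' Read phased haplotypes from FASTA
#'
#' FASTA headers follow the dialect `>{individual}__{gene}__{1|2}`. Within
#' each gene all sequences must have equal length; sequences with ambiguity
#' codes are flagged unresolved and individuals missing a mate haplotype are
#' reported by [incompleteIndividuals()].
#'
#' @param path FASTA file.
#' @return a named [S4Vectors::SimpleList] of [HaplotypeSet-class], one per
#'   gene.
#' @export
readHaplotypes <- function(path) {
    seqs <- Biostrings::readDNAStringSet(path)
    parts <- strsplit(names(seqs), "__", fixed = TRUE)
    if (any(lengths(parts) != 3L))
        stop("haplotype FASTA headers must follow individual__gene__{1|2}")
    ind <- vapply(parts, `[`, character(1), 1L)
    gene <- vapply(parts, `[`, character(1), 2L)
    hap <- suppressWarnings(as.integer(vapply(parts, `[`, character(1), 3L)))
    if (any(is.na(hap)) || !all(hap %in% 1:2))
        stop("haplotype index in FASTA headers must be 1 or 2")
    out <- lapply(split(seq_along(seqs), gene), function(i) {
        if (length(unique(width(seqs[i]))) != 1L)
            stop("sequences of gene ", gene[i[1]], " differ in length")
        HaplotypeSet(gene[i[1]], seqs[i], ind[i], hap[i])
    })
    SimpleList(out)
}

#' Write haplotype sets as FASTA
#'
#' @param haps a [HaplotypeSet-class] or list thereof.
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
writeHaplotypes <- function(haps, path) {
    if (is(haps, "HaplotypeSet")) haps <- list(haps)
    seqs <- do.call(c, lapply(haps, function(h) {
        s <- h@sequences
        names(s) <- paste(h@individual, h@geneId, h@hapIndex, sep = "__")
        s
    }))
    Biostrings::writeXStringSet(seqs, path)
    invisible(path)
}

#' A small ready-made GenotypeExperiment
#'
#' Convenience wrapper used in examples: simulates a two-region population
#' and returns its 30x call set.
#'
#' @param seed RNG seed.
#' @return a [GenotypeExperiment-class].
#' @export
exampleGenotypes <- function(seed = 1L) {
    cfg <- simConfig(nRegions = 2L, nIndividuals = 5L, seed = seed)
    truth <- simulateTruth(cfg)
    simulateCalls(truth, depth = 30, platform = "wgs", seed = seed + 1L)
}
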