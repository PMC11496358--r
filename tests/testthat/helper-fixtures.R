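# shared fixtures: all built in code, sized for speed

suppressPackageStartupMessages({
    library(S4Vectors)
    library(GenomicRanges)
    library(SummarizedExperiment)
    library(Biostrings)
})

# two-gene region set: a plus-strand two-exon MHC gene and a single-copy TLR
toyRegions <- function() {
    geneRegions(data.frame(
        chrom = "chr1",
        start = c(101, 301, 1001),
        end = c(200, 360, 1600),
        gene_id = c("UA", "UA", "TLR1"),
        family = c("MHC_I", "MHC_I", "TLR"),
        single_copy = c(FALSE, FALSE, TRUE),
        strand = "+",
        frame = 0))
}

# hand-built genotype matrix with controllable site annotations
toyGenotypes <- function(qual = NULL, mq = NULL, mqrs = NULL, rprs = NULL,
                         calls = NULL, depth = NULL, refd = NULL,
                         altd = NULL, pos = NULL, nInd = 3) {
    nS <- max(length(qual), length(mq), length(mqrs), length(rprs),
              length(pos), if (is.null(calls)) 0L else nrow(calls),
              if (is.null(depth)) 0L else nrow(depth), 1L)
    if (is.null(pos)) pos <- seq(110, by = 10, length.out = nS)
    fill <- function(x, default) if (is.null(x)) rep(default, nS) else x
    qual <- fill(qual, 200); mq <- fill(mq, 55)
    mqrs <- fill(mqrs, 0); rprs <- fill(rprs, 0)
    if (is.null(calls)) calls <- matrix(1L, nS, nInd)
    if (is.null(depth)) depth <- matrix(20L, nS, nInd)
    gr <- GRanges("chr1", IRanges(pos, width = 1))
    mcols(gr)$ref <- rep("A", nS)
    mcols(gr)$alt <- rep("G", nS)
    mcols(gr)$qual <- qual
    mcols(gr)$mq <- mq
    mcols(gr)$mqRankSum <- mqrs
    mcols(gr)$readPosRankSum <- rprs
    mcols(gr)$gene_id <- rep("UA", nS)
    GenotypeExperiment(calls, depth = depth, refDepth = refd,
                       altDepth = altd, rowRanges = gr,
                       individuals = paste0("K", seq_len(nInd)))
}

toyRegionsTwoRefs <- function() {
    geneRegions(data.frame(
        chrom = "chr1", start = c(101, 2001, 5001),
        end = c(1100, 4000, 7000),
        gene_id = c("UA", "TLR1", "TLR2"),
        family = c("MHC_I", "TLR", "TLR"),
        single_copy = c(FALSE, TRUE, TRUE), strand = "+", frame = 0))
}

siteKeys <- function(x) {
    si <- mcols(rowRanges(x))
    paste(start(rowRanges(x)), si$ref, si$alt, sep = ":")
}
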