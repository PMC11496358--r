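#' Exon-level gene regions for immune gene profiling
#'
#' Builds the exon-level `GRanges` the pipeline uses to restrict variant
#' sites to coding regions, attach sites to genes, and decide which genes
#' act as single-copy references for copy-number normalisation. Intervals
#' are stored 1-based closed (GRanges convention); the on-disk BED-like
#' table read by [readGeneRegions()] is 0-based half-open.
#'
#' @param table a data.frame with columns `chrom`, `start`, `end` (1-based
#'   closed exon interval), `gene_id`, `family` (one of `MHC_I`, `MHC_II_A`,
#'   `MHC_II_B`, `TLR`), `single_copy` (logical), `strand` (`+`/`-`) and
#'   `frame` (0-2 codon phase of the exon's first base).
#' @param allowNonTlrReference by default only TLR genes may be flagged
#'   single-copy references; set `TRUE` to allow others.
#' @return a `GRanges` of exons with the metadata columns above.
#' @details Invariants enforced: exons of a gene are sorted and
#'   non-overlapping; each gene's total exon length is at least one codon;
#'   `single_copy` is constant within a gene.
#' @export
#' @examples
#' df <- data.frame(chrom = "chr1", start = c(101, 301), end = c(200, 360),
#'                  gene_id = "UA", family = "MHC_I", single_copy = FALSE,
#'                  strand = "+", frame = 0)
#' geneRegions(df)
geneRegions <- function(table, allowNonTlrReference = FALSE) {
    need <- c("chrom", "start", "end", "gene_id", "family", "single_copy",
              "strand", "frame")
    miss <- setdiff(need, names(table))
    if (length(miss))
        stop("region table missing columns: ", paste(miss, collapse = ", "))
    fam_ok <- c("MHC_I", "MHC_II_A", "MHC_II_B", "TLR")
    if (!all(table$family %in% fam_ok))
        stop("family must be one of ", paste(fam_ok, collapse = ", "))
    if (!all(table$frame %in% 0:2)) stop("frame must be 0, 1 or 2")
    if (!allowNonTlrReference &&
        any(table$single_copy & table$family != "TLR"))
        stop("single-copy reference flag is restricted to TLR genes ",
             "(set allowNonTlrReference = TRUE to override)")
    gr <- GRanges(table$chrom, IRanges(table$start, table$end),
                  strand = table$strand)
    mcols(gr)$gene_id <- as.character(table$gene_id)
    mcols(gr)$family <- as.character(table$family)
    mcols(gr)$single_copy <- as.logical(table$single_copy)
    mcols(gr)$frame <- as.integer(table$frame)
    for (g in unique(mcols(gr)$gene_id)) {
        ex <- gr[mcols(gr)$gene_id == g]
        if (length(unique(mcols(ex)$single_copy)) != 1L)
            stop("single_copy flag must be constant within gene ", g)
        if (is.unsorted(start(ex)))
            stop("exons of gene ", g, " must be sorted by start")
        if (length(ex) > 1L && any(start(ex)[-1] <= end(ex)[-length(ex)]))
            stop("exons of gene ", g, " overlap")
        if (sum(width(ex)) < 3L)
            stop("gene ", g, " has total exon length < 3")
    }
    gr
}

#' Read a BED-like gene region table
#'
#' Tab-separated with header `chrom, start, end, gene_id, family,
#' single_copy, strand, frame`; `start`/`end` follow the BED convention
#' (0-based half-open) and are converted to the internal 1-based closed
#' representation.
#'
#' @param path file path.
#' @inheritParams geneRegions
#' @return a `GRanges`, as [geneRegions()].
#' @export
readGeneRegions <- function(path, allowNonTlrReference = FALSE) {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    tab$start <- tab$start + 1L  # BED 0-based half-open -> 1-based closed
    geneRegions(tab, allowNonTlrReference = allowNonTlrReference)
}

#' Write gene regions as a BED-like table
#'
#' @param regions a `GRanges` from [geneRegions()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGeneRegions <- function(regions, path) {
    df <- data.frame(chrom = as.character(seqnames(regions)),
                     start = start(regions) - 1L, end = end(regions),
                     gene_id = mcols(regions)$gene_id,
                     family = mcols(regions)$family,
                     single_copy = mcols(regions)$single_copy,
                     strand = as.character(strand(regions)),
                     frame = mcols(regions)$frame)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Total exon length per gene
#'
#' @param regions exon `GRanges` from [geneRegions()].
#' @return named integer vector of summed exon widths (bp).
#' @export
geneLengths <- function(regions) {
    vapply(split(width(regions), mcols(regions)$gene_id), sum, integer(1))
}

#' Genes flagged as single-copy references
#'
#' @param regions exon `GRanges` from [geneRegions()].
#' @return character vector of gene ids.
#' @export
referenceGenes <- function(regions) {
    unique(mcols(regions)$gene_id[mcols(regions)$single_copy])
}

## Map a genomic site to its 1-based position within a gene's CDS
## (exons concatenated 5'->3', honouring strand). Returns NA if the site is
## not exonic for that gene.
cdsPositionOf <- function(regions, gene, chrom, pos) {
    ex <- regions[mcols(regions)$gene_id == gene &
                  as.character(seqnames(regions)) == chrom]
    if (!length(ex)) return(NA_integer_)
    minus <- as.character(strand(ex)[1]) == "-"
    offs <- cumsum(c(0L, width(ex)[-length(ex)]))
    hit <- which(pos >= start(ex) & pos <= end(ex))
    if (!length(hit)) return(NA_integer_)
    fwd <- offs[hit] + (pos - start(ex)[hit]) + 1L
    if (!minus) return(fwd)
    sum(width(ex)) - fwd + 1L
}
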