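#' Assign alleles from phased haplotype sequences
#'
#' Distinct sequences become alleles labelled `H1`, `H2`, ... by descending
#' total count, ties broken by sequence lexicographic order. Counts are
#' tallied per region when a region lookup is given. Unresolved sequences
#' must have been removed beforehand.
#'
#' @param haps a [HaplotypeSet-class] with no unresolved sequences.
#' @param regionOf named character vector mapping individual id to region
#'   label (optional; defaults to a single region).
#' @return an [AlleleTable-class].
#' @export
assignAlleles <- function(haps, regionOf = NULL) {
    if (length(haps@sequences) == 0L) stop("empty haplotype set")
    if (any(haps@unresolved))
        stop("unresolved sequences present; remove them before allele ",
             "assignment")
    seqs <- as.character(haps@sequences)
    regions <- if (is.null(regionOf)) rep("all", length(seqs))
               else unname(regionOf[haps@individual])
    if (anyNA(regions)) stop("individuals missing from regionOf lookup")
    uniq <- unique(seqs)
    tot <- vapply(uniq, function(s) sum(seqs == s), integer(1))
    ord <- order(-tot, uniq)
    uniq <- uniq[ord]
    labels <- paste0("H", seq_along(uniq))
    regionLevels <- unique(regions)
    counts <- t(vapply(uniq, function(s)
        vapply(regionLevels, function(r) sum(seqs == s & regions == r),
               integer(1)), integer(length(regionLevels))))
    if (length(regionLevels) == 1L)
        counts <- matrix(counts, ncol = 1L)
    dimnames(counts) <- list(labels, regionLevels)
    alleles <- DNAStringSet(uniq)
    names(alleles) <- labels
    assignments <- DataFrame(individual = haps@individual,
                             hapIndex = haps@hapIndex,
                             allele = labels[match(seqs, uniq)])
    new("AlleleTable", geneId = haps@geneId, sequences = alleles,
        counts = counts, assignments = assignments)
}

#' Remove rare alleles from an allele table
#'
#' Alleles whose frequency (count over the table's total sequence count) is
#' strictly below `minFreq` are dropped, their carriers removed from the
#' assignments, and the total reduced accordingly. The relative order of
#' surviving labels is preserved (alleles are not relabelled). At the
#' default threshold and 900 sequences, alleles seen four times or fewer
#' are removed (4/900 < 0.005 <= 5/900).
#'
#' @param table an [AlleleTable-class].
#' @param minFreq frequency threshold (strict).
#' @return the filtered [AlleleTable-class].
#' @export
filterRareAlleles <- function(table, minFreq = 0.005) {
    n <- sum(table@counts)
    if (n == 0L) stop("allele table has no sequences")
    freq <- rowSums(table@counts) / n
    keep <- freq >= minFreq
    if (!any(keep)) stop("all alleles removed by the rare-allele filter")
    kept <- names(table@sequences)[keep]
    asg <- table@assignments[table@assignments$allele %in% kept, ,
                             drop = FALSE]
    new("AlleleTable", geneId = table@geneId,
        sequences = table@sequences[keep],
        counts = table@counts[keep, , drop = FALSE], assignments = asg)
}

#' Nucleotide diversity of a set of sequences
#'
#' The average proportion of differing sites between two randomly drawn
#' sequences: the mean over all unordered pairs of (pairwise differences /
#' sequence length). By default no small-sample correction is applied
#' (pairs are counted as `n (n - 1) / 2`), matching the convention of
#' standard sequence-polymorphism software; `corrected = TRUE` multiplies
#' by `n / (n - 1)`.
#'
#' @param x a [HaplotypeSet-class], `DNAStringSet` or character vector of
#'   equal-length sequences (>= 2).
#' @param corrected apply the `n/(n-1)` correction.
#' @return nucleotide diversity per site, in `[0, 1]`.
#' @export
nucleotideDiversity <- function(x, corrected = FALSE) {
    seqs <- if (is(x, "HaplotypeSet")) as.character(x@sequences)
            else as.character(x)
    n <- length(seqs)
    if (n < 2L) stop("need at least two sequences")
    L <- unique(nchar(seqs))
    if (length(L) != 1L) stop("sequences differ in length")
    mat <- matrix(unlist(strsplit(seqs, "")), nrow = n, byrow = TRUE)
    # per-site: number of differing unordered pairs = C(n,2) - sum_a C(c_a,2)
    totPairs <- n * (n - 1) / 2
    diffPairs <- apply(mat, 2, function(col) {
        cnt <- table(col)
        totPairs - sum(cnt * (cnt - 1) / 2)
    })
    pi <- sum(diffPairs) / (totPairs * L)
    if (corrected) pi <- pi * n / (n - 1)
    pi
}

#' Allelic (haplotype) diversity
#'
#' Unbiased gene diversity `h = n / (n - 1) * (1 - sum p_i^2)`: the
#' probability that two randomly drawn alleles differ, with small-sample
#' correction.
#'
#' @param counts integer vector of allele counts (or an
#'   [AlleleTable-class]).
#' @return `h` in `[0, 1]`.
#' @export
#' @examples
#' allelicDiversity(c(450, 450))  # 0.50056 at n = 900
allelicDiversity <- function(counts) {
    if (is(counts, "AlleleTable")) counts <- rowSums(counts@counts)
    n <- sum(counts)
    if (n < 2L) stop("need at least two sequences")
    p <- counts / n
    n / (n - 1) * (1 - sum(p^2))
}

#' Classify a coding SNP as synonymous or non-synonymous
#'
#' Builds the reference and alternate codons at a position of a coding
#' sequence (already in reading frame, 5' to 3') and translates both with
#' the standard genetic code.
#'
#' @param cds coding sequence (character or `DNAString`), length a multiple
#'   of 3 covering the site.
#' @param cdsPos 1-based position of the SNP within `cds`.
#' @param ref,alt reference and alternate base, given on the coding strand.
#' @return `"synonymous"` or `"nonsynonymous"`; `"indeterminate"` when the
#'   codon is truncated at the sequence edge.
#' @export
#' @examples
#' classifySnpEffect("GCTAAA", 3, "T", "C")  # GCT->GCC, Ala->Ala
#' classifySnpEffect("GCTAAA", 2, "C", "T")  # GCT->GTT, Ala->Val
classifySnpEffect <- function(cds, cdsPos, ref, alt) {
    cds <- as.character(cds)
    if (substr(cds, cdsPos, cdsPos) != ref)
        stop("reference base does not match the coding sequence at ", cdsPos)
    codonStart <- cdsPos - (cdsPos - 1L) %% 3L
    if (codonStart + 2L > nchar(cds)) return("indeterminate")
    codon <- substr(cds, codonStart, codonStart + 2L)
    offset <- cdsPos - codonStart + 1L
    altCodon <- codon
    substr(altCodon, offset, offset) <- alt
    aaRef <- GENETIC_CODE[[codon]]
    aaAlt <- GENETIC_CODE[[altCodon]]
    if (is.null(aaRef) || is.null(aaAlt)) return("indeterminate")
    if (aaRef == aaAlt) "synonymous" else "nonsynonymous"
}

#' SNP effects for all sites of a call set or truth set
#'
#' Maps each genomic site into its gene's coding sequence (honouring
#' strand: for minus-strand genes the stored genomic REF/ALT bases are
#' complemented) and classifies the substitution.
#'
#' @param sites `GRanges` with `ref`, `alt`, `gene_id` and `cdsPos`
#'   metadata columns (as produced by the simulator) or a
#'   [GenotypeExperiment-class].
#' @param cdsSeqs named list/`DNAStringSet` of per-gene coding sequences.
#' @param regions exon `GRanges` (supplies strand).
#' @return character vector of effects per site.
#' @export
snpEffects <- function(sites, cdsSeqs, regions) {
    if (is(sites, "GenotypeExperiment")) sites <- rowRanges(sites)
    si <- mcols(sites)
    strandOf <- vapply(si$gene_id, function(g)
        as.character(strand(regions[mcols(regions)$gene_id == g][1])),
        character(1))
    vapply(seq_along(sites), function(i) {
        ref <- si$ref[i]; alt <- si$alt[i]
        if (strandOf[i] == "-") {
            ref <- COMPLEMENT[[ref]]; alt <- COMPLEMENT[[alt]]
        }
        classifySnpEffect(as.character(cdsSeqs[[si$gene_id[i]]]),
                          si$cdsPos[i], ref, alt)
    }, character(1))
}

#' Weir-Cockerham F_ST
#'
#' Per-site variance components a (among populations), b (among individuals
#' within populations) and c (within individuals) of the Weir & Cockerham
#' (1984) estimator for biallelic diploid data, and the mean weighted
#' estimate `sum(a) / sum(a + b + c)` over sites. Monomorphic sites (0/0
#' components) are excluded from the sums.
#'
#' @param x a [GenotypeExperiment-class] or integer call matrix (sites x
#'   individuals, 0/1/2/NA).
#' @param regionLabels population label per individual (taken from the
#'   object when omitted).
#' @return list with `fst` (mean weighted estimate) and `perSite`
#'   data.frame of components.
#' @export
weirCockerhamFst <- function(x, regionLabels = NULL) {
    if (is(x, "GenotypeExperiment")) {
        if (is.null(regionLabels)) regionLabels <- regionLabels(x)
        x <- genotypeCalls(x)
    }
    if (is.null(regionLabels)) stop("regionLabels required")
    pops <- unique(regionLabels)
    r <- length(pops)
    if (r < 2L) stop("need at least two populations")
    comp <- t(apply(x, 1, function(g) {
        ni <- vapply(pops, function(p)
            sum(!is.na(g[regionLabels == p])), numeric(1))
        use <- ni > 0
        if (sum(use) < 2L) return(c(NA, NA, NA))
        ni <- ni[use]
        pi <- vapply(pops[use], function(p) {
            gi <- g[regionLabels == p]
            mean(gi[!is.na(gi)]) / 2
        }, numeric(1))
        hi <- vapply(pops[use], function(p) {
            gi <- g[regionLabels == p]
            mean(gi[!is.na(gi)] == 1)
        }, numeric(1))
        ri <- length(ni)
        nbar <- mean(ni)
        if (nbar <= 1) return(c(NA, NA, NA))
        nc <- (ri * nbar - sum(ni^2) / (ri * nbar)) / (ri - 1)
        pbar <- sum(ni * pi) / (ri * nbar)
        if (pbar <= 0 || pbar >= 1) return(c(NA, NA, NA))
        s2 <- sum(ni * (pi - pbar)^2) / ((ri - 1) * nbar)
        hbar <- sum(ni * hi) / (ri * nbar)
        a <- (nbar / nc) *
            (s2 - (1 / (nbar - 1)) *
                 (pbar * (1 - pbar) - s2 * (ri - 1) / ri - hbar / 4))
        b <- (nbar / (nbar - 1)) *
            (pbar * (1 - pbar) - s2 * (ri - 1) / ri -
                 hbar * (2 * nbar - 1) / (4 * nbar))
        cc <- hbar / 2
        c(a, b, cc)
    }))
    perSite <- data.frame(a = comp[, 1], b = comp[, 2], c = comp[, 3])
    perSite$fst <- perSite$a / (perSite$a + perSite$b + perSite$c)
    ok <- stats::complete.cases(perSite[c("a", "b", "c")])
    denom <- sum(perSite$a[ok] + perSite$b[ok] + perSite$c[ok])
    list(fst = if (denom > 0) sum(perSite$a[ok]) / denom else NA_real_,
         perSite = perSite)
}

#' Pairwise Weir-Cockerham F_ST between regions
#'
#' @param x a [GenotypeExperiment-class].
#' @return symmetric matrix of mean weighted F_ST between every pair of
#'   regions.
#' @export
pairwiseFst <- function(x) {
    regs <- unique(regionLabels(x))
    m <- matrix(NA_real_, length(regs), length(regs),
                dimnames = list(regs, regs))
    diag(m) <- 0
    for (i in seq_along(regs)[-1]) for (j in seq_len(i - 1)) {
        sel <- regionLabels(x) %in% regs[c(i, j)]
        est <- weirCockerhamFst(genotypeCalls(x)[, sel, drop = FALSE],
                                regionLabels(x)[sel])
        m[i, j] <- m[j, i] <- est$fst
    }
    m
}

#' Per-gene diversity statistics
#'
#' Computes, for one gene, the row of the headline diversity table: number
#' of sequences N (after unresolved-sequence removal and rare-allele
#' filtering), segregating exonic SNPs, non-synonymous SNPs, nucleotide
#' diversity, allele count and allelic diversity.
#'
#' @param haps a [HaplotypeSet-class] (resolved sequences only).
#' @param regionOf named region lookup, as in [assignAlleles()].
#' @param minFreq rare-allele threshold passed to [filterRareAlleles()].
#' @return one-row data.frame: `gene_id`, `n`, `snps`, `snps_ns`, `pi`,
#'   `n_alleles`, `allelic_diversity`.
#' @export
geneDiversityStats <- function(haps, regionOf = NULL, minFreq = 0.005) {
    keep <- !haps@unresolved
    haps <- HaplotypeSet(haps@geneId, haps@sequences[keep],
                         haps@individual[keep], haps@hapIndex[keep])
    tab <- filterRareAlleles(assignAlleles(haps, regionOf), minFreq)
    asg <- tab@assignments
    seqs <- tab@sequences[asg$allele]
    n <- length(seqs)
    segEffects <- alleleSegregatingEffects(tab)
    data.frame(gene_id = haps@geneId, n = n,
               snps = segEffects$snps, snps_ns = segEffects$nonsyn,
               pi = if (n >= 2) nucleotideDiversity(seqs) else 0,
               n_alleles = length(tab@sequences),
               allelic_diversity = if (n >= 2) {
                   counts <- vapply(names(tab@sequences), function(a)
                       sum(asg$allele == a), integer(1))
                   allelicDiversity(counts)
               } else 0)
}

## segregating sites among the retained alleles of a gene, and how many are
## non-synonymous relative to the most common allele (sequences are in
## frame, so codon effects come straight from the genetic code)
alleleSegregatingEffects <- function(tab) {
    seqs <- as.character(tab@sequences)
    if (length(seqs) < 2L) return(list(snps = 0L, nonsyn = 0L))
    mat <- matrix(unlist(strsplit(seqs, "")), nrow = length(seqs),
                  byrow = TRUE)
    seg <- which(apply(mat, 2, function(col) length(unique(col)) > 1))
    refSeq <- seqs[1]  # H1, the most common allele
    nonsyn <- 0L
    for (s in seg) {
        bases <- unique(mat[, s])
        ref <- substr(refSeq, s, s)
        for (altb in setdiff(bases, ref)) {
            eff <- classifySnpEffect(refSeq, s, ref, altb)
            if (eff == "nonsynonymous") { nonsyn <- nonsyn + 1L; break }
        }
    }
    list(snps = length(seg), nonsyn = nonsyn)
}

#' Aggregate a per-gene diversity table
#'
#' Summarises a diversity table (one row per gene, as from
#' [geneDiversityStats()]) into totals, means, minima and maxima per
#' column, overall and split by gene class when a `class` column is
#' present. Totals are exact integer sums; means are reported to two
#' decimals.
#'
#' @param stats data.frame with columns `gene_id`, numeric statistic
#'   columns, and optionally `class`.
#' @return list with elements `overall` and (if classes present)
#'   `by_class`, each a data.frame with rows sum / mean / min / max.
#' @export
aggregateGeneTable <- function(stats) {
    if (nrow(stats) == 0L) stop("empty gene table")
    numCols <- names(stats)[vapply(stats, is.numeric, logical(1))]
    summarise <- function(df) {
        out <- rbind(sum = colSums(df[numCols]),
                     mean = round(colMeans(df[numCols]), 2),
                     min = vapply(df[numCols], min, numeric(1)),
                     max = vapply(df[numCols], max, numeric(1)))
        as.data.frame(out)
    }
    res <- list(overall = summarise(stats))
    if ("class" %in% names(stats))
        res$by_class <- lapply(split(stats, stats$class), summarise)
    res
}

#' Published per-gene diversity summary for the koala MHC
#'
#' Per-gene diversity statistics for the 24 polymorphic MHC genes of a
#' range-wide koala resequencing survey (N phased sequences after
#' unresolved-sequence removal, exonic SNPs, non-synonymous SNPs,
#' nucleotide diversity, allele count, allelic diversity, and whether the
#' gene shows copy-number variation), shipped as a worked input for
#' [aggregateGeneTable()].
#'
#' @return data.frame with one row per gene.
#' @export
koalaGeneStats <- function() {
    path <- system.file("extdata", "koala_mhc_gene_diversity.tsv",
                        package = "mhcdepth")
    utils::read.delim(path, stringsAsFactors = FALSE)
}
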