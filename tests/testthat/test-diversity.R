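test_that("allele labels follow count-descending order with lexicographic ties", {
    haps <- HaplotypeSet("UA",
        c("AAAA", "AAAA", "AAAA", "AAAA", "CCCC", "CCCC", "GGGG", "TTTT"),
        individual = paste0("K", rep(1:4, each = 2)),
        hapIndex = rep(1:2, 4))
    tab <- assignAlleles(haps)
    expect_equal(names(alleleSequences(tab)), c("H1", "H2", "H3", "H4"))
    expect_equal(as.character(alleleSequences(tab)),
                 c(H1 = "AAAA", H2 = "CCCC", H3 = "GGGG", H4 = "TTTT"))
    expect_equal(unname(rowSums(alleleCountMatrix(tab))), c(4, 2, 1, 1))
    # all identical -> one allele, zero allelic diversity
    mono <- assignAlleles(HaplotypeSet("UA", rep("ACGT", 6),
                                       individual = paste0("K", rep(1:3, 2)),
                                       hapIndex = rep(1:2, each = 3)))
    expect_length(alleleSequences(mono), 1L)
    expect_error(allelicDiversity(c(6)), NA)
    expect_equal(allelicDiversity(c(6)), 0)
    # unresolved sequences are a precondition violation
    bad <- HaplotypeSet("UA", c("ACGT", "ACNT"), c("K1", "K1"), 1:2)
    expect_error(assignAlleles(bad), "unresolved")
})

test_that("regional allele counts are tallied from the lookup", {
    haps <- HaplotypeSet("UA", c("AAAA", "CCCC", "AAAA", "AAAA"),
                         individual = c("K1", "K1", "K2", "K2"),
                         hapIndex = c(1L, 2L, 1L, 2L))
    tab <- assignAlleles(haps, regionOf = c(K1 = "north", K2 = "south"))
    expect_equal(alleleCountMatrix(tab)["H1", "north"], 1L)
    expect_equal(alleleCountMatrix(tab)["H1", "south"], 2L)
    expect_equal(alleleCountMatrix(tab)["H2", "south"], 0L)
})

test_that("rare-allele removal uses a strict frequency threshold", {
    mkTab <- function(count, n) {
        seqs <- c(rep("AAAA", n - count), rep("CCCC", count))
        assignAlleles(HaplotypeSet("UA", seqs,
                                   individual = paste0("K", seq_along(seqs)),
                                   hapIndex = rep(1L, length(seqs))))
    }
    # n = 900: counts of four or fewer are below 0.005, five is retained
    expect_length(alleleSequences(filterRareAlleles(mkTab(4, 900))), 1L)
    expect_length(alleleSequences(filterRareAlleles(mkTab(5, 900))), 2L)
    # n = 100: a single occurrence is 0.01 >= 0.005 and survives
    expect_length(alleleSequences(filterRareAlleles(mkTab(1, 100))), 2L)
    # the total is reduced by the removed occurrences
    filt <- filterRareAlleles(mkTab(4, 900))
    expect_equal(sum(alleleCountMatrix(filt)), 896)
    # surviving labels keep their order (no relabelling)
    seqs <- c(rep("AAAA", 500), rep("CCCC", 396), rep("GGGG", 4))
    tab <- assignAlleles(HaplotypeSet("UA", seqs,
                                      individual = paste0("K", seq_along(seqs)),
                                      hapIndex = rep(1L, length(seqs))))
    expect_equal(names(alleleSequences(filterRareAlleles(tab))),
                 c("H1", "H2"))
    expect_error(filterRareAlleles(mkTab(0, 10), minFreq = 1.1), "removed")
})

test_that("nucleotide diversity matches a brute-force pairwise oracle", {
    seq100 <- function(diffAt) {
        base <- rep("A", 100)
        s2 <- base; s2[diffAt] <- "C"
        c(paste(base, collapse = ""), paste(s2, collapse = ""))
    }
    expect_equal(nucleotideDiversity(seq100(7)), 0.01)
    expect_equal(nucleotideDiversity(c("ACGT", "ACGT")), 0)
    bruteForce <- function(seqs) {
        pairs <- utils::combn(length(seqs), 2)
        mean(apply(pairs, 2, function(p) {
            a <- strsplit(seqs[p[1]], "")[[1]]
            b <- strsplit(seqs[p[2]], "")[[1]]
            sum(a != b) / length(a)
        }))
    }
    set.seed(99)
    for (i in 1:50) {
        n <- sample(3:8, 1)
        L <- sample(c(9, 12, 30), 1)
        seqs <- vapply(seq_len(n), function(j)
            paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                  collapse = ""), character(1))
        expect_equal(nucleotideDiversity(seqs), bruteForce(seqs),
                     tolerance = 1e-12)
        # corrected variant applies the n/(n-1) factor exactly
        expect_equal(nucleotideDiversity(seqs, corrected = TRUE),
                     bruteForce(seqs) * n / (n - 1), tolerance = 1e-12)
    }
    expect_error(nucleotideDiversity(c("ACGT", "ACG")), "length")
    expect_error(nucleotideDiversity("ACGT"), "two sequences")
})

test_that("allelic diversity is the corrected heterozygosity", {
    expect_equal(allelicDiversity(c(1, 1)), 1)
    expect_equal(allelicDiversity(c(450, 450)), 0.50056, tolerance = 1e-5)
    expect_error(allelicDiversity(c(1)), "two sequences")
    # brute-force oracle: probability two distinct draws differ
    bruteForce <- function(counts) {
        labels <- rep(seq_along(counts), counts)
        pairs <- utils::combn(length(labels), 2)
        mean(apply(pairs, 2, function(p) labels[p[1]] != labels[p[2]]))
    }
    set.seed(7)
    for (i in 1:20) {
        counts <- sample(1:6, sample(2:4, 1), replace = TRUE)
        expect_equal(allelicDiversity(counts), bruteForce(counts),
                     tolerance = 1e-12)
    }
})

test_that("SNP effects come from the genetic code", {
    expect_equal(classifySnpEffect("GCTAAA", 3, "T", "C"), "synonymous")
    expect_equal(classifySnpEffect("GCTAAA", 2, "C", "T"), "nonsynonymous")
    expect_equal(classifySnpEffect("GCTAA", 4, "A", "G"), "indeterminate")
    expect_error(classifySnpEffect("GCTAAA", 1, "T", "C"), "does not match")
})

test_that("minus-strand effects agree with whole-CDS translation", {
    cfg <- simConfig(nRegions = 1L, nIndividuals = 4L, seed = 61L)
    truth <- simulateTruth(cfg)
    # UE is the minus-strand gene in the default panel
    sel <- mcols(truth@sites)$gene_id == "UE"
    expect_gt(sum(sel), 0)
    sites <- truth@sites[sel]
    cds <- as.character(truth@alleleSeqs[["UE"]][1])
    eff <- snpEffects(sites, list(UE = cds), cfg@genes)
    # oracle: mutate the CDS base directly and translate both sequences
    oracle <- vapply(seq_along(sites), function(i) {
        p <- mcols(sites)$cdsPos[i]
        altCds <- cds
        # genomic alt complemented back onto the coding strand
        comp <- c(A = "T", C = "G", G = "C", T = "A")
        substr(altCds, p, p) <- unname(comp[mcols(sites)$alt[i]])
        aa1 <- as.character(Biostrings::translate(Biostrings::DNAString(cds),
                                                  no.init.codon = TRUE))
        aa2 <- as.character(Biostrings::translate(Biostrings::DNAString(altCds),
                                                  no.init.codon = TRUE))
        if (aa1 == aa2) "synonymous" else "nonsynonymous"
    }, character(1))
    expect_equal(eff, oracle)
})

test_that("Weir-Cockerham components match an independent evaluation", {
    # two populations of five diploids; components computed independently
    # (numpy transcription of the 1984 definitions) and frozen
    g <- rbind(c(0, 1, 1, 2, 2, 0, 0, 0, 1, 2),
               c(1, 1, 0, 0, 1, 2, 2, 1, 2, 2))
    pops <- rep(c("P1", "P2"), each = 5)
    est <- weirCockerhamFst(g, pops)
    expect_equal(est$perSite$a, c(0.0075, 0.1675), tolerance = 1e-8)
    expect_equal(est$perSite$b, c(0.1125, -0.0375), tolerance = 1e-8)
    expect_equal(est$perSite$c, c(0.15, 0.2), tolerance = 1e-8)
    expect_equal(est$perSite$fst[1], 0.027777778, tolerance = 1e-7)
    expect_equal(est$fst, 0.291666667, tolerance = 1e-8)
})

test_that("F_ST hits its limits and skips monomorphic sites", {
    set.seed(5)
    # identical allele frequencies, large n -> near zero
    g0 <- rbind(rbinom(400, 2, 0.4))
    est0 <- weirCockerhamFst(g0, rep(c("P1", "P2"), each = 200))
    expect_lt(abs(est0$fst), 0.02)
    # fixed difference -> 1
    g1 <- rbind(c(rep(2, 100), rep(0, 100)))
    est1 <- weirCockerhamFst(g1, rep(c("P1", "P2"), each = 100))
    expect_equal(est1$fst, 1)
    # monomorphic site contributes nothing
    g2 <- rbind(c(rep(2, 100), rep(0, 100)), rep(0, 200))
    est2 <- weirCockerhamFst(g2, rep(c("P1", "P2"), each = 100))
    expect_equal(est2$fst, 1)
    expect_true(is.na(est2$perSite$a[2]))
})

test_that("F_ST rises monotonically with the differentiation parameter", {
    levels <- c(0.02, 0.1, 0.2, 0.35, 0.5)
    fst <- vapply(levels, function(d) {
        cfg <- simConfig(nRegions = 2L, nIndividuals = 30L,
                         differentiation = d, seed = 71L)
        truth <- simulateTruth(cfg)
        weirCockerhamFst(truth@trueGenotypes,
                         truth@individuals$region)$fst
    }, numeric(1))
    expect_gt(stats::cor(levels, fst, method = "spearman"), 0.9)
})

test_that("gene-table aggregation reports exact sums and 2-dp means", {
    df <- data.frame(gene_id = c("g1", "g2", "g3"),
                     class = c("I", "I", "II"),
                     n_alleles = c(2L, 7L, 3L),
                     snps_ns = c(1L, 10L, 0L))
    agg <- aggregateGeneTable(df)
    expect_equal(agg$overall["sum", "n_alleles"], 12)
    expect_equal(agg$overall["mean", "n_alleles"], 4)
    expect_equal(agg$overall["max", "snps_ns"], 10)
    expect_equal(agg$by_class$I["sum", "n_alleles"], 9)
    expect_equal(agg$by_class$II["min", "snps_ns"], 0)
    expect_equal(agg$overall["mean", "snps_ns"], round(11 / 3, 2))
    expect_error(aggregateGeneTable(df[0, ]), "empty")
})
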