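test_that("BED-like region tables use 0-based half-open, internal 1-based", {
    tf <- tempfile(fileext = ".tsv")
    # a 1-bp exon covering only genomic base 101 (BED: start 100, end 101)
    writeLines(c("chrom\tstart\tend\tgene_id\tfamily\tsingle_copy\tstrand\tframe",
                 "chr1\t100\t101\tG1\tTLR\tTRUE\t+\t0",
                 "chr1\t200\t302\tG1\tTLR\tTRUE\t+\t0"), tf)
    gr <- readGeneRegions(tf)
    expect_equal(start(gr)[1], 101)
    expect_equal(end(gr)[1], 101)
    expect_equal(width(gr)[1], 1)
    # round trip back to BED coordinates
    tf2 <- tempfile(fileext = ".tsv")
    writeGeneRegions(gr, tf2)
    expect_equal(utils::read.delim(tf2)$start, c(100, 200))
})

test_that("gene region invariants are enforced", {
    df <- data.frame(chrom = "chr1", start = c(10, 15), end = c(20, 30),
                     gene_id = "G1", family = "TLR", single_copy = TRUE,
                     strand = "+", frame = 0)
    expect_error(geneRegions(df), "overlap")
    df2 <- data.frame(chrom = "chr1", start = 10, end = 11, gene_id = "G1",
                      family = "TLR", single_copy = TRUE, strand = "+",
                      frame = 0)
    expect_error(geneRegions(df2), "length < 3")
    df3 <- data.frame(chrom = "chr1", start = 10, end = 100, gene_id = "G1",
                      family = "MHC_I", single_copy = TRUE, strand = "+",
                      frame = 0)
    expect_error(geneRegions(df3), "restricted to TLR")
    expect_s4_class(geneRegions(df3, allowNonTlrReference = TRUE), "GRanges")
})

test_that("VCF reading keeps only biallelic exonic SNPs and maps GT", {
    tf <- tempfile(fileext = ".vcf")
    writeLines(c(
        "##fileformat=VCFv4.2",
        "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"GT\">",
        "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"DP\">",
        "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"MQ\">",
        "##contig=<ID=chr1>",
        "##contig=<ID=chrUn>",
        "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tK1\tK2",
        "chr1\t150\t.\tA\tG\t99\t.\tMQ=60\tGT:DP\t0/1:12\t1/1:8",   # exonic het
        "chr1\t150\t.\tA\tG,T\t99\t.\tMQ=60\tGT:DP\t0/1:12\t0/0:9", # multi-allelic
        "chr1\t500\t.\tC\tT\t99\t.\tMQ=60\tGT:DP\t0/0:10\t./.:0",   # intronic
        "chrUn\t10\t.\tG\tA\t99\t.\tMQ=60\tGT:DP\t0/0:4\t0/1:5"),   # unknown contig
        tf)
    expect_warning(ge <- readVcfGenotypes(tf, toyRegions()), "skipped")
    expect_equal(nrow(ge), 1L)
    expect_equal(unname(genotypeCalls(ge)[1, ]), c(1L, 2L))
    expect_equal(unname(genotypeDepth(ge)[1, ]), c(12L, 8L))
    expect_equal(start(rowRanges(ge)), 150)
})

test_that("VCF writing round-trips genotypes, depths and annotations", {
    calls <- matrix(c(0L, 1L, 2L, NA), 2, 2)
    refd <- matrix(c(10L, 6L, 0L, 0L), 2, 2)
    altd <- matrix(c(0L, 6L, 9L, 0L), 2, 2)
    ge <- toyGenotypes(calls = calls, depth = refd + altd, refd = refd,
                       altd = altd, qual = c(100, 85.5), mq = c(60, 42),
                       mqrs = c(0.5, -1), rprs = c(2, NA),
                       pos = c(150, 320), nInd = 2)
    tf <- tempfile(fileext = ".vcf")
    writeVcfGenotypes(ge, tf)
    back <- readVcfGenotypes(tf, toyRegions())
    expect_equal(genotypeCalls(back), genotypeCalls(ge),
                 ignore_attr = TRUE)
    expect_equal(genotypeDepth(back), genotypeDepth(ge),
                 ignore_attr = TRUE)
    expect_equal(refDepth(back), refDepth(ge), ignore_attr = TRUE)
    expect_equal(start(rowRanges(back)), c(150, 320))
    si <- mcols(rowRanges(back))
    expect_equal(si$qual, c(100, 85.5))
    expect_equal(si$mq, c(60, 42))
    expect_equal(si$mqRankSum, c(0.5, -1))
    expect_equal(si$readPosRankSum, c(2, NA))
})

test_that("coverage tables are validated on read", {
    tf <- tempfile(fileext = ".tsv")
    hdr <- "gene_id\tindividual\tread_count\tbases_covered\tgene_length_bp"
    writeLines(c(hdr, "UA\tK1\t100\t1800\t2000"), tf)
    cov <- readCoverageTable(tf)
    expect_equal(nrow(cov), 1L)
    expect_equal(cov$read_count, 100)
    writeLines(c(hdr, "UA\tK1\t100\t1800\t2000", "UA\tK1\t90\t1700\t2000"), tf)
    expect_error(readCoverageTable(tf), "duplicate")
    writeLines(c(hdr, "UA\tK1\t-5\t1800\t2000"), tf)
    expect_error(readCoverageTable(tf), "non-negative")
    writeLines(c(hdr, "UA\tK1\t10\t2500\t2000"), tf)
    expect_error(readCoverageTable(tf), "exceed")
    writeLines(hdr, tf)
    expect_warning(cov <- readCoverageTable(tf), "empty")
    expect_equal(nrow(cov), 0L)
})

test_that("haplotype FASTA reading parses the header dialect", {
    seqs <- DNAStringSet(c("ACGTAA", "ACGTAA", "ACGTTA", "ACGTTA",
                           "ACNTAA", "ACGTAA", "ACGTCA", "ACGTCA"))
    names(seqs) <- paste(rep(paste0("K", 1:4), each = 2), "UA",
                         rep(1:2, 4), sep = "__")
    tf <- tempfile(fileext = ".fa")
    writeXStringSet(seqs, tf)
    haps <- readHaplotypes(tf)
    expect_named(haps, "UA")
    h <- haps[["UA"]]
    expect_length(haplotypeSequences(h), 8L)
    # the 'N' sequence (K3 hap 1) is flagged unresolved
    expect_equal(sum(unresolvedFlags(h)), 1L)
    expect_equal(h@individual[unresolvedFlags(h)], "K3")
    # K3 therefore has fewer than two resolved haplotypes
    expect_true("K3" %in% incompleteIndividuals(h))
    # round trip
    tf2 <- tempfile(fileext = ".fa")
    writeHaplotypes(h, tf2)
    expect_equal(as.character(readHaplotypes(tf2)[["UA"]]@sequences),
                 as.character(h@sequences), ignore_attr = TRUE)
})

test_that("haplotype length mismatch within a gene is an error", {
    seqs <- DNAStringSet(c("ACGTAA", "ACGT"))
    names(seqs) <- c("K1__UA__1", "K1__UA__2")
    tf <- tempfile(fileext = ".fa")
    writeXStringSet(seqs, tf)
    expect_error(readHaplotypes(tf), "length")
})

test_that("missing mate haplotype marks the individual incomplete", {
    h <- HaplotypeSet("UA", c("ACGT", "ACGT", "AGGT"),
                      individual = c("K1", "K1", "K2"),
                      hapIndex = c(1L, 2L, 1L))
    expect_equal(incompleteIndividuals(h), "K2")
})
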