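test_that("the letter grid is the unique layout consistent with the metrics", {
    # diagonal: concordant states
    expect_equal(classifyGenotypePair(0, 0), "A")
    expect_equal(classifyGenotypePair(1, 1), "F")
    expect_equal(classifyGenotypePair(2, 2), "K")
    expect_equal(classifyGenotypePair(NA, NA), "P")
    # column 4: called by WGS, missing in the reference set
    expect_equal(classifyGenotypePair(NA, 0), "D")
    expect_equal(classifyGenotypePair(NA, 1), "H")
    expect_equal(classifyGenotypePair(NA, 2), "L")
    # row 4: called by the reference set, missing in WGS
    expect_equal(classifyGenotypePair(c(0, 1, 2), c(NA, NA, NA)),
                 c("M", "N", "O"))
    # discordant calls fill the remaining six letters
    expect_equal(classifyGenotypePair(c(1, 2, 0, 2, 0, 1),
                                      c(0, 0, 1, 1, 2, 2)),
                 c("B", "C", "E", "G", "I", "J"))
    # string states are accepted
    expect_equal(classifyGenotypePair("HOM_REF", "MISSING"), "M")
    expect_error(classifyGenotypePair("HEMI", "HET"), "unknown")
    expect_error(classifyGenotypePair(3, 0), "codes")
})

test_that("the four metrics implement the printed ratios", {
    counts <- stats::setNames(rep(0L, 16), LETTERS[1:16])
    counts[c("A", "B", "M", "P")] <- c(5L, 1L, 2L, 2L)
    tab <- new("ConcordanceTable", counts = counts)
    m <- concordanceMetrics(tab)
    expect_equal(unname(m["concordance"]), 0.7)
    expect_equal(unname(m["missing_wgs"]), 0.2)
    expect_equal(unname(m["missing_te"]), 0)
    expect_equal(unname(m["non_concordance"]), 0.1)
    only <- stats::setNames(rep(0L, 16), LETTERS[1:16])
    only["A"] <- 10L
    expect_equal(unname(concordanceMetrics(
        new("ConcordanceTable", counts = only))["concordance"]), 1)
    empty <- new("ConcordanceTable",
                 counts = stats::setNames(rep(0L, 16), LETTERS[1:16]))
    expect_error(concordanceMetrics(empty), "undefined")
})

test_that("metrics partition every random table (sum to one)", {
    set.seed(42)
    for (i in 1:200) {
        counts <- stats::setNames(as.integer(rpois(16, 5)), LETTERS[1:16])
        if (sum(counts) == 0) counts["A"] <- 1L
        m <- concordanceMetrics(new("ConcordanceTable", counts = counts))
        expect_equal(sum(m), 1, tolerance = 1e-12)
    }
})

test_that("strict mode drops both-missing pairs from the ratio", {
    counts <- stats::setNames(rep(0L, 16), LETTERS[1:16])
    counts[c("A", "P")] <- c(1L, 1L)
    tab <- new("ConcordanceTable", counts = counts)
    expect_equal(unname(concordanceMetrics(tab)["concordance"]), 1)
    expect_equal(unname(concordanceMetrics(tab,
                                           strict = TRUE)["concordance"]), 1)
    counts[c("A", "B", "P")] <- c(1L, 1L, 2L)
    tab2 <- new("ConcordanceTable", counts = counts)
    expect_equal(unname(concordanceMetrics(tab2)["concordance"]), 0.75)
    expect_equal(unname(concordanceMetrics(tab2, strict = TRUE)["concordance"]),
                 0.5)
})

test_that("site alignment matches on the strict chrom:pos:ref:alt key", {
    mkGE <- function(pos, ref, alt, inds) {
        gr <- GRanges("chr1", IRanges(pos, width = 1))
        mcols(gr)$ref <- ref; mcols(gr)$alt <- alt
        mcols(gr)$qual <- 100; mcols(gr)$mq <- 60
        mcols(gr)$mqRankSum <- 0; mcols(gr)$readPosRankSum <- 0
        mcols(gr)$gene_id <- "UA"
        GenotypeExperiment(matrix(1L, length(pos), length(inds)),
                           depth = matrix(10L, length(pos), length(inds)),
                           rowRanges = gr, individuals = inds)
    }
    te <- mkGE(c(110, 120, 130), c("A", "C", "G"), c("G", "T", "A"),
               c("K1", "K2", "K3"))
    wgs <- mkGE(c(110, 120, 140), c("A", "T", "G"), c("G", "C", "A"),
                c("K2", "K3", "K4"))
    pair <- alignSites(te, wgs)
    # site 120 has swapped REF/ALT -> not shared; site 110 shared
    expect_equal(nrow(pair$te), 1L)
    expect_equal(start(rowRanges(pair$te)), 110)
    expect_equal(colnames(pair$te), c("K2", "K3"))
    expect_identical(colnames(pair$te), colnames(pair$wgs))
    # disjoint sites warn; disjoint individuals error
    expect_warning(alignSites(mkGE(500, "A", "G", "K1"),
                              mkGE(600, "A", "G", "K1")), "no shared sites")
    expect_error(alignSites(te, mkGE(110, "A", "G", "K9")),
                 "no shared individuals")
})

test_that("concordance tabulation counts all site x individual pairs", {
    calls1 <- matrix(c(0L, 1L, 2L, NA), 2, 2)
    calls2 <- matrix(c(0L, NA, 1L, NA), 2, 2)
    ge1 <- toyGenotypes(calls = calls1, pos = c(110, 120), nInd = 2)
    ge2 <- toyGenotypes(calls = calls2, pos = c(110, 120), nInd = 2)
    tab <- concordanceTable(ge1, ge2)
    expect_equal(sum(tab@counts), 4L)
    expect_equal(unname(tab@counts["A"]), 1L)  # (te 0, wgs 0)
    expect_equal(unname(tab@counts["N"]), 1L)  # (te 1, wgs NA)
    expect_equal(unname(tab@counts["G"]), 1L)  # (te 2, wgs 1)
    expect_equal(unname(tab@counts["P"]), 1L)  # both missing
})
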