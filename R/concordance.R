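## Genotype-pair letter grid: rows = WGS state, columns = TE state, both
## ordered (hom-ref, het, hom-alt, missing); letters run row-major. This is
## the unique row-major layout consistent with the four concordance metrics:
## the diagonal A, F, K, P is concordant, column 4 (D, H, L) is TE-missing,
## row 4 (M, N, O) is WGS-missing.

CONCORDANT_LETTERS <- c("A", "F", "K", "P")
MISSING_WGS_LETTERS <- c("M", "N", "O")
MISSING_TE_LETTERS <- c("D", "H", "L")
DISCORDANT_LETTERS <- c("B", "C", "E", "G", "I", "J")

stateIndex <- function(gt) {
    if (is.character(gt)) {
        idx <- match(gt, c("HOM_REF", "HET", "HOM_ALT", "MISSING"))
        if (anyNA(idx)) stop("unknown genotype state: ",
                             paste(unique(gt[is.na(idx)]), collapse = ", "))
        return(idx)
    }
    bad <- !is.na(gt) & !(gt %in% 0:2)
    if (any(bad)) stop("genotype codes must be 0, 1, 2 or NA")
    ifelse(is.na(gt), 4L, gt + 1L)
}

#' Classify a genotype pair onto the 16-letter concordance grid
#'
#' @param gtTe,gtWgs genotype states from the reference (target-enrichment)
#'   and test (WGS) call sets: integer codes 0/1/2/NA or the strings
#'   `"HOM_REF"`, `"HET"`, `"HOM_ALT"`, `"MISSING"`. Vectorised.
#' @return character vector of letters A..P.
#' @export
#' @examples
#' classifyGenotypePair(0, 0)          # both hom-ref -> "A"
#' classifyGenotypePair(1, 1)          # both het     -> "F"
#' classifyGenotypePair(0, NA)         # WGS missing  -> "M"
classifyGenotypePair <- function(gtTe, gtWgs) {
    te <- stateIndex(gtTe); wgs <- stateIndex(gtWgs)
    LETTERS[4L * (wgs - 1L) + te]
}

#' Restrict two call sets to their shared sites and individuals
#'
#' Sites match only on the strict (chrom, pos, ref, alt) key: a site whose
#' REF/ALT are swapped between call sets is not shared. Individuals are
#' matched by id; zero shared individuals is an error, zero shared sites a
#' warning.
#'
#' @param te,wgs [GenotypeExperiment-class] objects for the reference and
#'   test call sets.
#' @return a list with elements `te` and `wgs`, subsetted to the shared
#'   sites (same order) and shared individuals.
#' @export
alignSites <- function(te, wgs) {
    inds <- intersect(colnames(te), colnames(wgs))
    if (length(inds) == 0L) stop("no shared individuals between call sets")
    key <- function(x) {
        si <- mcols(rowRanges(x))
        paste(as.character(seqnames(rowRanges(x))), start(rowRanges(x)),
              si$ref, si$alt, sep = ":")
    }
    kt <- key(te); kw <- key(wgs)
    shared <- intersect(kt, kw)
    if (length(shared) == 0L)
        warning("no shared sites between call sets")
    list(te = te[match(shared, kt), inds],
         wgs = wgs[match(shared, kw), inds])
}

#' Tabulate genotype pairs of two aligned call sets
#'
#' @param te,wgs aligned [GenotypeExperiment-class] objects (see
#'   [alignSites()]), or a list as returned by it in `te`.
#' @return a [ConcordanceTable-class] of the 16 letter counts over all
#'   (site, individual) pairs.
#' @export
concordanceTable <- function(te, wgs = NULL) {
    if (is.list(te) && is.null(wgs)) { wgs <- te$wgs; te <- te$te }
    stopifnot(identical(dim(te), dim(wgs)))
    letters <- classifyGenotypePair(as.vector(genotypeCalls(te)),
                                    as.vector(genotypeCalls(wgs)))
    counts <- table(factor(letters, levels = LETTERS[1:16]))
    new("ConcordanceTable",
        counts = stats::setNames(as.integer(counts), LETTERS[1:16]))
}

#' The four concordance metrics
#'
#' From the letter counts: concordance `(A+F+K+P)/total`, missing WGS calls
#' `(M+N+O)/total`, missing target-enrichment calls `(D+H+L)/total`, and
#' non-concordance `(B+C+E+G+I+J)/total`. The sixteen letters partition the
#' pairs, so the four metrics sum to one. Pairs missing in both call sets
#' (letter P) count as concordant by definition; `strict = TRUE` drops them
#' from both numerator and denominator.
#'
#' @param table a [ConcordanceTable-class].
#' @param strict drop both-missing pairs.
#' @return named numeric vector `concordance`, `missing_wgs`,
#'   `missing_te`, `non_concordance`.
#' @export
concordanceMetrics <- function(table, strict = FALSE) {
    cnt <- table@counts
    if (strict) cnt["P"] <- 0L
    total <- sum(cnt)
    if (total == 0L) stop("concordance metrics undefined for empty table")
    c(concordance = sum(cnt[CONCORDANT_LETTERS]) / total,
      missing_wgs = sum(cnt[MISSING_WGS_LETTERS]) / total,
      missing_te = sum(cnt[MISSING_TE_LETTERS]) / total,
      non_concordance = sum(cnt[DISCORDANT_LETTERS]) / total)
}
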