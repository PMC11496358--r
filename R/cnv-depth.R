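#' Reads per kilobase
#'
#' @param readCount reads mapped to the gene.
#' @param geneLengthBp gene length in bp (> 0).
#' @return `readCount / (geneLengthBp / 1000)`. Vectorised.
#' @export
#' @examples
#' rpk(100, 2000)  # 50
rpk <- function(readCount, geneLengthBp) {
    if (any(geneLengthBp <= 0)) stop("gene length must be positive")
    readCount / (geneLengthBp / 1000)
}

#' Allelic copy number from single-copy normalisation
#'
#' The gene's RPK is divided by the mean RPK of the single-copy reference
#' genes and multiplied by two, so a diploid single-copy gene scores 2 and
#' a complete deletion 0.
#'
#' @param rpkGene RPK of the gene of interest (vectorised).
#' @param rpkReference numeric vector of reference-gene RPK values for the
#'   same individual.
#' @return `2 * rpkGene / mean(rpkReference)`.
#' @export
allelicCopyNumber <- function(rpkGene, rpkReference) {
    if (length(rpkReference) == 0L || all(rpkReference == 0))
        stop("all reference-gene RPK values are zero: individual uncallable")
    2 * rpkGene / mean(rpkReference)
}

#' Classify allelic copy number into copy classes
#'
#' Bins are half-open `[n - 0.5, n + 0.5)` clamped to 0..6, generalising the
#' single-copy band: values in `[1.5, 2.5]` are single copy, and the band is
#' read inclusively, so an ACN of exactly 2.5 resolves to class 2 rather
#' than 3.
#'
#' @param acn numeric vector of allelic copy numbers (>= 0).
#' @return data.frame with `acn`, `copy_class` (integer 0..6) and
#'   `single_copy` (`1.5 <= acn <= 2.5`).
#' @export
#' @examples
#' classifyCopyNumber(c(0.2, 0.9, 2.0, 2.5, 5.8))
classifyCopyNumber <- function(acn) {
    if (any(acn < 0, na.rm = TRUE)) stop("acn must be non-negative")
    cls <- pmin(pmax(floor(acn + 0.5), 0), 6)
    cls[!is.na(acn) & acn == 2.5] <- 2   # inclusive upper edge of the band
    data.frame(acn = acn, copy_class = as.integer(cls),
               single_copy = !is.na(acn) & acn >= 1.5 & acn <= 2.5)
}

#' Per-individual allelic copy-number calls from a coverage summary
#'
#' For each individual, gene RPK values are computed from the coverage
#' table, the single-copy reference genes provide the normalising mean RPK,
#' and every non-reference gene receives an allelic copy number and copy
#' class. Reference genes themselves can be scored with
#' `selfTest = TRUE`, which normalises each reference gene by the mean of
#' the remaining references (leave-one-out).
#'
#' @param coverage coverage data.frame (see [readCoverageTable()]).
#' @param regions exon `GRanges`; its `single_copy` flag defines the
#'   reference set.
#' @param summarise `"mean"` (the default normalisation) or `"median"` of
#'   the reference RPK values.
#' @param selfTest score the reference genes (leave-one-out) instead of the
#'   target genes.
#' @return long-format data.frame: `gene_id`, `individual`, `rpk`, `acn`,
#'   `copy_class`, `single_copy`.
#' @export
copyNumberCalls <- function(coverage, regions,
                            summarise = c("mean", "median"),
                            selfTest = FALSE) {
    summarise <- match.arg(summarise)
    fun <- if (summarise == "mean") mean else stats::median
    validateCoverage(coverage)
    refs <- referenceGenes(regions)
    if (length(refs) == 0L) stop("no single-copy reference genes in regions")
    coverage$rpk <- rpk(coverage$read_count, coverage$gene_length_bp)
    out <- lapply(split(coverage, coverage$individual), function(cv) {
        refRpk <- cv$rpk[cv$gene_id %in% refs]
        if (length(refRpk) == 0L || all(refRpk == 0)) {
            warning("individual ", cv$individual[1],
                    " has no reference coverage; skipped")
            return(NULL)
        }
        if (selfTest) {
            rows <- cv[cv$gene_id %in% refs, ]
            acn <- vapply(seq_len(nrow(rows)), function(i) {
                others <- refRpk[cv$gene_id[cv$gene_id %in% refs] !=
                                 rows$gene_id[i]]
                2 * rows$rpk[i] / fun(others)
            }, numeric(1))
        } else {
            rows <- cv[!(cv$gene_id %in% refs), ]
            acn <- 2 * rows$rpk / fun(refRpk)
        }
        cbind(rows[c("gene_id", "individual", "rpk")],
              classifyCopyNumber(acn))
    })
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
}

#' Flag genes showing copy-number variation
#'
#' A gene is called CNV when the fraction of individuals whose allelic copy
#' number falls outside the single-copy band exceeds `minFraction`
#' (default: any individual).
#'
#' @param calls output of [copyNumberCalls()].
#' @param band single-copy band, default `c(1.5, 2.5)` (inclusive).
#' @param minFraction minimum fraction of out-of-band individuals.
#' @return data.frame per gene: `gene_id`, `n`, `fraction_outside`, `cnv`.
#' @export
callCnvGenes <- function(calls, band = c(1.5, 2.5), minFraction = 0) {
    if (length(unique(calls$individual)) < 2L)
        stop("CNV calling needs at least two individuals")
    agg <- lapply(split(calls, calls$gene_id), function(df) {
        outside <- df$acn < band[1] | df$acn > band[2]
        data.frame(gene_id = df$gene_id[1], n = nrow(df),
                   fraction_outside = mean(outside),
                   cnv = mean(outside) > minFraction |
                       (minFraction == 0 & any(outside)))
    })
    res <- do.call(rbind, agg)
    rownames(res) <- NULL
    res
}
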