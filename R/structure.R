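#' SNP dosage encoding of a call set
#'
#' @param x a [GenotypeExperiment-class].
#' @param genes optional gene ids to restrict to (e.g. only single-copy
#'   genes, or only CNV genes, for separate ordinations).
#' @return numeric matrix individuals x sites of alternate-allele dosages
#'   (0/1/2, NA for missing calls).
#' @export
snpDosage <- function(x, genes = NULL) {
    if (!is.null(genes))
        x <- x[mcols(rowRanges(x))$gene_id %in% genes, ]
    t(genotypeCalls(x))
}

#' Per-individual allele-count encoding
#'
#' @param tables list of [AlleleTable-class] (one per gene).
#' @param individuals individual ids defining the row order.
#' @return matrix individuals x alleles (columns labelled gene:allele) of
#'   allele copies carried.
#' @export
alleleDosage <- function(tables, individuals) {
    cols <- list()
    for (tab in tables) {
        asg <- tab@assignments
        for (a in names(tab@sequences)) {
            cnt <- vapply(individuals, function(i)
                sum(asg$individual == i & asg$allele == a), numeric(1))
            cols[[paste(tab@geneId, a, sep = ":")]] <- cnt
        }
    }
    m <- do.call(cbind, cols)
    rownames(m) <- individuals
    m
}

#' Euclidean genetic distance between individuals
#'
#' Missing entries are imputed with the feature (column) mean before
#' computing pairwise Euclidean distances; features can optionally be
#' standardised.
#'
#' @param encoding individuals x features matrix (SNP dosages, allele
#'   counts or supertype counts).
#' @param scale standardise columns to unit variance first.
#' @return a `dist` object labelled by individual.
#' @export
geneticDistance <- function(encoding, scale = FALSE) {
    allMissing <- rowSums(!is.na(encoding)) == 0
    if (any(allMissing))
        stop("individual(s) with all features missing: ",
             paste(rownames(encoding)[allMissing], collapse = ", "))
    for (j in seq_len(ncol(encoding))) {
        v <- encoding[, j]
        if (anyNA(v)) {
            m <- mean(v, na.rm = TRUE)
            if (is.nan(m)) m <- 0
            encoding[is.na(v), j] <- m
        }
    }
    if (scale) {
        sds <- apply(encoding, 2, stats::sd)
        sds[sds == 0] <- 1
        encoding <- sweep(encoding, 2, sds, "/")
    }
    stats::dist(encoding)
}

#' Principal coordinates analysis (classical metric MDS)
#'
#' Double-centres the squared distance matrix, `B = -1/2 J D^2 J`, and
#' eigendecomposes it; coordinates are eigenvectors scaled by the square
#' root of the positive eigenvalues, sorted descending. Axes follow the
#' sign convention that their first non-zero loading is positive. Negative
#' eigenvalues (semi-metric input) are dropped; requesting more axes than
#' there are positive eigenvalues truncates with a warning.
#'
#' @param d a `dist` or symmetric distance matrix.
#' @param k number of axes to return.
#' @return list with `points` (n x k coordinate matrix), `eig` (all
#'   eigenvalues, descending) and `varExplained` (share of the positive
#'   eigenvalue sum per returned axis).
#' @export
runPCoA <- function(d, k = 2) {
    D <- as.matrix(d)
    n <- nrow(D)
    J <- diag(n) - matrix(1 / n, n, n)
    B <- -0.5 * J %*% (D^2) %*% J
    B <- (B + t(B)) / 2
    e <- eigen(B, symmetric = TRUE)
    tol <- max(abs(e$values)) * 1e-9
    pos <- which(e$values > tol)
    if (length(pos) == 0L) {
        pts <- matrix(0, n, k, dimnames = list(rownames(D), NULL))
        return(list(points = pts, eig = e$values,
                    varExplained = rep(0, k)))
    }
    if (k > length(pos)) {
        warning("only ", length(pos), " positive eigenvalues; truncating")
        k <- length(pos)
    }
    vec <- e$vectors[, pos[seq_len(k)], drop = FALSE]
    val <- e$values[pos[seq_len(k)]]
    pts <- sweep(vec, 2, sqrt(val), "*")
    for (j in seq_len(ncol(pts))) {
        nz <- which(abs(pts[, j]) > tol)
        if (length(nz) && pts[nz[1], j] < 0) pts[, j] <- -pts[, j]
    }
    rownames(pts) <- rownames(D)
    colnames(pts) <- paste0("Axis", seq_len(k))
    list(points = pts, eig = e$values,
         varExplained = val / sum(e$values[pos]))
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation of the lower-triangle entries, with a one-sided
#' (greater) permutation p-value: rows and columns of `d2` are permuted
#' jointly and `p = (1 + #{perm r >= observed}) / (1 + nPerm)`.
#'
#' @param d1,d2 `dist` objects or symmetric matrices over the same ids in
#'   the same order.
#' @param nPerm number of permutations (>= 99).
#' @param seed RNG seed (required for reproducibility).
#' @return list with `r`, `p` and `nPerm`.
#' @export
mantelTest <- function(d1, d2, nPerm = 999, seed = 1L) {
    stopifnot(nPerm >= 99)
    m1 <- as.matrix(d1); m2 <- as.matrix(d2)
    stopifnot(identical(dim(m1), dim(m2)))
    n <- nrow(m1)
    lt <- lower.tri(m1)
    v1 <- m1[lt]
    if (stats::sd(v1) == 0 || stats::sd(m2[lt]) == 0)
        stop("Mantel r undefined for a constant distance matrix")
    obs <- stats::cor(v1, m2[lt])
    set.seed(seed)
    ge <- 0L
    for (i in seq_len(nPerm)) {
        p <- sample.int(n)
        if (stats::cor(v1, m2[p, p][lt]) >= obs) ge <- ge + 1L
    }
    list(r = obs, p = (1 + ge) / (1 + nPerm), nPerm = nPerm)
}
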