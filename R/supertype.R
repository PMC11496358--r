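#' Five-dimensional amino-acid z-descriptors
#'
#' The extended z-scales: five quantitative physiochemical descriptors per
#' standard amino acid (z1 lipophilicity, z2 steric bulk/polarisability,
#' z3 polarity, z4/z5 electronic effects), derived from principal component
#' analysis of a large panel of measured and computed physiochemical
#' properties of amino acids (Sandberg and co-workers' descriptor set).
#' Shipped as a versioned data file.
#'
#' @return data.frame with rownames the one-letter amino-acid codes and
#'   columns `z1`..`z5`.
#' @export
zDescriptors <- function() {
    path <- system.file("extdata", "z_descriptors.tsv",
                        package = "mhcdepth")
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    rownames(tab) <- tab$aa
    tab[c("z1", "z2", "z3", "z4", "z5")]
}

#' Extract peptide-binding residues from aligned protein sequences
#'
#' @param proteins `AAStringSet` or named character vector of aligned
#'   allele protein sequences (equal length).
#' @param positions 1-based residue positions of the peptide-binding
#'   region.
#' @return character matrix alleles x positions of residues. Alleles with a
#'   stop codon (`*`) at any PBR position are excluded with a warning.
#' @export
#' @examples
#' extractPbr(c(a1 = "MKV", a2 = "MRV"), c(1, 3))
extractPbr <- function(proteins, positions) {
    if (length(positions) == 0L) stop("empty position list")
    seqs <- stats::setNames(as.character(proteins), names(proteins))
    L <- unique(nchar(seqs))
    if (length(L) != 1L) stop("protein sequences must be aligned (equal length)")
    if (any(positions < 1L | positions > L))
        stop("PBR position out of range for alignment of length ", L)
    mat <- t(vapply(seqs, function(s)
        substring(s, positions, positions), character(length(positions))))
    if (length(positions) == 1L) mat <- matrix(mat, ncol = 1L,
                                               dimnames = list(names(seqs)))
    rownames(mat) <- names(seqs)
    colnames(mat) <- paste0("p", positions)
    hasStop <- apply(mat, 1, function(r) any(r == "*"))
    if (any(hasStop)) {
        warning("excluding allele(s) with stop codon in the PBR: ",
                paste(rownames(mat)[hasStop], collapse = ", "))
        mat <- mat[!hasStop, , drop = FALSE]
    }
    mat
}

#' Encode peptide-binding residues with z-descriptors
#'
#' Each residue is replaced by its five z-descriptor values, giving a
#' numeric matrix of `5 x n_positions` columns per allele.
#'
#' @param residues character matrix from [extractPbr()].
#' @return numeric matrix alleles x (positions x 5), with a `positions`
#'   attribute.
#' @export
zEncode <- function(residues) {
    z <- zDescriptors()
    bad <- matrix(!(residues %in% rownames(z)), nrow(residues),
                  dimnames = dimnames(residues))
    if (any(bad)) {
        i <- which(bad, arr.ind = TRUE)[1, ]
        stop("non-standard residue '", residues[bad][1], "' in allele ",
             rownames(residues)[i[1]], " at ", colnames(residues)[i[2]])
    }
    blocks <- lapply(seq_len(ncol(residues)), function(j) {
        m <- as.matrix(z[residues[, j], ])
        colnames(m) <- paste0(colnames(residues)[j], ".", colnames(z))
        m
    })
    out <- do.call(cbind, blocks)
    rownames(out) <- rownames(residues)
    attr(out, "positions") <- colnames(residues)
    out
}

kmeansBicTrace <- function(pcs, maxK, nStarts, iterMax) {
    n <- nrow(pcs)
    nDistinct <- nrow(unique(round(pcs, 10)))
    vapply(seq_len(maxK), function(k) {
        if (k > nDistinct) return(Inf)  # unreachable partition
        wss <- if (k == 1L) sum(scale(pcs, scale = FALSE)^2)
               else suppressWarnings(
                   stats::kmeans(pcs, k, nstart = nStarts,
                                 iter.max = iterMax)$tot.withinss)
        if (wss <= 0) wss <- .Machine$double.eps
        n * log(wss / n) + k * log(n)
    }, numeric(1))
}

#' Select the number of supertype clusters by modal minimum BIC
#'
#' Reduces the z-encoding to `nPca` principal components, runs k-means
#' (with `nStarts` restarts) for each k, scores each k with
#' `BIC(k) = n log(WSS_k / n) + k log(n)`, records the argmin per
#' replicate, and returns the most common argmin across replicates.
#'
#' @param z numeric matrix from [zEncode()].
#' @param nPca principal components retained (capped at
#'   `min(ncol, n - 1)`).
#' @param maxK largest k scored (reduced with a warning when `>= n`).
#' @param nReplicates replicates of the whole procedure.
#' @param nStarts k-means restarts per k.
#' @param iterMax k-means iteration cap.
#' @param seed RNG seed.
#' @return list with `k` (modal argmin), `bicTrace` (replicates x maxK
#'   matrix) and `kPerReplicate`.
#' @export
findClusterK <- function(z, nPca = 30, maxK = 30, nReplicates = 100,
                         nStarts = 50, iterMax = 100, seed = 1L) {
    n <- nrow(z)
    if (n < 2L) stop("need at least two alleles")
    nPca <- min(nPca, ncol(z), n - 1L)
    if (maxK >= n) {
        warning("maxK reduced to ", n - 1L)
        maxK <- n - 1L
    }
    pca <- stats::prcomp(z, center = TRUE, scale. = FALSE)
    pcs <- pca$x[, seq_len(nPca), drop = FALSE]
    set.seed(seed)
    trace <- t(vapply(seq_len(nReplicates), function(r)
        kmeansBicTrace(pcs, maxK, nStarts, iterMax), numeric(maxK)))
    kPer <- apply(trace, 1, which.min)
    tab <- table(kPer)
    k <- as.integer(names(tab)[which.max(tab)])
    list(k = k, bicTrace = trace, kPerReplicate = kPer, pca = pca,
         nPca = nPca)
}

ldaPosteriors <- function(scores, labels) {
    if (nlevels(labels) < 2L) stop("need at least two clusters for LDA")
    keep <- apply(scores, 2, function(v) {
        s <- tapply(v, labels, stats::sd)
        any(s[!is.na(s)] > 1e-10)
    })
    if (!any(keep))
        stop("no within-cluster variation left for the discriminant step")
    fit <- MASS::lda(scores[, keep, drop = FALSE], grouping = labels)
    pr <- stats::predict(fit, scores[, keep, drop = FALSE])
    list(fit = fit, class = pr$class, posterior = pr$posterior)
}

#' Discriminant analysis of principal components
#'
#' PCA-reduces the z-encoding to `nPca` dimensions, then fits a linear
#' discriminant analysis on the cluster labels, retaining all `k - 1`
#' discriminant functions; posterior memberships come from the
#' discriminant-space Gaussian model. `k = 1` returns a degenerate
#' single-cluster model without discriminants.
#'
#' @param z numeric matrix from [zEncode()].
#' @param clusters factor (or vector) of cluster labels per allele.
#' @param nPca principal components retained (must be >= 1 and < number of
#'   alleles).
#' @return a [SupertypeModel-class].
#' @export
dapc <- function(z, clusters, nPca = 15) {
    if (nPca < 1) stop("nPca must be >= 1")
    n <- nrow(z)
    if (nPca >= n) stop("nPca must be smaller than the number of alleles")
    clusters <- droplevels(factor(clusters))
    if (is.null(names(clusters)) && !is.null(rownames(z)))
        names(clusters) <- rownames(z)
    pca <- stats::prcomp(z, center = TRUE, scale. = FALSE)
    nPca <- min(nPca, ncol(pca$x))
    if (nlevels(clusters) == 1L) {
        post <- matrix(1, n, 1, dimnames = list(rownames(z), levels(clusters)))
        return(new("SupertypeModel", k = 1L, assignments = clusters,
                   bicTrace = matrix(numeric(0), 0, 0), nPca = as.integer(nPca),
                   posterior = post, pca = pca, lda = NULL))
    }
    scores <- pca$x[, seq_len(nPca), drop = FALSE]
    res <- tryCatch(ldaPosteriors(scores, clusters), error = function(e) e)
    if (inherits(res, "error")) {
        # clusters separate perfectly (e.g. singletons): no within-cluster
        # variation to model, so the discriminant step collapses to the
        # trivial classifier with hard posteriors
        post <- outer(clusters, levels(clusters), "==") * 1
        dimnames(post) <- list(rownames(z), levels(clusters))
        return(new("SupertypeModel", k = nlevels(clusters),
                   assignments = clusters,
                   bicTrace = matrix(numeric(0), 0, 0),
                   nPca = as.integer(nPca), posterior = post, pca = pca,
                   lda = NULL))
    }
    new("SupertypeModel", k = nlevels(clusters), assignments = clusters,
        bicTrace = matrix(numeric(0), 0, 0), nPca = as.integer(nPca),
        posterior = res$posterior, pca = pca, lda = res$fit)
}

#' Choose the number of PCs by the a-score
#'
#' For each candidate PC count the a-score is the mean over clusters of the
#' observed correct-reassignment proportion minus its expectation under
#' random cluster labels (estimated from `nSim` permutations); the count
#' with the largest a-score is returned. Near-zero scores for every count
#' indicate the clustering carries no signal.
#'
#' @param z numeric matrix from [zEncode()].
#' @param clusters cluster labels per allele.
#' @param pcCounts candidate PC counts (default 1 to `min(n - 2, 20)`).
#' @param nSim label permutations per candidate.
#' @param seed RNG seed.
#' @return list with `best` (optimal PC count) and `scores` (named
#'   a-score per candidate).
#' @export
optimAScore <- function(z, clusters, pcCounts = NULL, nSim = 10, seed = 1L) {
    clusters <- droplevels(factor(clusters))
    n <- nrow(z)
    if (is.null(pcCounts))
        pcCounts <- seq_len(max(1L, min(n - 2L, 20L)))
    pca <- stats::prcomp(z, center = TRUE, scale. = FALSE)
    pcCounts <- pcCounts[pcCounts <= ncol(pca$x)]
    set.seed(seed)
    reassign <- function(labels, npc) {
        scores <- pca$x[, seq_len(npc), drop = FALSE]
        res <- tryCatch(ldaPosteriors(scores, labels),
                        error = function(e) NULL)
        if (is.null(res)) return(NA_real_)
        mean(tapply(res$class == labels, labels, mean))
    }
    scores <- vapply(pcCounts, function(npc) {
        obs <- reassign(clusters, npc)
        null <- vapply(seq_len(nSim), function(i)
            reassign(sample(clusters), npc), numeric(1))
        obs - mean(null, na.rm = TRUE)
    }, numeric(1))
    names(scores) <- pcCounts
    list(best = pcCounts[which.max(scores)], scores = scores)
}

#' Full supertype clustering of class I alleles
#'
#' Runs the complete procedure on allele protein sequences: extract the
#' peptide-binding residues, z-encode them, select k by modal minimum BIC,
#' fit DAPC with `nPca` PCs, tune the PC count with the a-score, and refit.
#'
#' @param proteins aligned allele protein sequences (`AAStringSet` or named
#'   character).
#' @param pbrPositions peptide-binding residue positions.
#' @param nPca PCs for the first DAPC fit.
#' @param maxK,nReplicates,nStarts passed to [findClusterK()].
#' @param seed RNG seed.
#' @return a [SupertypeModel-class] with the BIC trace attached.
#' @export
clusterSupertypes <- function(proteins, pbrPositions, nPca = 15, maxK = 30,
                              nReplicates = 100, nStarts = 50, seed = 1L) {
    res <- extractPbr(proteins, pbrPositions)
    z <- zEncode(res)
    sel <- findClusterK(z, nPca = 30, maxK = maxK,
                        nReplicates = nReplicates, nStarts = nStarts,
                        seed = seed)
    set.seed(seed)
    km <- if (sel$k == 1L) list(cluster = rep(1L, nrow(z)))
          else stats::kmeans(sel$pca$x[, seq_len(sel$nPca), drop = FALSE],
                             sel$k, nstart = nStarts, iter.max = 100)
    clusters <- factor(km$cluster)
    names(clusters) <- rownames(z)
    model <- dapc(z, clusters, nPca = min(nPca, nrow(z) - 1L))
    if (model@k > 1L && !is.null(model@lda)) {
        tuned <- optimAScore(z, clusters, nSim = 10, seed = seed)
        if (length(tuned$best) == 1L && !is.na(tuned$best))
            model <- dapc(z, clusters, nPca = tuned$best)
    }
    model@bicTrace <- sel$bicTrace
    model
}

#' Assign supertypes to alleles and individuals
#'
#' The supertype of an allele is its cluster id. Individual profiles are
#' the multiset of supertypes over the alleles they carry across genes, and
#' the gene-to-supertype map reports which supertypes each gene's alleles
#' fall into (multicopy genes may carry several).
#'
#' @param model a [SupertypeModel-class] whose assignments are named
#'   `gene:allele` (as produced via [alleleDosage()] naming) or plain
#'   allele labels.
#' @param tables list of [AlleleTable-class] used to map alleles to
#'   individuals.
#' @param skipMissing alleles absent from the model (e.g. excluded for a
#'   stop codon in the PBR) are an error by default; `TRUE` drops their
#'   carriers from the profiles with a warning instead.
#' @return list with `alleleSupertypes` (named vector),
#'   `individualProfiles` (individuals x supertypes count matrix) and
#'   `geneSupertypes` (list per gene).
#' @export
assignSupertypes <- function(model, tables, skipMissing = FALSE) {
    st <- stats::setNames(as.character(model@assignments),
                          names(model@assignments))
    inds <- sort(unique(unlist(lapply(tables, function(t)
        t@assignments$individual))))
    levelsSt <- sort(unique(st))
    prof <- matrix(0L, length(inds), length(levelsSt),
                   dimnames = list(inds, paste0("ST", levelsSt)))
    geneMap <- list()
    for (tab in tables) {
        keys <- paste(tab@geneId, tab@assignments$allele, sep = ":")
        alt <- tab@assignments$allele
        lab <- ifelse(keys %in% names(st), keys,
                      ifelse(alt %in% names(st), alt, NA))
        if (anyNA(lab)) {
            if (!skipMissing)
                stop("allele(s) of gene ", tab@geneId,
                     " missing from the model")
            warning(sum(is.na(lab)), " haplotype(s) of gene ", tab@geneId,
                    " carry alleles absent from the model; dropped")
        }
        sup <- st[lab]
        inds2 <- tab@assignments$individual
        for (i in which(!is.na(lab)))
            prof[inds2[i], paste0("ST", sup[i])] <-
                prof[inds2[i], paste0("ST", sup[i])] + 1L
        geneMap[[tab@geneId]] <- sort(unique(unname(sup[!is.na(lab)])))
    }
    list(alleleSupertypes = st, individualProfiles = prof,
         geneSupertypes = geneMap)
}
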