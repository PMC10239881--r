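# Mixed-ploidy method-of-moments coancestry. Per locus with alternate
# frequency p (reference q = 1 - p) and dosage fractions x, y = d / v:
#   theta_l = x y / p + (1 - x)(1 - y) / q - 1
# averaged over pairwise-complete loci and rescaled by sqrt(vx * vy) so the
# expectation is 1 for a non-inbred self-comparison at any ploidy and 0 for
# non-relatives. Values outside [0, 1] are ordinary estimator noise.

#' Ploidy-weighted pooled allele frequencies
#'
#' @param dosageSet a \linkS4class{DosageSet}
#' @return per-site alternate-allele frequency over non-missing calls
#' @export
pooledAlleleFreqs <- function(dosageSet) {
    altAlleleFreq(dosages(dosageSet), ploidy(dosageSet))
}

#' Pairwise mixed-ploidy coancestry matrix
#'
#' Computes the product-moment coancestry for every pair of individuals,
#' using pooled ploidy-weighted allele frequencies (estimated from the
#' full sample unless supplied). Sites with frequency 0 or 1 are excluded;
#' each pair averages over its pairwise-complete loci. The estimate is
#' rescaled by sqrt of the two ploidies so self-relatedness expects 1 for
#' both diploids and tetraploids.
#'
#' @param dosageSet a \linkS4class{DosageSet}
#' @param freqs optional per-site alternate-allele frequencies
#' @return a \linkS4class{CoancestryMatrix}
#' @export
pairwiseCoancestry <- function(dosageSet, freqs = NULL) {
    stopifnot(is(dosageSet, "DosageSet"))
    d <- dosages(dosageSet)
    v <- ploidy(dosageSet)
    if (is.null(freqs)) freqs <- pooledAlleleFreqs(dosageSet)
    stopifnot(length(freqs) == nrow(d))
    use <- !is.na(freqs) & freqs > 0 & freqs < 1
    d <- d[use, , drop = FALSE]
    p <- freqs[use]
    L <- nrow(d); N <- ncol(d)
    x <- sweep(d, 2, v, "/")           # dosage fractions, NA where missing
    obs <- !is.na(x)
    U <- x / sqrt(p);       U[!obs] <- 0
    W <- (1 - x) / sqrt(1 - p); W[!obs] <- 0
    M <- matrix(as.numeric(obs), L, N)
    nShared <- crossprod(M)            # pairwise-complete locus counts
    S <- crossprod(U) + crossprod(W)   # sum_l (xy/p + (1-x)(1-y)/q)
    theta <- S / nShared - 1
    r <- theta * sqrt(outer(v, v))
    r[nShared == 0] <- NA_real_
    if (any(nShared == 0))
        warning("some pairs share zero loci: entries set NA")
    dimnames(r) <- list(colnames(d), colnames(d))
    storage.mode(nShared) <- "integer"
    new("CoancestryMatrix", relatedness = (r + t(r)) / 2, nLoci = nShared)
}

#' Principal coordinates of a relatedness matrix
#'
#' Eigen-decomposes the symmetrised relatedness matrix directly (no
#' distance conversion): coordinates are eigenvectors scaled by the square
#' root of the (non-negative part of the) eigenvalues, and variance
#' explained is each eigenvalue over the sum of positive eigenvalues.
#' Missing entries are imputed with column means before decomposition.
#'
#' @param cm a \linkS4class{CoancestryMatrix} (or symmetric matrix)
#' @param nAxes number of leading axes to return
#' @return list with \code{eigenvalues} (descending), \code{coordinates}
#'   (N x nAxes), \code{varianceExplained}
#' @export
pcoaRelatedness <- function(cm, nAxes = 3) {
    r <- if (is(cm, "CoancestryMatrix")) relatedness(cm) else as.matrix(cm)
    if (nrow(r) != ncol(r)) stop("relatedness matrix must be square")
    if (anyNA(r)) {
        cmeans <- colMeans(r, na.rm = TRUE)
        for (j in seq_len(ncol(r)))
            r[is.na(r[, j]), j] <- cmeans[j]
        message("missing relatedness entries imputed with column means")
    }
    r <- (r + t(r)) / 2
    eg <- eigen(r, symmetric = TRUE)
    nAxes <- min(nAxes, ncol(r))
    lam <- eg$values
    coords <- sweep(eg$vectors[, seq_len(nAxes), drop = FALSE], 2,
                    sqrt(pmax(lam[seq_len(nAxes)], 0)), "*")
    rownames(coords) <- rownames(r)
    posSum <- sum(lam[lam > 0])
    list(eigenvalues = lam,
         coordinates = coords,
         varianceExplained = lam / posSum)
}

#' Rank-sum comparison of two sets of pairwise relatedness values
#'
#' Extracts the relatedness values of two disjoint sets of individual
#' pairs and compares their distributions with a two-sided Wilcoxon
#' (Mann-Whitney) rank-sum test, e.g. tetraploids vs each candidate
#' diploid progenitor pool.
#'
#' @param cm a \linkS4class{CoancestryMatrix}
#' @param pairsA,pairsB 2-column index (or name) matrices of pairs
#' @return list: valuesA, valuesB, statistic, pValue, medianA, medianB
#' @export
groupRelatednessTest <- function(cm, pairsA, pairsB) {
    r <- relatedness(cm)
    getv <- function(p) {
        p <- as.matrix(p)
        if (nrow(p) == 0) stop("empty pair set")
        r[cbind(p[, 1], p[, 2])]
    }
    a <- getv(pairsA); b <- getv(pairsB)
    wt <- suppressWarnings(wilcox.test(a, b, exact = FALSE))
    list(valuesA = a, valuesB = b,
         statistic = unname(wt$statistic), pValue = wt$p.value,
         medianA = median(a, na.rm = TRUE), medianB = median(b, na.rm = TRUE))
}

#' Average-linkage clustering of individuals on 1 - relatedness
#'
#' Utility for ordering heatmap rows; missing entries are imputed with
#' column means as in \code{\link{pcoaRelatedness}}.
#'
#' @param cm a \linkS4class{CoancestryMatrix}
#' @return an \code{hclust} object
#' @export
relatednessClusters <- function(cm) {
    r <- relatedness(cm)
    if (anyNA(r)) {
        cmeans <- colMeans(r, na.rm = TRUE)
        for (j in seq_len(ncol(r))) r[is.na(r[, j]), j] <- cmeans[j]
    }
    hclust(as.dist(1 - (r + t(r)) / 2), method = "average")
}
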