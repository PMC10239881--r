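# Ploidy-aware dosage genotyping from allele read counts: a binomial
# read-count model with per-site sequencing error folded in symmetrically,
# a flat prior over the ploidy+1 genotypes (optionally replaced by an
# empirical-Bayes site-level genotype-frequency prior), and MAP dosage calls.

#' Genotype likelihoods for one read-count observation
#'
#' For dosage d out of ploidy v, the alternate-read count a out of n reads
#' is Binomial with success probability
#' \eqn{(d/v)(1 - e) + (1 - d/v) e}: a true alternate allele read as
#' alternate with probability 1 - e, a true reference allele misread as
#' alternate with probability e.
#'
#' @param a alternate-allele reads
#' @param n total reads
#' @param v ploidy (2 or 4)
#' @param e per-site error rate in [0, 0.5)
#' @return numeric vector of v + 1 unnormalised likelihoods for d = 0..v
#' @export
dosageLikelihoods <- function(a, n, v, e) {
    if (!v %in% c(2, 4)) stop("ploidy must be 2 or 4")
    if (a < 0 || n < 0 || a > n) stop("need 0 <= a <= n")
    if (e < 0 || e >= 0.5) stop("error rate must be in [0, 0.5)")
    d <- 0:v
    p <- (d / v) * (1 - e) + (1 - d / v) * e
    dbinom(a, n, p)
}

#' Posterior dosage under a flat genotype prior
#'
#' With a flat prior the posterior is the normalised likelihood vector.
#' Ties in the MAP call break toward the lower dosage for determinism.
#'
#' @param likelihoods non-negative vector over dosages 0..v
#' @return list with \code{posterior} (sums to 1) and \code{map}
#'   (integer dosage, NA if all likelihoods are zero)
#' @export
posteriorDosage <- function(likelihoods) {
    if (any(likelihoods < 0)) stop("likelihoods must be non-negative")
    s <- sum(likelihoods)
    if (s == 0)
        return(list(posterior = rep(NA_real_, length(likelihoods)),
                    map = NA_integer_))
    post <- likelihoods / s
    list(posterior = post, map = which.max(post) - 1L)
}

#' Per-site sequencing error from pileup base counts
#'
#' The error rate at a biallelic site is the fraction of reads matching
#' neither the reference nor the alternate allele, floored at 1e-3 and
#' capped at 0.49.
#'
#' @param ref,alt,other per-site read counts by base class (vectors ok)
#' @return per-site error rate(s)
#' @export
estimateSiteError <- function(ref, alt, other) {
    tot <- ref + alt + other
    e <- ifelse(tot == 0, 1e-3, other / pmax(tot, 1))
    if (any(tot == 0))
        warning(sum(tot == 0), " site(s) with zero coverage: error set to floor")
    pmin(pmax(e, 1e-3), 0.49)
}

#' Genotype every individual at every site
#'
#' Calls MAP dosage per cell from the binomial likelihoods; cells with
#' total depth not exceeding \code{minDepth} (strict: depth must be
#' > minDepth to be called) are set missing. With
#' \code{prior = "empirical"} a per-site genotype-frequency prior is
#' estimated per ploidy group by iterating prior <- mean posterior until
#' the prior changes by less than \code{tol} (or \code{maxIter}); the
#' default flat prior needs no iteration.
#'
#' @param reads a \linkS4class{ReadCountSet}
#' @param minDepth depth threshold; a cell is called only if depth > this
#' @param prior "flat" or "empirical"
#' @param maxIter,tol empirical-prior iteration controls
#' @return a \linkS4class{DosageSet}; metadata carries the call rate and
#'   iteration count
#' @export
genotypeAll <- function(reads, minDepth = 5, prior = c("flat", "empirical"),
                        maxIter = 10000, tol = 1e-8) {
    stopifnot(is(reads, "ReadCountSet"), minDepth >= 0)
    prior <- match.arg(prior)
    n <- assay(reads, "total"); a <- assay(reads, "alt")
    L <- nrow(n); N <- ncol(n)
    e <- rowData(reads)$errorRate
    if (is.null(e)) e <- rep(1e-3, L)
    v <- ploidy(reads)
    d <- matrix(NA_integer_, L, N)
    iters <- 0L
    for (vp in unique(v)) {
        cols <- which(v == vp)
        nk <- n[, cols, drop = FALSE]; ak <- a[, cols, drop = FALSE]
        # log-likelihood per dosage class, L x n_cols x (vp+1)
        ll <- array(NA_real_, c(L, length(cols), vp + 1))
        for (dd in 0:vp) {
            p <- (dd / vp) * (1 - e) + (1 - dd / vp) * e
            ll[, , dd + 1] <- dbinom(ak, nk, p, log = TRUE)
        }
        pri <- matrix(1 / (vp + 1), L, vp + 1)   # flat prior
        if (prior == "empirical") {
            for (it in seq_len(maxIter)) {
                po <- ll
                for (dd in 0:vp)
                    po[, , dd + 1] <- exp(ll[, , dd + 1] + log(pri[, dd + 1]))
                tot <- po[, , 1]
                for (dd in 1:vp) tot <- tot + po[, , dd + 1]
                newp <- matrix(0, L, vp + 1)
                for (dd in 0:vp)
                    newp[, dd + 1] <- rowMeans(po[, , dd + 1] /
                                               pmax(tot, 1e-300))
                newp <- pmax(newp, 1e-12)
                newp <- newp / rowSums(newp)
                iters <- iters + 1L
                done <- max(abs(pri - newp)) < tol
                pri <- newp
                if (done) break
            }
        }
        # MAP with ties toward lower dosage (first maximum wins)
        flat <- matrix(ll, L * length(cols), vp + 1) +
            log(pri)[rep(seq_len(L), length(cols)), , drop = FALSE]
        map <- matrix(max.col(flat, ties.method = "first") - 1L,
                      L, length(cols))
        map[nk <= minDepth] <- NA_integer_
        d[, cols] <- map
    }
    out <- DosageSet(d, ploidy = v,
                     chrom = rowData(reads)$chrom,
                     pos = rowData(reads)$pos,
                     ref = rowData(reads)$ref,
                     alt_allele = rowData(reads)$alt,
                     qual = rowData(reads)$qual)
    metadata(out)$callRate <- mean(!is.na(d))
    metadata(out)$priorIterations <- iters
    out
}
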