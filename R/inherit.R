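# Inheritance-mode inference for tetraploids: the genotype-frequency vs
# allele-frequency spectrum distinguishes tetrasomic segregation (all five
# dosage classes present at allele frequency 0.5, Binomial(4, p) under HWE)
# from disomic segregation with fixed subgenomes (only the duplex
# heterozygote AATT at frequency 0.5). The qualitative rule is quantified
# as a log-likelihood ratio between the two reference models.

#' Expected dosage-class probabilities under a segregation model
#'
#' Tetrasomic: Binomial(4, p). Disomic extreme (maximal subgenome
#' divergence consistent with mean allele frequency p): the convolution of
#' Binomial(2, p1) and Binomial(2, p2) with p1 = min(2p, 1),
#' p2 = max(2p - 1, 0); at p = 0.5 this is the pure duplex class
#' (0, 0, 1, 0, 0).
#'
#' @param mode "tetrasomic" or "disomic"
#' @param p allele frequency in (0, 1)
#' @return probability vector over dosage classes 0..4 (sums to 1)
#' @export
expectedSpectrum <- function(mode = c("tetrasomic", "disomic"), p) {
    mode <- match.arg(mode)
    if (!is.finite(p) || p <= 0 || p >= 1) stop("p must lie in (0,1)")
    if (mode == "tetrasomic") return(dbinom(0:4, 4, p))
    p1 <- min(2 * p, 1); p2 <- max(2 * p - 1, 0)
    g1 <- dbinom(0:2, 2, p1); g2 <- dbinom(0:2, 2, p2)
    out <- numeric(5)
    for (i in 0:2) for (j in 0:2) out[i + j + 1] <- out[i + j + 1] +
        g1[i + 1] * g2[j + 1]
    out
}

#' Genotype-frequency spectrum of a tetraploid sample
#'
#' Individuals are restricted to non-introgressed tetraploids (maximum q
#' at least \code{purity}); per retained site the allele frequency over
#' those individuals places the site in a half-open frequency bin, and
#' the observed dosage-class proportions accumulate per bin.
#'
#' @param dosageSet a \linkS4class{DosageSet} (tetraploids are selected
#'   internally)
#' @param fit optional \linkS4class{QMatrix} for the purity filter; when
#'   NULL all tetraploids are used
#' @param purity minimum max-q to keep an individual
#' @param binWidth allele-frequency bin width
#' @return list of class \code{mixploidy_spectrum}: \code{bins}
#'   (data.frame: lo, hi, nLoci, p0..p4), \code{siteAF}, \code{counts}
#'   (per-site dosage-class counts), \code{nIndividuals}
#' @export
buildSpectrum <- function(dosageSet, fit = NULL, purity = 0.9,
                          binWidth = 0.05) {
    stopifnot(is(dosageSet, "DosageSet"), binWidth > 0, binWidth <= 0.5)
    tet <- ploidy(dosageSet) == 4L
    keep <- tet
    if (!is.null(fit)) {
        q <- qvalues(fit)
        stopifnot(nrow(q) == ncol(dosageSet))
        keep <- tet & apply(q, 1, max) >= purity
    }
    if (!any(keep))
        stop("no tetraploid individual passes the purity filter")
    d <- dosages(dosageSet)[, keep, drop = FALSE]
    nObs <- rowSums(!is.na(d))
    af <- rowSums(d, na.rm = TRUE) / (4 * pmax(nObs, 1))
    use <- nObs > 0
    counts <- t(vapply(seq_len(nrow(d)), function(l)
        tabulate(d[l, ] + 1L, nbins = 5L), integer(5)))
    colnames(counts) <- paste0("n", 0:4)
    lo <- seq(0, 1 - binWidth, by = binWidth)
    hi <- lo + binWidth
    bin <- pmin(findInterval(af, lo), length(lo))  # half-open [lo, hi)
    bins <- data.frame(lo = lo, hi = hi, nLoci = 0L,
                       p0 = NA_real_, p1 = NA_real_, p2 = NA_real_,
                       p3 = NA_real_, p4 = NA_real_)
    for (b in seq_along(lo)) {
        sel <- use & bin == b
        bins$nLoci[b] <- sum(sel)
        if (any(sel)) {
            tot <- colSums(counts[sel, , drop = FALSE])
            bins[b, paste0("p", 0:4)] <- tot / sum(tot)
        }
    }
    structure(list(bins = bins, siteAF = af, counts = counts,
                   used = use, binWidth = binWidth,
                   nIndividuals = sum(keep)),
              class = "mixploidy_spectrum")
}

#' Classify inheritance mode from a genotype spectrum
#'
#' Sums, over loci whose allele frequency falls in the central bins
#' (those intersecting [0.4, 0.6]), the log-likelihood of the observed
#' dosage-class counts under the tetrasomic model against the
#' disomic-extreme model at the site's allele frequency. Expected class
#' probabilities are floored at 1e-6 (renormalised) so structural zeros
#' of the disomic extreme stay finite. Mode is tetrasomic when the summed
#' LLR exceeds +lambda, disomic below -lambda, indeterminate otherwise.
#' The count of distinct observed genotype classes in the central bins is
#' reported (all five present is the tetrasomic hallmark; only the duplex
#' class is the fixed-subgenome disomic hallmark).
#'
#' @param spectrum from \code{\link{buildSpectrum}}
#' @param lambda decision threshold in nats
#' @param central allele-frequency interval defining the central bins
#' @return list of class \code{mixploidy_mode_call}: mode, llr, nLoci,
#'   classesObserved
#' @export
classifyMode <- function(spectrum, lambda = 10, central = c(0.4, 0.6)) {
    stopifnot(inherits(spectrum, "mixploidy_spectrum"))
    af <- spectrum$siteAF
    sel <- spectrum$used & af >= central[1] & af < central[2] &
        af > 0 & af < 1
    if (!any(sel))
        return(structure(list(mode = "indeterminate", llr = 0, nLoci = 0L,
                              classesObserved = 0L),
                         class = "mixploidy_mode_call"))
    floorRenorm <- function(p) { p <- pmax(p, 1e-6); p / sum(p) }
    llr <- 0
    for (l in which(sel)) {
        cnt <- spectrum$counts[l, ]
        pT <- floorRenorm(expectedSpectrum("tetrasomic", af[l]))
        pD <- floorRenorm(expectedSpectrum("disomic", af[l]))
        llr <- llr + sum(cnt * (log(pT) - log(pD)))
    }
    classes <- sum(colSums(spectrum$counts[sel, , drop = FALSE]) > 0)
    mode <- if (llr > lambda) "tetrasomic"
            else if (llr < -lambda) "disomic"
            else "indeterminate"
    structure(list(mode = mode, llr = llr, nLoci = sum(sel),
                   classesObserved = as.integer(classes)),
              class = "mixploidy_mode_call")
}

#' @export
print.mixploidy_mode_call <- function(x, ...) {
    cat(sprintf(
        "Inheritance mode: %s (LLR %.1f nats over %d central loci; %d genotype classes observed)\n",
        x$mode, x$llr, x$nLoci, x$classesObserved))
    invisible(x)
}
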