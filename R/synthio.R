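# Synthetic mixed-ploidy populations: cluster frequencies under a
# Balding-Nichols drift model, dosage genotypes under tetrasomic or disomic
# segregation, read counts at ddRAD-like depths, flow-cytometry fluorescence,
# and presence/vote rasters. Everything is deterministic under (config, seed).

# run expr with a locally-seeded RNG, restoring global state afterwards
withSeed <- function(seed, expr) {
    if (!is.null(seed)) {
        old <- if (exists(".Random.seed", envir = globalenv()))
            get(".Random.seed", envir = globalenv()) else NULL
        on.exit({
            if (is.null(old)) {
                if (exists(".Random.seed", envir = globalenv()))
                    rm(".Random.seed", envir = globalenv())
            } else assign(".Random.seed", old, envir = globalenv())
        })
        set.seed(as.integer(seed))
    }
    force(expr)
}

#' Simulation configuration for a mixed-ploidy study design
#'
#' Describes a set of diverged gene pools (diploid and/or tetraploid),
#' optional admixed individuals, the tetraploid segregation mode, and the
#' sequencing and flow-cytometry noise model. The defaults emulate the
#' sampling design the package's analyses assume: two divergent diploid
#' pools plus two tetraploid pools, ddRAD-like read depths, and bimodal
#' relative-fluorescence bands with the tetraploid band at twice the
#' diploid one.
#'
#' @param nClusters number of gene pools
#' @param clusterPloidy integer vector of ploidy (2 or 4) per cluster
#' @param nPerCluster individuals per cluster (recycled)
#' @param nLoci number of biallelic loci
#' @param divergenceF Balding-Nichols drift parameter per cluster, in (0,1)
#' @param progenitor per-cluster index of the gene pool each cluster
#'   drifted from: 0 (default) = the shared ancestral pool, j = cluster
#'   j (which must precede it). Deriving each tetraploid pool from one
#'   diploid cluster reproduces the progenitor-specific relatedness
#'   contrast between tetraploid lineages and their diploid parents
#' @param admixtureSpec list of hybrid specs, each
#'   \code{list(n =, q =, ploidy =)} with \code{q} a length-\code{nClusters}
#'   vector summing to 1
#' @param inheritanceMode per-cluster mode, \code{"tetrasomic"} or
#'   \code{"disomic"}; only meaningful for tetraploid clusters
#' @param subgenomeDivergence in [0,1]: 0 = identical subgenome
#'   frequencies, 1 = fully fixed subgenomes (every site heterozygous
#'   between subgenomes)
#' @param meanDepth mean sequencing depth (reads/site)
#' @param errorRate mean per-site sequencing error
#' @param rfBands named list keyed by ploidy ("2", "4") of
#'   \code{c(mean, sd)} relative-fluorescence bands
#' @param baseFreqRange range of ancestral allele frequencies
#' @param seed integer seed
#' @return a validated list of class \code{mixploidy_sim_config}
#' @export
simConfig <- function(nClusters = 4,
                      clusterPloidy = c(2L, 2L, 4L, 4L),
                      nPerCluster = 25,
                      nLoci = 500,
                      divergenceF = 0.2,
                      progenitor = NULL,
                      admixtureSpec = list(),
                      inheritanceMode = "tetrasomic",
                      subgenomeDivergence = 1,
                      meanDepth = 50,
                      errorRate = 0.01,
                      rfBands = list(`2` = c(6.73, 0.15),
                                     `4` = c(12.2, 0.49)),
                      baseFreqRange = c(0.05, 0.95),
                      seed = 1L) {
    clusterPloidy <- as.integer(rep_len(clusterPloidy, nClusters))
    nPerCluster <- as.integer(rep_len(nPerCluster, nClusters))
    divergenceF <- rep_len(divergenceF, nClusters)
    inheritanceMode <- rep_len(inheritanceMode, nClusters)
    if (is.null(progenitor)) progenitor <- integer(nClusters)
    progenitor <- as.integer(rep_len(progenitor, nClusters))
    if (any(progenitor >= seq_len(nClusters)) || any(progenitor < 0))
        stop("progenitor must be 0 or the index of an earlier cluster")
    stopifnot(all(clusterPloidy %in% c(2L, 4L)),
              all(nPerCluster >= 0),
              all(is.finite(divergenceF)),
              all(divergenceF > 0 & divergenceF < 1),
              meanDepth > 0, errorRate >= 0, errorRate < 0.5,
              subgenomeDivergence >= 0, subgenomeDivergence <= 1,
              all(inheritanceMode %in% c("tetrasomic", "disomic")))
    if (any(inheritanceMode == "disomic" & clusterPloidy == 2L))
        stop("disomic inheritance requested for a diploid cluster")
    for (h in admixtureSpec) {
        stopifnot(is.list(h), h$n >= 1, length(h$q) == nClusters)
        if (abs(sum(h$q) - 1) > 1e-9)
            stop("hybrid q-vector must sum to 1 within 1e-9")
        if (!is.null(h$ploidy)) stopifnot(h$ploidy %in% c(2L, 4L))
    }
    structure(list(nClusters = nClusters, clusterPloidy = clusterPloidy,
                   nPerCluster = nPerCluster, nLoci = as.integer(nLoci),
                   divergenceF = divergenceF, progenitor = progenitor,
                   admixtureSpec = admixtureSpec,
                   inheritanceMode = inheritanceMode,
                   subgenomeDivergence = subgenomeDivergence,
                   meanDepth = meanDepth, errorRate = errorRate,
                   rfBands = rfBands, baseFreqRange = baseFreqRange,
                   seed = as.integer(seed)),
              class = "mixploidy_sim_config")
}

#' Default mixed-ploidy study design
#'
#' Two anciently diverged diploid gene pools (drift F = 0.3 each from the
#' shared ancestor), two younger tetraploid pools (F = 0.15), equal
#' sample sizes, and a handful of diploid hybrids at q = (0.5, 0.5)
#' between the diploid pools. The deep-diploid / shallow-tetraploid
#' divergence contrast mirrors old subspecies splits with recent
#' within-range whole-genome duplication, and balances the information
#' content of successive cluster splits (tetraploids carry twice the
#' allele copies per individual).
#'
#' @param nLoci loci to simulate
#' @param nPerCluster individuals per gene pool
#' @param nHybrids diploid F1-like hybrids between the diploid pools
#' @param seed integer seed
#' @param ... further arguments passed to \code{\link{simConfig}}
#' @return a \code{\link{simConfig}}
#' @export
studyConfig <- function(nLoci = 300, nPerCluster = 15, nHybrids = 6,
                        seed = 1L, ...) {
    simConfig(nClusters = 4, clusterPloidy = c(2L, 2L, 4L, 4L),
              nPerCluster = nPerCluster, nLoci = nLoci,
              divergenceF = c(0.3, 0.3, 0.15, 0.15),
              admixtureSpec = if (nHybrids > 0)
                  list(list(n = nHybrids, q = c(.5, .5, 0, 0),
                            ploidy = 2L)) else list(),
              seed = seed, ...)
}

#' Simulate diverged cluster allele frequencies (Balding-Nichols model)
#'
#' Each cluster's frequency at a locus is drawn from a Beta distribution
#' with mean equal to the ancestral frequency p and variance F p (1 - p),
#' i.e. shape parameters p (1 - F) / F and (1 - p)(1 - F) / F.
#'
#' @param baseFreqs ancestral allele frequencies, each in (0,1)
#' @param divergenceF drift parameter per cluster, each in (0,1)
#' @param seed integer seed
#' @return K x L matrix of cluster allele frequencies
#' @export
simulateClusterFreqs <- function(baseFreqs, divergenceF, seed = NULL) {
    if (!all(is.finite(baseFreqs)) || any(baseFreqs <= 0 | baseFreqs >= 1))
        stop("baseFreqs must be finite and in (0,1)")
    if (!all(is.finite(divergenceF)) ||
        any(divergenceF <= 0 | divergenceF >= 1))
        stop("divergenceF must be finite and in (0,1)")
    L <- length(baseFreqs); K <- length(divergenceF)
    withSeed(seed, {
        out <- matrix(NA_real_, K, L)
        for (k in seq_len(K)) {
            lam <- (1 - divergenceF[k]) / divergenceF[k]
            out[k, ] <- rbeta(L, baseFreqs * lam, (1 - baseFreqs) * lam)
        }
        # guard against numerically degenerate draws
        pmin(pmax(out, 1e-12), 1 - 1e-12)
    })
}

#' Build the ground-truth parameter set for a simulation configuration
#'
#' Draws ancestral frequencies, per-cluster diverged frequencies (and, for
#' disomic clusters, the two subgenome frequencies), and lays out the true
#' per-individual ancestry matrix and ploidy vector: pure cluster members
#' first, then the admixed individuals of \code{admixtureSpec}.
#'
#' For a disomic cluster with subgenome divergence \eqn{\delta}, subgenome
#' frequencies are \eqn{f_1 = f (1 - \delta)} and
#' \eqn{f_2 = f + \delta (1 - f)}: at \eqn{\delta = 1} the subgenomes are
#' fixed for opposite alleles at every site, the allopolyploid extreme.
#'
#' @param config a \code{\link{simConfig}}
#' @return list with \code{trueQ} (N x K), \code{clusterFreqs} (K x L),
#'   \code{subgenomeFreqs} (per-cluster list of 2 x L matrices or NULL),
#'   \code{ploidy}, \code{cluster} (home-cluster index, NA for hybrids),
#'   \code{mode}
#' @export
simulateTruth <- function(config) {
    stopifnot(inherits(config, "mixploidy_sim_config"))
    withSeed(config$seed, {
        L <- config$nLoci; K <- config$nClusters
        base <- runif(L, config$baseFreqRange[1], config$baseFreqRange[2])
        freqs <- matrix(NA_real_, K, L)
        for (k in seq_len(K)) {
            src <- if (config$progenitor[k] == 0L) base
                   else freqs[config$progenitor[k], ]
            freqs[k, ] <- simulateClusterFreqs(
                pmin(pmax(src, 1e-6), 1 - 1e-6),
                config$divergenceF[k], seed = NULL)
        }
        sub <- vector("list", K)
        for (k in seq_len(K)) {
            if (config$inheritanceMode[k] == "disomic") {
                d <- config$subgenomeDivergence
                f <- freqs[k, ]
                sub[[k]] <- rbind(f * (1 - d), f + d * (1 - f))
            }
        }
        nPure <- sum(config$nPerCluster)
        nHyb <- sum(vapply(config$admixtureSpec,
                           function(h) as.integer(h$n), integer(1)))
        N <- nPure + nHyb
        trueQ <- matrix(0, N, K)
        ploidy <- integer(N); cluster <- rep(NA_integer_, N)
        i <- 0L
        for (k in seq_len(K)) {
            idx <- i + seq_len(config$nPerCluster[k])
            trueQ[idx, k] <- 1
            ploidy[idx] <- config$clusterPloidy[k]
            cluster[idx] <- k
            i <- i + config$nPerCluster[k]
        }
        for (h in config$admixtureSpec) {
            idx <- i + seq_len(h$n)
            trueQ[idx, ] <- matrix(h$q, h$n, K, byrow = TRUE)
            ploidy[idx] <- if (is.null(h$ploidy)) 2L else as.integer(h$ploidy)
            i <- i + h$n
        }
        list(trueQ = trueQ, clusterFreqs = freqs, subgenomeFreqs = sub,
             ploidy = ploidy, cluster = cluster,
             mode = config$inheritanceMode, baseFreqs = base)
    })
}

#' Simulate dosage genotypes from a truth set
#'
#' Diploids and tetrasomic tetraploids draw dosage from
#' Binomial(ploidy, pi) with pi the q-weighted mixture of cluster
#' frequencies (each allele copy's cluster of origin drawn independently
#' from q). Pure members of a disomic tetraploid cluster draw the sum of
#' two independent Binomial(2, .) subgenome contributions with no
#' inter-subgenome exchange; admixed tetraploids always segregate
#' tetrasomically.
#'
#' @param config a \code{\link{simConfig}}
#' @param truth output of \code{\link{simulateTruth}}
#' @param seed seed; defaults to \code{config$seed + 1}
#' @return a \linkS4class{DosageSet} with true dosages (no missingness)
#' @export
simulateDosages <- function(config, truth, seed = config$seed + 1L) {
    stopifnot(inherits(config, "mixploidy_sim_config"),
              nrow(truth$trueQ) == length(truth$ploidy))
    L <- config$nLoci; N <- length(truth$ploidy)
    withSeed(seed, {
        d <- matrix(0L, L, N)
        pi_all <- truth$clusterFreqs # K x L
        for (i in seq_len(N)) {
            k <- truth$cluster[i]
            if (!is.na(k) && truth$ploidy[i] == 4L &&
                truth$mode[k] == "disomic") {
                sg <- truth$subgenomeFreqs[[k]]
                d[, i] <- rbinom(L, 2L, sg[1, ]) + rbinom(L, 2L, sg[2, ])
            } else {
                pii <- as.vector(truth$trueQ[i, ] %*% pi_all)
                d[, i] <- rbinom(L, truth$ploidy[i], pii)
            }
        }
        DosageSet(d, ploidy = truth$ploidy)
    })
}

#' Simulate allele read counts from true dosages
#'
#' Per cell, total reads are Poisson(meanDepth); alternate reads are
#' Binomial(n, (d/v)(1 - e) + (1 - d/v) e) with d the true dosage, v the
#' ploidy and e the per-site error rate, folded in symmetrically.
#'
#' @param dosageSet a \linkS4class{DosageSet} of true dosages
#' @param meanDepth mean total depth per site
#' @param errorRate per-site error rate (scalar or length-L vector; stored
#'   per site in the output)
#' @param seed integer seed
#' @return a \linkS4class{ReadCountSet}
#' @export
simulateReads <- function(dosageSet, meanDepth = 50, errorRate = 0.01,
                          seed = NULL) {
    stopifnot(is(dosageSet, "DosageSet"), meanDepth > 0,
              all(errorRate >= 0 & errorRate < 0.5))
    d <- dosages(dosageSet)
    L <- nrow(d); N <- ncol(d)
    v <- matrix(rep(ploidy(dosageSet), each = L), L, N)
    e <- rep_len(errorRate, L)
    withSeed(seed, {
        n <- matrix(rpois(L * N, meanDepth), L, N)
        p <- (d / v) * (1 - e) + (1 - d / v) * e
        a <- matrix(rbinom(L * N, as.vector(n), as.vector(p)), L, N)
        ReadCountSet(n, a, ploidy = ploidy(dosageSet),
                     chrom = rowData(dosageSet)$chrom,
                     pos = rowData(dosageSet)$pos,
                     errorRate = e)
    })
}

#' Simulate replicated flow-cytometry relative-fluorescence measurements
#'
#' Each individual yields \code{replicates} RF values drawn from the
#' Normal band for its ploidy, truncated to be positive.
#'
#' @param ploidyVec per-individual ploidy
#' @param rfBands named list keyed by ploidy of c(mean, sd)
#' @param replicates measurements per individual (at least 2)
#' @param seed integer seed
#' @return data.frame with columns sampleId, ploidyTrue, replicate, rf
#' @export
simulateFluorescence <- function(ploidyVec,
                                 rfBands = list(`2` = c(6.73, 0.15),
                                                `4` = c(12.2, 0.49)),
                                 replicates = 2, seed = NULL) {
    stopifnot(replicates >= 2)
    key <- as.character(ploidyVec)
    if (!all(key %in% names(rfBands)))
        stop("missing fluorescence band for ploidy ",
             paste(setdiff(key, names(rfBands)), collapse = ", "))
    withSeed(seed, {
        n <- length(ploidyVec)
        mu <- vapply(rfBands[key], `[`, numeric(1), 1)
        sg <- vapply(rfBands[key], `[`, numeric(1), 2)
        rf <- matrix(NA_real_, n, replicates)
        for (r in seq_len(replicates)) {
            x <- rnorm(n, mu, sg)
            while (any(x <= 0)) {   # truncate positive by redraw
                bad <- x <= 0
                x[bad] <- rnorm(sum(bad), mu[bad], sg[bad])
            }
            rf[, r] <- x
        }
        data.frame(sampleId = rep(sprintf("ind%03d", seq_len(n)),
                                  each = replicates),
                   ploidyTrue = rep(ploidyVec, each = replicates),
                   replicate = rep(seq_len(replicates), n),
                   rf = as.vector(t(rf)))
    })
}

#' Simulate a pair of presence/vote rasters with controlled overlap
#'
#' Builds two vote grids whose thresholded presence regions have a designed
#' spatial relationship: \code{"disjoint"} (no shared presence),
#' \code{"identical"} (same presence), or \code{"overlap"} with the
#' requested overlap fraction of the union, exact on the designed boolean
#' grid. Present cells carry vote 0.9, absent cells 0.1.
#'
#' @param shape c(nrow, ncol) of the grid
#' @param cellArea cell area in km^2
#' @param pattern "disjoint", "identical" or "overlap"
#' @param overlapFraction designed overlap / union fraction for
#'   pattern = "overlap"
#' @param fillFraction fraction of the grid covered by the union
#' @param seed unused for the deterministic patterns; kept for interface
#'   stability
#' @return list of two \linkS4class{PresenceGrid} objects
#' @export
simulateVoteGrids <- function(shape = c(20, 20), cellArea = 1,
                              pattern = c("overlap", "disjoint", "identical"),
                              overlapFraction = 0.25, fillFraction = 0.5,
                              seed = NULL) {
    pattern <- match.arg(pattern)
    stopifnot(all(shape >= 1), cellArea > 0,
              overlapFraction >= 0, overlapFraction <= 1)
    nc <- prod(shape)
    u <- max(2L, round(nc * fillFraction))   # union size in cells
    a <- matrix(0.1, shape[1], shape[2])
    b <- matrix(0.1, shape[1], shape[2])
    idx <- seq_len(u)                        # row-major run of union cells
    if (pattern == "identical") {
        a[idx] <- 0.9; b[idx] <- 0.9
    } else if (pattern == "disjoint") {
        half <- u %/% 2L
        a[idx[seq_len(half)]] <- 0.9
        b[idx[half + seq_len(u - half)]] <- 0.9
    } else {
        o <- round(u * overlapFraction)      # shared cells
        rest <- u - o
        ha <- rest %/% 2L
        a[idx[seq_len(o + ha)]] <- 0.9
        b[idx[c(seq_len(o), o + ha + seq_len(rest - ha))]] <- 0.9
    }
    list(PresenceGrid(a, cellArea, "contemporary"),
         PresenceGrid(b, cellArea, "contemporary"))
}

#' Simulate diploid parent-offspring duos from a gene pool
#'
#' Parents draw Binomial(2, p) dosages; each offspring inherits one allele
#' sampled from its parent plus one allele drawn from the pool. Used for
#' relatedness-estimator calibration (expected coancestry: self 1,
#' parent-offspring 0.5, unrelated 0 after ploidy rescaling).
#'
#' @param freqs per-locus allele frequencies of the pool
#' @param nPairs number of parent-offspring duos
#' @param seed integer seed
#' @return list with \code{dosages} (a DosageSet; parents first, then
#'   offspring in the same order) and \code{pairs} (2-column index matrix)
#' @export
simulateParentOffspring <- function(freqs, nPairs = 10, seed = NULL) {
    stopifnot(all(freqs > 0 & freqs < 1), nPairs >= 1)
    L <- length(freqs)
    withSeed(seed, {
        par <- matrix(rbinom(L * nPairs, 2L, freqs), L, nPairs)
        fromPar <- matrix(rbinom(L * nPairs, 1L, as.vector(par) / 2), L, nPairs)
        fromPool <- matrix(rbinom(L * nPairs, 1L, freqs), L, nPairs)
        off <- fromPar + fromPool
        list(dosages = DosageSet(cbind(par, off),
                                 ploidy = rep(2L, 2 * nPairs)),
             pairs = cbind(parent = seq_len(nPairs),
                           offspring = nPairs + seq_len(nPairs)))
    })
}
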