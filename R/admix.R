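# Dosage-aware admixture estimation: maximum-likelihood EM on the binomial
# dosage model d_il ~ Binomial(v_i, sum_k q_ik f_kl), the estimand of
# model-based clustering with a polyploid model. Replicate fits across K
# feed Evanno-style delta-K selection, and a q-threshold rule classifies
# introgressed individuals.

EPS_F <- 1e-8   # frequency clip keeping the log-likelihood finite

admixLogLik <- function(D, V, Q, F_, obs) {
    P <- Q %*% F_
    P <- pmin(pmax(P, EPS_F), 1 - EPS_F)
    sum((D * log(P) + (V - D) * log(1 - P))[obs])
}

#' Fit a K-cluster admixture model to a dosage matrix
#'
#' EM on allele-copy ancestries: each of an individual's v allele copies
#' carries a latent cluster of origin; the E-step distributes observed
#' alternate and reference copies over clusters, the M-step re-estimates
#' ancestry proportions q and cluster frequencies f. The log-likelihood is
#' non-decreasing across iterations. Multiple random restarts are run and
#' the best likelihood kept.
#'
#' @param dosageSet a filtered, thinned \linkS4class{DosageSet}
#' @param K number of clusters (>= 1)
#' @param seed integer seed (restart r uses seed + r - 1)
#' @param maxIter maximum EM iterations
#' @param tol relative log-likelihood change at which to stop
#' @param nRestarts random restarts; best final likelihood wins
#' @return a \linkS4class{QMatrix} (slots: q, clusterFreqs, logLik,
#'   converged, seed)
#' @export
fitAdmixture <- function(dosageSet, K, seed = 1L, maxIter = 2000,
                         tol = 1e-8, nRestarts = 1) {
    stopifnot(is(dosageSet, "DosageSet"), K >= 1)
    D <- t(dosages(dosageSet))            # N x L
    N <- nrow(D); L <- ncol(D)
    if (K > N) stop("K cannot exceed the number of individuals")
    v <- ploidy(dosageSet)
    V <- matrix(v, N, L)
    obs <- !is.na(D)
    D0 <- D; D0[!obs] <- 0
    Vm <- V; Vm[!obs] <- 0                # allele copies actually observed
    if (K == 1) {                          # closed form
        f <- colSums(D0) / pmax(colSums(Vm), 1)
        f <- pmin(pmax(f, EPS_F), 1 - EPS_F)
        Q <- matrix(1, N, 1)
        F_ <- matrix(f, 1, L)
        ll <- admixLogLik(D0, V, Q, F_, obs)
        return(new("QMatrix", q = Q, clusterFreqs = F_, logLik = ll,
                   converged = TRUE, seed = as.integer(seed)))
    }
    pooled <- colSums(D0) / pmax(colSums(Vm), 1)
    best <- NULL
    for (r in seq_len(nRestarts)) {
        fit <- withSeed(as.integer(seed) + r - 1L, {
            # init: Dirichlet(1) rows for q, pooled freqs + noise for f
            Q <- matrix(rexp(N * K), N, K)
            Q <- Q / rowSums(Q)
            F_ <- matrix(pmin(pmax(
                rep(pooled, each = K) + rnorm(K * L, 0, 0.1),
                EPS_F), 1 - EPS_F), K, L)
            em <- .admixEM(D0, obs * 1, as.numeric(v), Q, F_,
                           as.integer(maxIter), tol)
            list(Q = em$Q, F_ = em$F, ll = em$ll, conv = em$conv,
                 hist = as.numeric(em$trace),
                 seed = as.integer(seed) + r - 1L)
        })
        if (is.null(best) || fit$ll > best$ll) best <- fit
    }
    q <- best$Q / rowSums(best$Q)         # guard rounding
    rownames(q) <- colnames(dosages(dosageSet))
    new("QMatrix", q = q, clusterFreqs = best$F_, logLik = best$ll,
        converged = best$conv, seed = best$seed, llTrace = best$hist)
}

#' Align cluster labels to a reference by frequency correlation
#'
#' Greedy matching: repeatedly pair the estimated and reference clusters
#' whose allele-frequency vectors correlate best, removing both from the
#' pool. Needed before comparing q matrices across runs (label switching).
#'
#' @param fit a \linkS4class{QMatrix}
#' @param refFreqs K x L reference cluster frequencies (e.g. simulation
#'   truth, or another run's \code{clusterFreqs})
#' @return the permutation p such that estimated cluster p[j] matches
#'   reference cluster j
#' @export
alignClusters <- function(fit, refFreqs) {
    F_ <- clusterFreqs(fit)
    K <- nrow(F_)
    stopifnot(nrow(refFreqs) == K)
    cc <- suppressWarnings(cor(t(F_), t(refFreqs)))  # K_est x K_ref
    cc[!is.finite(cc)] <- -2
    perm <- integer(K)
    for (step in seq_len(K)) {
        ij <- arrayInd(which.max(cc), dim(cc))
        perm[ij[2]] <- ij[1]
        cc[ij[1], ] <- -Inf; cc[, ij[2]] <- -Inf
    }
    perm
}

#' Replicate admixture fits over a range of K
#'
#' Replicates feed the delta-K statistic, whose denominator is the
#' replicate SD of the log-likelihood. A deterministic EM started from
#' random points converges to (near-)identical optima at well-supported
#' K, which degenerates that SD; by default each replicate therefore
#' refits on a random subsample of \code{subsampleFrac} of the loci
#' (with a fresh random start) and rescales its log-likelihood to the
#' full locus count, so replicate spread reflects locus-sampling
#' variance on a scale comparable across K. Set
#' \code{subsampleFrac = 1} for plain restart replicates.
#'
#' @param dosageSet a \linkS4class{DosageSet}
#' @param Ks vector of K values (>= 3 consecutive values for delta-K)
#' @param nReps replicate fits per K (different seeds)
#' @param seed base seed
#' @param subsampleFrac fraction of loci fit per replicate (sampled
#'   without replacement); replicate log-likelihoods are divided by this
#' @param ... passed to \code{\link{fitAdmixture}}
#' @return data.frame with columns K, rep, logLik
#' @export
runAdmixtureScan <- function(dosageSet, Ks = 1:10, nReps = 10,
                             seed = 1L, subsampleFrac = 0.8, ...) {
    L <- nrow(dosageSet)
    stopifnot(subsampleFrac > 0, subsampleFrac <= 1)
    m <- max(2L, round(L * subsampleFrac))
    out <- do.call(rbind, lapply(Ks, function(K) {
        ll <- vapply(seq_len(nReps), function(r) {
            s <- as.integer(seed) + 1000L * K + r
            ds <- if (m < L)
                withSeed(s * 2L + 1L, dosageSet[sort(sample.int(L, m)), ])
            else dosageSet
            fitAdmixture(ds, K, seed = s, ...)@logLik * (L / m)
        }, numeric(1))
        data.frame(K = K, rep = seq_len(nReps), logLik = ll)
    }))
    rownames(out) <- NULL
    out
}

#' Evanno-style delta-K selection of the number of clusters
#'
#' delta-K(K) = |mean L(K+1) - 2 mean L(K) + mean L(K-1)| / sd(L(K)),
#' defined only for interior K with a positive replicate SD; the chosen K
#' maximises delta-K.
#'
#' @param runs data.frame with columns K, logLik (replicates as rows), as
#'   from \code{\link{runAdmixtureScan}}
#' @return list: table (K, meanL, sdL, deltaK), chosenK (NA when no
#'   interior K has a defined, positive delta-K)
#' @export
selectK <- function(runs) {
    stopifnot(all(c("K", "logLik") %in% names(runs)))
    Ks <- sort(unique(runs$K))
    if (length(Ks) < 3) stop("need at least 3 consecutive K values")
    reps <- table(runs$K)
    if (any(reps < 2)) stop("need at least 2 replicates per K")
    meanL <- vapply(Ks, function(k) mean(runs$logLik[runs$K == k]), 0)
    sdL <- vapply(Ks, function(k) sd(runs$logLik[runs$K == k]), 0)
    dK <- rep(NA_real_, length(Ks))
    for (i in seq_along(Ks)[-c(1, length(Ks))]) {
        if (sdL[i] > 0)
            dK[i] <- abs(meanL[i + 1] - 2 * meanL[i] + meanL[i - 1]) / sdL[i]
    }
    tab <- data.frame(K = Ks, meanL = meanL, sdL = sdL, deltaK = dK)
    chosen <- if (all(is.na(dK)) || max(dK, na.rm = TRUE) == 0) NA_integer_
              else Ks[which.max(dK)]
    list(table = tab, chosenK = chosen)
}

#' Threshold-based introgression classification
#'
#' Each individual's home cluster is its argmax-q cluster; at threshold t
#' it counts as introgressed by donor cluster j != home iff q_ij > t
#' (strict). The summary table gives, per (home, donor) pair and
#' threshold, the percentage of the home cluster's individuals that are
#' introgressed.
#'
#' @param fit a \linkS4class{QMatrix}
#' @param thresholds q cut-offs (strict >)
#' @return list: \code{individuals} (data.frame: id, homeCluster, and one
#'   logical column per threshold flagging any-donor introgression),
#'   \code{table} (home, donor, one percentage column per threshold)
#' @export
classifyIntrogression <- function(fit, thresholds = c(0.05, 0.10, 0.15)) {
    q <- qvalues(fit)
    if (nrow(q) == 0) stop("empty q matrix")
    K <- ncol(q)
    home <- max.col(q, ties.method = "first")
    tcols <- paste0("t_", thresholds)
    ind <- data.frame(id = if (is.null(rownames(q)))
                          seq_len(nrow(q)) else rownames(q),
                      homeCluster = home)
    for (j in seq_along(thresholds)) {
        t <- thresholds[j]
        ind[[tcols[j]]] <- vapply(seq_len(nrow(q)), function(i)
            any(q[i, -home[i]] > t), logical(1))
    }
    grid <- expand.grid(home = seq_len(K), donor = seq_len(K))
    grid <- grid[grid$home != grid$donor, ]
    tab <- grid[order(grid$home, grid$donor), ]
    rownames(tab) <- NULL
    for (j in seq_along(thresholds)) {
        t <- thresholds[j]
        tab[[tcols[j]]] <- mapply(function(h, dn) {
            members <- which(home == h)
            if (!length(members)) return(NA_real_)
            100 * mean(q[members, dn] > t)
        }, tab$home, tab$donor)
    }
    list(individuals = ind, table = tab, thresholds = thresholds)
}
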