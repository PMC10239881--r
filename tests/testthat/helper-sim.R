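# shared fixtures built in code
suppressPackageStartupMessages(library(SummarizedExperiment))

# small 4-pool mixed-ploidy design with a handful of diploid hybrids
smallFourPoolConfig <- function(seed = 1L, nLoci = 200, n = 15,
                                divergenceF = 0.3) {
    simConfig(nClusters = 4, clusterPloidy = c(2L, 2L, 4L, 4L),
              nPerCluster = n, nLoci = nLoci, divergenceF = divergenceF,
              admixtureSpec = list(list(n = 6, q = c(.5, .5, 0, 0),
                                        ploidy = 2L)),
              seed = seed)
}

# brute-force per-pair coancestry, deliberately naive (loops, no matrix
# algebra) so it is an independent oracle for pairwiseCoancestry()
bruteCoancestry <- function(d, v, p) {
    N <- ncol(d)
    r <- matrix(NA_real_, N, N)
    for (i in seq_len(N)) for (j in seq_len(N)) {
        th <- c();
        for (l in seq_len(nrow(d))) {
            if (is.na(d[l, i]) || is.na(d[l, j])) next
            if (p[l] <= 0 || p[l] >= 1) next
            x <- d[l, i] / v[i]; y <- d[l, j] / v[j]
            th <- c(th, x * y / p[l] + (1 - x) * (1 - y) / (1 - p[l]) - 1)
        }
        if (length(th))
            r[i, j] <- mean(th) * sqrt(v[i] * v[j])
    }
    r
}
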