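test_that("cluster frequencies follow the drift model's moments", {
    base <- rep(0.4, 2000)
    fr <- simulateClusterFreqs(base, 0.3, seed = 11)
    se <- sqrt(0.3 * 0.4 * 0.6 / 2000)
    expect_lt(abs(mean(fr) - 0.4), 3 * se)
    # near-zero drift collapses onto the base frequencies
    fr0 <- simulateClusterFreqs(base, 1e-4, seed = 11)
    expect_lt(max(abs(fr0 - 0.4)), 0.05)
    expect_error(simulateClusterFreqs(c(0.5, 1.2), 0.3), "0,1")
    expect_error(simulateClusterFreqs(0.5, 0), "divergenceF")
})

test_that("generators are deterministic under a fixed seed", {
    base <- seq(0.1, 0.9, length.out = 50)
    expect_identical(simulateClusterFreqs(base, 0.2, seed = 5),
                     simulateClusterFreqs(base, 0.2, seed = 5))
    cfg <- smallFourPoolConfig(seed = 3, nLoci = 40, n = 4)
    t1 <- simulateTruth(cfg); t2 <- simulateTruth(cfg)
    expect_identical(t1, t2)
    d1 <- simulateDosages(cfg, t1); d2 <- simulateDosages(cfg, t2)
    expect_identical(dosages(d1), dosages(d2))
    r1 <- simulateReads(d1, 30, 0.01, seed = 9)
    r2 <- simulateReads(d2, 30, 0.01, seed = 9)
    expect_identical(assay(r1, "alt"), assay(r2, "alt"))
})

test_that("tetrasomic dosages follow Binomial(4, pi)", {
    L <- 5; n <- 200
    truth <- list(trueQ = matrix(1, n, 1),
                  clusterFreqs = matrix(0.5, 1, L),
                  subgenomeFreqs = list(NULL),
                  ploidy = rep(4L, n), cluster = rep(1L, n),
                  mode = "tetrasomic")
    cfg <- simConfig(nClusters = 1, clusterPloidy = 4L, nPerCluster = n,
                     nLoci = L, divergenceF = 0.2, seed = 2)
    ds <- simulateDosages(cfg, truth, seed = 21)
    expected <- dbinom(0:4, 4, 0.5)
    obs <- tabulate(dosages(ds) + 1L, 5) / (L * n)
    se <- sqrt(expected * (1 - expected) / (L * n))
    expect_true(all(abs(obs - expected) < 3 * se + 1e-9))
    # degenerate pool: pi = 0 means dosage 0 everywhere
    truth0 <- truth; truth0$clusterFreqs <- matrix(1e-12, 1, L)
    expect_true(all(dosages(simulateDosages(cfg, truth0, seed = 1)) == 0))
})

test_that("fully divergent disomic subgenomes give the duplex genotype only", {
    cfg <- simConfig(nClusters = 1, clusterPloidy = 4L, nPerCluster = 50,
                     nLoci = 100, divergenceF = 0.2,
                     inheritanceMode = "disomic", subgenomeDivergence = 1,
                     seed = 4)
    tr <- simulateTruth(cfg)
    expect_true(all(tr$subgenomeFreqs[[1]][1, ] == 0))
    expect_true(all(tr$subgenomeFreqs[[1]][2, ] == 1))
    ds <- simulateDosages(cfg, tr)
    expect_true(all(dosages(ds) == 2L))
    # disomic mode on a diploid cluster is a config error
    expect_error(simConfig(nClusters = 1, clusterPloidy = 2L,
                           inheritanceMode = "disomic"),
                 "diploid")
})

test_that("read simulation respects the error-folded binomial model", {
    d0 <- DosageSet(matrix(0L, 50, 4), ploidy = rep(2L, 4))
    r0 <- simulateReads(d0, 30, 0, seed = 1)
    expect_true(all(assay(r0, "alt") == 0))
    dv <- DosageSet(matrix(4L, 50, 4), ploidy = rep(4L, 4))
    rv <- simulateReads(dv, 30, 0, seed = 1)
    expect_identical(assay(rv, "alt"), assay(rv, "total"))
    # heterozygous duplex: alt fraction centred on 1/2 regardless of e
    dh <- DosageSet(matrix(2L, 10000, 1), ploidy = 4L)
    rh <- simulateReads(dh, 50, 0.01, seed = 7)
    frac <- sum(assay(rh, "alt")) / sum(assay(rh, "total"))
    se <- 0.5 / sqrt(sum(assay(rh, "total")))
    expect_lt(abs(frac - 0.5), 3 * se)
})

test_that("fluorescence draws recover the ploidy band parameters", {
    rf <- simulateFluorescence(rep(2L, 50), replicates = 2, seed = 3)
    se <- 0.15 / sqrt(nrow(rf))
    expect_lt(abs(mean(rf$rf) - 6.73), 3 * se)
    rf4 <- simulateFluorescence(rep(4L, 50), replicates = 2, seed = 3)
    expect_lt(abs(mean(rf4$rf) / mean(rf$rf) - 12.2 / 6.73), 0.05)
    rf0 <- simulateFluorescence(rep(2L, 5),
                                rfBands = list(`2` = c(6.7, 0)),
                                replicates = 3, seed = 1)
    expect_true(all(rf0$rf == 6.7))
    expect_error(simulateFluorescence(c(2L, 4L),
                                      rfBands = list(`2` = c(6.7, .1))),
                 "missing fluorescence band")
})

test_that("vote-grid patterns control the designed overlap exactly", {
    g <- simulateVoteGrids(c(10, 10), pattern = "disjoint")
    cls <- mergeModels(thresholdVotes(g[[1]]), thresholdVotes(g[[2]]))
    expect_equal(unname(areaSummary(cls)["areaCo"]), 0)
    g <- simulateVoteGrids(c(10, 10), pattern = "identical")
    a <- areaSummary(mergeModels(thresholdVotes(g[[1]]),
                                 thresholdVotes(g[[2]])))
    expect_equal(unname(a["areaCo"]), unname(a["total"]))
    g <- simulateVoteGrids(c(20, 20), pattern = "overlap",
                           overlapFraction = 0.25)
    a <- areaSummary(mergeModels(thresholdVotes(g[[1]]),
                                 thresholdVotes(g[[2]])))
    expect_equal(unname(a["areaCo"] / a["total"]), 0.25)
})

test_that("pooled within-cluster frequencies converge on the truth", {
    cfg <- simConfig(nClusters = 2, clusterPloidy = c(2L, 4L),
                     nPerCluster = 150, nLoci = 30, divergenceF = 0.2,
                     seed = 8)
    tr <- simulateTruth(cfg)
    ds <- simulateDosages(cfg, tr)
    for (k in 1:2) {
        idx <- which(tr$cluster == k)
        v <- tr$ploidy[idx][1]
        phat <- rowSums(dosages(ds)[, idx]) / (length(idx) * v)
        se <- sqrt(tr$clusterFreqs[k, ] * (1 - tr$clusterFreqs[k, ]) /
                   (length(idx) * v))
        expect_true(all(abs(phat - tr$clusterFreqs[k, ]) < 3 * se + 1e-9))
    }
})

test_that("hybrid specs are validated and placed after the pure pools", {
    expect_error(simConfig(admixtureSpec = list(list(n = 2,
        q = c(.6, .5, 0, 0)))), "sum to 1")
    cfg <- smallFourPoolConfig(seed = 2, nLoci = 20, n = 5)
    tr <- simulateTruth(cfg)
    expect_equal(nrow(tr$trueQ), 26)
    expect_true(all(abs(rowSums(tr$trueQ) - 1) < 1e-9))
    expect_equal(unname(tr$trueQ[26, ]), c(.5, .5, 0, 0))
})
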