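test_that("expected spectra match the two segregation references", {
    expect_equal(expectedSpectrum("tetrasomic", 0.5),
                 c(1, 4, 6, 4, 1) / 16)
    expect_equal(expectedSpectrum("disomic", 0.5), c(0, 0, 1, 0, 0))
    # mass concentrates on class 0 as p -> 0
    expect_gt(expectedSpectrum("tetrasomic", 1e-4)[1], 0.999)
    for (p in seq(0.05, 0.95, by = 0.09)) {
        expect_equal(sum(expectedSpectrum("tetrasomic", p)), 1)
        expect_equal(sum(expectedSpectrum("disomic", p)), 1)
    }
    expect_error(expectedSpectrum("tetrasomic", 0), "0,1")
})

test_that("tetrasomic spectra near AF 0.5 show all five classes at HWE", {
    cfg <- simConfig(nClusters = 1, clusterPloidy = 4L, nPerCluster = 200,
                     nLoci = 400, divergenceF = 0.05,
                     baseFreqRange = c(0.35, 0.65), seed = 77)
    tr <- simulateTruth(cfg)
    ds <- simulateDosages(cfg, tr)
    sp <- buildSpectrum(ds)
    ctr <- sp$bins[sp$bins$lo >= 0.45 & sp$bins$hi <= 0.55, ]
    tot <- colSums(ctr[, paste0("p", 0:4)] * ctr$nLoci) / sum(ctr$nLoci)
    want <- dbinom(0:4, 4, 0.5)
    nEff <- sum(ctr$nLoci) * sp$nIndividuals
    se <- sqrt(want * (1 - want) / nEff)
    # bin-averaged AF differs a little from 0.5; allow a small buffer
    expect_true(all(abs(tot - want) < 3 * se + 0.02))
})

test_that("fixed-subgenome disomic spectra are pure duplex", {
    cfg <- simConfig(nClusters = 1, clusterPloidy = 4L, nPerCluster = 100,
                     nLoci = 200, divergenceF = 0.2,
                     inheritanceMode = "disomic", subgenomeDivergence = 1,
                     seed = 78)
    tr <- simulateTruth(cfg)
    ds <- simulateDosages(cfg, tr)
    sp <- buildSpectrum(ds)
    ctr <- sp$bins[sp$bins$lo == 0.5, ]
    expect_gt(ctr$nLoci, 0)
    expect_equal(ctr$p2, 1)
})

test_that("purity filtering uses the q matrix and can empty the sample", {
    d <- matrix(2L, 10, 4)
    ds <- DosageSet(d, ploidy = rep(4L, 4))
    q <- matrix(c(.95, .05, .95, .05, .95, .05, .95, .05), 4, 2,
                byrow = TRUE)
    fit <- new("QMatrix", q = q, clusterFreqs = matrix(.5, 2, 10))
    expect_error(buildSpectrum(ds, fit, purity = 0.99), "purity")
    sp <- buildSpectrum(ds, fit, purity = 0.9)
    expect_equal(sp$nIndividuals, 4)
})

test_that("mode classification recovers the generating segregation", {
    cfgA <- simConfig(nClusters = 1, clusterPloidy = 4L, nPerCluster = 200,
                      nLoci = 300, divergenceF = 0.05,
                      baseFreqRange = c(0.3, 0.7), seed = 91)
    trA <- simulateTruth(cfgA)
    spA <- buildSpectrum(simulateDosages(cfgA, trA))
    callA <- classifyMode(spA)
    expect_equal(callA$mode, "tetrasomic")
    expect_equal(callA$classesObserved, 5L)
    expect_gte(callA$nLoci, 50)

    cfgD <- simConfig(nClusters = 1, clusterPloidy = 4L, nPerCluster = 200,
                      nLoci = 300, divergenceF = 0.2,
                      inheritanceMode = "disomic",
                      subgenomeDivergence = 1, seed = 92)
    trD <- simulateTruth(cfgD)
    spD <- buildSpectrum(simulateDosages(cfgD, trD))
    callD <- classifyMode(spD)
    expect_equal(callD$mode, "disomic")
    expect_equal(callD$classesObserved, 1L)
})

test_that("a single ambiguous locus stays indeterminate", {
    # 4 duplex individuals at one central locus: plausible either way
    d <- matrix(c(2L, 2L, 2L, 2L), 1, 4)
    ds <- DosageSet(d, ploidy = rep(4L, 4))
    sp <- buildSpectrum(ds)
    call <- classifyMode(sp, lambda = 10)
    expect_equal(call$mode, "indeterminate")
})

test_that("subgenome homogenisation moves the LLR toward tetrasomic", {
    # near the allopolyploid extreme every loss of subgenome divergence
    # raises the LLR; far from it the extreme-model comparator saturates,
    # so monotonicity is asserted over the decision-relevant range
    llrs <- vapply(c(1, 0.98, 0.95, 0.9), function(delta) {
        cfg <- simConfig(nClusters = 1, clusterPloidy = 4L,
                         nPerCluster = 150, nLoci = 300,
                         divergenceF = 0.05, baseFreqRange = c(0.35, 0.65),
                         inheritanceMode = "disomic",
                         subgenomeDivergence = delta, seed = 55)
        tr <- simulateTruth(cfg)
        classifyMode(buildSpectrum(simulateDosages(cfg, tr)))$llr
    }, numeric(1))
    expect_true(all(diff(llrs) > 0))
    expect_lt(llrs[1], 0)                 # fixed subgenomes: disomic
    expect_gt(llrs[4], 0)                 # mostly homogenised: tetrasomic
})
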