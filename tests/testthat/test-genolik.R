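test_that("dosage likelihoods match the error-folded binomial pmf", {
    lik <- dosageLikelihoods(0, 10, 2, 0)
    expect_equal(lik, c(1, 0.5^10, 0))
    expect_equal(lik[2], 9.765625e-4)
    # heterozygote read probability is exactly 1/2 when e = 0
    expect_equal(dosageLikelihoods(3, 10, 2, 0)[2], dbinom(3, 10, 0.5))
    # direct pmf evaluation over all dosages picks the duplex at 50% reads
    lik4 <- dosageLikelihoods(5, 10, 4, 0.01)
    expect_equal(which.max(lik4) - 1L, 2L)
    expect_error(dosageLikelihoods(11, 10, 2, 0), "a <= n")
    expect_error(dosageLikelihoods(1, 10, 3, 0), "ploidy")
    expect_error(dosageLikelihoods(1, 10, 2, 0.6), "error rate")
})

test_that("flat-prior posterior normalises and breaks ties downward", {
    p <- posteriorDosage(c(1, 0, 0))
    expect_equal(p$posterior, c(1, 0, 0))
    expect_equal(p$map, 0L)
    u <- posteriorDosage(c(1, 1, 1))
    expect_equal(u$posterior, rep(1 / 3, 3))
    expect_equal(u$map, 0L)
    expect_lt(abs(sum(posteriorDosage(dosageLikelihoods(5, 10, 4,
        0.01))$posterior) - 1), 1e-12)
    expect_equal(posteriorDosage(dosageLikelihoods(5, 10, 4, 0.01))$map, 2L)
    miss <- posteriorDosage(c(0, 0, 0))
    expect_true(is.na(miss$map))
})

test_that("site error is the other-base fraction with floor and cap", {
    expect_equal(estimateSiteError(90, 10, 0), 1e-3)
    expect_equal(estimateSiteError(48, 48, 4), 0.04)
    expect_equal(estimateSiteError(0, 0, 10), 0.49)
    expect_warning(e0 <- estimateSiteError(0, 0, 0), "zero coverage")
    expect_equal(e0, 1e-3)
})

test_that("genotypeAll applies strict DP>5 missingness and calls MAP", {
    tot <- matrix(c(5L, 6L, 50L), 3, 1)
    alt <- matrix(c(5L, 6L, 25L), 3, 1)
    rc <- ReadCountSet(tot, alt, ploidy = 4L, errorRate = 0)
    g <- genotypeAll(rc, minDepth = 5)
    d <- dosages(g)
    expect_true(is.na(d[1, 1]))      # depth 5 is not > 5
    expect_equal(d[2, 1], 4L)        # all-alt reads at depth 6
    expect_equal(d[3, 1], 2L)
})

test_that("MAP calls agree with exhaustive enumeration and are symmetric", {
    set.seed(42)
    n <- rpois(2000, 30) + 1L
    a <- rbinom(2000, n, runif(2000))
    v <- sample(c(2L, 4L), 2000, TRUE)
    e <- runif(2000, 0, 0.2)
    for (i in sample(2000, 400)) {
        lik <- vapply(0:v[i], function(d)
            dbinom(a[i], n[i], (d / v[i]) * (1 - e[i]) +
                   (1 - d / v[i]) * e[i]), numeric(1))
        oracle <- which.max(lik) - 1L
        expect_equal(posteriorDosage(
            dosageLikelihoods(a[i], n[i], v[i], e[i]))$map, oracle)
        # swapping ref/alt counts mirrors the dosage
        swapped <- posteriorDosage(
            dosageLikelihoods(n[i] - a[i], n[i], v[i], e[i]))$map
        direct <- posteriorDosage(
            dosageLikelihoods(a[i], n[i], v[i], e[i]))$map
        # mirror holds exactly unless the likelihood is tied (then both
        # calls take the lower dosage of their own tie)
        likSw <- vapply(0:v[i], function(d)
            dbinom(n[i] - a[i], n[i], (d / v[i]) * (1 - e[i]) +
                   (1 - d / v[i]) * e[i]), numeric(1))
        if (max(lik) > max(lik[-(direct + 1L)]))
            expect_equal(swapped, v[i] - direct)
    }
})

test_that("dosage recovery improves with depth and is near-perfect at 50x", {
    cfg <- simConfig(nClusters = 2, clusterPloidy = c(2L, 4L),
                     nPerCluster = 20, nLoci = 300, divergenceF = 0.2,
                     seed = 31)
    tr <- simulateTruth(cfg)
    ds <- simulateDosages(cfg, tr)
    err <- vapply(c(5, 20, 50), function(dep) {
        rc <- simulateReads(ds, dep, 0.01, seed = 100 + dep)
        g <- genotypeAll(rc, minDepth = 0)
        mean(dosages(g) != dosages(ds), na.rm = TRUE)
    }, numeric(1))
    expect_true(all(diff(err) < 0))
    # at 50x the residual error is the irreducible overlap between
    # adjacent tetraploid dosage classes (~2% of tetraploid cells)
    expect_lt(err[3], 0.02)
})

test_that("empirical genotype-frequency prior sharpens monomorphic sites", {
    # at a site where nearly all individuals are dosage 0, the empirical
    # prior should not flip clear flat-prior calls
    set.seed(5)
    tot <- matrix(rpois(400, 30) + 6L, 20, 20)
    alt <- matrix(0L, 20, 20); alt[1, 1] <- 2L
    rc <- ReadCountSet(tot, alt, ploidy = rep(2L, 20), errorRate = 0.01)
    gFlat <- genotypeAll(rc, prior = "flat")
    gEB <- genotypeAll(rc, prior = "empirical")
    expect_gte(mean(dosages(gEB) == dosages(gFlat), na.rm = TRUE), 0.95)
    expect_gt(metadata(gEB)$priorIterations, 0)
})
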