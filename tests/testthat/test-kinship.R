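test_that("coancestry matches a brute-force oracle on tiny instances", {
    set.seed(77)
    for (rep in 1:5) {
        N <- sample(2:4, 1); L <- sample(1:3, 1)
        v <- sample(c(2L, 4L), N, TRUE)
        p <- runif(L, 0.2, 0.8)
        d <- matrix(NA_integer_, L, N)
        for (i in seq_len(N)) d[, i] <- rbinom(L, v[i], p)
        d[sample(length(d), 1)] <- NA   # a missing cell
        ds <- DosageSet(d, ploidy = v)
        # tiny instances can leave a pair with zero usable loci, which
        # pairwiseCoancestry flags; the oracle reproduces the NA
        got <- relatedness(suppressWarnings(pairwiseCoancestry(ds,
                                                               freqs = p)))
        want <- bruteCoancestry(d, v, p)
        expect_equal(got, want, tolerance = 1e-12,
                     ignore_attr = TRUE)
    }
})

test_that("a shared homozygous-alternate locus at p=0.5 gives r-hat 2", {
    ds <- DosageSet(matrix(c(2L, 2L), 1, 2), ploidy = c(2L, 2L))
    r <- relatedness(pairwiseCoancestry(ds, freqs = 0.5))
    expect_equal(unname(r[1, 2]), 2)   # theta = 1, scaled by sqrt(2*2)
})

test_that("estimator calibrates to 1 (self), 0.5 (parent-offspring), 0", {
    set.seed(123)
    p <- runif(2000, 0.1, 0.9)
    po <- simulateParentOffspring(p, nPairs = 12, seed = 9)
    r <- relatedness(pairwiseCoancestry(po$dosages, freqs = p))
    selfs <- diag(r)
    pov <- r[po$pairs]
    unrel <- r[cbind(seq(1, 11, 2), seq(2, 12, 2))]  # unrelated parents
    se <- function(x) sd(x) / sqrt(length(x))
    expect_lt(abs(mean(selfs) - 1), 3 * se(selfs) + 0.02)
    expect_lt(abs(mean(pov) - 0.5), 3 * se(pov) + 0.02)
    expect_lt(abs(mean(unrel)), 3 * se(unrel) + 0.02)
})

test_that("tetraploid self-coancestry also expects 1 after rescaling", {
    set.seed(11)
    p <- runif(2000, 0.1, 0.9)
    d <- matrix(rbinom(2000 * 6, 4L, p), 2000, 6)
    ds <- DosageSet(d, ploidy = rep(4L, 6))
    r <- relatedness(pairwiseCoancestry(ds, freqs = p))
    expect_lt(abs(mean(diag(r)) - 1), 0.05)        # unscaled theta = 0.25
    expect_lt(abs(mean(r[upper.tri(r)])), 0.05)
})

test_that("matrix is symmetric and permutation-equivariant", {
    cfg <- smallFourPoolConfig(seed = 6, nLoci = 150, n = 6)
    tr <- simulateTruth(cfg)
    ds <- simulateDosages(cfg, tr)
    cm <- pairwiseCoancestry(ds)
    r <- relatedness(cm)
    expect_equal(r, t(r))
    perm <- sample(ncol(ds))
    r2 <- relatedness(pairwiseCoancestry(ds[, perm]))
    expect_equal(unname(r2), unname(r[perm, perm]), tolerance = 1e-10)
})

test_that("PCoA of block-structured relatedness separates the blocks", {
    pc <- pcoaRelatedness(diag(4), nAxes = 2)
    expect_equal(pc$eigenvalues, rep(1, 4))
    # within = 1, between = 0: the leading eigenpair is degenerate, so
    # assert block separation in the leading plane rather than on a
    # single (rotation-dependent) axis
    blk <- rbind(cbind(matrix(1, 3, 3), matrix(0, 3, 3)),
                 cbind(matrix(0, 3, 3), matrix(1, 3, 3)))
    pc2 <- pcoaRelatedness(blk, nAxes = 2)
    co <- pc2$coordinates
    expect_lt(max(dist(co[1:3, ])), 1e-8)
    expect_lt(max(dist(co[4:6, ])), 1e-8)
    expect_gt(sqrt(sum((co[1, ] - co[4, ])^2)), 1)
    # a touch of between-block relatedness lifts the degeneracy: axis 2
    # then separates the blocks with opposite signs
    blk2 <- blk; blk2[blk2 == 0] <- 0.1
    a2 <- pcoaRelatedness(blk2, nAxes = 2)$coordinates[, 2]
    expect_true(all(sign(a2[1:3]) == sign(a2[1])))
    expect_true(all(sign(a2[4:6]) == -sign(a2[1])))
    expect_true(all(pc2$varianceExplained[1:2] > 0))
    expect_lt(sum(pc2$varianceExplained[1:2]), 1 + 1e-12)
    expect_error(pcoaRelatedness(matrix(1, 2, 3)), "square")
})

test_that("rank-sum comparison behaves under null and shift", {
    set.seed(21)
    r <- matrix(rnorm(40 * 40, 0, 0.05), 40, 40); r <- (r + t(r)) / 2
    cm <- new("CoancestryMatrix", relatedness = r,
              nLoci = matrix(100L, 40, 40))
    pa <- cbind(1:10, 11:20); pb <- cbind(21:30, 31:40)
    null <- groupRelatednessTest(cm, pa, pa)
    expect_equal(null$pValue, 1, tolerance = 1e-6)
    r2 <- r; r2[pa] <- r2[pa] + 0.2; r2 <- (r2 + t(r2)) / 2
    cm2 <- new("CoancestryMatrix", relatedness = r2,
               nLoci = matrix(100L, 40, 40))
    shift <- groupRelatednessTest(cm2, pa, pb)
    expect_lt(shift$pValue, 0.001)
    expect_gt(shift$medianA, shift$medianB)
    expect_error(groupRelatednessTest(cm, pa[0, , drop = FALSE], pb),
                 "empty")
})

test_that("tetraploid lineages are more related to their progenitor pool", {
    cfg <- simConfig(nClusters = 4, clusterPloidy = c(2L, 2L, 4L, 4L),
                     nPerCluster = 12, nLoci = 500, divergenceF = 0.2,
                     progenitor = c(0L, 0L, 1L, 2L), seed = 42)
    tr <- simulateTruth(cfg)
    ds <- simulateDosages(cfg, tr)
    cm <- pairwiseCoancestry(ds)
    tet1 <- which(tr$cluster == 3); dip1 <- which(tr$cluster == 1)
    dip2 <- which(tr$cluster == 2)
    toPool <- function(tet, pool)
        as.matrix(expand.grid(tet, pool))
    res <- groupRelatednessTest(cm, toPool(tet1, dip1), toPool(tet1, dip2))
    expect_gt(res$medianA, res$medianB)
    expect_lt(res$pValue, 0.001)
})
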