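test_that("simulateGamete handles degenerate chromosomes and rejects unphased input", {
    g0 <- genomeSpec("1R", 0, list(c(0, 0, 0)))
    parent <- list(hap1 = c(0L, 0L, 0L), hap2 = c(1L, 1L, 1L))
    set.seed(1)
    for (i in 1:20) {
        gam <- simulateGamete(parent, g0)
        # no crossover possible on a 0 cM chromosome: one haplotype intact
        expect_true(all(gam == 0L) || all(gam == 1L))
    }
    expect_error(simulateGamete(c(0, 1, 0), g0), "phased")
    expect_error(simulateGamete(list(hap1 = c(0, 1), hap2 = c(1, 0)), g0),
                 "marker positions")
})

test_that("recombinant fraction matches the Haldane closed form", {
    set.seed(1)
    g <- genomeSpec("1R", 100, list(c(0, 50)))
    orig <- ryeqtl:::.simulateOrigins(g, 100000L)
    rec <- mean(orig[1L, ] != orig[2L, ])
    expected <- (1 - exp(-1)) / 2            # d = 50 cM, r = (1-e^(-2d/100))/2
    expect_lt(abs(rec - expected), 3 * sqrt(expected * (1 - expected) / 1e5))
    # coincident positions can never recombine
    g2 <- genomeSpec("1R", 100, list(c(25, 25)))
    orig2 <- ryeqtl:::.simulateOrigins(g2, 5000L)
    expect_identical(sum(orig2[1L, ] != orig2[2L, ]), 0L)
})

test_that("neutral F2 segregates 1:2:1 at essentially all markers", {
    set.seed(1)
    f2 <- simulateF2(smallGenome(10), 10000L)
    ds <- distortionScan(f2)
    # expect >= 99% of markers non-significant at alpha = 0.01 (20 markers:
    # allow one exceedance)
    expect_gte(mean(ds$p > 0.01), 0.95)
    expect_lt(abs(mean(calls(f2) == "H") - 0.5), 0.01)
})

test_that("Z pollen selection empties the B class and leaves other chromosomes Mendelian", {
    set.seed(2)
    g <- smallGenome(5)
    sel <- selectionSpec(zLocus = list(chrom = "2R", posCM = 50))
    f2 <- simulateF2(g, 4000L, sel)
    cnt <- genotypeCounts(f2, "2R_M003")
    expect_identical(unname(cnt[["B"]]), 0L)
    expect_lt(abs(cnt[["A"]] - cnt[["H"]]) / 4000, 3 * sqrt(0.25 / 4000) * 2)
    # unlinked chromosome stays 1:2:1
    other <- genotypeCounts(f2, "1R_M003")
    expect_gt(pchisq((other[["A"]] - 1000)^2 / 1000 +
                     (other[["H"]] - 2000)^2 / 2000 +
                     (other[["B"]] - 1000)^2 / 1000, 2, lower.tail = FALSE),
              0.001)
})

test_that("multivalent mode forces co-segregation of the ring trio only", {
    set.seed(3)
    g <- genomeSpec(c("1R", "2R", "6R", "7R"), rep(50, 4), 5)
    sel <- selectionSpec(multivalentChrom = c("2R", "6R", "7R"))
    f2 <- simulateF2(g, 300L, sel)
    tr <- truthRecord(f2)
    ch <- markerChrom(f2)
    mv <- ch %in% c("2R", "6R", "7R")
    for (hap in list(tr$hapEgg, tr$hapPollen)) {
        cs <- colSums(hap[mv, , drop = FALSE])
        # never mixes parental origins within one gamete
        expect_true(all(cs == 0L | cs == sum(mv)))
    }
    scr <- multivalentScreen(f2)
    expect_gt(min(scr$maxCor[c("2R", "6R", "7R"), c("2R", "6R", "7R")],
                  na.rm = TRUE), 0.8)
    expect_lt(max(scr$maxCor["1R", ], na.rm = TRUE), 0.5)
})

test_that("simulation is bit-reproducible from the seed", {
    st1 <- simulateStudy(smallGenome(4), n = 30L, seed = 99L)
    st2 <- simulateStudy(smallGenome(4), n = 30L, seed = 99L)
    expect_identical(calls(genoData(st1)), calls(genoData(st2)))
    expect_identical(phenoData(st1), phenoData(st2))
    st3 <- simulateStudy(smallGenome(4), n = 30L, seed = 100L)
    expect_false(identical(calls(genoData(st1)), calls(genoData(st3))))
})

test_that("F3 selfing respects the stigma and pollen rules", {
    g <- genomeSpec("5R", 50, list(c(0, 25, 50)))
    sel <- selectionSpec(s5Locus = list(chrom = "5R", posCM = 25))
    set.seed(4)
    # parents: exact 1:2:1 at S5
    f2 <- idealizedF2(g, 40, 80, 40)
    f3 <- simulateF3Selfing(f2, sel, famSize = 2L)
    tr <- truthRecord(f3)
    # BB parents (last 40 columns) excluded
    expect_true(all(tr$parents <= 120L))
    expect_identical(ncol(f3), 2L * 120L)
    # offspring of AA parents are all AA at S5
    offAA <- calls(f3)["5R_M002", tr$parents <= 40L]
    expect_true(all(offAA == "A"))
    # pooled S5 genotype ratio ~ 3:2:1
    cnt <- genotypeCounts(f3, "5R_M002")
    p <- cnt / sum(cnt)
    exp_ <- c(A = 3, H = 2, B = 1) / 6
    for (s in names(exp_))
        expect_lt(abs(p[[s]] - exp_[[s]]),
                  3 * sqrt(exp_[[s]] * (1 - exp_[[s]]) / sum(cnt)))
    expect_error(simulateF3Selfing(f2, selectionSpec()), "s5Locus")
})

test_that("phenotype simulation hits the deterministic limit and clips", {
    g <- genomeSpec("1R", 50, list(c(0, 25, 50)))
    set.seed(5)
    f2 <- simulateF2(g, 50L)
    qt <- qtlEffects("t", "1R", 25, effCd = 1, effD = 0)
    des <- oneTraitDesign(mean = 2, sigma2E = 0)
    ph <- simulatePhenotypes(f2, qt, des)
    cd <- cdCodes(f2)[, "1R_M002"]
    expect_equal(ph$value,
                 2 + cd[match(ph$genotype, names(cd))],
                 ignore_attr = TRUE)
    # clipping applies after noise and is recorded
    desClip <- oneTraitDesign(mean = 2, sigma2E = 0, upper = 3)
    ph2 <- simulatePhenotypes(f2, qt, desClip)
    expect_lte(max(ph2$value), 3)
    expect_identical(attr(ph2, "truth")$clipped[["t"]],
                     sum(2 + cd > 3) * 2L)
    expect_error(simulatePhenotypes(f2, qtlEffects("t", "1R", 33, 1), des),
                 "no unique marker")
})

test_that("a shared QTL induces genetic covariance of the planted sign", {
    g <- genomeSpec("1R", 50, list(c(0, 25, 50)))
    set.seed(6)
    f2 <- simulateF2(g, 150L)
    qt <- qtlEffects(c("t1", "t2"), c("1R", "1R"), c(25, 25),
                     effCd = c(1, -2))
    des <- trialDesign(data.frame(trait = c("t1", "t2"), sigma2E = c(0.5, 0.5)))
    ph <- simulatePhenotypes(f2, qt, des)
    gv <- attr(ph, "truth")$geneticValues
    expect_lt(cov(gv[, "t1"], gv[, "t2"]), 0)   # 1 * (-2) * var(cd) < 0
})
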