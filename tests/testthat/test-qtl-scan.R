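test_that("effective marker number from eigenvalue shares", {
    set.seed(1)
    one <- matrix(sample(0:2, 30, TRUE), 30, 1)
    expect_identical(effectiveMarkerNumber(one), 1L)
    thr <- simpleMThreshold(one)
    expect_equal(thr$threshold, 0.05)

    # 10 identical pairs built from mutually orthogonal +-1 patterns:
    # eigenvalues are ten 2's and ten 0's, so 10 components carry all
    # variation
    H <- matrix(1, 16, 16)
    for (i in 0:15) for (j in 0:15)
        H[i + 1, j + 1] <- (-1)^sum(bitwAnd(i, j) %/% 2^(0:4) %% 2)
    pats <- H[, 2:11]                       # orthogonal, balanced columns
    M <- pats[, rep(1:10, each = 2)]        # duplicate each pattern
    expect_identical(effectiveMarkerNumber(M), 10L)
    thr2 <- simpleMThreshold(M)
    expect_equal(thr2$threshold, 0.005)
    expect_equal(thr2$epistasisThreshold, 0.05 / 90)

    # ~independent markers: qEff close to the marker count
    set.seed(2)
    Mi <- matrix(sample(0:2, 1000 * 100, TRUE, prob = c(1, 2, 1)), 1000, 100)
    q <- effectiveMarkerNumber(Mi)
    expect_gte(q, 90L); expect_lte(q, 100L)

    expect_warning(effectiveMarkerNumber(cbind(Mi[, 1:3], const = 1)),
                   "constant")
})

test_that("single-marker scan separates codominant and dominance signals", {
    set.seed(3)
    g <- genomeSpec("1R", 60, list(c(0, 30, 60)))
    f2 <- simulateF2(g, 150L)
    cd <- cdCodes(f2)[, "1R_M002"]
    dd <- dCodes(f2)[, "1R_M002"]

    mkPheno <- function(gv) {
        ids <- colnames(f2)
        expand.grid(genotype = ids, location = "L1",
                    replicate = c("R1", "R2")) |>
            transform(trait = "t",
                      value = gv[match(genotype, ids)] + rnorm(2 * length(ids),
                                                              0, 0.5))
    }
    # pure dominance: A and B classes share a mean, H shifted
    phD <- mkPheno(setNames(2 * dd, names(dd)))
    rowD <- scanSingleMarker(phD, f2, "t", "1R_M002")
    expect_lt(rowD$pD, 1e-8)
    expect_gt(rowD$pCd, 1e-4)      # no additive contrast planted
    expect_equal(rowD$effD, 2, tolerance = 0.15)
    # pure additive signal
    phA <- mkPheno(setNames(1.5 * cd, names(cd)))
    rowA <- scanSingleMarker(phA, f2, "t", "1R_M002")
    expect_lt(rowA$pCd, 1e-10)
    expect_equal(rowA$effCd, 1.5, tolerance = 0.1)
    # incremental statistics add up to the joint 2-df test
    wCd <- qchisq(rowA$pCd, 1, lower.tail = FALSE)
    wD <- qchisq(rowA$pD, 1, lower.tail = FALSE)
    expect_equal(pchisq(wCd + wD, 2, lower.tail = FALSE), rowA$pCdD,
                 tolerance = 1e-8)
    # counts reflect the scanned sample
    expect_equal(rowA$nA + rowA$nH + rowA$nB, 150)
    expect_error(scanSingleMarker(phA, f2, "t", "1R_M002",
                                  cofactors = "1R_M002"), "cofactor")
})

test_that("negative effCd means the inbred-parent allele raises the trait", {
    set.seed(4)
    g <- genomeSpec("1R", 60, list(c(0, 30, 60)))
    f2 <- simulateF2(g, 120L)
    cd <- cdCodes(f2)[, "1R_M002"]
    ids <- colnames(f2)
    ph <- expand.grid(genotype = ids, location = "L1",
                      replicate = c("R1", "R2"))
    ph$trait <- "t"
    # the A allele increases the trait: effect per B copy is negative
    ph$value <- -1 * cd[match(ph$genotype, ids)] + rnorm(nrow(ph), 0, 0.1)
    row <- scanSingleMarker(ph, f2, "t", "1R_M002")
    expect_lt(row$effCd, 0)
    expect_equal(row$effCd, -1, tolerance = 0.1)
})

test_that("an empty heterozygote class flags the dominance term", {
    set.seed(5)
    x <- rbind(m1 = rep(c("A", "B"), 30),
               m2 = sample(c("A", "H", "B"), 60, TRUE, prob = c(1, 2, 1)))
    abh <- abhFrom(x)
    ids <- colnames(calls(abh))
    ph <- expand.grid(genotype = ids, location = "L1",
                      replicate = c("R1", "R2"))
    ph$trait <- "t"
    cd <- cdCodes(abh)[, "m1"]
    ph$value <- cd[match(ph$genotype, ids)] + rnorm(nrow(ph), 0, 0.3)
    row <- scanSingleMarker(ph, abh, "t", "m1")
    expect_true(row$dInestimable)
    expect_identical(row$pD, 1)
    expect_identical(row$nH, 0L)
})

test_that("CM1 picks per-chromosome peaks that pass the threshold", {
    sc <- data.frame(marker = paste0("m", 1:6),
                     chrom = rep(c("1R", "2R", "3R"), each = 2),
                     posCM = rep(c(0, 10), 3),
                     pCdD = c(1e-6, 1e-4, 0.2, 0.3, 1e-3, 1e-8))
    expect_identical(sort(selectCofactorsCM1(sc, 1e-2)),
                     c("m1", "m6"))
    expect_identical(selectCofactorsCM1(sc, 1e-10), character())
})

test_that("CM1 on a simulated multi-QTL trait recovers the planted peaks", {
    set.seed(6)
    genome <- genomeSpec(c("1R", "2R", "3R"), rep(80, 3), 5)
    qt <- qtlEffects(rep("t", 3), c("1R", "2R", "3R"), rep(40, 3),
                     effCd = c(2, 2, 2))
    f2 <- simulateF2(genome, 178L)
    ph <- simulatePhenotypes(f2, qt, oneTraitDesign(sigma2E = 1))
    sc <- scanGenome(ph, f2, "t")
    thr <- simpleMThreshold(f2)
    cof <- selectCofactorsCM1(sc, thr$threshold)
    expect_setequal(cof, c("1R_M003", "2R_M003", "3R_M003"))
    # cofactor scan drops own-chromosome cofactors and never reports a
    # cofactor as its own QTL
    sc2 <- scanGenome(ph, f2, "t", markers = "1R_M003", cofactors = cof,
                      dropSameChromCofactors = TRUE)
    expect_lt(sc2$pCdD, thr$threshold)
})

test_that("CM2 stepwise-BIC selection is sparse, accurate and deterministic", {
    set.seed(7)
    genome <- genomeSpec(c("1R", "2R"), c(80, 80), 5)
    f2 <- simulateF2(genome, 150L)
    cd <- cdCodes(f2)
    # pure noise: empty set
    noise <- setNames(rnorm(150), colnames(f2))
    expect_identical(selectCofactorsCM2(noise, f2), character())
    # one strong QTL
    y <- setNames(2 * cd[, "1R_M003"] + rnorm(150, 0, 0.8), colnames(f2))
    sel <- selectCofactorsCM2(y, f2)
    expect_identical(sel, "1R_M003")
    expect_identical(selectCofactorsCM2(y, f2), sel)   # deterministic
})

test_that("confidence intervals follow the 1-unit log10 drop rule", {
    prof <- data.frame(marker = paste0("m", 1:5), chrom = "1R",
                       posCM = c(0, 10, 20, 30, 40),
                       pCdD = 10^(-c(2, 4, 6, 4, 2)))
    expect_equal(confidenceInterval(prof, "m3"),
                 c(left = 10, right = 30))
    # single-marker chromosome: zero-width interval
    one <- prof[3L, ]
    expect_equal(confidenceInterval(one, "m3"), c(left = 20, right = 20))
    # monotone profile peaking at the end: one-sided
    mono <- data.frame(marker = paste0("m", 1:4), chrom = "1R",
                       posCM = c(0, 10, 20, 30), pCdD = 10^(-(1:4)))
    expect_equal(confidenceInterval(mono, "m4"),
                 c(left = 10, right = 30))
    expect_error(confidenceInterval(prof, "zz"), "peak")
})

test_that("explained genetic variance behaves at its limits", {
    set.seed(8)
    g <- genomeSpec("1R", 60, list(c(0, 30, 60)))
    f2 <- simulateF2(g, 120L)
    qt <- qtlEffects("t", "1R", 30, effCd = 2)
    ph <- simulatePhenotypes(f2, qt, oneTraitDesign(sigma2E = 0.01))
    expect_identical(as.numeric(explainedVariance(ph, f2, "t", character())),
                     0)
    pg <- explainedVariance(ph, f2, "t", "1R_M002")
    expect_gt(pg, 0.95)
    # affine invariance
    ph2 <- ph; ph2$value <- 3 * ph2$value + 10
    pg2 <- explainedVariance(ph2, f2, "t", "1R_M002")
    expect_equal(as.numeric(pg), as.numeric(pg2), tolerance = 1e-3)
})

test_that("explained genetic covariance isolates shared QTL effects", {
    set.seed(9)
    g <- genomeSpec("1R", 60, list(c(0, 30, 60)))
    f2 <- simulateF2(g, 178L)
    # one shared pleiotropic QTL, no polygenic covariance
    qt <- qtlEffects(c("t1", "t2"), c("1R", "1R"), c(30, 30),
                     effCd = c(1.5, 2))
    des <- trialDesign(data.frame(trait = c("t1", "t2"),
                                  sigma2R = c(0.1, 0.1),
                                  sigma2E = c(0.5, 0.5),
                                  sigma2Gres = c(1, 1)))
    ph <- simulatePhenotypes(f2, qt, des)
    pcov <- explainedCovariance(ph, f2, "t1", "t2", "1R_M002")
    expect_equal(as.numeric(pcov), 1, tolerance = 0.3)
    # marker affecting only trait1 under shared polygenics: ~0
    qt1 <- qtlEffects("t1", "1R", 30, effCd = 1.5)
    des2 <- trialDesign(data.frame(trait = c("t1", "t2"),
                                   sigma2R = c(0.1, 0.1),
                                   sigma2E = c(0.5, 0.5),
                                   sigma2Gres = c(2, 2)),
                       polygenicCor = matrix(c(1, .7, .7, 1), 2))
    ph2 <- simulatePhenotypes(f2, qt1, des2)
    pcov2 <- explainedCovariance(ph2, f2, "t1", "t2", "1R_M002")
    expect_lt(abs(pcov2), 0.35)
    expect_identical(as.numeric(
        explainedCovariance(ph2, f2, "t1", "t2", character())), 0)
})

test_that("epistasis scan detects complementary gene action and stays null-calibrated", {
    set.seed(10)
    g <- genomeSpec(c("1R", "2R"), c(60, 60), 3)
    f2 <- simulateF2(g, 178L)
    cd <- cdCodes(f2)
    ids <- colnames(f2)
    ph <- expand.grid(genotype = ids, location = "L1",
                      replicate = c("R1", "R2"))
    ph$trait <- "t"
    # complementary epistasis: effect only when both loci carry >= 1 B
    both <- (cd[, "1R_M002"] >= 1) & (cd[, "2R_M002"] >= 1)
    ph$value <- 2 * both[match(ph$genotype, ids)] + rnorm(nrow(ph), 0, 0.1)
    ep <- epistasisScan(ph, f2, "t", cbind("1R_M002", "2R_M002"), qEff = 6)
    expect_lt(ep$p[ep$term == "m1cd:m2cd"], 0.05)
    # additive two-QTL trait: no interaction survives the pair-adjusted level
    ph$value <- cd[match(ph$genotype, ids), "1R_M002"] +
        cd[match(ph$genotype, ids), "2R_M002"] + rnorm(nrow(ph), 0, 0.5)
    ep0 <- epistasisScan(ph, f2, "t", cbind("1R_M002", "2R_M002"), qEff = 6)
    expect_false(any(ep0$significant))
    expect_identical(nrow(ep0), 4L)        # includes the swapped d:cd test
    expect_error(epistasisScan(ph, f2, "t", cbind("1R_M002", "1R_M002"),
                               qEff = 6), "itself")
})
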