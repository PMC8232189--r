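test_that("REML equals ANOVA method-of-moments on balanced data", {
    set.seed(42)
    ph <- balancedTrial(nG = 60)
    vc <- fitUnivariate(ph, "t", "random")
    expect_equal(varComp(vc), anovaComponents(ph), tolerance = 1e-6)
    expect_true(all(varComp(vc) >= 0))
})

test_that("REML matches lme4 on unbalanced data", {
    skip_if_not_installed("lme4")
    set.seed(43)
    ph <- balancedTrial(nG = 40)
    ph <- ph[-sample(nrow(ph), 25), ]        # knock out plots
    vc <- fitUnivariate(ph, "t", "random")
    m <- lme4::lmer(value ~ (1 | genotype) + (1 | location) +
                        (1 | location:replicate) + (1 | genotype:location),
                    ph, REML = TRUE)
    vl <- as.data.frame(lme4::VarCorr(m))
    ref <- setNames(vl$vcov, vl$grp)
    expect_equal(varComp(vc)[["genotype"]], ref[["genotype"]],
                 tolerance = 1e-4)
    expect_equal(varComp(vc)[["genotype:location"]],
                 ref[["genotype:location"]], tolerance = 1e-3)
    expect_equal(varComp(vc)[["residual"]], ref[["Residual"]],
                 tolerance = 1e-4)
})

test_that("zero-noise data give zero residual and exact BLUEs", {
    consts <- setNames(seq(1, 5, length.out = 20), sprintf("G%03d", 1:20))
    ph <- expand.grid(genotype = names(consts), location = "L1",
                      replicate = c("R1", "R2"))
    ph$trait <- "t"
    ph$value <- consts[ph$genotype]
    vc <- fitUnivariate(ph, "t", "random")
    expect_lt(varComp(vc)[["residual"]], 1e-6)
    bl <- fitUnivariate(ph, "t", "fixed")
    b <- setNames(blues(bl)$blue, blues(bl)$genotype)
    expect_equal(b[names(consts)], consts, tolerance = 1e-6)
})

test_that("BLUEs are translation-equivariant", {
    set.seed(44)
    ph <- balancedTrial(nG = 25)
    b1 <- fitUnivariate(ph, "t", "fixed")
    ph2 <- ph; ph2$value <- ph2$value + 7
    b2 <- fitUnivariate(ph2, "t", "fixed")
    expect_equal(blues(b2)$blue, blues(b1)$blue + 7, tolerance = 1e-4)
    expect_equal(avVD(b2), avVD(b1), tolerance = 1e-4)
})

test_that("non-identifiable fixed-genotype designs are rejected", {
    ph <- data.frame(genotype = sprintf("G%02d", 1:10), location = "L1",
                     replicate = "R1", trait = "t", value = rnorm(10))
    expect_error(fitUnivariate(ph, "t", "fixed"), "residual degrees")
})

test_that("entry-mean heritability formula and its limits", {
    # fertility worked example: single location, two replicates
    expect_equal(round(heritabilityBalanced(313.7, sigma2E = 94.9,
                                            nLocations = 1, nReps = 2), 2),
                 0.87)
    # the same arithmetic written out
    expect_equal(heritability(313.7, 94.9), 313.7 / (313.7 + 94.9 / 2))
    expect_equal(heritability(5, 1e-9), 1, tolerance = 1e-6)
    expect_equal(heritability(0, 2), 0)
    expect_error(heritability(1, 0))
    # monotone in sigma2G, decreasing in avVD
    h <- vapply(1:5, heritability, numeric(1), avVD = 2)
    expect_true(all(diff(h) > 0))
    h2 <- vapply(c(0.5, 1, 2, 4), function(v) heritability(3, v), numeric(1))
    expect_true(all(diff(h2) < 0))
})

test_that("fertility/non-fertility conversion is an involution", {
    x <- c(0, 10, 55.5, 100)
    expect_equal(asFertility(asNonFertility(x)), x)
})

test_that("bivariate fit with zero cross-covariance matches univariate fits", {
    set.seed(45)
    g <- genomeSpec("1R", 50, list(c(0, 25, 50)))
    f2 <- simulateF2(g, 80L)
    des <- trialDesign(data.frame(trait = c("t1", "t2"),
                                  sigma2R = c(0.2, 0.3),
                                  sigma2E = c(1, 2),
                                  sigma2Gres = c(2, 3)))
    ph <- simulatePhenotypes(f2, qtlEffects(character(), character(),
                                            numeric(), numeric()), des)
    bv <- fitBivariate(ph, "t1", "t2", zeroGenCov = TRUE, computeSE = FALSE)
    u1 <- fitUnivariate(ph, "t1", "random")
    u2 <- fitUnivariate(ph, "t2", "random")
    expect_equal(genCov(bv)[1L, 1L], varComp(u1)[["genotype"]],
                 tolerance = 1e-3)
    expect_equal(genCov(bv)[2L, 2L], varComp(u2)[["genotype"]],
                 tolerance = 1e-3)
    expect_equal(bv@resCov[1L, 1L], varComp(u1)[["residual"]],
                 tolerance = 1e-3)
    expect_equal(genCov(bv)[1L, 2L], 0)
})

test_that("bivariate fit recovers a planted genetic correlation", {
    set.seed(46)
    g <- genomeSpec("1R", 50, list(c(0, 25, 50)))
    ests <- replicate(8, {
        f2 <- simulateF2(g, 178L)
        des <- trialDesign(data.frame(trait = c("t1", "t2"),
                                      sigma2R = c(0.1, 0.1),
                                      sigma2E = c(1, 1),
                                      sigma2Gres = c(3, 3)),
                          polygenicCor = matrix(c(1, .5, .5, 1), 2))
        ph <- simulatePhenotypes(f2, qtlEffects(character(), character(),
                                                numeric(), numeric()), des)
        genCor(fitBivariate(ph, "t1", "t2", computeSE = FALSE))
    })
    expect_lt(abs(mean(ests) - 0.5), 0.15)
    # PSD by construction
    expect_true(all(is.finite(ests)) && all(abs(ests) <= 1))
})

test_that("independent traits give a genetic covariance near zero", {
    set.seed(47)
    g <- genomeSpec("1R", 50, list(c(0, 25, 50)))
    cover <- replicate(10, {
        f2 <- simulateF2(g, 100L)
        des <- trialDesign(data.frame(trait = c("t1", "t2"),
                                      sigma2R = c(0.1, 0.1),
                                      sigma2E = c(1, 1),
                                      sigma2Gres = c(2, 2)))
        ph <- simulatePhenotypes(f2, qtlEffects(character(), character(),
                                                numeric(), numeric()), des)
        bv <- fitBivariate(ph, "t1", "t2")
        abs(genCov(bv)[1L, 2L]) < 2 * bv@genCovSE
    })
    expect_gte(mean(cover), 0.8)
})
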