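test_that("ABH encoding follows the parental reference rules", {
    raw <- rbind(
        P1 = c("GG", "NA", "GT", "CC", "AA"),
        P2 = c("TT", "TT", "NA", "CC", "TT"),
        o1 = c("GT", "GG", "GG", "CC", "AA"),
        o2 = c("GG", "TT", "TT", "CC", "AT"),
        o3 = c("TT", "GT", "GT", "CC", "TT"))
    colnames(raw) <- paste0("m", 1:5)
    abh <- encodeAbh(raw)
    # m1: both parents homozygous
    expect_equal(unname(calls(abh)["m1", ]), c("H", "A", "B"))
    # m2: parent1 missing, parent2 = TT is the reference; GG -> A
    expect_equal(unname(calls(abh)["m2", ]), c("A", "B", "H"))
    # m3: parent1 heterozygous, parent2 missing -> dropped
    expect_false("m3" %in% rownames(abh))
    # m4: parents share the same allele -> dropped; m5 kept
    expect_false("m4" %in% rownames(abh))
    log <- S4Vectors::metadata(abh)$encodeLog
    expect_match(log$reason[log$marker == "m3"], "heterozygous")
    expect_error(encodeAbh(raw[-1L, ]), "parent")
})

test_that("non-segregating markers are dropped by encoding", {
    raw <- rbind(P1 = c("GG", "GG"), P2 = c("TT", "TT"),
                 o1 = c("GG", "GT"), o2 = c("GG", "GG"), o3 = c("GG", "TT"))
    colnames(raw) <- c("mono", "seg")
    abh <- encodeAbh(raw)
    expect_identical(rownames(abh), "seg")
})

test_that("missingness filter uses a strict 10% boundary", {
    set.seed(1)
    x <- matrix(sample(c("A", "H", "B"), 3 * 182, TRUE), 3, 182)
    x[1L, seq_len(19)] <- NA      # 19/182 = 10.4% -> dropped
    x[2L, seq_len(18)] <- NA      # 18/182 =  9.9% -> retained
    abh <- abhFrom(x)
    kept <- rownames(filterMissing(abh))
    expect_identical(kept, c("m02", "m03"))
})

test_that("redundancy collapse groups |r| = 1 markers transitively", {
    set.seed(2)
    m1 <- sample(c("A", "H", "B"), 10, TRUE, prob = c(1, 2, 1))
    m3 <- sample(c("A", "H", "B"), 10, TRUE, prob = c(1, 2, 1))
    m4 <- sample(c("A", "H", "B"), 10, TRUE, prob = c(1, 2, 1))
    x <- rbind(m1 = m1, m2 = m1, m3 = m3, m4 = m4, m5 = m4)
    abh <- abhFrom(x)
    cr <- collapseRedundant(abh)
    expect_identical(nrow(cr$abh), 3L)
    expect_identical(sort(unique(cr$groups$group)), 1:3)
    # brute-force oracle: pairwise correlation magnitudes on cd codes
    cd <- cdCodes(abh)
    r <- cor(cd)
    expect_true(all(abs(r[cbind(c("m1", "m4"), c("m2", "m5"))] - 1) < 1e-12))
    # a marker identical up to an extra missing value joins the group and
    # the complete member is kept
    x2 <- rbind(full = m1, gappy = replace(m1, 3L, NA))
    cr2 <- collapseRedundant(abhFrom(x2))
    expect_identical(rownames(cr2$abh), "full")
    # representatives never increase missingness
    nm <- rowSums(is.na(calls(abh)))
    for (g_ in unique(cr$groups$group)) {
        mem <- cr$groups$marker[cr$groups$group == g_]
        rep_ <- unique(cr$groups$representative[cr$groups$group == g_])
        expect_equal(nm[[rep_]], min(nm[mem]))
    }
})

test_that("flank imputation fills agreeing flanks, then the modal state", {
    x <- rbind(g = c("A", NA, "A", NA, "H", NA))
    x <- rbind(x, matrix("A", 3, 6))          # more genotypes for the mode
    x[2:4, 4L] <- c("H", "H", "B")
    rownames(x) <- paste0("g", 1:4)
    abh <- AbhMatrix(t(x), chrom = "1R", posCM = seq(0, 50, 10))
    suppressMessages(imp <- imputeByFlanks(abh))
    y <- calls(imp)
    expect_identical(y["m0002", "g1"], "A")        # agreeing flanks
    expect_identical(y["m0004", "g1"], "H")        # disagreeing -> modal state
    expect_identical(y["m0006", "g1"], "A")        # chromosome end -> modal
    expect_false(anyNA(y))
    expect_identical(S4Vectors::metadata(imp)$imputation$secondPassFilled, 2L)
    # unordered positions are rejected
    bad <- AbhMatrix(t(x), chrom = "1R", posCM = c(0, 30, 10, 20, 40, 50))
    expect_error(imputeByFlanks(bad), "ordered")
})

test_that("distortion scan reproduces hand-computed chi-square values", {
    pad <- function(counts, len = 180)
        c(rep(c("A", "H", "B"), counts), rep(NA, len - sum(counts)))
    x <- rbind(fit = pad(c(45, 90, 45)),
               qtl = pad(c(62, 96, 18)),
               zlike = pad(c(90, 90, 0)))
    abh <- abhFrom(x)
    ds <- distortionScan(abh)
    expect_equal(ds$chi2[1L], 0)
    expect_equal(ds$p[1L], 1)
    # QTL-type counts (62, 96, 18): direct formula with expected (44, 88, 44)
    expect_equal(ds$chi2[2L], 324 / 44 + 64 / 88 + 676 / 44, tolerance = 1e-12)
    expect_equal(ds$p[2L], pchisq(23.45455, 2, lower.tail = FALSE),
                 tolerance = 1e-4)
    # idealized Z pattern (90, 90, 0): (90-45)^2/45 + 0 + 45
    expect_equal(ds$chi2[3L], 90)
    expect_error(distortionScan(abhFrom(rbind(m = rep(NA_character_, 4)))),
                 "zero non-missing")
})

test_that("allele frequencies count the missing class separately", {
    x <- rbind(m = c("A", "A", "H", "H", "B", "B", NA, NA))
    af <- alleleFrequencyProfile(abhFrom(x))
    expect_equal(unlist(af[1L, c("freqA", "freqH", "freqB", "freqMissing")]),
                 c(freqA = 0.25, freqH = 0.25, freqB = 0.25,
                   freqMissing = 0.25))
})

test_that("multivalent screen excludes within-chromosome pairs and stays quiet on neutral data", {
    set.seed(7)
    f2 <- simulateF2(smallGenome(6), 500L)
    scr <- multivalentScreen(f2)
    expect_true(all(is.na(diag(scr$maxCor))))
    expect_identical(nrow(scr$flags), 0L)
})

test_that("QC pipeline is idempotent and recovers a planted unique-marker count", {
    set.seed(8)
    f2 <- simulateF2(smallGenome(8), 120L)
    x <- calls(f2)
    # plant redundancy (4 duplicated markers) and missingness
    dup <- x[c(3L, 7L, 11L, 15L), ]
    rownames(dup) <- paste0("dup", 1:4)
    dup[1L, 1:30] <- NA                     # 25% missing -> filtered out
    x2 <- rbind(x, dup)
    abh <- AbhMatrix(x2, chrom = c(markerChrom(f2), rep("1R", 4)),
                     posCM = c(markerPos(f2), markerPos(f2)[c(3, 7, 11, 15)]))
    filtered <- filterMissing(abh)
    expect_identical(nrow(filtered), nrow(x) + 3L)
    cr <- collapseRedundant(filtered)
    expect_identical(nrow(cr$abh), nrow(x))          # planted unique count
    # re-running changes nothing
    again <- collapseRedundant(filterMissing(cr$abh))
    expect_identical(calls(again$abh), calls(cr$abh))
})

test_that("duplicate genotypes are detected by near-identity", {
    set.seed(9)
    f2 <- simulateF2(smallGenome(10), 20L)
    x <- calls(f2)
    x <- cbind(x, clone = x[, 5L])
    dup <- findDuplicateGenotypes(AbhMatrix(x, chrom = markerChrom(f2),
                                            posCM = markerPos(f2)))
    expect_identical(nrow(dup), 1L)
    expect_setequal(c(dup$genotype1, dup$genotype2),
                    c(colnames(calls(f2))[5L], "clone"))
})

test_that("duplicate genotypes can be dropped one-sided or both-sided", {
    set.seed(10)
    f2 <- simulateF2(smallGenome(10), 15L)
    x <- cbind(calls(f2), clone = calls(f2)[, 4L])
    abh <- AbhMatrix(x, chrom = markerChrom(f2), posCM = markerPos(f2))
    one <- dropDuplicateGenotypes(abh, drop = "one")
    expect_identical(ncol(one), 15L)
    both <- dropDuplicateGenotypes(abh, drop = "both")
    expect_identical(ncol(both), 14L)
    expect_false(any(c(colnames(calls(f2))[4L], "clone") %in% colnames(both)))
})
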