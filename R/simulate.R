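## Meiosis is simulated as a no-interference (Haldane) process: per
## chromosome, crossover count ~ Poisson(length/100), positions uniform,
## starting haplotype equiprobable.  The Kosambi function is used only for
## map estimation downstream; the deliberate mismatch exercises robustness.

# Parental-origin matrix (markers x n) for n independent gametes.
.simulateOrigins <- function(genome, n) {
    out <- vector("list", length(genome@chromNames))
    for (i in seq_along(genome@chromNames)) {
        pos <- genome@markerPos[[i]]
        L <- genome@chromLengths[i]
        k <- length(pos)
        start <- sample(0:1, n, replace = TRUE)
        orig <- matrix(rep(start, each = k), k, n)
        nxo <- rpois(n, L / 100)
        for (g in which(nxo > 0L)) {
            xo <- sort.int(runif(nxo[g], 0, L))
            orig[, g] <- (start[g] + findInterval(pos, xo)) %% 2L
        }
        out[[i]] <- orig
    }
    do.call(rbind, out)
}

#' Simulate a single gamete from a phased parent
#'
#' Draws one haplotype per chromosome from a phased diplotype by simulated
#' meiosis: crossover counts are Poisson with mean `length/100`, crossover
#' positions uniform, no interference.
#'
#' @param parent phased diplotype: `list(hap1=, hap2=)`, each a 0/1 vector
#'   over all marker positions of `genome` (0 = parent-A allele).  Unphased
#'   input (anything else) is rejected.
#' @param genome a [GenomeSpec-class].
#' @return integer 0/1 vector of gamete alleles over all markers.
#' @export
simulateGamete <- function(parent, genome) {
    k <- length(unlist(genome@markerPos))
    if (!is.list(parent) || !all(c("hap1", "hap2") %in% names(parent)))
        stop("parent must be a phased diplotype: list(hap1=, hap2=)")
    if (length(parent$hap1) != k || length(parent$hap2) != k)
        stop("haplotypes must cover all ", k, " marker positions")
    if (!all(unlist(parent) %in% 0:1))
        stop("haplotypes must be 0/1 vectors (phased)")
    s <- .simulateOrigins(genome, 1L)[, 1L]
    ifelse(s == 0L, parent$hap1, parent$hap2)
}

.chromRows <- function(genome) {
    k <- lengths(genome@markerPos)
    split(seq_len(sum(k)), rep(seq_along(k), k))
}

# Logical vector: gamete violates a selection rule.  origins: markers x m.
.gameteInviable <- function(origins, genome, selection, pollen) {
    m <- ncol(origins)
    bad <- rep(FALSE, m)
    if (length(selection@multivalentChrom)) {
        rows <- .chromRows(genome)
        idx <- match(selection@multivalentChrom, genome@chromNames)
        if (anyNA(idx)) stop("multivalent chromosomes not on genome")
        mvRows <- unlist(rows[idx])
        sub <- origins[mvRows, , drop = FALSE]
        cs <- colSums(sub)
        bad <- bad | (cs != 0L & cs != nrow(sub))
    }
    if (pollen && !is.null(selection@zLocus)) {
        zi <- .locusRow(genome, selection@zLocus)
        bad <- bad | (origins[zi, ] == 1L)
    }
    bad
}

.locusRow <- function(genome, locus) {
    ci <- match(locus$chrom, genome@chromNames)
    if (is.na(ci)) stop("selection locus chromosome not on genome: ", locus$chrom)
    off <- c(0L, cumsum(lengths(genome@markerPos)))[ci]
    j <- which(abs(genome@markerPos[[ci]] - locus$posCM) < 1e-9)
    if (length(j) != 1L)
        stop(sprintf("no unique marker at %s:%.3f cM", locus$chrom, locus$posCM))
    off + j
}

# Draw m gametes (F1 parent: hap1 all-A, hap2 all-B), rejection-sampling
# against the selection rules.  For the F1 the allele equals the origin.
.drawF1Gametes <- function(genome, m, selection, pollen) {
    orig <- .simulateOrigins(genome, m)
    repeat {
        bad <- which(.gameteInviable(orig, genome, selection, pollen))
        if (!length(bad)) break
        orig[, bad] <- .simulateOrigins(genome, length(bad))
    }
    orig
}

.originsToCalls <- function(egg, pollen) {
    g <- egg + pollen
    x <- matrix(.ABH_STATES[g + 1L], nrow(g), ncol(g))
    x
}

#' Simulate an F2 population
#'
#' Selfs a fully heterozygous F1 (A/B at every marker): each F2 individual
#' is the union of an egg and a pollen gamete.  If a *Z* locus is set,
#' pollen gametes carrying the B allele there are discarded and redrawn
#' (pollen-side gametophytic selection; eggs are never Z-filtered).  If a
#' multivalent chromosome set is given, any gamete (egg or pollen) whose
#' ring chromosomes do not all derive from one parental haplotype is
#' discarded and redrawn.
#'
#' @param genome a [GenomeSpec-class].
#' @param n number of F2 individuals (>= 1).
#' @param selection a [SelectionSpec-class].
#' @return an [AbhMatrix-class]; `metadata(x)$truth` holds the phased
#'   haplotypes (`hapEgg`, `hapPollen`), the genome, the selection regime
#'   and realized genotype frequencies.
#' @examples
#' set.seed(1)
#' g <- genomeSpec("1R", 100, list(c(0, 50, 100)))
#' f2 <- simulateF2(g, 200)
#' rowMeans(calls(f2) == "H")   # ~0.5
#' @export
simulateF2 <- function(genome, n, selection = selectionSpec()) {
    stopifnot(n >= 1)
    egg <- .drawF1Gametes(genome, n, selection, pollen = FALSE)
    pol <- .drawF1Gametes(genome, n, selection, pollen = TRUE)
    x <- .originsToCalls(egg, pol)
    rownames(x) <- unlist(genome@markerNames)
    colnames(x) <- sprintf("F2_%05d", seq_len(n))
    chrom <- rep(genome@chromNames, lengths(genome@markerPos))
    pos <- unlist(genome@markerPos)
    freq <- cbind(A = rowMeans(x == "A"), H = rowMeans(x == "H"),
                  B = rowMeans(x == "B"))
    truth <- list(generation = "F2", genome = genome, selection = selection,
                  hapEgg = egg, hapPollen = pol, genotypeFreq = freq)
    AbhMatrix(x, chrom = chrom, posCM = pos, truth = truth)
}

#' Simulate pooled F3 progeny by selfing an F2
#'
#' F2 plants homozygous B at *S5* cannot be self-pollinated (the stigma
#' lacks the dominant self-fertility allele) and contribute no offspring.
#' Each selfable plant contributes an equal-sized family whose pollen
#' gametes are Z-filtered (when a *Z* locus is set) and whose egg gametes
#' are unfiltered; families are pooled.  An F2 plant homozygous B at *Z*
#' can emit no compatible pollen and likewise contributes nothing.
#'
#' @param f2 an [AbhMatrix-class] from [simulateF2()] (phased truth needed).
#' @param selection a [SelectionSpec-class]; must include `s5Locus`.
#' @param famSize offspring per selfable parent (default 2).
#' @return an [AbhMatrix-class] of pooled F3 offspring with truth record.
#' @export
simulateF3Selfing <- function(f2, selection, famSize = 2L) {
    truth <- truthRecord(f2)
    if (is.null(truth$hapEgg))
        stop("f2 must carry phased truth (simulated object)")
    if (is.null(selection@s5Locus))
        stop("selection must include s5Locus")
    genome <- truth$genome
    s5 <- .locusRow(genome, selection@s5Locus)
    hap1 <- truth$hapEgg; hap2 <- truth$hapPollen
    s5geno <- hap1[s5, ] + hap2[s5, ]
    selfable <- s5geno < 2L                      # at least one A at S5
    if (!is.null(selection@zLocus)) {
        z <- .locusRow(genome, selection@zLocus)
        selfable <- selfable & (hap1[z, ] + hap2[z, ] < 2L)
    }
    parents <- which(selfable)
    if (!length(parents)) {
        x <- matrix(character(), nrow(f2), 0)
        rownames(x) <- rownames(f2)
        return(AbhMatrix(x, chrom = markerChrom(f2), posCM = markerPos(f2),
                         truth = list(generation = "F3", genome = genome,
                                      parents = integer())))
    }
    pv <- rep(parents, each = famSize)
    m <- length(pv)
    drawParental <- function(filterPollen) {
        s <- .simulateOrigins(genome, m)
        al <- hap1[, pv, drop = FALSE] * (1 - s) + hap2[, pv, drop = FALSE] * s
        if (filterPollen && !is.null(selection@zLocus)) {
            z <- .locusRow(genome, selection@zLocus)
            repeat {
                bad <- which(al[z, ] == 1L)
                if (!length(bad)) break
                s2 <- .simulateOrigins(genome, length(bad))
                al[, bad] <- hap1[, pv[bad], drop = FALSE] * (1 - s2) +
                    hap2[, pv[bad], drop = FALSE] * s2
            }
        }
        al
    }
    egg <- drawParental(FALSE)
    pol <- drawParental(TRUE)
    x <- .originsToCalls(egg, pol)
    rownames(x) <- rownames(f2)
    colnames(x) <- sprintf("F3_%05d", seq_len(m))
    truth3 <- list(generation = "F3", genome = genome, selection = selection,
                   parents = pv, parentIds = colnames(f2)[pv],
                   hapEgg = egg, hapPollen = pol, famSize = famSize)
    AbhMatrix(x, chrom = markerChrom(f2), posCM = markerPos(f2), truth = truth3)
}

#' Simulate plot-level phenotypes under the trial design
#'
#' Genotypic value of individual *i* for a trait:
#' \eqn{g_i = \sum_q (cd_q x_{cd,iq} + d_q x_{d,iq}) + N(0, \sigma^2_{Gres})},
#' with polygenic draws correlated across traits via the design's polygenic
#' correlation.  Plot values add location, replicate-in-location,
#' genotype-by-location and residual draws; optional trait bounds are
#' applied by clipping after noise and the clip count recorded.
#'
#' @param f2 an [AbhMatrix-class].
#' @param qtls data.frame from [qtlEffects()] (may have zero rows); each
#'   locus must coincide with a genotyped marker.
#' @param design a [TrialDesign-class].
#' @return data.frame (`genotype`, `location`, `replicate`, `trait`,
#'   `value`) with attribute `"truth"`: genotypic values, QTL table, clip
#'   counts.
#' @export
simulatePhenotypes <- function(f2, qtls, design) {
    tr <- design@traits
    n <- ncol(f2)
    ids <- colnames(f2)
    K <- nrow(tr)
    ## correlated polygenic deviations
    D <- sqrt(tr$sigma2Gres)
    Sigma <- outer(D, D) * design@polygenicCor
    ev <- eigen(Sigma, symmetric = TRUE)
    Shalf <- ev$vectors %*% (sqrt(pmax(ev$values, 0)) * t(ev$vectors))
    poly <- matrix(rnorm(n * K), n, K) %*% Shalf
    colnames(poly) <- tr$trait
    cd <- cdCodes(f2); dd <- dCodes(f2)
    gvals <- matrix(0, n, K, dimnames = list(ids, tr$trait))
    if (nrow(qtls)) {
        for (q in seq_len(nrow(qtls))) {
            j <- .markerIndex(f2, qtls$chrom[q], qtls$posCM[q])
            t <- match(qtls$trait[q], tr$trait)
            if (is.na(t)) stop("QTL trait not in design: ", qtls$trait[q])
            gvals[, t] <- gvals[, t] +
                qtls$effCd[q] * cd[, j] + qtls$effD[q] * dd[, j]
        }
    }
    gvals <- gvals + poly
    out <- vector("list", K)
    clipped <- integer(K)
    for (t in seq_len(K)) {
        L <- tr$nLocations[t]; R <- tr$nReps[t]
        lEff <- rnorm(L, 0, sqrt(tr$sigma2L[t]))
        rEff <- matrix(rnorm(L * R, 0, sqrt(tr$sigma2R[t])), L, R)
        glEff <- matrix(rnorm(n * L, 0, sqrt(tr$sigma2GL[t])), n, L)
        df <- expand.grid(genotype = seq_len(n), location = seq_len(L),
                          replicate = seq_len(R))
        y <- tr$mean[t] + gvals[df$genotype, t] + lEff[df$location] +
            rEff[cbind(df$location, df$replicate)] +
            glEff[cbind(df$genotype, df$location)] +
            rnorm(nrow(df), 0, sqrt(tr$sigma2E[t]))
        lo <- tr$lower[t]; hi <- tr$upper[t]
        nc <- 0L
        if (!is.na(lo)) { nc <- nc + sum(y < lo); y[y < lo] <- lo }
        if (!is.na(hi)) { nc <- nc + sum(y > hi); y[y > hi] <- hi }
        clipped[t] <- nc
        out[[t]] <- data.frame(genotype = ids[df$genotype],
                               location = paste0("L", df$location),
                               replicate = paste0("R", df$replicate),
                               trait = tr$trait[t], value = y)
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    attr(res, "truth") <- list(geneticValues = gvals, qtls = qtls,
                               clipped = setNames(clipped, tr$trait),
                               design = design)
    res
}

#' Simulate a complete F2 study
#'
#' Convenience wrapper: seeds the RNG, simulates the F2, the phenotypes,
#' and bundles everything with the truth record into a
#' [SimulatedStudy-class] that can be regenerated bit-identically from the
#' seed.
#'
#' @param genome,n,selection passed to [simulateF2()].
#' @param qtls,design passed to [simulatePhenotypes()].
#' @param seed integer seed.
#' @return a [SimulatedStudy-class].
#' @export
simulateStudy <- function(genome = ryeGenome(), n = 178L,
                          selection = selectionSpec(),
                          qtls = qtlEffects(character(), character(),
                                            numeric(), numeric()),
                          design = ryeTrialDesign(), seed = 1L) {
    set.seed(seed)
    geno <- simulateF2(genome, n, selection)
    pheno <- simulatePhenotypes(geno, qtls, design)
    truth <- c(truthRecord(geno),
               list(seed = seed, qtls = qtls, design = design,
                    phenoTruth = attr(pheno, "truth")))
    md <- S4Vectors::metadata(geno); md$truth <- truth
    S4Vectors::metadata(geno) <- md
    new("SimulatedStudy", geno = geno, pheno = pheno, truth = truth)
}
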