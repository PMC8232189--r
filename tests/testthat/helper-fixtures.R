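# Shared fixtures, all built in code.

# small two-chromosome genome with evenly spaced markers
smallGenome <- function(nMarkers = 10L, len = 100, chroms = c("1R", "2R"))
    genomeSpec(chroms, rep(len, length(chroms)), nMarkers)

# AbhMatrix straight from a call matrix (markers x genotypes)
abhFrom <- function(calls, chrom = "1R", posCM = NULL) {
    if (is.null(posCM)) posCM <- seq(0, by = 10, length.out = nrow(calls))
    if (is.null(rownames(calls)))
        rownames(calls) <- sprintf("m%02d", seq_len(nrow(calls)))
    if (is.null(colnames(calls)))
        colnames(calls) <- sprintf("g%03d", seq_len(ncol(calls)))
    AbhMatrix(calls, chrom = chrom, posCM = posCM)
}

# balanced two-location clonal trial drawn from the plot-level model
balancedTrial <- function(nG = 60L, L = 2L, R = 2L,
                          s2g = 3, s2l = 0.5, s2r = 0.3, s2gl = 1,
                          s2e = 1.2, mu = 5) {
    g <- rnorm(nG, 0, sqrt(s2g))
    l <- rnorm(L, 0, sqrt(s2l))
    r <- matrix(rnorm(L * R, 0, sqrt(s2r)), L, R)
    gl <- matrix(rnorm(nG * L, 0, sqrt(s2gl)), nG, L)
    d <- expand.grid(gi = seq_len(nG), li = seq_len(L), ri = seq_len(R))
    data.frame(genotype = sprintf("G%03d", d$gi),
               location = paste0("L", d$li),
               replicate = paste0("R", d$ri), trait = "t",
               value = mu + g[d$gi] + l[d$li] + r[cbind(d$li, d$ri)] +
                   gl[cbind(d$gi, d$li)] +
                   rnorm(nrow(d), 0, sqrt(s2e)))
}

# ANOVA method-of-moments variance components for the balanced trial
anovaComponents <- function(ph) {
    nG <- length(unique(ph$genotype))
    L <- length(unique(ph$location))
    R <- length(unique(ph$replicate))
    m <- anova(lm(value ~ factor(genotype) * factor(location) +
                      factor(location):factor(paste0(location, replicate)),
                  ph))
    MSg <- m["factor(genotype)", "Mean Sq"]
    MSl <- m["factor(location)", "Mean Sq"]
    MSr <- m["factor(location):factor(paste0(location, replicate))", "Mean Sq"]
    MSgl <- m["factor(genotype):factor(location)", "Mean Sq"]
    MSe <- m["Residuals", "Mean Sq"]
    c(genotype = (MSg - MSgl) / (L * R),
      location = (MSl - MSr - MSgl + MSe) / (nG * R),
      `rep:location` = (MSr - MSe) / nG,
      `genotype:location` = (MSgl - MSe) / R,
      residual = MSe)
}

# single-trait TrialDesign shorthand
oneTraitDesign <- function(trait = "t", mean = 0, nLocations = 1L, nReps = 2L,
                           sigma2L = 0, sigma2R = 0, sigma2GL = 0,
                           sigma2E = 1, sigma2Gres = 0,
                           lower = NA_real_, upper = NA_real_) {
    trialDesign(data.frame(trait = trait, mean = mean,
                           nLocations = nLocations, nReps = nReps,
                           sigma2L = sigma2L, sigma2R = sigma2R,
                           sigma2GL = sigma2GL, sigma2E = sigma2E,
                           sigma2Gres = sigma2Gres,
                           lower = lower, upper = upper))
}

# idealized F2 with exact genotype counts at every marker position of a
# one-chromosome genome; phased truth so it can be selfed
idealizedF2 <- function(genome, nAA, nAH, nBB) {
    k <- length(unlist(genome@markerPos))
    n <- nAA + nAH + nBB
    hap1 <- matrix(rep(c(0L, 0L, 1L), c(nAA, nAH, nBB)), k, n, byrow = TRUE)
    hap2 <- matrix(rep(c(0L, 1L, 1L), c(nAA, nAH, nBB)), k, n, byrow = TRUE)
    x <- matrix(c("A", "H", "B")[hap1 + hap2 + 1L], k, n)
    rownames(x) <- unlist(genome@markerNames)
    colnames(x) <- sprintf("F2_%05d", seq_len(n))
    AbhMatrix(x, chrom = rep(genome@chromNames, lengths(genome@markerPos)),
              posCM = unlist(genome@markerPos),
              truth = list(generation = "F2", genome = genome,
                           hapEgg = hap1, hapPollen = hap2))
}
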