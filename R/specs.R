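#' Construct a GenomeSpec
#'
#' @param chromNames chromosome names.
#' @param chromLengths lengths in cM.
#' @param markerPos list of sorted marker positions per chromosome; if a
#'   single integer, that many evenly spaced markers per chromosome.
#' @return a [GenomeSpec-class].
#' @export
genomeSpec <- function(chromNames, chromLengths, markerPos) {
    if (is.numeric(markerPos) && length(markerPos) == 1L)
        markerPos <- lapply(chromLengths, function(L)
            seq(0, L, length.out = markerPos))
    names(markerPos) <- chromNames
    markerNames <- lapply(seq_along(chromNames), function(i)
        sprintf("%s_M%03d", chromNames[i], seq_along(markerPos[[i]])))
    names(markerNames) <- chromNames
    new("GenomeSpec", chromNames = chromNames,
        chromLengths = as.numeric(chromLengths),
        markerPos = markerPos, markerNames = markerNames)
}

#' Default rye genome preset
#'
#' Seven chromosomes `1R`--`7R` of 120 cM with 113 evenly spaced markers
#' each (791 markers in total), mirroring the scale of a rye 10K-chip F2
#' study after redundancy collapse (~789 unique segregating markers).
#'
#' @param nMarkersPerChrom markers per chromosome (default 113).
#' @param chromLength chromosome length in cM (default 120).
#' @return a [GenomeSpec-class].
#' @export
ryeGenome <- function(nMarkersPerChrom = 113L, chromLength = 120) {
    genomeSpec(paste0(1:7, "R"), rep(chromLength, 7), nMarkersPerChrom)
}

#' Construct a SelectionSpec
#'
#' @param zLocus `NULL` or `list(chrom=, posCM=)`: pollen-side gametophytic
#'   self-incompatibility locus *Z*; pollen gametes carrying the B allele
#'   there cannot fertilize.
#' @param s5Locus `NULL` or `list(chrom=, posCM=)`: stigma-side locus *S5*;
#'   plants homozygous B there cannot be self-pollinated (the self-fertility
#'   allele A is dominant on the diploid stigma).
#' @param multivalentChrom character(0) or exactly three chromosome names
#'   forming a ring multivalent whose chromosomes must co-segregate from one
#'   parental species for a gamete to be viable.
#' @return a [SelectionSpec-class].
#' @export
selectionSpec <- function(zLocus = NULL, s5Locus = NULL,
                          multivalentChrom = character()) {
    new("SelectionSpec", zLocus = zLocus, s5Locus = s5Locus,
        multivalentChrom = as.character(multivalentChrom))
}

#' Default rye selection regime
#'
#' *Z* on chromosome 2R (top-arm region) and *S5* on chromosome 5R, at the
#' nearest default-preset marker positions; no multivalent.
#'
#' @param genome a [GenomeSpec-class] whose markers anchor the loci.
#' @return a [SelectionSpec-class].
#' @export
ryeSelection <- function(genome = ryeGenome()) {
    near <- function(chrom, target) {
        p <- genome@markerPos[[chrom]]
        list(chrom = chrom, posCM = p[which.min(abs(p - target))])
    }
    selectionSpec(zLocus = near("2R", 118), s5Locus = near("5R", 42))
}

#' Construct a TrialDesign
#'
#' @param traits data.frame as documented in [TrialDesign-class]; missing
#'   columns are filled with defaults (`nLocations=2`, `nReps=2`, zero
#'   variances, unbounded).
#' @param polygenicCor polygenic correlation matrix across traits.
#' @return a [TrialDesign-class].
#' @export
trialDesign <- function(traits, polygenicCor = NULL) {
    defaults <- list(mean = 0, nLocations = 2L, nReps = 2L, sigma2L = 0,
                     sigma2R = 0, sigma2GL = 0, sigma2E = 0, sigma2Gres = 0,
                     lower = NA_real_, upper = NA_real_)
    for (nm in names(defaults))
        if (!nm %in% colnames(traits)) traits[[nm]] <- defaults[[nm]]
    k <- nrow(traits)
    if (is.null(polygenicCor)) polygenicCor <- diag(k)
    new("TrialDesign", traits = traits, polygenicCor = polygenicCor)
}

#' Default rye trial design preset
#'
#' Perenniality (0--9 regrowth score) assessed at two locations with two
#' clonal replicates each; fertility (0--100 %) at a single location with
#' two replicates.  Variance components follow the magnitudes observed in
#' the motivating rye field trial (perenniality: location 0.22, replicate
#' 0.08, genotype-by-location 1.18, residual 1.39, genetic 3.72; fertility:
#' replicate 2.6, residual 94.9, genetic 313.7).  The genetic variance is
#' supplied as residual polygenic variance `sigma2Gres`; planted QTLs add to
#' it.
#'
#' @param polygenicCor polygenic correlation between the two traits
#'   (default 0.35, a moderate genetic overlap).
#' @return a [TrialDesign-class].
#' @export
ryeTrialDesign <- function(polygenicCor = 0.35) {
    traits <- data.frame(
        trait = c("perenniality", "fertility"),
        mean = c(3, 60),
        nLocations = c(2L, 1L),
        nReps = c(2L, 2L),
        sigma2L = c(0.22, 0),
        sigma2R = c(0.08, 2.6),
        sigma2GL = c(1.18, 0),
        sigma2E = c(1.39, 94.9),
        sigma2Gres = c(3.72, 313.7),
        lower = c(0, 0),
        upper = c(9, 100))
    trialDesign(traits, matrix(c(1, polygenicCor, polygenicCor, 1), 2, 2))
}

#' QTL effect specification table
#'
#' @param trait trait name per QTL.
#' @param chrom chromosome per QTL.
#' @param posCM map position per QTL (must coincide with a marker when used
#'   with [simulatePhenotypes()]).
#' @param effCd additive effect: phenotype units per B-allele copy.
#' @param effD dominance effect: units added to heterozygotes.
#' @return data.frame with one row per QTL.
#' @export
qtlEffects <- function(trait, chrom, posCM, effCd, effD = 0) {
    effD <- rep_len(effD, length(effCd))
    stopifnot(all(is.finite(effCd)), all(is.finite(effD)))
    data.frame(trait = trait, chrom = chrom, posCM = posCM,
               effCd = effCd, effD = effD)
}
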