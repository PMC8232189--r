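#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   rowData
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom stats chisq.test cor dist optim pchisq pnorm pt qt rbinom rnorm
#'   rpois runif sd setNames var complete.cases aggregate
#' @importFrom utils head read.csv write.csv combn
NULL

.ABH_STATES <- c("A", "H", "B")

#' ABH-coded genotype matrix for an F2 intercross
#'
#' `AbhMatrix` is the central exchange object of the package: a
#' \linkS4class{SummarizedExperiment} whose single assay `"calls"` holds
#' character genotype calls in \{`"A"`, `"H"`, `"B"`, `NA`\} with markers as
#' rows and genotypes (individuals) as columns.  `rowData` carries the marker
#' metadata columns `chrom` (linkage group, e.g. `"1R"`--`"7R"`) and `posCM`
#' (map position in centimorgan; may be `NA` before map construction).
#'
#' `A` denotes the homozygote for the inbred annual parent allele, `B` the
#' homozygote for the perennial parent allele and `H` the heterozygote.
#'
#' @slot metadata inherited; simulated objects store a `truth` list there
#'   (phased haplotypes, selection regime, seed) sufficient to regenerate the
#'   study.
#'
#' @seealso [AbhMatrix()] for construction, [calls()], [markerChrom()],
#'   [markerPos()], [cdCodes()], [dCodes()].
#' @export
setClass("AbhMatrix", contains = "SummarizedExperiment")

setValidity("AbhMatrix", function(object) {
    if (!"calls" %in% SummarizedExperiment::assayNames(object))
        return("assay 'calls' is required")
    x <- SummarizedExperiment::assay(object, "calls")
    if (!is.character(x))
        return("assay 'calls' must be a character matrix")
    bad <- !is.na(x) & !(x %in% .ABH_STATES)
    if (any(bad))
        return(sprintf("invalid call symbols: %s",
                       paste(unique(x[bad]), collapse = ", ")))
    rd <- SummarizedExperiment::rowData(object)
    if (!all(c("chrom", "posCM") %in% colnames(rd)))
        return("rowData must contain 'chrom' and 'posCM'")
    if (anyDuplicated(rownames(object)))
        return("marker IDs must be unique")
    if (!is.null(colnames(object)) && anyDuplicated(colnames(object)))
        return("genotype IDs must be unique")
    TRUE
})

#' Marker map specification for a simulated genome
#'
#' Chromosome names and lengths (cM) together with ordered marker positions
#' per chromosome.  The default preset ([ryeGenome()]) mirrors a rye F2
#' mapping study: seven chromosomes `1R`--`7R` of 120 cM, 113 markers each.
#'
#' @slot chromNames character, chromosome names.
#' @slot chromLengths numeric, chromosome lengths in cM (> 0).
#' @slot markerPos named list of sorted numeric vectors, marker positions in
#'   cM within `[0, length]`.
#' @slot markerNames named list of character vectors, marker IDs.
#' @export
setClass("GenomeSpec", representation(
    chromNames = "character",
    chromLengths = "numeric",
    markerPos = "list",
    markerNames = "list"
))

setValidity("GenomeSpec", function(object) {
    n <- length(object@chromNames)
    if (length(object@chromLengths) != n || length(object@markerPos) != n ||
        length(object@markerNames) != n)
        return("chromosome slots must have equal length")
    if (any(object@chromLengths < 0))
        return("chromosome lengths must be >= 0")
    if (anyDuplicated(object@chromNames))
        return("chromosome names must be unique")
    for (i in seq_len(n)) {
        p <- object@markerPos[[i]]
        if (is.unsorted(p)) return("marker positions must be sorted")
        if (length(p) && (min(p) < 0 || max(p) > object@chromLengths[i]))
            return("marker positions must lie within [0, length]")
        if (length(p) != length(object@markerNames[[i]]))
            return("markerPos and markerNames lengths differ")
    }
    if (anyDuplicated(unlist(object@markerNames)))
        return("marker names must be globally unique")
    TRUE
})

#' Gametophytic selection regime
#'
#' Positions of the pollen-side self-incompatibility locus *Z* and the
#' stigma-side locus *S5*, plus the set of chromosomes locked in a ring
#' multivalent (empty = off; otherwise exactly three).  Loci are
#' `(chrom, posCM)` pairs that must coincide with a genotyped marker.
#'
#' @slot zLocus numeric(0) or named list `list(chrom=, posCM=)`.
#' @slot s5Locus as `zLocus`.
#' @slot multivalentChrom character, length 0 or 3.
#' @export
setClass("SelectionSpec", representation(
    zLocus = "ANY",
    s5Locus = "ANY",
    multivalentChrom = "character"
))

setValidity("SelectionSpec", function(object) {
    chkLocus <- function(l, what) {
        if (is.null(l)) return(NULL)
        if (!is.list(l) || !all(c("chrom", "posCM") %in% names(l)))
            return(sprintf("%s must be NULL or list(chrom=, posCM=)", what))
        NULL
    }
    msg <- c(chkLocus(object@zLocus, "zLocus"),
             chkLocus(object@s5Locus, "s5Locus"))
    if (length(msg)) return(msg[1])
    if (!length(object@multivalentChrom) %in% c(0L, 3L))
        return("multivalentChrom must be empty or have exactly 3 chromosomes")
    TRUE
})

#' Field-trial design and noise model for simulated phenotypes
#'
#' Per-trait rows describe the trial layout (`nLocations`, `nReps` clonal
#' replicates nested in location) and the variance components of the
#' plot-level model
#' \deqn{y_{ijkl} = \mu + g_i + l_j + r_{jk} + (gl)_{ij} + e_{ijkl},}
#' plus a residual polygenic genetic variance `sigma2Gres` (background
#' genetics not attached to any marker) and optional trait bounds applied by
#' clipping after noise.
#'
#' @slot traits data.frame with columns `trait`, `mean`, `nLocations`,
#'   `nReps`, `sigma2L`, `sigma2R`, `sigma2GL`, `sigma2E`, `sigma2Gres`,
#'   `lower`, `upper` (bounds may be `NA` = unbounded).
#' @slot polygenicCor correlation matrix of the polygenic effects across
#'   traits (identity by default).
#' @export
setClass("TrialDesign", representation(
    traits = "data.frame",
    polygenicCor = "matrix"
))

setValidity("TrialDesign", function(object) {
    need <- c("trait", "mean", "nLocations", "nReps", "sigma2L", "sigma2R",
              "sigma2GL", "sigma2E", "sigma2Gres", "lower", "upper")
    if (!all(need %in% colnames(object@traits)))
        return(sprintf("traits must have columns: %s", paste(need, collapse = ", ")))
    tr <- object@traits
    if (any(tr$nLocations < 1) || any(tr$nReps < 1))
        return("nLocations and nReps must be >= 1")
    vc <- as.matrix(tr[, c("sigma2L", "sigma2R", "sigma2GL", "sigma2E", "sigma2Gres")])
    if (any(vc < 0)) return("variance components must be >= 0")
    k <- nrow(tr)
    if (!identical(dim(object@polygenicCor), c(k, k)))
        return("polygenicCor must be nTraits x nTraits")
    TRUE
})

#' A simulated F2 study with ground truth
#'
#' Bundles the marker matrix, the long-format plot phenotype table and a
#' `truth` list (QTL specs, selection regime, seed, realized genotype
#' frequencies, phased haplotypes) sufficient to regenerate the study from
#' the seed.
#'
#' @slot geno an [AbhMatrix-class].
#' @slot pheno data.frame with columns `genotype`, `location`, `replicate`,
#'   `trait`, `value`.
#' @slot truth list.
#' @export
setClass("SimulatedStudy", representation(
    geno = "AbhMatrix",
    pheno = "data.frame",
    truth = "list"
))

setValidity("SimulatedStudy", function(object) {
    if (nrow(object@pheno) &&
        !all(object@pheno$genotype %in% colnames(object@geno)))
        return("every phenotype genotype ID must exist in the marker matrix")
    TRUE
})

#' REML variance-component estimates
#'
#' @slot components named numeric vector of variance components (e.g.
#'   `genotype`, `location`, `rep:location`, `genotype:location`, `residual`).
#' @slot se standard errors (delta method from the curvature of the
#'   restricted log-likelihood; `NA` at a boundary).
#' @slot logLik restricted log-likelihood at the optimum.
#' @slot converged logical.
#' @slot nobs number of observations used.
#' @export
setClass("VarianceComponents", representation(
    components = "numeric",
    se = "numeric",
    logLik = "numeric",
    converged = "logical",
    nobs = "integer"
))

#' Genotype BLUEs from a fixed-genotype mixed model
#'
#' @slot blues data.frame with columns `genotype`, `blue`, `se`.
#' @slot avVD mean variance of a difference of two BLUEs over all pairs.
#' @slot lsd least significant difference at alpha = 0.05.
#' @slot residDf residual degrees of freedom used for the LSD t quantile.
#' @slot components variance components of the non-genetic random terms.
#' @export
setClass("BlueTable", representation(
    blues = "data.frame",
    avVD = "numeric",
    lsd = "numeric",
    residDf = "numeric",
    components = "numeric"
))

#' Bivariate REML fit (two traits, unstructured genotype and residual)
#'
#' @slot traits the two trait names.
#' @slot genCov 2x2 unstructured genotype covariance matrix.
#' @slot resCov 2x2 unstructured residual covariance matrix.
#' @slot repVar diagonal replicate variances (one per trait).
#' @slot genCor genetic correlation.
#' @slot genCovSE standard error of the genetic covariance.
#' @slot logLik restricted log-likelihood.
#' @slot converged logical.
#' @export
setClass("BivariateFit", representation(
    traits = "character",
    genCov = "matrix",
    resCov = "matrix",
    repVar = "numeric",
    genCor = "numeric",
    genCovSE = "numeric",
    logLik = "numeric",
    converged = "logical"
))

setValidity("BivariateFit", function(object) {
    for (m in list(object@genCov, object@resCov)) {
        if (!isTRUE(all.equal(m, t(m)))) return("covariance matrices must be symmetric")
        if (min(eigen(m, symmetric = TRUE, only.values = TRUE)$values) < -1e-8)
            return("covariance matrices must be positive semi-definite")
    }
    TRUE
})

setMethod("show", "AbhMatrix", function(object) {
    cat(sprintf("AbhMatrix: %d markers x %d genotypes\n",
                nrow(object), ncol(object)))
    ch <- unique(as.character(SummarizedExperiment::rowData(object)$chrom))
    cat(sprintf("chromosomes: %s\n", paste(ch, collapse = ", ")))
    x <- SummarizedExperiment::assay(object, "calls")
    miss <- mean(is.na(x))
    cat(sprintf("missing calls: %.2f%%\n", 100 * miss))
    if (!is.null(S4Vectors::metadata(object)$truth))
        cat("simulated object with truth record\n")
})

setMethod("show", "GenomeSpec", function(object) {
    cat(sprintf("GenomeSpec: %d chromosomes, %d markers\n",
                length(object@chromNames), length(unlist(object@markerPos))))
    for (i in seq_along(object@chromNames))
        cat(sprintf("  %s: %.1f cM, %d markers\n", object@chromNames[i],
                    object@chromLengths[i], length(object@markerPos[[i]])))
})

setMethod("show", "VarianceComponents", function(object) {
    cat("REML variance components\n")
    df <- data.frame(Var.comp. = round(object@components, 4),
                     St.Error = round(object@se, 4))
    print(df)
    cat(sprintf("REML logLik = %.3f (%s)\n", object@logLik,
                if (object@converged) "converged" else "NOT converged"))
})

setMethod("show", "BlueTable", function(object) {
    cat(sprintf("BLUEs for %d genotypes; av.VD = %.4f; LSD(5%%) = %.4f\n",
                nrow(object@blues), object@avVD, object@lsd))
    print(head(object@blues, 5))
    if (nrow(object@blues) > 5) cat("...\n")
})

setMethod("show", "BivariateFit", function(object) {
    cat(sprintf("Bivariate REML fit: %s\n", paste(object@traits, collapse = " / ")))
    cat("genotype covariance:\n"); print(round(object@genCov, 4))
    cat("residual covariance:\n"); print(round(object@resCov, 4))
    cat(sprintf("genetic correlation = %.3f\n", object@genCor))
})

setMethod("show", "SimulatedStudy", function(object) {
    cat(sprintf("SimulatedStudy: %d genotypes, %d markers, %d plot records\n",
                ncol(object@geno), nrow(object@geno), nrow(object@pheno)))
})
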