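## User-facing mixed-model interface for the plot-level phenotype model
##   y_ijkl = mu + g_i + l_j + r_jk + (gl)_ij + e_ijkl
## with genotype fixed (BLUEs) or random (variance components); the
## location effect and its interactions are dropped for single-location
## traits.

.checkPheno <- function(data) {
    need <- c("genotype", "location", "replicate", "trait", "value")
    if (!all(need %in% colnames(data)))
        stop("phenotype data must have columns: ", paste(need, collapse = ", "))
    data
}

# Build y, X, Zlist for one trait.  extraFixed: numeric matrix of
# genotype-level covariates (rownames = genotype IDs) entered as fixed
# effects after the intercept / cofactors.  markerRandomLoc: genotype-level
# covariates entered as random slopes by location (one common variance per
# covariate).
.buildPhenoModel <- function(data, trait, genotypeAs = "random",
                             extraFixed = NULL, markerRandomLoc = NULL) {
    d <- .checkPheno(data)
    d <- d[d$trait == trait & !is.na(d$value), , drop = FALSE]
    if (!nrow(d)) stop("no records for trait ", trait)
    d$genotype <- factor(d$genotype)
    d$location <- factor(d$location)
    multiLoc <- nlevels(d$location) > 1L
    d$repf <- factor(paste(d$location, d$replicate, sep = ":"))
    y <- d$value
    Zlist <- list()
    if (genotypeAs == "random")
        Zlist$genotype <- .sparseIndicator(d$genotype)
    if (multiLoc) {
        Zlist$location <- .sparseIndicator(d$location)
        Zlist$`rep:location` <- .sparseIndicator(d$repf)
        Zlist$`genotype:location` <-
            .sparseIndicator(paste(d$genotype, d$location, sep = ":"))
    } else {
        Zlist$replicate <- .sparseIndicator(d$repf)
    }
    if (genotypeAs == "fixed") {
        X <- stats::model.matrix(~ 0 + genotype, d)
        colnames(X) <- levels(d$genotype)
    } else {
        X <- matrix(1, nrow(d), 1L, dimnames = list(NULL, "(Intercept)"))
    }
    if (!is.null(extraFixed)) {
        ix <- match(as.character(d$genotype), rownames(extraFixed))
        if (anyNA(ix)) {
            ok <- !is.na(ix)
            d <- d[ok, , drop = FALSE]; y <- y[ok]
            X <- X[ok, , drop = FALSE]
            Zlist <- lapply(Zlist, function(z) z[ok, , drop = FALSE])
            ix <- ix[ok]
        }
        ex <- extraFixed[ix, , drop = FALSE]
        if (anyNA(ex)) {            # genotypes with missing marker calls
            ok <- stats::complete.cases(ex)
            d <- d[ok, , drop = FALSE]; y <- y[ok]
            X <- X[ok, , drop = FALSE]; ex <- ex[ok, , drop = FALSE]
            Zlist <- lapply(Zlist, function(z) z[ok, , drop = FALSE])
        }
        X <- cbind(X, ex)
    }
    if (!is.null(markerRandomLoc) && nlevels(droplevels(d$location)) > 1L) {
        loc <- .sparseIndicator(droplevels(d$location))
        ix <- match(as.character(d$genotype), rownames(markerRandomLoc))
        for (cn in colnames(markerRandomLoc)) {
            v <- markerRandomLoc[ix, cn]
            v[is.na(v)] <- 0
            Zlist[[paste0(cn, ":location")]] <- loc * v
        }
    }
    list(y = y, X = X, Zlist = Zlist, data = d, multiLoc = multiLoc)
}

#' Fit the univariate plot-level mixed model by REML
#'
#' With `genotypeAs = "random"` returns REML variance components with
#' standard errors; with `"fixed"` returns genotype BLUEs, the mean
#' variance of a difference of two BLUEs (av.VD) and the 5 % LSD.
#' Multi-location data fit location, replicate-in-location and
#' genotype-by-location random effects; single-location data fit the
#' replicate effect only.
#'
#' @param data long-format phenotype table (`genotype`, `location`,
#'   `replicate`, `trait`, `value`).
#' @param trait trait name to fit.
#' @param genotypeAs `"random"` (variance components) or `"fixed"` (BLUEs).
#' @param computeSE compute variance-component standard errors (numeric
#'   curvature of the restricted likelihood; skip for speed in simulation
#'   loops).
#' @param fast single optimizer start with a coarser stopping rule (point
#'   estimates in simulation loops); the default uses three starts.
#' @return a [VarianceComponents-class] or [BlueTable-class].
#' @examples
#' set.seed(7)
#' st <- simulateStudy(genomeSpec("1R", 50, list(c(0, 25, 50))), n = 40,
#'                     seed = 7)
#' fitUnivariate(phenoData(st), "perenniality")
#' @export
fitUnivariate <- function(data, trait, genotypeAs = c("random", "fixed"),
                          computeSE = TRUE, fast = FALSE) {
    genotypeAs <- match.arg(genotypeAs)
    bm <- .buildPhenoModel(data, trait, genotypeAs)
    if (genotypeAs == "fixed" && length(bm$y) - nlevels(bm$data$genotype) -
        0L <= 0L)
        stop("non-identifiable design: no residual degrees of freedom")
    fit <- .remlFit(bm$y, bm$X, bm$Zlist, computeSE = computeSE, fast = fast)
    if (genotypeAs == "random") {
        return(new("VarianceComponents",
                   components = fit$sigma2, se = fit$se,
                   logLik = fit$logLik, converged = fit$converged,
                   nobs = length(bm$y)))
    }
    b <- fit$beta
    Cb <- fit$covBeta
    g <- length(b)
    dC <- diag(Cb)
    avVD <- 2 * (mean(dC) - (sum(Cb) - sum(dC)) / (g * (g - 1L)))
    residDf <- length(bm$y) - ncol(bm$X)
    lsd <- qt(0.975, residDf) * sqrt(avVD)
    new("BlueTable",
        blues = data.frame(genotype = names(b), blue = unname(b),
                           se = sqrt(dC), row.names = NULL),
        avVD = avVD, lsd = lsd, residDf = as.numeric(residDf),
        components = fit$sigma2)
}

#' @rdname VarianceComponents-class
#' @param object a `VarianceComponents`.
#' @export
varComp <- function(object) object@components

#' @rdname VarianceComponents-class
#' @export
varCompSE <- function(object) object@se

#' @rdname BlueTable-class
#' @param object a `BlueTable`.
#' @export
blues <- function(object) object@blues

#' @rdname BlueTable-class
#' @export
avVD <- function(object) object@avVD

#' Entry-mean heritability
#'
#' \eqn{H^2 = \sigma^2_G / (\sigma^2_G + av.VD / 2)}, with `av.VD` the mean
#' variance of a difference of two genotype BLUEs.  [heritabilityBalanced()]
#' uses the balanced-design approximation
#' \eqn{av.VD = 2(\sigma^2_{GL}/L + \sigma^2_E/(LR))} for `L` locations and
#' `R` replicates.
#'
#' @param sigma2G genetic variance (>= 0).
#' @param avVD mean variance of a difference of two BLUEs (> 0).
#' @return heritability in `[0, 1]`.
#' @examples
#' heritabilityBalanced(313.7, sigma2E = 94.9, nLocations = 1, nReps = 2)
#' @export
heritability <- function(sigma2G, avVD) {
    stopifnot(sigma2G >= 0)
    if (avVD <= 0) stop("avVD must be > 0")
    sigma2G / (sigma2G + avVD / 2)
}

#' @rdname heritability
#' @param sigma2GL genotype-by-location variance.
#' @param sigma2E residual variance.
#' @param nLocations,nReps trial dimensions.
#' @export
heritabilityBalanced <- function(sigma2G, sigma2GL = 0, sigma2E,
                                 nLocations, nReps) {
    heritability(sigma2G,
                 2 * (sigma2GL / nLocations + sigma2E / (nLocations * nReps)))
}

#' Bivariate REML fit of two traits
#'
#' Fits both traits jointly on plot records present for both, with an
#' unstructured 2x2 covariance matrix for the genotype and the residual and
#' a diagonal matrix for the replicate; no location effect is fitted (the
#' paired records come from the shared location).  Estimated via a
#' log-Cholesky parameterization, which keeps the covariance matrices
#' positive semi-definite by construction.
#'
#' @param data long-format phenotype table.
#' @param trait1,trait2 the two trait names.
#' @param markerEffects optional numeric matrix of genotype-level marker
#'   covariates (rownames = genotype IDs) entered as trait-specific fixed
#'   effects (used by [explainedCovariance()]).
#' @param zeroGenCov constrain both cross-covariances (genotype and
#'   residual) to zero; the fit then decomposes into two univariate fits.
#' @param computeSE compute the standard error of the genetic covariance
#'   (numeric Hessian; skip for speed when only point estimates are
#'   needed).
#' @return a [BivariateFit-class].
#' @export
fitBivariate <- function(data, trait1, trait2, markerEffects = NULL,
                         zeroGenCov = FALSE, computeSE = TRUE) {
    bp <- .bivPrep(.checkPheno(data), trait1, trait2, markerEffects)
    f <- .bivFit(bp, zeroCov = zeroGenCov, computeSE = computeSE)
    gc_ <- f$SG[1L, 2L]
    new("BivariateFit", traits = c(trait1, trait2),
        genCov = f$SG, resCov = f$SE, repVar = f$repVar,
        genCor = gc_ / sqrt(f$SG[1L, 1L] * f$SG[2L, 2L]),
        genCovSE = f$covGse, logLik = f$logLik, converged = f$converged)
}

#' @rdname BivariateFit-class
#' @param object a `BivariateFit`.
#' @export
genCov <- function(object) object@genCov

#' @rdname BivariateFit-class
#' @export
genCor <- function(object) object@genCor

#' Derive fertility from non-seed-set scores
#'
#' Fertility is defined as 100 % minus the percentage of florets without
#' seed; [asNonFertility()] is its complement, the scale used by the
#' bivariate genetic-covariance model.
#'
#' @param nonSeedSet numeric vector of non-seed-set percentages (0--100).
#' @return numeric vector.
#' @export
asFertility <- function(nonSeedSet) 100 - nonSeedSet

#' @rdname asFertility
#' @param fertility numeric vector of fertility percentages.
#' @export
asNonFertility <- function(fertility) 100 - fertility
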