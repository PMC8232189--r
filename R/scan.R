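## Single-marker mixed-model genome scans with incremental (type-I) Wald
## tests, simpleM multiple-testing thresholds, cofactor selection (CM1 from
## a cofactor-free scan, CM2 by BIC-stepwise on BLUEs), explained genetic
## (co)variance, and the pairwise epistasis scan.  Incremental Wald
## statistics for an ordered term sequence are backward differences of
## joint Wald statistics, so they add up to the joint test.

#' Effective number of markers (simpleM)
#'
#' Eigendecomposition of the marker correlation matrix (codominant 0/1/2
#' coding); the effective number of tests is the smallest number of
#' eigenvalues whose cumulative share of the total variation reaches
#' `share` (default 99.5 %).  Constant marker columns are excluded with a
#' warning.
#'
#' @param x an [AbhMatrix-class] or a genotypes x markers numeric matrix.
#' @param share cumulative eigenvalue share (default 0.995).
#' @return integer, the effective marker number `qEff`.
#' @export
effectiveMarkerNumber <- function(x, share = 0.995) {
    M <- if (is(x, "AbhMatrix")) cdCodes(x) else as.matrix(x)
    if (ncol(M) < 1L) stop("at least 1 marker required")
    if (nrow(M) < 3L) stop("at least 3 genotypes required")
    sds <- apply(M, 2L, sd, na.rm = TRUE)
    if (any(con <- (is.na(sds) | sds == 0))) {
        warning(sum(con), " constant marker column(s) excluded")
        M <- M[, !con, drop = FALSE]
    }
    if (ncol(M) == 1L) return(1L)
    R <- suppressWarnings(cor(M, use = "pairwise.complete.obs"))
    R[is.na(R)] <- 0; diag(R) <- 1
    ev <- pmax(eigen(R, symmetric = TRUE, only.values = TRUE)$values, 0)
    as.integer(which(cumsum(ev) / sum(ev) >= share)[1L])
}

#' simpleM significance thresholds
#'
#' @param x as in [effectiveMarkerNumber()].
#' @param alpha genome-wide error level (default 0.05).
#' @param share eigenvalue share (default 0.995).
#' @return list: `qEff`, `alpha`, `threshold` (= alpha/qEff) and
#'   `epistasisThreshold` (= alpha/(qEff (qEff - 1)), the ordered-pair
#'   divisor used for marker-marker interactions).
#' @export
simpleMThreshold <- function(x, alpha = 0.05, share = 0.995) {
    q <- effectiveMarkerNumber(x, share)
    list(qEff = q, alpha = alpha, threshold = alpha / q,
         epistasisThreshold = if (q > 1L) alpha / (q * (q - 1L)) else alpha)
}

.markerCodes <- function(abh, markers, suffixes = c("_cd", "_d")) {
    cd <- cdCodes(abh)[, markers, drop = FALSE]
    dd <- dCodes(abh)[, markers, drop = FALSE]
    out <- matrix(NA_real_, nrow(cd), 2L * length(markers),
                  dimnames = list(rownames(cd), NULL))
    cn <- character(2L * length(markers))
    for (i in seq_along(markers)) {
        out[, 2L * i - 1L] <- cd[, i]
        out[, 2L * i] <- dd[, i]
        cn[2L * i - 1L] <- paste0(markers[i], suffixes[1L])
        cn[2L * i] <- paste0(markers[i], suffixes[2L])
    }
    colnames(out) <- cn
    out
}

#' Single-marker mixed-model test
#'
#' Fits the plot-level phenotype model (genotype random, plus the trial's
#' location/replicate structure) with fixed effects in the order
#' [cofactors..., marker cd, marker d].  Incremental Wald chi-squares are
#' reported for the codominant term (df 1), the dominance term (df 1), and
#' their sum referred to chi-square with df 2 (the combined cd+d test).
#' For multi-location traits, random marker-by-location (cd and d) effects
#' are added when `markerByLocation` is `TRUE` (the default resolves to the
#' multi-location case).  If a genotype class is empty the dominance term
#' is inestimable: `pD` is reported as 1 and the row flagged.
#'
#' @param pheno long-format phenotype table.
#' @param abh an [AbhMatrix-class].
#' @param trait trait name.
#' @param marker tested marker ID.
#' @param cofactors marker IDs entered as cd+d fixed cofactors before the
#'   tested marker (must exclude the tested marker and its redundancy
#'   group).
#' @param markerByLocation logical or `NULL` (auto: `TRUE` iff the trait is
#'   observed in more than one location).
#' @return one-row data.frame (`marker`, `chrom`, `posCM`, `pCd`, `pD`,
#'   `pCdD`, `effCd`, `seCd`, `effD`, `seD`, `nA`, `nH`, `nB`,
#'   `dInestimable`).
#' @export
scanSingleMarker <- function(pheno, abh, trait, marker,
                             cofactors = character(),
                             markerByLocation = NULL) {
    if (marker %in% cofactors)
        stop("tested marker must not be among the cofactors")
    mcalls <- calls(abh)[marker, ]
    if (length(unique(mcalls[!is.na(mcalls)])) < 2L)
        stop("marker does not segregate in the scanned sample: ", marker)
    ex <- .markerCodes(abh, c(cofactors, marker))
    testCols <- paste0(marker, c("_cd", "_d"))
    d <- pheno[pheno$trait == trait & !is.na(pheno$value), , drop = FALSE]
    multiLoc <- length(unique(d$location)) > 1L
    if (is.null(markerByLocation)) markerByLocation <- multiLoc
    mrl <- if (markerByLocation && multiLoc)
        .markerCodes(abh, marker, suffixes = c("_cdLoc", "_dLoc"))
    else NULL
    bm <- .buildPhenoModel(pheno, trait, "random", extraFixed = ex,
                           markerRandomLoc = mrl)
    fit <- .remlFit(bm$y, bm$X, bm$Zlist, computeSE = FALSE,
                    fast = TRUE)
    aliasCof <- intersect(fit$prep$aliased,
                          setdiff(colnames(ex), testCols))
    if (length(aliasCof))
        warning("collinear cofactor column(s) dropped: ",
                paste(aliasCof, collapse = ", "))
    dAliased <- testCols[2L] %in% fit$prep$aliased
    cdAliased <- testCols[1L] %in% fit$prep$aliased
    if (cdAliased) stop("codominant term collinear with model: ", marker)
    wJoint <- .waldJoint(fit, testCols)$stat
    wD <- if (dAliased) 0 else .waldJoint(fit, testCols[2L])$stat
    wCd <- max(wJoint - wD, 0)
    pD <- if (dAliased) 1 else pchisq(wD, 1L, lower.tail = FALSE)
    genosUsed <- unique(as.character(bm$data$genotype))
    cc <- mcalls[genosUsed]
    data.frame(marker = marker,
               chrom = markerChrom(abh)[match(marker, rownames(abh))],
               posCM = markerPos(abh)[match(marker, rownames(abh))],
               pCd = pchisq(wCd, 1L, lower.tail = FALSE),
               pD = pD,
               pCdD = pchisq(wJoint, 2L, lower.tail = FALSE),
               effCd = unname(fit$beta[testCols[1L]]),
               seCd = sqrt(fit$covBeta[testCols[1L], testCols[1L]]),
               effD = if (dAliased) NA_real_ else unname(fit$beta[testCols[2L]]),
               seD = if (dAliased) NA_real_
                     else sqrt(fit$covBeta[testCols[2L], testCols[2L]]),
               nA = sum(cc == "A", na.rm = TRUE),
               nH = sum(cc == "H", na.rm = TRUE),
               nB = sum(cc == "B", na.rm = TRUE),
               dInestimable = dAliased,
               row.names = NULL)
}

#' Genome scan by single-marker regression
#'
#' Runs [scanSingleMarker()] over markers.  With cofactors, markers in the
#' tested marker's redundancy group are always excluded, and (for the CM1
#' scheme) cofactors on the tested marker's own chromosome are dropped.
#'
#' @inheritParams scanSingleMarker
#' @param markers markers to test (default all).
#' @param cofactors character vector of cofactor marker IDs (empty = plain
#'   scan).
#' @param redundancyGroups optional data.frame from [collapseRedundant()]
#'   used to exclude the tested marker's redundancy group from the
#'   cofactors.
#' @param dropSameChromCofactors drop cofactors on the tested marker's
#'   chromosome (CM1 rule; default `FALSE`).
#' @return data.frame of scan rows, one per tested marker.
#' @export
scanGenome <- function(pheno, abh, trait, markers = rownames(abh),
                       cofactors = character(), redundancyGroups = NULL,
                       dropSameChromCofactors = FALSE,
                       markerByLocation = NULL) {
    ch <- setNames(markerChrom(abh), rownames(abh))
    rows <- vector("list", length(markers))
    for (i in seq_along(markers)) {
        m <- markers[i]
        cof <- setdiff(cofactors, m)
        if (!is.null(redundancyGroups)) {
            gi <- redundancyGroups$group[match(m, redundancyGroups$marker)]
            if (!is.na(gi))
                cof <- setdiff(cof, redundancyGroups$marker[
                    redundancyGroups$group == gi])
        }
        if (dropSameChromCofactors)
            cof <- cof[ch[cof] != ch[m]]
        rows[[i]] <- scanSingleMarker(pheno, abh, trait, m, cof,
                                      markerByLocation)
    }
    do.call(rbind, rows)
}

#' CM1 cofactor selection
#'
#' From a completed cofactor-free scan: per chromosome the marker with the
#' smallest combined cd+d p-value among those passing the global
#' (simpleM) threshold; chromosomes with no passing marker contribute
#' nothing.
#'
#' @param scan data.frame from [scanGenome()].
#' @param threshold per-test significance level (alpha / qEff).
#' @return character vector of cofactor marker IDs.
#' @export
selectCofactorsCM1 <- function(scan, threshold) {
    pass <- scan[scan$pCdD < threshold, , drop = FALSE]
    if (!nrow(pass)) return(character())
    unname(vapply(split(pass, pass$chrom),
                  function(d) d$marker[which.min(d$pCdD)], character(1L)))
}

#' CM2 cofactor selection by BIC-stepwise regression on BLUEs
#'
#' Simultaneous forward/backward selection on a linear model of the
#' genotype BLUEs against codominant (0/1/2) marker codes, starting from
#' the intercept-only model.  Each step takes the single add-or-drop move
#' that most decreases the Schwarz BIC (penalty `log(N)` per parameter);
#' the procedure stops when no move improves and is deterministic given
#' the input order (ties resolve to the lower marker index).  Missing
#' marker codes are mean-imputed for the selection.
#'
#' @param blues named numeric vector of BLUEs (names = genotype IDs) or a
#'   [BlueTable-class].
#' @param abh an [AbhMatrix-class].
#' @param markers candidate markers (default all).
#' @return character vector of selected marker IDs (possibly empty).
#' @export
selectCofactorsCM2 <- function(blues, abh, markers = rownames(abh)) {
    if (is(blues, "BlueTable"))
        blues <- setNames(blues@blues$blue, blues@blues$genotype)
    cd <- cdCodes(abh)[names(blues), markers, drop = FALSE]
    for (j in seq_len(ncol(cd)))
        if (anyNA(cd[, j])) cd[is.na(cd[, j]), j] <- mean(cd[, j], na.rm = TRUE)
    y <- unname(blues)
    n <- length(y)
    bicOf <- function(set) {
        X <- cbind(1, cd[, set, drop = FALSE])
        rss <- sum(stats::lm.fit(X, y)$residuals^2)
        n * log(rss / n) + (length(set) + 1L) * log(n)
    }
    sel <- character()
    cur <- bicOf(sel)
    repeat {
        bestMove <- NULL; bestBic <- cur
        for (m in markers) {       # input order fixes the tie-break
            cand <- if (m %in% sel) setdiff(sel, m) else c(sel, m)
            b <- bicOf(cand)
            if (b < bestBic - 1e-8) { bestBic <- b; bestMove <- cand }
        }
        if (is.null(bestMove)) break
        sel <- bestMove; cur <- bestBic
    }
    markers[markers %in% sel]
}

#' log10-drop confidence interval around a scan peak
#'
#' Walks outward from the peak while `-log10(pCdD)` stays within `drop` of
#' the peak value and closes the interval at the first marker below the
#' cutoff, so the limits bracket the positions where the drop of 1 log10
#' unit occurs.  A single-marker chromosome yields a zero-width interval;
#' a profile still above the cutoff at the chromosome end is one-sided.
#'
#' @param scan data.frame from [scanGenome()] (any chromosome subset).
#' @param peakMarker marker ID of the peak; must be in `scan`.
#' @param drop log10 drop defining the interval (default 1).
#' @return named numeric `c(left =, right =)` in cM.
#' @export
confidenceInterval <- function(scan, peakMarker, drop = 1) {
    i0 <- match(peakMarker, scan$marker)
    if (is.na(i0)) stop("peak marker not in scan profile")
    prof <- scan[scan$chrom == scan$chrom[i0], , drop = FALSE]
    prof <- prof[order(prof$posCM), , drop = FALSE]
    i <- match(peakMarker, prof$marker)
    nl <- -log10(prof$pCdD)
    lim <- nl[i] - drop
    l <- i; while (l > 1L && nl[l - 1L] >= lim) l <- l - 1L
    r <- i; while (r < nrow(prof) && nl[r + 1L] >= lim) r <- r + 1L
    if (l > 1L) l <- l - 1L               # boundary marker where the drop occurs
    if (r < nrow(prof)) r <- r + 1L
    c(left = prof$posCM[l], right = prof$posCM[r])
}

#' Explained genetic variance of a marker set
#'
#' \eqn{p_G}: the reduction of the REML genetic variance of the plot-level
#' model when the markers' cd+d effects are added as fixed effects,
#' divided by the full genetic variance.  Negative estimates are truncated
#' to 0 and flagged (attribute `"truncated"`).
#'
#' @inheritParams scanSingleMarker
#' @param markers marker IDs whose joint explained variance is computed
#'   (may be empty: returns 0).
#' @param base optional [VarianceComponents-class] of the marker-free model
#'   (refit when omitted; pass it when computing several marker sets on the
#'   same data).
#' @return numeric `pG` in `[0, 1]` (attribute `"truncated"`).
#' @export
explainedVariance <- function(pheno, abh, trait, markers, base = NULL) {
    if (is.null(base)) base <- fitUnivariate(pheno, trait, "random",
                                             computeSE = FALSE)
    s2base <- varComp(base)[["genotype"]]
    if (s2base <= 0) stop("base genetic variance is zero")
    if (!length(markers)) {
        out <- 0; attr(out, "truncated") <- FALSE
        return(out)
    }
    ex <- .markerCodes(abh, markers)
    bm <- .buildPhenoModel(pheno, trait, "random", extraFixed = ex)
    fit <- .remlFit(bm$y, bm$X, bm$Zlist, computeSE = FALSE,
                    fast = TRUE)
    pg <- (s2base - fit$sigma2[["genotype"]]) / s2base
    out <- max(pg, 0)
    attr(out, "truncated") <- pg < 0
    out
}

#' Explained genetic covariance of a marker set
#'
#' \eqn{p_{CovG}}: the reduction of the genetic covariance in the
#' bivariate REML model when the markers' cd+d effects are added as
#' trait-specific fixed effects, divided by the full genetic covariance.
#' Undefined (NA, flagged) when the base genetic covariance is within
#' 1e-8 of zero.
#'
#' @inheritParams explainedVariance
#' @param trait1,trait2 the two traits of the bivariate model.
#' @return numeric `pCovG` (attribute `"undefined"`).
#' @export
explainedCovariance <- function(pheno, abh, trait1, trait2, markers) {
    base <- fitBivariate(pheno, trait1, trait2, computeSE = FALSE)
    cb <- genCov(base)[1L, 2L]
    if (abs(cb) < 1e-8) {
        out <- NA_real_; attr(out, "undefined") <- TRUE
        return(out)
    }
    if (!length(markers)) {
        out <- 0; attr(out, "undefined") <- FALSE
        return(out)
    }
    ex <- .markerCodes(abh, markers)
    adj <- fitBivariate(pheno, trait1, trait2, markerEffects = ex,
                        computeSE = FALSE)
    out <- (cb - genCov(adj)[1L, 2L]) / cb
    attr(out, "undefined") <- FALSE
    out
}

#' Pairwise epistasis scan
#'
#' For each marker pair the fixed-effect sequence is
#' `m1_cd + m2_cd + m1_d + m2_d + m1_cd:m2_cd + m1_d:m2_d + m1_d:m2_cd`,
#' with incremental Wald p-values per term; the asymmetric `d:cd`
#' interaction is additionally tested with the roles swapped
#' (`m2_d:m1_cd` as the last term of a second fit).  Interaction terms
#' with an empty genotype cell are flagged inestimable.  Significance is
#' declared at `alpha / (qEff (qEff - 1))`.  For multi-location traits the
#' four marker main effects also enter as random marker-by-location
#' terms.
#'
#' @inheritParams scanSingleMarker
#' @param pairs two-column matrix or data.frame of marker IDs.
#' @param qEff effective marker number from the single-marker scan.
#' @param alpha genome-wide level (default 0.05).
#' @return data.frame: `marker1`, `marker2`, `term`, `wald`, `p`,
#'   `significant`, `inestimable`.
#' @export
epistasisScan <- function(pheno, abh, trait, pairs, qEff, alpha = 0.05,
                          markerByLocation = NULL) {
    pairs <- as.matrix(pairs)
    if (any(pairs[, 1L] == pairs[, 2L]))
        stop("invalid pair: a marker cannot interact with itself")
    thr <- if (qEff > 1L) alpha / (qEff * (qEff - 1L)) else alpha
    d <- pheno[pheno$trait == trait & !is.na(pheno$value), , drop = FALSE]
    multiLoc <- length(unique(d$location)) > 1L
    if (is.null(markerByLocation)) markerByLocation <- multiLoc
    out <- vector("list", nrow(pairs))
    for (k in seq_len(nrow(pairs))) {
        m1 <- pairs[k, 1L]; m2 <- pairs[k, 2L]
        base <- .markerCodes(abh, c(m1, m2))
        cd1 <- base[, paste0(m1, "_cd")]; cd2 <- base[, paste0(m2, "_cd")]
        d1 <- base[, paste0(m1, "_d")]; d2 <- base[, paste0(m2, "_d")]
        mk <- function(last) {
            X <- cbind(cd1, cd2, d1, d2, cd1 * cd2, d1 * d2, last)
            colnames(X) <- c("m1_cd", "m2_cd", "m1_d", "m2_d",
                             "cd:cd", "d:d", "d:cd")
            rownames(X) <- rownames(base)
            X
        }
        mrl <- if (markerByLocation && multiLoc) {
            z <- base; colnames(z) <- paste0(colnames(z), "Loc"); z
        } else NULL
        fitOne <- function(X) {
            bm <- .buildPhenoModel(pheno, trait, "random", extraFixed = X,
                                   markerRandomLoc = mrl)
            .remlFit(bm$y, bm$X, bm$Zlist, computeSE = FALSE,
                     fast = TRUE)
        }
        fitA <- fitOne(mk(d1 * cd2))
        fitB <- fitOne(mk(d2 * cd1))
        seqCols <- c("m1_cd", "m2_cd", "m1_d", "m2_d", "cd:cd", "d:d", "d:cd")
        increments <- function(fit) {
            est <- setdiff(seqCols, fit$prep$aliased)
            w <- numeric(length(seqCols)); names(w) <- seqCols
            prev <- 0
            for (i in rev(seq_along(seqCols))) {
                tail_ <- intersect(seqCols[i:length(seqCols)], est)
                wj <- if (length(tail_)) .waldJoint(fit, tail_)$stat else 0
                w[i] <- max(wj - prev, 0)
                prev <- wj
            }
            list(w = w, aliased = intersect(seqCols, fit$prep$aliased))
        }
        ia <- increments(fitA)
        ib <- increments(fitB)
        terms <- c("m1cd:m2cd", "m1d:m2d", "m1d:m2cd", "m2d:m1cd")
        wald <- c(ia$w["cd:cd"], ia$w["d:d"], ia$w["d:cd"], ib$w["d:cd"])
        inest <- c("cd:cd" %in% ia$aliased, "d:d" %in% ia$aliased,
                   "d:cd" %in% ia$aliased, "d:cd" %in% ib$aliased)
        p <- ifelse(inest, NA_real_, pchisq(wald, 1L, lower.tail = FALSE))
        out[[k]] <- data.frame(marker1 = m1, marker2 = m2, term = terms,
                               wald = unname(wald), p = p,
                               significant = !is.na(p) & p < thr,
                               inestimable = inest, row.names = NULL)
    }
    do.call(rbind, out)
}
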