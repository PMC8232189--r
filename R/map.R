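## Two-point linkage mapping for an F2 intercross: EM maximum-likelihood
## recombination fractions (phase-known coupling cross, codominant
## markers; the double-heterozygote class is the ambiguous one), LOD
## against rf = 0.5, single-linkage grouping and MST/2-opt ordering with
## Kosambi distances.

#' Kosambi map function
#'
#' `kosambiCM()` converts a recombination fraction `r` in `[0, 0.5)` to a
#' map distance `d = 25 ln((1 + 2r)/(1 - 2r))` cM; `kosambiInverse()` is
#' the inverse, `r = tanh(d/50)/2`.
#'
#' @param r recombination fraction(s) in `[0, 0.5)`.
#' @return map distance in cM.
#' @examples
#' kosambiCM(0.2)              # ~21.18
#' kosambiInverse(kosambiCM(0.3))
#' @export
kosambiCM <- function(r) {
    if (any(r < 0 | r >= 0.5)) stop("r must lie in [0, 0.5)")
    25 * log((1 + 2 * r) / (1 - 2 * r))
}

#' @rdname kosambiCM
#' @param d map distance(s) in cM (>= 0).
#' @export
kosambiInverse <- function(d) {
    if (any(d < 0)) stop("d must be >= 0")
    tanh(d / 50) / 2
}

# vectorized EM over all marker pairs; counts from indicator crossproducts
.rfEM <- function(x, maxit = 200L, tol = 1e-12) {
    ## x: character calls matrix, markers x genotypes
    IA <- (x == "A"); IH <- (x == "H"); IB <- (x == "B")
    IA[is.na(IA)] <- FALSE; IH[is.na(IH)] <- FALSE; IB[is.na(IB)] <- FALSE
    storage.mode(IA) <- storage.mode(IH) <- storage.mode(IB) <- "double"
    nAA <- tcrossprod(IA); nAH <- tcrossprod(IA, IH); nAB <- tcrossprod(IA, IB)
    nHH <- tcrossprod(IH); nHB <- tcrossprod(IH, IB)
    nBB <- tcrossprod(IB)
    n1 <- nAH + t(nAH) + nHB + t(nHB)          # 1 recombinant gamete
    n2 <- nAB + t(nAB)                          # 2 recombinant gametes
    N <- nAA + nBB + nHH + n1 + n2
    r <- matrix(0.25, nrow(N), ncol(N))
    for (it in seq_len(maxit)) {
        eHH <- 2 * r^2 / ((1 - r)^2 + r^2)      # E[rec | double het]
        rNew <- (n1 + 2 * n2 + nHH * eHH) / pmax(2 * N, 1)
        rNew <- pmin(pmax(rNew, 0), 0.5)
        if (max(abs(rNew - r)) < tol) { r <- rNew; break }
        r <- rNew
    }
    ## LOD at the MLE vs r = 0.5
    ll <- function(r) {
        r <- pmin(pmax(r, 1e-9), 0.5 - 1e-12)
        (nAA + nBB) * log((1 - r)^2 / 4) + n2 * log(r^2 / 4) +
            n1 * log(r * (1 - r) / 2) + nHH * log(((1 - r)^2 + r^2) / 2)
    }
    lod <- (ll(r) - ll(matrix(0.5 - 1e-9, nrow(N), ncol(N)))) / log(10)
    lod[lod < 0] <- 0
    diag(r) <- 0; diag(lod) <- Inf
    dimnames(r) <- dimnames(lod) <- dimnames(N) <- list(rownames(x), rownames(x))
    list(rf = r, lod = lod, n = N)
}

#' Pairwise recombination-fraction estimates
#'
#' Maximum-likelihood recombination fractions for every marker pair of an
#' F2 intercross (both markers codominant, phase-known coupling), via EM
#' over the ambiguous double-heterozygote class, with base-10 LOD scores
#' against independence (rf = 0.5).  Pairs with fewer than `minInformative`
#' jointly non-missing genotypes are flagged.
#'
#' @param abh an [AbhMatrix-class] (>= 2 genotypes).
#' @param minInformative flag threshold on informative genotypes (default 10).
#' @return list: `rf`, `lod`, `n` (marker x marker matrices) and `flagged`
#'   (logical matrix).
#' @export
estimateRfMatrix <- function(abh, minInformative = 10L) {
    stopifnot(ncol(abh) >= 2L)
    res <- .rfEM(calls(abh))
    res$flagged <- res$n < minInformative
    diag(res$flagged) <- FALSE
    res
}

#' @rdname estimateRfMatrix
#' @param marker1,marker2 marker IDs or row indices.
#' @return for `estimateRf()`: list `rf`, `lod`, `n`, `flagged` for the pair.
#' @export
estimateRf <- function(abh, marker1, marker2, minInformative = 10L) {
    sub <- abh[c(marker1, marker2), ]
    ok <- colSums(is.na(calls(sub))) == 0L
    if (sum(ok) < 2L) stop("fewer than 2 genotypes with both markers observed")
    res <- .rfEM(calls(sub))
    list(rf = res$rf[1L, 2L], lod = res$lod[1L, 2L], n = res$n[1L, 2L],
         flagged = res$n[1L, 2L] < minInformative)
}

#' Single-linkage grouping of markers
#'
#' Markers joined by any edge with `rf <= rfMax` and `LOD >= lodMin` end up
#' in one linkage group (connected components of the thresholded graph).
#'
#' @param rfResult result of [estimateRfMatrix()].
#' @param rfMax maximum recombination fraction for an edge (default 0.35).
#' @param lodMin minimum LOD for an edge (default 6).
#' @return integer vector of group memberships named by marker, groups
#'   numbered by first occurrence.
#' @export
groupMarkers <- function(rfResult, rfMax = 0.35, lodMin = 6) {
    adj <- rfResult$rf <= rfMax & rfResult$lod >= lodMin
    diag(adj) <- FALSE
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    mem <- igraph::components(g)$membership
    out <- match(mem, unique(mem))
    setNames(out, rownames(rfResult$rf))
}

.pathCost <- function(ord, rf)
    sum(rf[cbind(ord[-length(ord)], ord[-1L])])

.twoOpt <- function(ord, rf, maxSweeps = 100L) {
    k <- length(ord)
    if (k < 4L) return(ord)
    for (s in seq_len(maxSweeps)) {
        improved <- FALSE
        for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
            left <- if (i > 1L) rf[ord[i - 1L], ord[i]] else 0
            right <- if (j < k) rf[ord[j], ord[j + 1L]] else 0
            newLeft <- if (i > 1L) rf[ord[i - 1L], ord[j]] else 0
            newRight <- if (j < k) rf[ord[i], ord[j + 1L]] else 0
            if (newLeft + newRight < left + right - 1e-12) {
                ord[i:j] <- rev(ord[i:j])
                improved <- TRUE
            }
        }
        if (!improved) break
    }
    ord
}

#' Order markers within a linkage group
#'
#' Seriation minimizing the sum of adjacent recombination fractions: a
#' minimum-spanning-tree backbone (its diameter path), cheapest insertion
#' of the remaining markers, then 2-opt refinement.  Whole-group
#' orientation is fixed by anchoring the group's first input marker to the
#' first half of the order (reversal is unidentifiable).  Cumulative
#' Kosambi cM positions are assigned from the adjacent recombination
#' fractions.
#'
#' @param markers marker IDs of the group (>= 1).
#' @param rfResult result of [estimateRfMatrix()].
#' @return data.frame `marker`, `cM` in map order.
#' @export
orderMarkers <- function(markers, rfResult) {
    rf <- rfResult$rf[markers, markers, drop = FALSE]
    k <- length(markers)
    if (k == 1L) return(data.frame(marker = markers, cM = 0))
    if (k == 2L) {
        d <- kosambiCM(min(rf[1L, 2L], 0.4999))
        return(data.frame(marker = markers, cM = c(0, d)))
    }
    g <- igraph::graph_from_adjacency_matrix(rf + 1e-9, mode = "undirected",
                                             weighted = TRUE, diag = FALSE)
    tree <- igraph::mst(g)
    backbone <- as.integer(igraph::get_diameter(tree))
    remaining <- setdiff(seq_len(k), backbone)
    ord <- backbone
    for (v in remaining) {
        best <- Inf; bestPos <- 1L
        for (pos in 0:length(ord)) {
            cand <- append(ord, v, after = pos)
            cost <- .pathCost(cand, rf)
            if (cost < best - 1e-15) { best <- cost; bestPos <- pos }
        }
        ord <- append(ord, v, after = bestPos)
    }
    ord <- .twoOpt(ord, rf)
    if (match(1L, ord) > (k + 1L) / 2) ord <- rev(ord)
    adj <- rf[cbind(ord[-k], ord[-1L])]
    data.frame(marker = markers[ord],
               cM = cumsum(c(0, kosambiCM(pmin(adj, 0.4999)))))
}

#' Build a genetic map from an ABH matrix
#'
#' Two-point recombination fractions, single-linkage grouping and per-group
#' MST/2-opt ordering with cumulative Kosambi distances.
#'
#' @param abh an [AbhMatrix-class].
#' @inheritParams groupMarkers
#' @inheritParams estimateRfMatrix
#' @return data.frame `marker`, `group` (e.g. `"LG1"`), `cM`, with the
#'   [estimateRfMatrix()] result attached as attribute `"rf"`.
#' @export
buildLinkageMap <- function(abh, rfMax = 0.35, lodMin = 6,
                            minInformative = 10L) {
    rfRes <- estimateRfMatrix(abh, minInformative)
    grp <- groupMarkers(rfRes, rfMax, lodMin)
    out <- lapply(sort(unique(grp)), function(g_) {
        om <- orderMarkers(names(grp)[grp == g_], rfRes)
        om$group <- paste0("LG", g_)
        om
    })
    map <- do.call(rbind, out)[, c("marker", "group", "cM")]
    rownames(map) <- NULL
    attr(map, "rf") <- rfRes
    map
}

#' Concordance of an estimated map with a reference map
#'
#' For each estimated linkage group: the majority reference chromosome of
#' its markers, the fraction of markers agreeing with it, and the absolute
#' Spearman correlation of estimated vs reference positions (orientation-
#' free order concordance).
#'
#' @param map data.frame from [buildLinkageMap()].
#' @param refChrom,refPos reference chromosome and position, named by marker.
#' @return data.frame per group: `group`, `n`, `refChrom`, `purity`,
#'   `orderCor`.
#' @export
mapConcordance <- function(map, refChrom, refPos) {
    out <- lapply(split(map, map$group), function(d) {
        rc <- refChrom[d$marker]
        maj <- names(sort(table(rc), decreasing = TRUE))[1L]
        oc <- if (nrow(d) > 2L)
            abs(suppressWarnings(cor(d$cM, refPos[d$marker],
                                     method = "spearman")))
        else NA_real_
        data.frame(group = d$group[1L], n = nrow(d), refChrom = maj,
                   purity = mean(rc == maj), orderCor = oc)
    })
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
}
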