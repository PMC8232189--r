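.MISSING_RAW <- c(NA, "", "-", "NA", "NN", "--")

.classifyCall <- function(x) {
    ## returns list(type = "missing"|"het"|"hom", allele = char)
    if (is.na(x) || x %in% .MISSING_RAW) return(list(type = "missing"))
    a <- strsplit(x, "")[[1L]]
    if (length(a) == 1L) a <- c(a, a)
    if (length(a) != 2L) stop("malformed call: ", x)
    if (a[1L] == a[2L]) list(type = "hom", allele = a[1L])
    else list(type = "het", alleles = sort(a))
}

#' Encode raw biallelic calls as ABH relative to the cross parents
#'
#' Offspring calls equal to parent 1's homozygous call become `A`, equal to
#' parent 2's become `B`, heterozygous calls become `H`.  When one parent is
#' missing or heterozygous at a marker, the other parent is used as the
#' reference (its allele anchors its own side of the coding; the opposite
#' homozygote is assigned to the other side).  Markers where both parents
#' are heterozygous and/or missing are dropped, as are markers that do not
#' segregate among the offspring (fewer than two genotype classes).
#'
#' @param raw character matrix of two-letter calls (e.g. `"GG"`, `"GT"`),
#'   genotypes in rows, markers in columns, including both parent rows.
#' @param parent1,parent2 row names of the two parents (parent 1 = inbred
#'   annual line, coded A; parent 2 = perennial parent, coded B).
#' @param chrom,posCM optional per-marker metadata.
#' @return an [AbhMatrix-class] of the offspring (parents removed); dropped
#'   markers are reported in `metadata(x)$encodeLog`.
#' @export
encodeAbh <- function(raw, parent1 = "P1", parent2 = "P2",
                      chrom = NA_character_, posCM = NA_real_) {
    if (!all(c(parent1, parent2) %in% rownames(raw)))
        stop("both parent rows must be present")
    off <- raw[setdiff(rownames(raw), c(parent1, parent2)), , drop = FALSE]
    nm <- ncol(raw)
    chrom <- rep_len(chrom, nm); posCM <- rep_len(posCM, nm)
    keep <- logical(nm)
    dropReason <- character(nm)
    out <- matrix(NA_character_, nrow(off), nm, dimnames = dimnames(off))
    for (j in seq_len(nm)) {
        p1 <- .classifyCall(raw[parent1, j])
        p2 <- .classifyCall(raw[parent2, j])
        if (p1$type != "hom" && p2$type != "hom") {
            dropReason[j] <- "both parents heterozygous/missing"
            next
        }
        aA <- if (p1$type == "hom") p1$allele else NA
        aB <- if (p2$type == "hom") p2$allele else NA
        if (!is.na(aA) && !is.na(aB) && aA == aB) {
            dropReason[j] <- "parents share the same homozygous allele"
            next
        }
        v <- vapply(off[, j], function(x) {
            cl <- .classifyCall(x)
            if (cl$type == "missing") return(NA_character_)
            if (cl$type == "het") return("H")
            if (!is.na(aA) && cl$allele == aA) return("A")
            if (!is.na(aB) && cl$allele == aB) return("B")
            ## reference rule: the known parent anchors its side, any other
            ## homozygote goes to the unknown parent's side
            if (is.na(aA)) "A" else if (is.na(aB)) "B" else NA_character_
        }, character(1L))
        states <- unique(v[!is.na(v)])
        if (length(states) < 2L) {
            dropReason[j] <- "non-segregating"
            next
        }
        out[, j] <- v
        keep[j] <- TRUE
    }
    abh <- AbhMatrix(t(out[, keep, drop = FALSE]),
                     chrom = chrom[keep], posCM = posCM[keep])
    md <- S4Vectors::metadata(abh)
    md$encodeLog <- data.frame(marker = colnames(raw), kept = keep,
                               reason = dropReason)
    S4Vectors::metadata(abh) <- md
    abh
}

#' Drop markers by missing-call fraction
#'
#' Retains markers whose missing fraction is at most `maxMissing`
#' (strictly-greater fractions are dropped), mirroring the 10 % rule used
#' for F2 chip data.
#'
#' @param abh an [AbhMatrix-class].
#' @param maxMissing maximum tolerated missing fraction (default 0.10).
#' @return filtered [AbhMatrix-class].
#' @export
filterMissing <- function(abh, maxMissing = 0.10) {
    fr <- rowMeans(is.na(calls(abh)))
    abh[fr <= maxMissing, ]
}

#' Collapse perfectly correlated (redundant) markers
#'
#' Markers whose pairwise correlation magnitude equals 1 (on the shared
#' non-missing entries of the 0/1/2 codominant coding, within `tol`) are
#' grouped transitively; from each group a single representative with the
#' fewest missing calls is kept (ties broken by input order).
#'
#' @param abh an [AbhMatrix-class] (>= 2 genotypes).
#' @param tol tolerance on `1 - |r|` (default 1e-12).
#' @return list with `abh` (unique markers) and `groups`
#'   (data.frame `marker`, `group`, `representative`).
#' @export
collapseRedundant <- function(abh, tol = 1e-12) {
    stopifnot(ncol(abh) >= 2L)
    cd <- cdCodes(abh)                       # genotypes x markers
    r <- suppressWarnings(cor(cd, use = "pairwise.complete.obs"))
    adj <- !is.na(r) & abs(r) >= 1 - tol
    diag(adj) <- TRUE
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                             diag = FALSE)
    comp <- igraph::components(g)$membership
    ## renumber groups by first member for determinism
    comp <- match(comp, unique(comp))
    nmiss <- rowSums(is.na(calls(abh)))
    rep_ <- vapply(split(seq_along(comp), comp), function(ix)
        ix[which.min(nmiss[ix])], integer(1L))
    keep <- sort(unname(rep_))
    groups <- data.frame(marker = rownames(abh), group = comp,
                         representative = rownames(abh)[rep_[comp]])
    list(abh = abh[keep, ], groups = groups)
}

.imputeVectorByFlanks <- function(v) {
    nn <- which(!is.na(v))
    if (length(nn) < 2L) return(v)
    for (j in which(is.na(v))) {
        lo <- nn[nn < j]; hi <- nn[nn > j]
        if (!length(lo) || !length(hi)) next
        l <- v[max(lo)]; r <- v[min(hi)]
        if (l == r) v[j] <- l
    }
    v
}

#' Impute missing calls from agreeing flanking markers
#'
#' Within each chromosome (markers must be ordered by position) a missing
#' call whose nearest non-missing left and right neighbors in the same
#' genotype agree is set to that shared state.  Calls left unresolved
#' (disagreeing flanks, chromosome ends) are then filled by a second pass
#' with the most frequent state at that marker; the second-pass fill count
#' is recorded in `metadata(x)$imputation` so it can be audited.
#'
#' @param abh an [AbhMatrix-class] with markers ordered within chromosomes.
#' @return imputed [AbhMatrix-class].
#' @export
imputeByFlanks <- function(abh) {
    ch <- markerChrom(abh); pos <- markerPos(abh)
    for (c_ in unique(ch)) {
        p <- pos[ch == c_]
        if (anyNA(p) || is.unsorted(p))
            stop("markers must be ordered by position within chromosomes")
    }
    x <- calls(abh)
    nMissBefore <- sum(is.na(x))
    for (c_ in unique(ch)) {
        rows <- which(ch == c_)
        sub <- x[rows, , drop = FALSE]
        if (anyNA(sub))
            sub <- apply(sub, 2L, .imputeVectorByFlanks)
        x[rows, ] <- sub
    }
    afterFlanks <- sum(is.na(x))
    for (i in which(rowSums(is.na(x)) > 0)) {
        tab <- table(factor(x[i, ], levels = .ABH_STATES))
        x[i, is.na(x[i, ])] <- .ABH_STATES[which.max(tab)]
    }
    out <- AbhMatrix(x, chrom = ch, posCM = pos, truth = truthRecord(abh))
    md <- S4Vectors::metadata(out)
    md$imputation <- list(flankFilled = nMissBefore - afterFlanks,
                          secondPassFilled = afterFlanks)
    S4Vectors::metadata(out) <- md
    if (afterFlanks > 0)
        message(afterFlanks, " call(s) filled by the second (modal) pass")
    out
}

#' Segregation-distortion scan
#'
#' Chi-square goodness-of-fit of each marker's non-missing genotype counts
#' against the Mendelian F2 expectation 1:2:1 (df = 2, no continuity
#' correction), with `-log10(p)` and an unadjusted 5 %-level flag.
#'
#' @param abh an [AbhMatrix-class].
#' @return data.frame: `marker`, `chrom`, `posCM`, `nA`, `nH`, `nB`,
#'   `chi2`, `p`, `neglog10p`, `sig5`.
#' @export
distortionScan <- function(abh) {
    x <- calls(abh)
    nA <- rowSums(x == "A", na.rm = TRUE)
    nH <- rowSums(x == "H", na.rm = TRUE)
    nB <- rowSums(x == "B", na.rm = TRUE)
    n <- nA + nH + nB
    if (any(n == 0L))
        stop("marker(s) with zero non-missing calls: ",
             paste(rownames(abh)[n == 0L], collapse = ", "))
    chi2 <- (nA - n / 4)^2 / (n / 4) + (nH - n / 2)^2 / (n / 2) +
        (nB - n / 4)^2 / (n / 4)
    p <- pchisq(chi2, df = 2, lower.tail = FALSE)
    data.frame(marker = rownames(abh), chrom = markerChrom(abh),
               posCM = markerPos(abh), nA = nA, nH = nH, nB = nB,
               chi2 = chi2, p = p, neglog10p = -log10(p), sig5 = p < 0.05,
               row.names = NULL)
}

#' Per-marker allele-frequency profile
#'
#' Frequencies of the A, H, B and missing classes over all calls, ordered
#' by chromosome and map position (a Fig.-4-style track; expected values in
#' a neutral F2 are 0.25, 0.5, 0.25).
#'
#' @param abh an [AbhMatrix-class].
#' @return data.frame: `marker`, `chrom`, `posCM`, `freqA`, `freqH`,
#'   `freqB`, `freqMissing`.
#' @export
alleleFrequencyProfile <- function(abh) {
    x <- calls(abh)
    n <- ncol(x)
    df <- data.frame(marker = rownames(abh), chrom = markerChrom(abh),
                     posCM = markerPos(abh),
                     freqA = rowSums(x == "A", na.rm = TRUE) / n,
                     freqH = rowSums(x == "H", na.rm = TRUE) / n,
                     freqB = rowSums(x == "B", na.rm = TRUE) / n,
                     freqMissing = rowMeans(is.na(x)), row.names = NULL)
    df[order(df$chrom, df$posCM), , drop = FALSE]
}

#' Inter-chromosome marker-correlation screen for multivalents
#'
#' For every pair of distinct chromosomes, the maximum absolute pairwise
#' marker correlation (codominant coding, pairwise-complete observations).
#' Co-segregation of translocated chromosomes in a ring multivalent would
#' show up as near-perfect correlation between markers on different
#' chromosomes; independent chromosomes stay near zero.  Markers on the
#' same chromosome are excluded (linkage is expected there).
#'
#' @param abh an [AbhMatrix-class] with chromosome assignment.
#' @param flagThreshold absolute-correlation flag level (default 0.5).
#' @return list with `maxCor` (chromosome pair matrix) and `flags`
#'   (data.frame of flagged pairs).
#' @export
multivalentScreen <- function(abh, flagThreshold = 0.5) {
    ch <- markerChrom(abh)
    if (all(is.na(ch))) stop("chromosome assignment required")
    cd <- cdCodes(abh)
    r <- suppressWarnings(cor(cd, use = "pairwise.complete.obs"))
    chs <- unique(ch)
    k <- length(chs)
    mx <- matrix(NA_real_, k, k, dimnames = list(chs, chs))
    for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
        sub <- abs(r[ch == chs[i], ch == chs[j], drop = FALSE])
        mx[i, j] <- mx[j, i] <- if (all(is.na(sub))) NA_real_
                                else max(sub, na.rm = TRUE)
    }
    ij <- which(upper.tri(mx) & !is.na(mx) & mx > flagThreshold, arr.ind = TRUE)
    flags <- data.frame(chrom1 = chs[ij[, 1L]], chrom2 = chs[ij[, 2L]],
                        maxAbsCor = mx[ij])
    list(maxCor = mx, flags = flags[order(flags$chrom1, flags$chrom2), ,
                                    drop = FALSE])
}

#' Detect genotype duplicates
#'
#' Pairs of genotypes whose calls are identical over at least `minIdentity`
#' of their shared non-missing markers, as used to spot accidental clone
#' duplication in F2 panels.
#'
#' @param abh an [AbhMatrix-class].
#' @param minIdentity identity threshold (default 0.99).
#' @return data.frame: `genotype1`, `genotype2`, `identity`, `shared`.
#' @export
findDuplicateGenotypes <- function(abh, minIdentity = 0.99) {
    x <- calls(abh)
    ids <- colnames(x)
    out <- list()
    for (i in seq_len(ncol(x) - 1L)) for (j in (i + 1L):ncol(x)) {
        ok <- !is.na(x[, i]) & !is.na(x[, j])
        sh <- sum(ok)
        if (sh == 0L) next
        idn <- sum(x[ok, i] == x[ok, j]) / sh
        if (idn >= minIdentity)
            out[[length(out) + 1L]] <- data.frame(
                genotype1 = ids[i], genotype2 = ids[j],
                identity = idn, shared = sh)
    }
    if (!length(out))
        return(data.frame(genotype1 = character(), genotype2 = character(),
                          identity = numeric(), shared = integer()))
    do.call(rbind, out)
}

#' @rdname findDuplicateGenotypes
#' @param drop `"one"` keeps one member of each duplicate pair (map
#'   construction); `"both"` removes both members (marker studies and
#'   mapping), mirroring the two uses of duplicate removal in F2 panels.
#' @return for `dropDuplicateGenotypes()`: the reduced [AbhMatrix-class].
#' @export
dropDuplicateGenotypes <- function(abh, minIdentity = 0.99,
                                   drop = c("one", "both")) {
    drop <- match.arg(drop)
    dup <- findDuplicateGenotypes(abh, minIdentity)
    rm_ <- if (drop == "one") unique(dup$genotype2)
           else unique(c(dup$genotype1, dup$genotype2))
    abh[, !colnames(abh) %in% rm_]
}
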