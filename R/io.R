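.MISSING_IO <- c("", "-", "NA")

#' Read / write the genotype CSV dialect
#'
#' The cross-file CSV layout used by common QTL software: a header row of
#' marker names (first cell `id`), two optional metadata rows whose first
#' cell is `chromosome` and `cM`, then one row per genotype.  Missing
#' calls are `NA`, `-` or empty.  If all calls are ABH symbols an
#' [AbhMatrix-class] is returned; otherwise (raw two-letter calls,
#' typically including parent rows) a plain character matrix with
#' attributes `chrom` and `posCM`, ready for [encodeAbh()].
#'
#' @param path file path.
#' @return an [AbhMatrix-class] or a character matrix.
#' @export
readGenotypeCsv <- function(path) {
    nf <- utils::count.fields(path, sep = ",", quote = "\"")
    if (length(unique(nf)) != 1L)
        stop("ragged CSV: rows have differing field counts")
    x <- read.csv(path, header = TRUE, colClasses = "character",
                  check.names = FALSE)
    markers <- colnames(x)[-1L]
    if (anyDuplicated(markers))
        stop("duplicate marker IDs: ",
             paste(unique(markers[duplicated(markers)]), collapse = ", "))
    chrom <- rep(NA_character_, length(markers))
    posCM <- rep(NA_real_, length(markers))
    meta <- x[[1L]] %in% c("chromosome", "cM")
    if (any(x[[1L]] == "chromosome"))
        chrom <- unlist(x[x[[1L]] == "chromosome", -1L][1L, ], use.names = FALSE)
    if (any(x[[1L]] == "cM"))
        posCM <- as.numeric(unlist(x[x[[1L]] == "cM", -1L][1L, ],
                                   use.names = FALSE))
    g <- x[!meta, , drop = FALSE]
    ids <- g[[1L]]
    m <- as.matrix(g[, -1L, drop = FALSE])
    rownames(m) <- ids
    m[m %in% .MISSING_IO] <- NA_character_
    if (all(is.na(m) | m %in% .ABH_STATES))
        return(AbhMatrix(t(m), chrom = chrom, posCM = posCM))
    ok <- is.na(m) | grepl("^[ACGT]{1,2}$|^[AHB]$", m)
    if (!all(ok)) {
        ij <- which(!ok, arr.ind = TRUE)[1L, ]
        stop(sprintf("invalid call symbol '%s' at genotype '%s', marker '%s'",
                     m[ij[1L], ij[2L]], rownames(m)[ij[1L]],
                     markers[ij[2L]]))
    }
    attr(m, "chrom") <- chrom
    attr(m, "posCM") <- posCM
    m
}

#' @rdname readGenotypeCsv
#' @param abh an [AbhMatrix-class].
#' @export
writeGenotypeCsv <- function(abh, path) {
    x <- calls(abh)
    header <- c("id", rownames(x))
    chromRow <- c("chromosome", markerChrom(abh))
    cmRow <- c("cM", markerPos(abh))
    body <- cbind(colnames(x), t(x))
    body[is.na(body)] <- "NA"
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste(header, collapse = ","), con)
    writeLines(paste(chromRow, collapse = ","), con)
    writeLines(paste(cmRow, collapse = ","), con)
    apply(body, 1L, function(r) writeLines(paste(r, collapse = ","), con))
    invisible(path)
}

#' Read / write the long-format phenotype CSV
#'
#' Columns `genotype`, `location`, `replicate`, `trait`, `value`.
#'
#' @param path file path.
#' @return data.frame.
#' @export
readPhenotypeCsv <- function(path) {
    d <- read.csv(path, check.names = FALSE)
    .checkPheno(d)
    d$value <- as.numeric(d$value)
    d
}

#' @rdname readPhenotypeCsv
#' @param pheno a long-format phenotype data.frame.
#' @export
writePhenotypeCsv <- function(pheno, path) {
    write.csv(.checkPheno(pheno), path, row.names = FALSE, quote = FALSE)
    invisible(path)
}
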