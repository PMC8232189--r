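#' Construct an AbhMatrix
#'
#' @param calls character matrix of `"A"`/`"H"`/`"B"`/`NA` calls, markers in
#'   rows, genotypes in columns; dimnames give marker and genotype IDs.
#' @param chrom chromosome assignment per marker (recycled if length 1).
#' @param posCM map position in cM per marker (`NA` allowed before mapping).
#' @param truth optional list stored in `metadata(x)$truth`.
#' @return an [AbhMatrix-class].
#' @examples
#' m <- matrix(c("A","H","B","H"), 2, 2,
#'             dimnames = list(c("m1","m2"), c("g1","g2")))
#' AbhMatrix(m, chrom = "1R", posCM = c(0, 10))
#' @export
AbhMatrix <- function(calls, chrom = NA_character_, posCM = NA_real_,
                      truth = NULL) {
    if (is.null(rownames(calls)))
        rownames(calls) <- sprintf("m%04d", seq_len(nrow(calls)))
    if (is.null(colnames(calls)))
        colnames(calls) <- sprintf("G%04d", seq_len(ncol(calls)))
    rd <- S4Vectors::DataFrame(
        chrom = rep_len(as.character(chrom), nrow(calls)),
        posCM = rep_len(as.numeric(posCM), nrow(calls)),
        row.names = rownames(calls))
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(calls = calls), rowData = rd)
    md <- S4Vectors::metadata(se)
    md$truth <- truth
    S4Vectors::metadata(se) <- md
    new("AbhMatrix", se)
}

#' @rdname AbhMatrix
#' @param x an `AbhMatrix`.
#' @export
calls <- function(x) SummarizedExperiment::assay(x, "calls")

#' @rdname AbhMatrix
#' @export
markerChrom <- function(x)
    as.character(SummarizedExperiment::rowData(x)$chrom)

#' @rdname AbhMatrix
#' @export
markerPos <- function(x) as.numeric(SummarizedExperiment::rowData(x)$posCM)

#' Numeric marker codings
#'
#' `cdCodes()` returns the codominant (additive dosage) coding 0/1/2 for
#' A/H/B; `dCodes()` the dominant (heterozygote indicator) coding 0/1/0.
#' Both return a genotypes x markers numeric matrix (`NA` preserved), i.e.
#' the transpose of the call matrix, ready for regression.
#'
#' @param x an [AbhMatrix-class].
#' @return numeric matrix, genotypes in rows, markers in columns.
#' @export
cdCodes <- function(x) {
    m <- calls(x)
    out <- matrix(NA_real_, nrow(m), ncol(m), dimnames = dimnames(m))
    out[m == "A"] <- 0; out[m == "H"] <- 1; out[m == "B"] <- 2
    t(out)
}

#' @rdname cdCodes
#' @export
dCodes <- function(x) {
    m <- calls(x)
    out <- matrix(NA_real_, nrow(m), ncol(m), dimnames = dimnames(m))
    out[m == "A"] <- 0; out[m == "H"] <- 1; out[m == "B"] <- 0
    t(out)
}

#' Truth record of a simulated object
#' @param x an [AbhMatrix-class] or [SimulatedStudy-class].
#' @return the truth list, or `NULL` for real data.
#' @export
truthRecord <- function(x) {
    if (is(x, "SimulatedStudy")) return(x@truth)
    S4Vectors::metadata(x)$truth
}

#' @rdname SimulatedStudy-class
#' @param x a `SimulatedStudy`.
#' @export
genoData <- function(x) x@geno

#' @rdname SimulatedStudy-class
#' @export
phenoData <- function(x) x@pheno

.markerIndex <- function(abh, chrom, posCM) {
    i <- which(markerChrom(abh) == chrom & abs(markerPos(abh) - posCM) < 1e-9)
    if (length(i) != 1L)
        stop(sprintf("no unique marker at %s:%.3f cM", chrom, posCM))
    i
}

#' Genotype counts at one marker
#' @param x an [AbhMatrix-class].
#' @param marker marker ID or row index.
#' @return named integer vector `c(A=, H=, B=)` over non-missing calls.
#' @export
genotypeCounts <- function(x, marker) {
    v <- calls(x)[marker, ]
    c(A = sum(v == "A", na.rm = TRUE),
      H = sum(v == "H", na.rm = TRUE),
      B = sum(v == "B", na.rm = TRUE))
}
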