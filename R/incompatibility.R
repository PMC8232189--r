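#' Gametophytic self-incompatibility predicates
#'
#' In the two-locus self-fertility model for the rye intercross, pollen is
#' haploid: a pollen grain is compatible on a selfed stigma iff it carries
#' the self-fertility (A) allele at the pollen-side locus *Z*, regardless of
#' its *S5* allele.  The stigma is diploid and the *S5* self-fertility
#' allele is dominant: a plant can be self-pollinated iff it carries at
#' least one A allele at *S5*.
#'
#' @param zAllele pollen allele at *Z*, `"A"` or `"B"` (vectorized).
#' @param s5Allele pollen allele at *S5* (ignored for compatibility; kept to
#'   document that compatibility is independent of it).
#' @return logical.
#' @examples
#' pollenCompatible("A")  # TRUE
#' pollenCompatible("B")  # FALSE
#' stigmaSelfable(c("A","B"))  # heterozygote selfable: TRUE
#' @export
pollenCompatible <- function(zAllele, s5Allele = NULL) {
    stopifnot(all(zAllele %in% c("A", "B")))
    zAllele == "A"
}

#' @rdname pollenCompatible
#' @param s5Genotype character vector of two alleles from \{"A","B"\}, the
#'   stigma (plant) genotype at *S5*; or a single call `"A"`, `"H"`, `"B"`.
#' @export
stigmaSelfable <- function(s5Genotype) {
    if (length(s5Genotype) == 1L && s5Genotype %in% c("A", "H", "B"))
        s5Genotype <- switch(s5Genotype, A = c("A", "A"), H = c("A", "B"),
                             B = c("B", "B"))
    stopifnot(length(s5Genotype) == 2L, all(s5Genotype %in% c("A", "B")))
    any(s5Genotype == "A")
}

#' Expected F2 genotype ratio at a selection locus
#'
#' Enumerates egg gametes crossed with compatible pollen gametes from a
#' heterozygous F1.  With pollen-side selection at *Z*, B-carrying pollen is
#' excluded, giving A:H:B = 1:1:0; *S5* acts on the stigma only and the F1
#' stigma (A/B heterozygote) is selfable, so *S5* segregates 1:2:1 in the
#' F2, as does any unselected locus.
#'
#' @param locus `"Z"`, `"S5"`, or any other name (treated as neutral).
#' @param selection logical; apply the locus' selection rule (default TRUE).
#' @return integer ratio `c(A=, H=, B=)` in lowest terms.
#' @export
expectedF2Ratio <- function(locus = c("Z", "S5"), selection = TRUE) {
    locus <- match.arg(locus)
    egg <- c(A = 1L, B = 1L)
    pollen <- c(A = 1L, B = 1L)
    if (selection && locus == "Z") pollen["B"] <- 0L
    # S5 stigma rule applies to the (heterozygous, selfable) F1 stigma: no-op
    ratio <- c(A = 0L, H = 0L, B = 0L)
    for (e in names(egg)) for (p in names(pollen)) {
        g <- if (e == p) e else "H"
        ratio[g] <- ratio[g] + egg[e] * pollen[p]
    }
    ratio %/% .gcdVec(ratio)
}

.gcdVec <- function(x) {
    g <- function(a, b) if (b == 0) a else g(b, a %% b)
    Reduce(g, x[x > 0])
}

#' Expected S5 ratios in pooled F3 progeny
#'
#' Enumerates selfed offspring over the F2 *S5* genotype classes
#' (1 AA : 2 AH : 1 BB).  With stigma selection, BB plants cannot be selfed;
#' AA and AH plants contribute equal-sized Mendelian selfed families.
#' Pooling gives the genotype ratio A:H:B = 3:2:1 and a 2:1 ratio of
#' parental A to B alleles.  With `stigmaSelection = FALSE` neutral selfing
#' preserves 1:2:1 (allele ratio 1:1).
#'
#' @param stigmaSelection apply the dominant stigma-side rule (default TRUE).
#' @return list with integer `genotypeRatio` `c(A=,H=,B=)` and
#'   `alleleRatio` `c(A=,B=)`, both in lowest terms.
#' @export
expectedF3RatioS5 <- function(stigmaSelection = TRUE) {
    f2 <- c(A = 1L, H = 2L, B = 1L)          # F2 S5 genotype classes
    selfed <- list(A = c(A = 4L, H = 0L, B = 0L),  # AA x AA
                   H = c(A = 1L, H = 2L, B = 1L),  # Mendelian selfing
                   B = c(A = 0L, H = 0L, B = 4L))
    pooled <- c(A = 0L, H = 0L, B = 0L)
    for (g in names(f2)) {
        if (stigmaSelection && !stigmaSelfable(g)) next
        pooled <- pooled + f2[[g]] * selfed[[g]]
    }
    geno <- pooled %/% .gcdVec(pooled)
    allele <- c(A = 2L * pooled[["A"]] + pooled[["H"]],
                B = 2L * pooled[["B"]] + pooled[["H"]])
    allele <- allele %/% .gcdVec(allele)
    list(genotypeRatio = geno, alleleRatio = allele)
}

#' Viable gamete fraction from a ring multivalent
#'
#' A ring multivalent of `2 * nPairs` chromosomes (e.g. a hexavalent for
#' `nPairs = 3`) is modeled by independent disjunction: each homologous pair
#' contributes exactly one chromosome to the gamete, independently and
#' equiprobably.  A gamete is viable iff all contributed ring chromosomes
#' derive from the same parental species (a full haploid complement requires
#' DNA of every chromosome).  The fraction is computed by enumerating all
#' `2^nPairs` gamete types; it equals `2^(1 - nPairs)`.
#'
#' @param nPairs number of homologous chromosome pairs in the ring
#'   (default 3, the classical rye hexavalent, giving 25 %).
#' @return list with `viable`, `total` (integer counts) and `fraction`.
#' @examples
#' multivalentViableFraction(3)$fraction  # 0.25
#' @export
multivalentViableFraction <- function(nPairs = 3L) {
    nPairs <- as.integer(nPairs)
    stopifnot(nPairs >= 1L)
    types <- as.matrix(expand.grid(rep(list(c(0L, 1L)), nPairs)))
    viable <- sum(apply(types, 1L, function(z) all(z == z[1L])))
    list(viable = viable, total = nrow(types),
         fraction = viable / nrow(types))
}

#' Self-incompatibility model report
#'
#' Collects the closed-form expectations of the incompatibility and
#' multivalent models into one list, suitable for JSON/YAML serialization.
#'
#' @param nPairs ring size for [multivalentViableFraction()].
#' @return nested list of ratios and fractions.
#' @export
incompatibilityReport <- function(nPairs = 3L) {
    f3 <- expectedF3RatioS5()
    list(
        f2ZRatio = as.list(expectedF2Ratio("Z")),
        f2S5Ratio = as.list(expectedF2Ratio("S5")),
        f3S5GenotypeRatio = as.list(f3$genotypeRatio),
        f3S5AlleleRatio = as.list(f3$alleleRatio),
        multivalent = multivalentViableFraction(nPairs))
}
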