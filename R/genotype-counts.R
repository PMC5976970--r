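.asCount <- function(x, what) {
    if (length(x) != 1L || is.na(x) || !is.numeric(x) ||
        abs(x - round(x)) > 1e-8 || x < 0)
        stop(sprintf("'%s' must be a single non-negative integer", what),
             call. = FALSE)
    as.integer(round(x))
}

#' Construct a GenotypeCounts object
#'
#' Builds a [GenotypeCounts-class] tally for one SNP in one group. By
#' default the constructor keeps the major/minor labelling honest: when the
#' allele labelled minor has sample frequency above 0.5, labels and
#' homozygote counts are swapped; an exact tie at 0.5 is broken by putting
#' the alphabetically earlier allele in the major slot. Set
#' `relabel = FALSE` to keep the given orientation (used internally to hold
#' a pooled-sample orientation fixed across groups).
#'
#' @param snpId character(1) SNP identifier.
#' @param alleleMajor,alleleMinor single-character allele symbols.
#' @param nHomMajor,nHet,nHomMinor,nMissing non-negative integer counts;
#'   `nMissing` counts individuals whose genotype could not be determined
#'   and is excluded from every frequency or model computation.
#' @param gene optional gene symbol.
#' @param relabel logical(1); enforce the minor-allele labelling (default).
#' @return a validated `GenotypeCounts` object.
#' @examples
#' g <- GenotypeCounts("rs0001", "G", "A", nHomMajor = 73, nHet = 39,
#'                     nHomMinor = 1)
#' maf(g)  # 41/226
#' @export
GenotypeCounts <- function(snpId, alleleMajor, alleleMinor,
                           nHomMajor, nHet, nHomMinor, nMissing = 0L,
                           gene = NA_character_, relabel = TRUE) {
    nHomMajor <- .asCount(nHomMajor, "nHomMajor")
    nHet <- .asCount(nHet, "nHet")
    nHomMinor <- .asCount(nHomMinor, "nHomMinor")
    nMissing <- .asCount(nMissing, "nMissing")
    alleleMajor <- as.character(alleleMajor)
    alleleMinor <- as.character(alleleMinor)
    if (relabel) {
        tot <- nHomMajor + nHet + nHomMinor
        if (tot < 1L)
            stop("at least one genotyped individual is required", call. = FALSE)
        fMinor <- (2 * nHomMinor + nHet) / (2 * tot)
        swap <- fMinor > 0.5 ||
            (fMinor == 0.5 && alleleMajor > alleleMinor)
        if (swap) {
            tmpA <- alleleMajor; alleleMajor <- alleleMinor; alleleMinor <- tmpA
            tmpN <- nHomMajor; nHomMajor <- nHomMinor; nHomMinor <- tmpN
        }
    }
    new("GenotypeCounts", snpId = as.character(snpId),
        gene = as.character(gene),
        alleleMajor = alleleMajor, alleleMinor = alleleMinor,
        nHomMajor = nHomMajor, nHet = nHet, nHomMinor = nHomMinor,
        nMissing = nMissing)
}

#' Construct a CaseControlCounts object
#'
#' Pairs the case and control tallies of one SNP. The allele orientation is
#' recomputed on the pooled counts (cases + controls) so both groups agree
#' on which allele is minor; within-group frequencies may then exceed 0.5.
#'
#' @param cases,controls [GenotypeCounts-class] objects for the same SNP
#'   with the same unordered allele pair.
#' @return a validated `CaseControlCounts` object.
#' @export
CaseControlCounts <- function(cases, controls) {
    stopifnot(is(cases, "GenotypeCounts"), is(controls, "GenotypeCounts"))
    if (!identical(cases@snpId, controls@snpId))
        stop("cases and controls refer to different SNPs: '", cases@snpId,
             "' vs '", controls@snpId, "'", call. = FALSE)
    pairCa <- sort(c(cases@alleleMajor, cases@alleleMinor))
    pairCo <- sort(c(controls@alleleMajor, controls@alleleMinor))
    if (!identical(pairCa, pairCo))
        stop("allele pairs differ between cases (", paste(pairCa, collapse = "/"),
             ") and controls (", paste(pairCo, collapse = "/"), ")",
             call. = FALSE)
    ## pooled orientation: align controls to cases' labels, pool, then decide
    co <- controls
    if (!identical(co@alleleMajor, cases@alleleMajor))
        co <- GenotypeCounts(co@snpId, cases@alleleMajor, cases@alleleMinor,
                             nHomMajor = co@nHomMinor, nHet = co@nHet,
                             nHomMinor = co@nHomMajor, nMissing = co@nMissing,
                             gene = co@gene, relabel = FALSE)
    pooledHomMaj <- cases@nHomMajor + co@nHomMajor
    pooledHomMin <- cases@nHomMinor + co@nHomMinor
    pooledHet <- cases@nHet + co@nHet
    fMinor <- (2 * pooledHomMin + pooledHet) /
        (2 * (pooledHomMaj + pooledHet + pooledHomMin))
    swap <- fMinor > 0.5 ||
        (fMinor == 0.5 && cases@alleleMajor > cases@alleleMinor)
    orient <- function(g) {
        if (!swap) return(g)
        GenotypeCounts(g@snpId, g@alleleMinor, g@alleleMajor,
                       nHomMajor = g@nHomMinor, nHet = g@nHet,
                       nHomMinor = g@nHomMajor, nMissing = g@nMissing,
                       gene = g@gene, relabel = FALSE)
    }
    new("CaseControlCounts", snpId = cases@snpId,
        cases = orient(cases), controls = orient(co))
}

#' Construct a PopulationTable
#'
#' @param populationLabel character(1).
#' @param entries list of [GenotypeCounts-class]; names are taken from the
#'   entries' SNP ids.
#' @return a validated `PopulationTable`.
#' @export
PopulationTable <- function(populationLabel, entries = list()) {
    names(entries) <- vapply(entries, function(g) g@snpId, character(1))
    new("PopulationTable", populationLabel = as.character(populationLabel),
        entries = entries)
}

## ---- accessors --------------------------------------------------------

#' Accessors for the genotype containers
#'
#' `snpId()`, `alleleMajor()`, `alleleMinor()`, `genotypeCounts()` (named
#' vector homMajor/het/homMinor), `nMissing()` for [GenotypeCounts-class]
#' and [CaseControlCounts-class]; `cases()`/`controls()` for
#' `CaseControlCounts`; `populationLabel()` and `snpIds()` for
#' [PopulationTable-class].
#'
#' @param x the object.
#' @name accessors
NULL

#' @rdname accessors
setMethod("snpId", "GenotypeCounts", function(x) x@snpId)
#' @rdname accessors
setMethod("snpId", "CaseControlCounts", function(x) x@snpId)
#' @rdname accessors
setMethod("alleleMajor", "GenotypeCounts", function(x) x@alleleMajor)
#' @rdname accessors
setMethod("alleleMajor", "CaseControlCounts", function(x) x@cases@alleleMajor)
#' @rdname accessors
setMethod("alleleMinor", "GenotypeCounts", function(x) x@alleleMinor)
#' @rdname accessors
setMethod("alleleMinor", "CaseControlCounts", function(x) x@cases@alleleMinor)
#' @rdname accessors
setMethod("genotypeCounts", "GenotypeCounts", function(x)
    c(homMajor = x@nHomMajor, het = x@nHet, homMinor = x@nHomMinor))
#' @rdname accessors
setMethod("nMissing", "GenotypeCounts", function(x) x@nMissing)
#' @rdname accessors
setMethod("cases", "CaseControlCounts", function(x) x@cases)
#' @rdname accessors
setMethod("controls", "CaseControlCounts", function(x) x@controls)
#' @rdname accessors
setMethod("populationLabel", "PopulationTable", function(x) x@populationLabel)
#' @rdname accessors
setMethod("snpIds", "PopulationTable", function(x) names(x@entries))

#' @describeIn accessors extract one SNP's GenotypeCounts by id
#' @param i SNP id (character) or index.
#' @export
setMethod("[[", "PopulationTable", function(x, i) {
    g <- x@entries[[i]]
    if (is.null(g))
        stop("SNP '", i, "' not present in population '",
             x@populationLabel, "'", call. = FALSE)
    g
})

#' @describeIn accessors number of SNPs in a PopulationTable
#' @export
setMethod("length", "PopulationTable", function(x) length(x@entries))

## ---- frequencies ------------------------------------------------------

.nonMissingTotal <- function(g) g@nHomMajor + g@nHet + g@nHomMinor

#' @rdname alleleFrequencies
setMethod("alleleFrequencies", "GenotypeCounts", function(x) {
    tot <- .nonMissingTotal(x)
    if (tot < 1L)
        stop("no non-missing genotypes for SNP '", x@snpId, "'", call. = FALSE)
    fMinor <- (2 * x@nHomMinor + x@nHet) / (2 * tot)
    stats::setNames(c(1 - fMinor, fMinor), c(x@alleleMajor, x@alleleMinor))
})

#' @rdname maf
setMethod("maf", "GenotypeCounts", function(x) {
    unname(min(alleleFrequencies(x)))
})

## ---- show methods -----------------------------------------------------

setMethod("show", "GenotypeCounts", function(object) {
    fr <- alleleFrequencies(object)
    cat(sprintf("GenotypeCounts: %s%s [%s/%s]\n", object@snpId,
                if (is.na(object@gene)) "" else paste0(" (", object@gene, ")"),
                object@alleleMajor, object@alleleMinor))
    cat(sprintf("  %s%s=%d  %s%s=%d  %s%s=%d  missing=%d\n",
                object@alleleMajor, object@alleleMajor, object@nHomMajor,
                object@alleleMajor, object@alleleMinor, object@nHet,
                object@alleleMinor, object@alleleMinor, object@nHomMinor,
                object@nMissing))
    cat(sprintf("  freq(%s)=%.4f  freq(%s)=%.4f  MAF=%.4f\n",
                names(fr)[1], fr[1], names(fr)[2], fr[2], min(fr)))
})

setMethod("show", "CaseControlCounts", function(object) {
    cat(sprintf("CaseControlCounts: %s [%s/%s]\n", object@snpId,
                alleleMajor(object), alleleMinor(object)))
    ca <- genotypeCounts(object@cases); co <- genotypeCounts(object@controls)
    cat(sprintf("  cases:    %3d %3d %3d (missing %d)\n",
                ca[1], ca[2], ca[3], object@cases@nMissing))
    cat(sprintf("  controls: %3d %3d %3d (missing %d)\n",
                co[1], co[2], co[3], object@controls@nMissing))
})

setMethod("show", "PopulationTable", function(object) {
    cat(sprintf("PopulationTable '%s': %d SNP(s)\n",
                object@populationLabel, length(object@entries)))
    if (length(object@entries))
        cat("  ", paste(utils::head(names(object@entries), 8), collapse = ", "),
            if (length(object@entries) > 8) ", ..." else "", "\n", sep = "")
})

## ---- tallying and HWE -------------------------------------------------

#' Tally diploid genotype calls into a GenotypeCounts
#'
#' Converts per-individual genotype calls (e.g. a column of a genotype
#' matrix or parsed VCF GT fields) into counts. Calls are unordered:
#' "AG" and "GA" are the same heterozygote. Recognised missing codes are
#' `NA`, `""`, `"NA"`, `"."`, `".."`, `"./."` and `".|."`; a half-missing
#' call (one named allele, one missing) also counts as missing.
#'
#' @param calls character vector of two-letter calls, optionally separated
#'   by "/" or "|".
#' @param alleles character(2), the allele pair; any other symbol in a call
#'   is an error.
#' @param snpId,gene passed to the result.
#' @return a [GenotypeCounts-class]; the major/minor labelling is taken
#'   from the tallied counts.
#' @examples
#' tallyFromCalls(c("AG", "GA", "GG", "./."), c("A", "G"))
#' @export
tallyFromCalls <- function(calls, alleles, snpId = "SNP",
                           gene = NA_character_) {
    if (length(calls) == 0L)
        stop("no genotype calls supplied", call. = FALSE)
    if (length(alleles) != 2L || anyDuplicated(alleles))
        stop("'alleles' must be two distinct symbols", call. = FALSE)
    a1 <- alleles[1]; a2 <- alleles[2]
    norm <- gsub("[/|]", "", as.character(calls))
    missing <- is.na(norm) | norm %in% c("", "NA", ".", "..")
    halfMiss <- !missing & nchar(norm) == 2 &
        (substr(norm, 1, 1) == "." | substr(norm, 2, 2) == ".")
    missing <- missing | halfMiss
    ok <- norm[!missing]
    if (any(nchar(ok) != 2))
        stop("malformed genotype call(s): ",
             paste(unique(ok[nchar(ok) != 2]), collapse = ", "), call. = FALSE)
    obsAll <- c(substr(ok, 1, 1), substr(ok, 2, 2))
    bad <- setdiff(unique(obsAll), c(a1, a2))
    if (length(bad))
        stop("allele symbol(s) outside the declared pair: ",
             paste(bad, collapse = ", "), call. = FALSE)
    hom1 <- sum(ok == paste0(a1, a1))
    hom2 <- sum(ok == paste0(a2, a2))
    het <- length(ok) - hom1 - hom2
    if (hom1 + het + hom2 < 1L)
        stop("all calls are missing", call. = FALSE)
    GenotypeCounts(snpId, a1, a2, nHomMajor = hom1, nHet = het,
                   nHomMinor = hom2, nMissing = sum(missing), gene = gene)
}

#' Hardy-Weinberg equilibrium chi-square test
#'
#' One-degree-of-freedom Pearson chi-square of the observed genotype counts
#' against the HWE expectations p^2, 2pq, q^2 computed from the sample
#' allele frequencies (missing individuals excluded). Used as a quality
#' check on genotype data and on the synthetic generator; a monomorphic SNP
#' yields the defined result statistic = 0, p = 1 with `monomorphic = TRUE`.
#'
#' @param g a [GenotypeCounts-class].
#' @return list with `statistic`, `df` (always 1), `p.value`, `monomorphic`.
#' @examples
#' hweChisq(GenotypeCounts("s", "A", "B", 25, 50, 25))  # exact HWE: stat 0
#' @export
hweChisq <- function(g) {
    stopifnot(is(g, "GenotypeCounts"))
    n <- .nonMissingTotal(g)
    q <- (2 * g@nHomMinor + g@nHet) / (2 * n)
    if (q == 0 || q == 1)
        return(list(statistic = 0, df = 1L, p.value = 1, monomorphic = TRUE))
    p <- 1 - q
    expected <- n * c(p^2, 2 * p * q, q^2)
    observed <- c(g@nHomMajor, g@nHet, g@nHomMinor)
    stat <- sum((observed - expected)^2 / expected)
    list(statistic = stat, df = 1L,
         p.value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
         monomorphic = FALSE)
}
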