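#' @import methods
NULL

#' GenotypeCounts: genotype tally of one SNP in one group
#'
#' Stores the genotype counts of a single biallelic SNP in one group of
#' individuals: major-allele homozygotes, heterozygotes, minor-allele
#' homozygotes, and individuals whose genotype could not be determined.
#' Counts are kept as exact integers; allele frequencies are derived on
#' demand and never rounded internally.
#'
#' @slot snpId character(1), SNP identifier (typically an rsID).
#' @slot gene character(1), gene symbol the SNP is annotated to (may be NA).
#' @slot alleleMajor character(1), single-character symbol of the major allele.
#' @slot alleleMinor character(1), single-character symbol of the minor allele.
#' @slot nHomMajor integer(1), count of major-allele homozygotes.
#' @slot nHet integer(1), count of heterozygotes.
#' @slot nHomMinor integer(1), count of minor-allele homozygotes.
#' @slot nMissing integer(1), count of individuals with undetermined genotype.
#'
#' @seealso [GenotypeCounts()] for the user constructor, which enforces the
#'   major/minor labelling; [alleleFrequencies()], [maf()].
#' @name GenotypeCounts-class
#' @rdname GenotypeCounts-class
#' @exportClass GenotypeCounts
setClass("GenotypeCounts",
    representation(
        snpId = "character",
        gene = "character",
        alleleMajor = "character",
        alleleMinor = "character",
        nHomMajor = "integer",
        nHet = "integer",
        nHomMinor = "integer",
        nMissing = "integer"
    ),
    prototype(
        snpId = NA_character_, gene = NA_character_,
        alleleMajor = "A", alleleMinor = "B",
        nHomMajor = 1L, nHet = 0L, nHomMinor = 0L, nMissing = 0L
    )
)

setValidity("GenotypeCounts", function(object) {
    msgs <- character()
    for (sl in c("snpId", "gene", "alleleMajor", "alleleMinor",
                 "nHomMajor", "nHet", "nHomMinor", "nMissing")) {
        if (length(slot(object, sl)) != 1L)
            msgs <- c(msgs, sprintf("slot '%s' must have length 1", sl))
    }
    if (length(msgs)) return(msgs)
    cnts <- c(object@nHomMajor, object@nHet, object@nHomMinor, object@nMissing)
    if (anyNA(cnts) || any(cnts < 0L))
        msgs <- c(msgs, "genotype counts must be non-negative integers")
    else if (object@nHomMajor + object@nHet + object@nHomMinor < 1L)
        msgs <- c(msgs, "at least one genotyped individual is required")
    if (is.na(object@alleleMajor) || is.na(object@alleleMinor) ||
        nchar(object@alleleMajor) != 1L || nchar(object@alleleMinor) != 1L)
        msgs <- c(msgs, "alleles must be single-character symbols")
    else if (object@alleleMajor == object@alleleMinor)
        msgs <- c(msgs, "major and minor allele must differ")
    if (length(msgs)) msgs else TRUE
})

#' PopulationTable: genotype counts of many SNPs in one population
#'
#' A named collection of [GenotypeCounts-class] objects (one per SNP) for a
#' single population, e.g. one row block of a multi-population genotype
#' count table.
#'
#' @slot populationLabel character(1), e.g. "SLO", "CEU", "case".
#' @slot entries named list of GenotypeCounts, names = SNP ids, unique.
#'
#' @name PopulationTable-class
#' @rdname PopulationTable-class
#' @exportClass PopulationTable
setClass("PopulationTable",
    representation(populationLabel = "character", entries = "list"),
    prototype(populationLabel = NA_character_, entries = list())
)

setValidity("PopulationTable", function(object) {
    msgs <- character()
    if (length(object@populationLabel) != 1L || is.na(object@populationLabel))
        msgs <- c(msgs, "populationLabel must be a single non-NA string")
    if (length(object@entries)) {
        if (!all(vapply(object@entries, is, logical(1), "GenotypeCounts")))
            msgs <- c(msgs, "all entries must be GenotypeCounts")
        else {
            ids <- vapply(object@entries, function(g) g@snpId, character(1))
            if (is.null(names(object@entries)) ||
                !identical(unname(ids), unname(names(object@entries))))
                msgs <- c(msgs, "entries must be named by their snpId")
            if (anyDuplicated(ids))
                msgs <- c(msgs, "duplicated snpId within a population")
        }
    }
    if (length(msgs)) msgs else TRUE
})

#' CaseControlCounts: paired case and control genotype counts for one SNP
#'
#' Holds one SNP's [GenotypeCounts-class] in cases and in controls with a
#' consistent allele orientation: the major/minor assignment is made on the
#' pooled (cases + controls) counts so that both groups code the same allele
#' as minor even when the within-group frequencies straddle 0.5.
#'
#' @slot snpId character(1).
#' @slot cases,controls GenotypeCounts with identical snpId and allele pair.
#'
#' @seealso [CaseControlCounts()], [fitModel()], [perturbOnce()].
#' @name CaseControlCounts-class
#' @rdname CaseControlCounts-class
#' @exportClass CaseControlCounts
setClass("CaseControlCounts",
    representation(
        snpId = "character",
        cases = "GenotypeCounts",
        controls = "GenotypeCounts"
    )
)

setValidity("CaseControlCounts", function(object) {
    msgs <- character()
    if (!identical(object@cases@snpId, object@snpId) ||
        !identical(object@controls@snpId, object@snpId))
        msgs <- c(msgs, "cases and controls must carry the object's snpId")
    if (!identical(object@cases@alleleMajor, object@controls@alleleMajor) ||
        !identical(object@cases@alleleMinor, object@controls@alleleMinor))
        msgs <- c(msgs, "cases and controls must share the same allele orientation")
    if (length(msgs)) msgs else TRUE
})

#' SyntheticConfig: parameters of the synthetic-data generator
#'
#' Ground-truth parameters for [genPopulationPanel()] (multi-population
#' genotype panels under the Balding-Nichols model) and [genCaseControl()]
#' (retrospectively sampled case-control cohorts under a logistic disease
#' model). Identical config + seed always yields identical output.
#'
#' @slot nSnps integer(1), number of independent SNPs in a panel.
#' @slot ancestralMaf numeric, ancestral minor-allele frequency, length 1 or
#'   nSnps, each in (0, 0.5].
#' @slot nPopulations integer(1).
#' @slot fst numeric(1) in [0, 1), Balding-Nichols differentiation; 0 means
#'   every population uses the ancestral frequency exactly.
#' @slot nPerPopulation integer, sample size per population (length 1 or
#'   nPopulations).
#' @slot populationLabels character, length nPopulations.
#' @slot nCases,nControls integer(1), cohort sizes.
#' @slot effectModel character(1), inheritance model of the simulated effect.
#' @slot effectOr numeric, ground-truth odds ratio(s); length 2 for the
#'   codominant model (het, minor homozygote vs major homozygote), length 1
#'   otherwise.
#' @slot baselinePrevalence numeric(1) in (0, 1), disease probability in the
#'   reference (major-homozygote) genotype.
#' @slot seed integer(1).
#'
#' @name SyntheticConfig-class
#' @rdname SyntheticConfig-class
#' @exportClass SyntheticConfig
setClass("SyntheticConfig",
    representation(
        nSnps = "integer",
        ancestralMaf = "numeric",
        nPopulations = "integer",
        fst = "numeric",
        nPerPopulation = "integer",
        populationLabels = "character",
        nCases = "integer",
        nControls = "integer",
        effectModel = "character",
        effectOr = "numeric",
        baselinePrevalence = "numeric",
        seed = "integer"
    )
)

setValidity("SyntheticConfig", function(object) {
    msgs <- character()
    chk <- function(cond, msg) if (!cond) msgs <<- c(msgs, msg)
    chk(length(object@nSnps) == 1L && object@nSnps >= 1L,
        "nSnps must be a positive integer")
    chk(length(object@ancestralMaf) %in% c(1L, object@nSnps) &&
        all(object@ancestralMaf > 0 & object@ancestralMaf <= 0.5),
        "ancestralMaf must lie in (0, 0.5], length 1 or nSnps")
    chk(length(object@nPopulations) == 1L && object@nPopulations >= 1L,
        "nPopulations must be a positive integer")
    chk(length(object@fst) == 1L && object@fst >= 0 && object@fst < 1,
        "fst must lie in [0, 1)")
    chk(length(object@nPerPopulation) == object@nPopulations &&
        all(object@nPerPopulation >= 1L),
        "nPerPopulation must be positive, one value per population")
    chk(length(object@populationLabels) == object@nPopulations &&
        !anyDuplicated(object@populationLabels),
        "populationLabels must be unique, one per population")
    chk(length(object@nCases) == 1L && object@nCases >= 1L,
        "nCases must be a positive integer")
    chk(length(object@nControls) == 1L && object@nControls >= 1L,
        "nControls must be a positive integer")
    chk(length(object@effectModel) == 1L &&
        object@effectModel %in% inheritanceModels(),
        "effectModel must be one of the five inheritance models")
    chk(length(object@effectOr) ==
            (if (identical(object@effectModel, "codominant")) 2L else 1L) &&
        all(object@effectOr > 0),
        "effectOr must be positive (length 2 for codominant, 1 otherwise)")
    chk(length(object@baselinePrevalence) == 1L &&
        object@baselinePrevalence > 0 && object@baselinePrevalence < 1,
        "baselinePrevalence must lie in (0, 1)")
    chk(length(object@seed) == 1L && !is.na(object@seed),
        "seed must be a single integer")
    if (length(msgs)) msgs else TRUE
})
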