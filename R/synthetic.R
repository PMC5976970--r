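## Synthetic genotype data with known ground truth: Balding-Nichols
## population panels and retrospectively sampled case-control cohorts.

## Deterministic substreams: each generator stage draws under its own
## derived seed, so adding a stage never perturbs another stage's draws.
.subSeed <- function(seed, stream) {
    (as.numeric(seed) * 48271 + stream * 7919) %% 2147483647
}

.withSubSeed <- function(seed, stream, code) {
    withr::with_seed(as.integer(.subSeed(seed, stream)), code)
}

#' Construct a SyntheticConfig
#'
#' Parameters of the synthetic generator with defaults emulating the study
#' conditions the package is designed around: a four-population European
#' panel (96/99/91/107 individuals, labels SLO/CEU/GBR/IBS), mild
#' differentiation (fst 0.01), ancestral MAF 0.2, and a cohort of 153
#' cases vs 96 controls with no genetic effect (OR 1) at baseline
#' prevalence 0.1.
#'
#' @param nSnps number of independent SNPs.
#' @param ancestralMaf ancestral minor-allele frequency (scalar or per
#'   SNP), in (0, 0.5].
#' @param nPopulations number of populations.
#' @param fst Balding-Nichols differentiation in [0, 1).
#' @param nPerPopulation per-population sample size (recycled).
#' @param populationLabels population names.
#' @param nCases,nControls cohort sizes.
#' @param effectModel inheritance model of the simulated effect.
#' @param effectOr ground-truth odds ratio(s); length 2 for codominant.
#' @param baselinePrevalence disease probability in major-allele
#'   homozygotes.
#' @param seed integer seed; identical config + seed gives identical data.
#' @return a validated [SyntheticConfig-class].
#' @export
syntheticConfig <- function(nSnps = 10L, ancestralMaf = 0.2,
                            nPopulations = 4L, fst = 0.01,
                            nPerPopulation = c(96L, 99L, 91L, 107L),
                            populationLabels = NULL,
                            nCases = 153L, nControls = 96L,
                            effectModel = "additive", effectOr = 1,
                            baselinePrevalence = 0.1, seed = 1L) {
    if (is.null(populationLabels)) {
        populationLabels <- if (nPopulations == 4L)
            c("SLO", "CEU", "GBR", "IBS")
        else sprintf("POP%d", seq_len(nPopulations))
    }
    if (length(nPerPopulation) == 1L)
        nPerPopulation <- rep(nPerPopulation, nPopulations)
    if (length(nPerPopulation) != nPopulations)
        nPerPopulation <- rep_len(nPerPopulation, nPopulations)
    new("SyntheticConfig",
        nSnps = as.integer(nSnps), ancestralMaf = as.numeric(ancestralMaf),
        nPopulations = as.integer(nPopulations), fst = as.numeric(fst),
        nPerPopulation = as.integer(nPerPopulation),
        populationLabels = as.character(populationLabels),
        nCases = as.integer(nCases), nControls = as.integer(nControls),
        effectModel = as.character(effectModel),
        effectOr = as.numeric(effectOr),
        baselinePrevalence = as.numeric(baselinePrevalence),
        seed = as.integer(seed))
}

setMethod("show", "SyntheticConfig", function(object) {
    cat(sprintf(paste0("SyntheticConfig: %d SNP(s), %d population(s) ",
                       "(fst=%.3g), cohort %d/%d, effect %s OR=%s, seed %d\n"),
                object@nSnps, object@nPopulations, object@fst,
                object@nCases, object@nControls, object@effectModel,
                paste(object@effectOr, collapse = "/"), object@seed))
})

.hweProbs <- function(m) c((1 - m)^2, 2 * m * (1 - m), m^2)

#' Generate a multi-population genotype panel
#'
#' For each population and SNP, the population allele frequency is drawn
#' from the Balding-Nichols beta distribution with mean equal to the
#' ancestral minor-allele frequency and shape parameters
#' m(1-fst)/fst and (1-m)(1-fst)/fst; fst = 0 is handled as a point mass
#' at the ancestral frequency. Genotypes are then drawn multinomially
#' under Hardy-Weinberg proportions. Alleles are labelled A (the
#' ancestrally minor allele) and G; the labelling is held fixed across
#' populations so tables remain comparable even when a drawn frequency
#' exceeds 0.5.
#'
#' @param cfg a [SyntheticConfig-class].
#' @return named list of [PopulationTable-class], one per population.
#' @export
genPopulationPanel <- function(cfg) {
    stopifnot(is(cfg, "SyntheticConfig"))
    validObject(cfg)
    mafs <- rep_len(cfg@ancestralMaf, cfg@nSnps)
    ids <- sprintf("snp%03d", seq_len(cfg@nSnps))
    .withSubSeed(cfg@seed, 1L, {
        out <- lapply(seq_len(cfg@nPopulations), function(p) {
            entries <- lapply(seq_len(cfg@nSnps), function(s) {
                m <- mafs[s]
                q <- if (cfg@fst == 0) m else
                    stats::rbeta(1, m * (1 - cfg@fst) / cfg@fst,
                                 (1 - m) * (1 - cfg@fst) / cfg@fst)
                cnt <- stats::rmultinom(1, cfg@nPerPopulation[p],
                                        .hweProbs(q))[, 1]
                GenotypeCounts(ids[s], "G", "A", nHomMajor = cnt[1],
                               nHet = cnt[2], nHomMinor = cnt[3],
                               relabel = FALSE)
            })
            PopulationTable(cfg@populationLabels[p], entries)
        })
        stats::setNames(out, cfg@populationLabels)
    })
}

## Genotype-category probabilities in cases and controls under a logistic
## disease model: P(case|g) = plogis(logit(prev0) + log(OR) . x(g)) with
## x the prospective encoding (major homozygote = reference), inverted by
## Bayes' rule against the HWE population distribution.
.retrospectiveProbs <- function(maf, effectModel, effectOr,
                                baselinePrevalence) {
    pg <- .hweProbs(maf)
    x <- switch(effectModel,
        additive = cbind(c(0, 1, 2)),
        dominant = cbind(c(0, 1, 1)),
        recessive = cbind(c(0, 0, 1)),
        overdominant = cbind(c(0, 1, 0)),
        codominant = cbind(c(0, 1, 0), c(0, 0, 1)))
    eta <- stats::qlogis(baselinePrevalence) + drop(x %*% log(effectOr))
    pCase <- stats::plogis(eta)
    list(case = pg * pCase / sum(pg * pCase),
         control = pg * (1 - pCase) / sum(pg * (1 - pCase)),
         pCaseGivenG = pCase, pg = pg)
}

#' Generate a case-control cohort with a known genetic effect
#'
#' Disease probability follows a logistic model on the prospectively
#' encoded genotype (major homozygote as reference) with slope log(OR)
#' and intercept from the baseline prevalence. The genotype distributions
#' within cases and within controls are obtained analytically by Bayes
#' inversion against the Hardy-Weinberg population distribution at the
#' ancestral MAF, then sampled multinomially at the requested sizes —
#' retrospective sampling without rejection loops, so `effectOr = 1`
#' makes both groups draws from the same HWE distribution.
#'
#' @param cfg a [SyntheticConfig-class]; uses `ancestralMaf[1]`,
#'   `effectModel`, `effectOr`, `baselinePrevalence`, `nCases`,
#'   `nControls` and `seed`.
#' @param snpId identifier for the simulated SNP.
#' @return a [CaseControlCounts-class] (allele orientation fixed at
#'   A = simulated minor allele, G = major).
#' @export
genCaseControl <- function(cfg, snpId = "snp001") {
    stopifnot(is(cfg, "SyntheticConfig"))
    validObject(cfg)
    pr <- .retrospectiveProbs(cfg@ancestralMaf[1], cfg@effectModel,
                              cfg@effectOr, cfg@baselinePrevalence)
    .withSubSeed(cfg@seed, 2L, {
        ca <- stats::rmultinom(1, cfg@nCases, pr$case)[, 1]
        co <- stats::rmultinom(1, cfg@nControls, pr$control)[, 1]
        new("CaseControlCounts", snpId = snpId,
            cases = GenotypeCounts(snpId, "G", "A", nHomMajor = ca[1],
                                   nHet = ca[2], nHomMinor = ca[3],
                                   relabel = FALSE),
            controls = GenotypeCounts(snpId, "G", "A", nHomMajor = co[1],
                                      nHet = co[2], nHomMinor = co[3],
                                      relabel = FALSE))
    })
}
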