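## Population comparison of genotype distributions.

.genotypeMatrix2xk <- function(a, b) {
    m <- rbind(genotypeCounts(a), genotypeCounts(b))
    rownames(m) <- c("a", "b")
    m[, colSums(m) > 0, drop = FALSE]  # drop categories empty in both groups
}

#' Chi-square comparison of two genotype distributions
#'
#' Pearson (default) or likelihood-ratio chi-square on the 2 x k table of
#' genotype counts of one SNP in two groups, where k is 3 minus the number
#' of genotype categories empty in both groups. No continuity correction is
#' applied; missing individuals are excluded. The smallest expected cell
#' count is reported and flagged when below 5 (the classical validity
#' heuristic) — the test is still carried out.
#'
#' @param a,b [GenotypeCounts-class] objects for the same SNP and allele
#'   pair.
#' @param statistic "pearson" (default) or "lrt" (deviance
#'   2 * sum(O * log(O/E))).
#' @return one-row data.frame: snp_id, pop_a, pop_b, statistic, df, p_value,
#'   expected_min, flag_low_expected, test.
#' @examples
#' a <- GenotypeCounts("rs17561", "C", "A", 49, 38, 9)
#' b <- GenotypeCounts("rs17561", "C", "A", 49, 59, 3)
#' chisqGenotypeTest(a, b)  # X2 ~ 6.49, df 2, p ~ 0.039
#' @export
chisqGenotypeTest <- function(a, b, statistic = c("pearson", "lrt")) {
    statistic <- match.arg(statistic)
    stopifnot(is(a, "GenotypeCounts"), is(b, "GenotypeCounts"))
    if (!identical(a@snpId, b@snpId))
        stop("comparing different SNPs: '", a@snpId, "' vs '", b@snpId, "'",
             call. = FALSE)
    if (!identical(sort(c(a@alleleMajor, a@alleleMinor)),
                   sort(c(b@alleleMajor, b@alleleMinor))))
        stop("allele pairs differ for SNP '", a@snpId, "'", call. = FALSE)
    ## align b's orientation to a's
    if (!identical(b@alleleMajor, a@alleleMajor))
        b <- GenotypeCounts(b@snpId, a@alleleMajor, a@alleleMinor,
                            nHomMajor = b@nHomMinor, nHet = b@nHet,
                            nHomMinor = b@nHomMajor, nMissing = b@nMissing,
                            gene = b@gene, relabel = FALSE)
    m <- .genotypeMatrix2xk(a, b)
    df <- ncol(m) - 1L
    expected <- outer(rowSums(m), colSums(m)) / sum(m)
    if (df == 0L) {
        stat <- 0; p <- 1
    } else if (statistic == "pearson") {
        stat <- sum((m - expected)^2 / expected)
        p <- stats::pchisq(stat, df, lower.tail = FALSE)
    } else {
        terms <- m * log(m / expected)
        terms[m == 0] <- 0
        stat <- 2 * sum(terms)
        p <- stats::pchisq(stat, df, lower.tail = FALSE)
    }
    data.frame(snp_id = a@snpId, pop_a = NA_character_, pop_b = NA_character_,
               statistic = stat, df = df, p_value = p,
               expected_min = min(expected),
               flag_low_expected = min(expected) < 5,
               test = statistic, stringsAsFactors = FALSE)
}

.requireSnps <- function(tables, snpIds) {
    if (is(tables, "PopulationTable")) tables <- list(tables)
    if (is.null(names(tables)) || any(!nzchar(names(tables))))
        names(tables) <- vapply(tables, populationLabel, character(1))
    if (is.null(snpIds))
        snpIds <- sort(unique(unlist(lapply(tables, snpIds))))
    gaps <- unlist(lapply(tables, function(tab) {
        miss <- setdiff(snpIds, snpIds(tab))
        if (length(miss))
            paste0(populationLabel(tab), ": ", paste(miss, collapse = ", "))
        else character()
    }))
    if (length(gaps))
        stop("SNP(s) absent from population(s) -- ",
             paste(gaps, collapse = "; "), call. = FALSE)
    list(tables = tables, snpIds = snpIds)
}

#' Pairwise population scan of genotype distributions
#'
#' Runs [chisqGenotypeTest()] for every unordered pair of populations at
#' every requested SNP. Output is ordered deterministically by SNP id, then
#' by the lexicographic population pair. P values can optionally be
#' adjusted for multiple testing; by default they are not, matching the
#' common practice of reporting raw per-test significance at a fixed alpha.
#'
#' @param tables list of [PopulationTable-class] (>= 2 populations).
#' @param snpIds SNPs to test; default: all SNPs, which must then be
#'   present in every population.
#' @param alpha significance threshold applied to the (adjusted) p value.
#' @param adjust "none" (default), "holm" or "bonferroni".
#' @param statistic passed to [chisqGenotypeTest()].
#' @return data.frame, one row per SNP x population pair, with columns of
#'   [chisqGenotypeTest()] plus `p_adjusted` and `significant`.
#' @export
pairwiseScan <- function(tables, snpIds = NULL, alpha = 0.05,
                         adjust = c("none", "holm", "bonferroni"),
                         statistic = c("pearson", "lrt")) {
    adjust <- match.arg(adjust)
    statistic <- match.arg(statistic)
    stopifnot(alpha > 0, alpha < 1)
    req <- .requireSnps(tables, snpIds)
    tables <- req$tables
    if (length(tables) < 2L)
        stop("need at least two populations", call. = FALSE)
    labs <- sort(names(tables))
    rows <- list()
    for (id in sort(req$snpIds)) {
        for (i in seq_len(length(labs) - 1L)) {
            for (j in (i + 1L):length(labs)) {
                r <- chisqGenotypeTest(tables[[labs[i]]][[id]],
                                       tables[[labs[j]]][[id]],
                                       statistic = statistic)
                r$pop_a <- labs[i]; r$pop_b <- labs[j]
                rows[[length(rows) + 1L]] <- r
            }
        }
    }
    out <- do.call(rbind, rows)
    out$p_adjusted <- stats::p.adjust(out$p_value, method = adjust)
    out$significant <- out$p_adjusted < alpha
    rownames(out) <- NULL
    out
}

#' Genotype frequency report
#'
#' Per population and SNP: genotype percentages and the minor allele
#' frequency, both rounded to 2 decimals at report time (internal values
#' stay exact). Percentages are taken over all enrolled individuals
#' including those with undetermined genotype, mirroring how published
#' genotype tables display group totals; the MAF uses non-missing
#' individuals only.
#'
#' @inheritParams pairwiseScan
#' @return data.frame: population, snp_id, pct_hom_major, pct_het,
#'   pct_hom_minor, maf.
#' @export
frequencyReport <- function(tables, snpIds = NULL) {
    req <- .requireSnps(tables, snpIds)
    rows <- lapply(req$tables, function(tab) {
        do.call(rbind, lapply(req$snpIds, function(id) {
            g <- tab[[id]]
            denom <- .nonMissingTotal(g) + g@nMissing
            data.frame(population = populationLabel(tab), snp_id = id,
                       pct_hom_major = round(100 * g@nHomMajor / denom, 2),
                       pct_het = round(100 * g@nHet / denom, 2),
                       pct_hom_minor = round(100 * g@nHomMinor / denom, 2),
                       maf = round(maf(g), 2), stringsAsFactors = FALSE)
        }))
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}
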