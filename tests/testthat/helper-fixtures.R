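## Shared builders for the test suite. All random fixtures are generated
## under withr::with_seed so runs are reproducible.

gc_ <- function(homMajor, het, homMinor, nMissing = 0, snp = "snp",
                a = "G", b = "A", relabel = TRUE) {
    GenotypeCounts(snp, a, b, nHomMajor = homMajor, nHet = het,
                   nHomMinor = homMinor, nMissing = nMissing,
                   relabel = relabel)
}

cc_ <- function(caseCounts, controlCounts, snp = "snp", a = "G", b = "A") {
    CaseControlCounts(gc_(caseCounts[1], caseCounts[2], caseCounts[3],
                          snp = snp, a = a, b = b),
                      gc_(controlCounts[1], controlCounts[2],
                          controlCounts[3], snp = snp, a = a, b = b))
}

## random non-degenerate 2x3 genotype table (case, control rows)
randomTable <- function() {
    repeat {
        ca <- rmultinom(1, sample(50:200, 1), rdirichlet1())[, 1]
        co <- rmultinom(1, sample(50:200, 1), rdirichlet1())[, 1]
        if (all(ca + co > 0) && sum(ca) > 0 && sum(co) > 0 &&
            length(unique(c(0, 1, 2)[(ca + co) > 0])) == 3)
            return(list(case = ca, control = co))
    }
}

rdirichlet1 <- function() {
    g <- rgamma(3, shape = 1)
    g / sum(g)
}

## independent textbook Pearson chi-square on a 2 x k matrix
oraclePearson <- function(m) {
    m <- m[, colSums(m) > 0, drop = FALSE]
    E <- outer(rowSums(m), colSums(m)) / sum(m)
    stat <- 0
    for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m)))
        stat <- stat + (m[i, j] - E[i, j])^2 / E[i, j]
    list(statistic = stat, df = (nrow(m) - 1) * (ncol(m) - 1),
         p = pchisq(stat, (nrow(m) - 1) * (ncol(m) - 1), lower.tail = FALSE))
}

## independent deviance 2*sum(O*ln(O/E)) on a 2 x k matrix
oracleDeviance <- function(m) {
    m <- m[, colSums(m) > 0, drop = FALSE]
    E <- outer(rowSums(m), colSums(m)) / sum(m)
    stat <- 0
    for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m)))
        if (m[i, j] > 0) stat <- stat + 2 * m[i, j] * log(m[i, j] / E[i, j])
    stat
}

## Table-2-style published cohort counts, as plain vectors
## (homMajor, het, homMinor), for direct construction in tests
PVR_COUNTS <- list(
    rs17561   = list(gene = "IL1A", alleles = c("C", "A"),
                     control = c(49, 38, 9), case = c(49, 59, 3),
                     caseMissing = 2),
    rs2069763 = list(gene = "IL2", alleles = c("C", "A"),
                     control = c(39, 39, 18), case = c(52, 46, 15),
                     caseMissing = 0),
    rs2229094 = list(gene = "LTA", alleles = c("T", "C"),
                     control = c(55, 33, 8), case = c(79, 55, 15),
                     caseMissing = 4),
    rs1800629 = list(gene = "TNF", alleles = c("G", "A"),
                     control = c(74, 20, 2), case = c(96, 54, 3),
                     caseMissing = 0))
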