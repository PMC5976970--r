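## MAF perturbation: add genotypes one by one to a case dataset, keep the
## control dataset fixed, and track how the case-control P value responds
## to small minor-allele-frequency changes.

.perturbTests <- c("genotypic", "allelic", "lrt")

.alleleChisq <- function(case, control) {
    m <- rbind(c(2 * case@nHomMajor + case@nHet,
                 2 * case@nHomMinor + case@nHet),
               c(2 * control@nHomMajor + control@nHet,
                 2 * control@nHomMinor + control@nHet))
    m <- m[, colSums(m) > 0, drop = FALSE]
    if (ncol(m) < 2L) return(1)
    expected <- outer(rowSums(m), colSums(m)) / sum(m)
    stats::pchisq(sum((m - expected)^2 / expected), df = 1,
                  lower.tail = FALSE)
}

.perturbPValue <- function(case, control, test) {
    switch(test,
        genotypic = chisqGenotypeTest(case, control, "pearson")$p_value,
        lrt = chisqGenotypeTest(case, control, "lrt")$p_value,
        allelic = .alleleChisq(case, control))
}

#' Apply one perturbation to a case dataset
#'
#' Adds the given numbers of minor-homozygote, heterozygote and
#' major-homozygote individuals to the case counts (the control counts are
#' never touched), then recomputes allele frequencies, MAF and the
#' case-vs-control P value. Internally everything is exact; 2-decimal
#' rounding belongs to the report stage.
#'
#' @param case,control [GenotypeCounts-class] for the same SNP; orientation
#'   is taken from `case` and held fixed through the perturbation.
#' @param add integer(3): added (hom_minor, het, hom_major) individuals.
#' @param test "genotypic" (Pearson chi-square on the 2 x 3 genotype
#'   table, the default), "allelic" (Pearson on the 2 x 2 allele table) or
#'   "lrt" (genotypic deviance).
#' @param alpha significance threshold for the `significant` flag.
#' @return one-row data.frame: sim_index (NA; filled by [perturbScan()]),
#'   added_hom_minor, added_het, added_hom_major, n_hom_major, n_het,
#'   n_hom_minor, freq_minor, freq_major, maf, p_value, significant, test.
#' @examples
#' ca <- GenotypeCounts("snp", "G", "A", 73, 39, 1)
#' co <- GenotypeCounts("snp", "G", "A", 74, 21, 1)
#' perturbOnce(ca, co, add = c(0, 6, 0))$maf  # 0.1975 -> prints as 0.20
#' @export
perturbOnce <- function(case, control, add = c(0L, 0L, 0L),
                        test = .perturbTests, alpha = 0.05) {
    test <- match.arg(test)
    stopifnot(is(case, "GenotypeCounts"), is(control, "GenotypeCounts"),
              length(add) == 3L)
    if (anyNA(add) || any(add < 0) || any(add != round(add)))
        stop("additions must be non-negative integers", call. = FALSE)
    add <- as.integer(round(add))
    newCase <- GenotypeCounts(case@snpId, case@alleleMajor, case@alleleMinor,
                              nHomMajor = case@nHomMajor + add[3],
                              nHet = case@nHet + add[2],
                              nHomMinor = case@nHomMinor + add[1],
                              nMissing = case@nMissing, gene = case@gene,
                              relabel = FALSE)
    fr <- alleleFrequencies(newCase)
    p <- .perturbPValue(newCase, control, test)
    data.frame(sim_index = NA_integer_,
               added_hom_minor = add[1], added_het = add[2],
               added_hom_major = add[3],
               n_hom_major = newCase@nHomMajor, n_het = newCase@nHet,
               n_hom_minor = newCase@nHomMinor,
               freq_minor = unname(fr[2]), freq_major = unname(fr[1]),
               maf = unname(min(fr)),
               p_value = p,
               significant = p < alpha,
               test = test, stringsAsFactors = FALSE)
}

#' Scan a grid of case-dataset perturbations
#'
#' Enumerates every combination of added genotypes with total additions up
#' to `maxAdded` over the selected categories and evaluates each with
#' [perturbOnce()]. By default minor-homozygote and heterozygote additions
#' are enumerated and major-homozygote additions are off. Steps are
#' ordered lexicographically by (added hom_minor, added het, added
#' hom_major): the heterozygote-only series first, then the series with 1
#' added minor homozygote, and so on. The scan is fully deterministic.
#'
#' @inheritParams perturbOnce
#' @param maxAdded maximum total number of added individuals (>= 0).
#' @param categories subset of c("hom_minor", "het", "hom_major") to
#'   enumerate over.
#' @return data.frame of [perturbOnce()] rows with `sim_index` = 1, 2, ...
#' @export
perturbScan <- function(case, control, maxAdded = 6L, alpha = 0.05,
                        test = .perturbTests,
                        categories = c("hom_minor", "het")) {
    test <- match.arg(test)
    stopifnot(maxAdded >= 0)
    categories <- match.arg(categories,
                            c("hom_minor", "het", "hom_major"),
                            several.ok = TRUE)
    maxI <- if ("hom_minor" %in% categories) maxAdded else 0L
    rows <- list()
    for (i in 0:maxI) {
        maxJ <- if ("het" %in% categories) maxAdded - i else 0L
        for (j in 0:maxJ) {
            maxK <- if ("hom_major" %in% categories) maxAdded - i - j else 0L
            for (k in 0:maxK) {
                rows[[length(rows) + 1L]] <-
                    perturbOnce(case, control, add = c(i, j, k),
                                test = test, alpha = alpha)
            }
        }
    }
    out <- do.call(rbind, rows)
    out$sim_index <- seq_len(nrow(out))
    rownames(out) <- NULL
    out
}

#' Smallest perturbation that crosses the significance threshold
#'
#' @param steps data.frame from [perturbScan()].
#' @return the significant step with the smallest total number of added
#'   individuals (ties: fewest added minor homozygotes, then enumeration
#'   order), or `NULL` when no step is significant.
#' @export
minimalFlip <- function(steps) {
    sig <- steps[steps$significant, , drop = FALSE]
    if (!nrow(sig)) return(NULL)
    tot <- sig$added_hom_minor + sig$added_het + sig$added_hom_major
    sig <- sig[order(tot, sig$added_hom_minor, sig$sim_index), , drop = FALSE]
    sig[1, , drop = FALSE]
}

#' MAF-change report for a perturbation scan
#'
#' Tabulates, per step, the MAF change from the unperturbed baseline: the
#' exact change (`maf_delta`) and the change between the 2-decimal
#' report-precision MAFs (`maf_delta_2dp`), alongside the significance
#' flag. The attribute `"minimal_flip"` carries the [minimalFlip()] step
#' (with both deltas attached) or `NULL`.
#'
#' @param steps data.frame from [perturbScan()]; must contain the
#'   zero-addition baseline step.
#' @return data.frame: sim_index, added_hom_minor, added_het,
#'   added_hom_major, maf, maf_delta, maf_delta_2dp, p_value, significant.
#' @export
mafDeltaReport <- function(steps) {
    base <- steps[steps$added_hom_minor == 0 & steps$added_het == 0 &
                  steps$added_hom_major == 0, , drop = FALSE]
    if (!nrow(base))
        stop("scan does not contain the unperturbed baseline step",
             call. = FALSE)
    maf0 <- base$maf[1]
    out <- data.frame(sim_index = steps$sim_index,
                      added_hom_minor = steps$added_hom_minor,
                      added_het = steps$added_het,
                      added_hom_major = steps$added_hom_major,
                      maf = steps$maf,
                      maf_delta = steps$maf - maf0,
                      maf_delta_2dp = round(steps$maf, 2) - round(maf0, 2),
                      p_value = steps$p_value,
                      significant = steps$significant,
                      stringsAsFactors = FALSE)
    flip <- minimalFlip(steps)
    if (!is.null(flip)) {
        flip$maf_delta <- flip$maf - maf0
        flip$maf_delta_2dp <- round(flip$maf, 2) - round(maf0, 2)
    }
    attr(out, "minimal_flip") <- flip
    out
}
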