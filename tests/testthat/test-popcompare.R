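test_that("genotype chi-square matches hand-computed and oracle values", {
    ## identical distributions
    r <- chisqGenotypeTest(gc_(10, 20, 10), gc_(10, 20, 10))
    expect_equal(r$statistic, 0)
    expect_equal(r$p_value, 1)

    ## cohort counts of the IL1A SNP as a worked 2x3 example
    a <- gc_(49, 38, 9, snp = "rs17561", a = "C", b = "A")
    b <- gc_(49, 59, 3, snp = "rs17561", a = "C", b = "A")
    r <- chisqGenotypeTest(a, b)
    expect_equal(r$statistic, 6.4935, tolerance = 1e-4)
    expect_equal(r$df, 2)
    expect_equal(round(r$p_value, 3), 0.039)

    ## symmetry
    r2 <- chisqGenotypeTest(b, a)
    expect_equal(r2$statistic, r$statistic)
    expect_equal(r2$p_value, r$p_value)
    expect_false(r$flag_low_expected)  # smallest expected cell is 5.57

    ## rare-homozygote table triggers the low-expected flag
    rTnf <- chisqGenotypeTest(gc_(74, 20, 2, snp = "rs1800629"),
                              gc_(96, 54, 3, snp = "rs1800629"))
    expect_true(rTnf$flag_low_expected)
    expect_lt(rTnf$expected_min, 5)

    ## category empty in both groups is dropped, reducing df
    r <- chisqGenotypeTest(gc_(30, 10, 0), gc_(20, 20, 0))
    expect_equal(r$df, 1)

    expect_error(chisqGenotypeTest(gc_(1, 1, 1, snp = "x"),
                                   gc_(1, 1, 1, snp = "y")), "different SNPs")
})

test_that("Pearson and LRT statistics agree with independent oracles", {
    withr::with_seed(41, {
        for (rep in 1:200) {
            tab <- randomTable()
            a <- gc_(tab$case[1], tab$case[2], tab$case[3],
                     relabel = FALSE)
            b <- gc_(tab$control[1], tab$control[2], tab$control[3],
                     relabel = FALSE)
            m <- rbind(tab$case, tab$control)
            o <- oraclePearson(m)
            r <- chisqGenotypeTest(a, b)
            expect_equal(r$statistic, o$statistic, tolerance = 1e-10)
            expect_equal(r$p_value, o$p, tolerance = 1e-10)
            r <- chisqGenotypeTest(a, b, statistic = "lrt")
            expect_equal(r$statistic, oracleDeviance(m), tolerance = 1e-10)
        }
    })
})

test_that("pairwise scans enumerate unordered pairs deterministically", {
    mkTab <- function(lab, seed) withr::with_seed(seed, {
        entries <- lapply(sprintf("rs%02d", 1:10), function(id) {
            n <- rmultinom(1, 100, c(0.5, 0.4, 0.1))[, 1]
            GenotypeCounts(id, "G", "A", n[1], n[2], n[3], relabel = FALSE)
        })
        PopulationTable(lab, entries)
    })
    tabs <- list(mkTab("B", 1), mkTab("A", 2), mkTab("D", 3), mkTab("C", 4))
    res <- pairwiseScan(tabs)
    expect_equal(nrow(res), 60)  # 6 pairs x 10 SNPs
    expect_true(all(res$pop_a < res$pop_b))
    expect_equal(res$snp_id, sort(res$snp_id))
    res2 <- pairwiseScan(tabs[1:2], snpIds = "rs01")
    expect_equal(nrow(res2), 1)
    expect_error(pairwiseScan(tabs, snpIds = "rs99"), "absent")

    ## Holm/Bonferroni adjust through stats::p.adjust
    resH <- pairwiseScan(tabs, adjust = "holm")
    expect_equal(resH$p_adjusted, p.adjust(resH$p_value, "holm"))
    expect_true(all(resH$p_adjusted >= resH$p_value))
})

test_that("null pairwise comparisons are calibrated and p-values uniform", {
    withr::with_seed(53, {
        ps <- replicate(2000, {
            a <- rmultinom(1, 100, c(0.49, 0.42, 0.09))[, 1]
            b <- rmultinom(1, 100, c(0.49, 0.42, 0.09))[, 1]
            chisqGenotypeTest(gc_(a[1], a[2], a[3], relabel = FALSE),
                              gc_(b[1], b[2], b[3],
                                  relabel = FALSE))$p_value
        })
        expect_lt(abs(mean(ps < 0.05) - 0.05), 0.015)
        expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.001)
    })
})

test_that("frequency reports give percentages over enrolled individuals", {
    tab <- PopulationTable("P", list(gc_(10, 20, 10, snp = "rs1")))
    rep <- frequencyReport(tab)
    expect_equal(rep$pct_hom_major, 25)
    expect_equal(rep$pct_het, 50)
    expect_equal(rep$pct_hom_minor, 25)
    expect_equal(rep$pct_hom_major + rep$pct_het + rep$pct_hom_minor, 100)

    ## the published control percentages of the IL1A SNP: 51/40/9
    tab <- PopulationTable("control",
        list(gc_(49, 38, 9, snp = "rs17561", a = "C", b = "A")))
    rep <- frequencyReport(tab)
    expect_equal(round(c(rep$pct_hom_major, rep$pct_het,
                         rep$pct_hom_minor)), c(51, 40, 9))

    ## rows sum to 100 up to rounding
    withr::with_seed(61, for (r in 1:20) {
        n <- rmultinom(1, 150, rdirichlet1())[, 1]
        if (sum(n) == 0) next
        tab <- PopulationTable("P", list(gc_(n[1], n[2], n[3], snp = "s")))
        rep <- frequencyReport(tab)
        expect_lt(abs(rep$pct_hom_major + rep$pct_het +
                      rep$pct_hom_minor - 100), 0.02)
    })
})
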