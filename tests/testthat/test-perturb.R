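test_that("the identity perturbation reproduces the baseline analysis", {
    fx <- mafSimFixture()
    step <- perturbOnce(fx$case, fx$control, add = c(0, 0, 0))
    expect_equal(step$maf, maf(fx$case))
    expect_equal(step$p_value,
                 chisqGenotypeTest(fx$case, fx$control)$p_value)
    expect_false(step$significant)
    expect_error(perturbOnce(fx$case, fx$control, add = c(-1, 0, 0)),
                 "non-negative")
})

test_that("MAF after published perturbations prints as 0.20", {
    fx <- mafSimFixture()
    expect_equal(round(maf(fx$case), 2), 0.18)
    sixHet <- perturbOnce(fx$case, fx$control, add = c(0, 6, 0))
    expect_equal(round(sixHet$maf, 2), 0.20)
    threeHom <- perturbOnce(fx$case, fx$control, add = c(3, 0, 0))
    expect_equal(threeHom$maf, 47 / 232)
    expect_equal(round(threeHom$maf, 2), 0.20)
    ## conservation of individuals
    expect_equal(sixHet$n_hom_major + sixHet$n_het + sixHet$n_hom_minor,
                 113 + 6)
})

test_that("scan enumerates the addition grid in the published layout", {
    fx <- mafSimFixture()
    expect_equal(nrow(perturbScan(fx$case, fx$control, maxAdded = 0)), 1)
    s <- perturbScan(fx$case, fx$control, maxAdded = 6)
    expect_equal(nrow(s), 28)  # all (hom_minor, het) pairs with sum <= 6
    ## lexicographic by (added hom_minor, added het): het-only series
    ## first, then the 1-hom series, and so on
    expect_equal(s$added_hom_minor[1:8], c(rep(0, 7), 1))
    expect_equal(s$added_het[1:8], c(0:6, 0))
    expect_true(!is.unsorted(s$added_hom_minor))
    expect_equal(s$sim_index, 1:28)
    ## the optional hom_major axis enlarges the grid
    s3 <- perturbScan(fx$case, fx$control, maxAdded = 2,
                      categories = c("hom_minor", "het", "hom_major"))
    expect_equal(nrow(s3), 10)  # compositions of <=2 into 3 categories
    ## re-running is bit-identical
    expect_identical(perturbScan(fx$case, fx$control, maxAdded = 6), s)
})

test_that("het-only series decreases monotonically and flips at 6 added", {
    fx <- mafSimFixture()
    s <- perturbScan(fx$case, fx$control, maxAdded = 6, categories = "het")
    expect_equal(nrow(s), 7)
    expect_true(all(diff(s$p_value) < 0))
    expect_gt(s$p_value[1], 0.12); expect_lt(s$p_value[1], 0.14)
    flip <- minimalFlip(s)
    expect_equal(c(flip$added_hom_minor, flip$added_het,
                   flip$added_hom_major), c(0, 6, 0))
    ## MAF increases monotonically along the series
    expect_true(all(diff(s$maf) > 0))
})

test_that("minimalFlip prefers the smallest total, then fewest hom-minor", {
    fx <- mafSimFixture()
    ## near-identical groups never flip
    none <- perturbScan(fx$case,
                        GenotypeCounts("snp_sim", "G", "A", 73, 39, 1),
                        maxAdded = 1)
    expect_null(minimalFlip(none))
    ## every step significant: the baseline step is the minimal flip
    far <- GenotypeCounts("snp_sim", "G", "A", 20, 40, 36)
    s <- perturbScan(fx$case, far, maxAdded = 2)
    expect_true(all(s$significant))
    flip <- minimalFlip(s)
    expect_equal(c(flip$added_hom_minor, flip$added_het), c(0, 0))
    ## in the full grid of the bundled pair, hom-minor additions flip
    ## before the het-only series does
    full <- minimalFlip(perturbScan(fx$case, fx$control, maxAdded = 6))
    expect_lt(full$added_hom_minor + full$added_het + full$added_hom_major,
              6)
})

test_that("MAF delta report recovers the 0.02 change at the flip", {
    fx <- mafSimFixture()
    s <- perturbScan(fx$case, fx$control, maxAdded = 6, categories = "het")
    rep <- mafDeltaReport(s)
    expect_equal(rep$maf_delta[1], 0)
    expect_true(all(diff(rep$maf_delta) > 0))
    flip <- attr(rep, "minimal_flip")
    expect_equal(flip$maf_delta_2dp, 0.02)  # 0.18 -> 0.20
})

test_that("adding a heterozygote raises the MAF whenever it is below 0.5", {
    withr::with_seed(101, {
        for (r in 1:50) {
            n <- rmultinom(1, 80, rdirichlet1())[, 1]
            if (sum(n) == 0) next
            g <- GenotypeCounts("s", "G", "A", n[1], n[2], n[3],
                                relabel = FALSE)
            fr0 <- unname(alleleFrequencies(g)["A"])
            g1 <- GenotypeCounts("s", "G", "A", n[1], n[2] + 1, n[3],
                                 relabel = FALSE)
            fr1 <- unname(alleleFrequencies(g1)["A"])
            if (fr0 < 0.5) expect_gt(fr1, fr0) else expect_lte(fr1, fr0)
        }
    })
})

test_that("allelic test depends on additions only through allele counts", {
    fx <- mafSimFixture()
    ## +1 hom_minor and +2 het both add 2 minor alleles; the allelic
    ## 2x2 table differs only in the major-allele count, so compare
    ## additions with equal allele tables: +2 hom_minor vs +2 het +1 each
    a <- perturbOnce(fx$case, fx$control, add = c(1, 0, 1),
                     test = "allelic")
    b <- perturbOnce(fx$case, fx$control, add = c(0, 2, 0),
                     test = "allelic")
    ## both add 2 minor and 2 major alleles
    expect_equal(a$p_value, b$p_value)
    ## while the genotypic test distinguishes the two splits
    ag <- perturbOnce(fx$case, fx$control, add = c(1, 0, 1))
    bg <- perturbOnce(fx$case, fx$control, add = c(0, 2, 0))
    expect_false(isTRUE(all.equal(ag$p_value, bg$p_value)))
})
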