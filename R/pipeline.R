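## End-to-end orchestration: run a named analysis stage (or the whole
## pipeline) from a config list, write result TSVs plus a JSON run
## manifest that is sufficient to re-run the analysis exactly.

.writeTsv <- function(df, path) {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    path
}

.configAsList <- function(x) {
    if (isS4(x))
        return(lapply(stats::setNames(nm = slotNames(class(x))),
                      function(sl) slot(x, sl)))
    if (is.list(x)) return(lapply(x, .configAsList))
    x
}

.writeManifest <- function(dir, config, outputs) {
    manifest <- list(
        package = "genoCaseControl",
        version = as.character(utils::packageVersion("genoCaseControl")),
        config = .configAsList(config),
        outputs = basename(unlist(outputs)))
    path <- file.path(dir, "manifest.json")
    jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
    path
}

.ccFromCounts <- function(countsFile, caseLabel, controlLabel) {
    tabs <- readGenotypeCounts(countsFile)
    for (lab in c(caseLabel, controlLabel))
        if (!lab %in% names(tabs))
            stop("population '", lab, "' not found in '", countsFile, "'",
                 call. = FALSE)
    list(case = tabs[[caseLabel]], control = tabs[[controlLabel]],
         all = tabs)
}

#' Run an analysis stage from a configuration
#'
#' Dispatches on `config$subcommand`:
#' \describe{
#'   \item{compare-pops}{pairwise chi-square scan plus frequency report of
#'     a genotype count table (`counts`; options `alpha`, `adjust`,
#'     `statistic`).}
#'   \item{assoc}{inheritance-model association with AIC selection
#'     (`counts`, `caseLabel`/`controlLabel` defaulting to "case" and
#'     "control", `effectAllele`).}
#'   \item{perturb}{MAF perturbation scan of a case/control pair
#'     (`counts`, `maxAdded`, `alpha`, `test`, `categories`).}
#'   \item{simulate}{writes a synthetic population panel and cohort from a
#'     [SyntheticConfig-class] (`synthetic`, a config object or argument
#'     list; `seed` overrides the config's seed).}
#'   \item{pipeline}{simulate, then compare-pops and assoc on the
#'     generated data.}
#' }
#' Every stage writes TSV artifacts into `config$outDir` together with a
#' `manifest.json` recording package version, full configuration and
#' output names, so any artifact can be regenerated from its manifest.
#' Input files are never modified. Reports print odds ratios and MAFs at
#' 2 decimals and P values at 3; the TSVs keep full precision.
#'
#' @param config named list as above; `outDir` is created if needed.
#' @return invisibly, a named list of written file paths.
#' @export
runAnalysis <- function(config) {
    stopifnot(is.list(config), !is.null(config$subcommand))
    sub <- match.arg(config$subcommand,
                     c("compare-pops", "assoc", "perturb", "simulate",
                       "pipeline"))
    outDir <- config$outDir %||% "."
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    alpha <- config$alpha %||% 0.05
    if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)",
                                       call. = FALSE)
    outputs <- list()

    if (sub == "compare-pops") {
        tabs <- readGenotypeCounts(config$counts)
        scan <- pairwiseScan(tabs, snpIds = config$snpIds, alpha = alpha,
                             adjust = config$adjust %||% "none",
                             statistic = config$statistic %||% "pearson")
        outputs$comparisons <- .writeTsv(scan,
            file.path(outDir, "population_comparisons.tsv"))
        outputs$frequencies <- .writeTsv(frequencyReport(tabs,
                                                         config$snpIds),
            file.path(outDir, "genotype_frequencies.tsv"))
        message(sprintf("compare-pops: %d comparison(s), %d significant",
                        nrow(scan), sum(scan$significant)))
    } else if (sub == "assoc") {
        io <- .ccFromCounts(config$counts,
                            config$caseLabel %||% "case",
                            config$controlLabel %||% "control")
        res <- associationTable(io$case, io$control,
                                snpIds = config$snpIds,
                                effectAllele = config$effectAllele %||%
                                    "minor")
        outputs$association <- .writeTsv(res,
            file.path(outDir, "association_models.tsv"))
        message(sprintf("assoc: %d SNP(s), %d model row(s)",
                        length(unique(res$snp_id)), nrow(res)))
    } else if (sub == "perturb") {
        io <- .ccFromCounts(config$counts,
                            config$caseLabel %||% "case",
                            config$controlLabel %||% "control")
        id <- (config$snpIds %||% snpIds(io$case))[1]
        steps <- perturbScan(io$case[[id]], io$control[[id]],
                             maxAdded = config$maxAdded %||% 6L,
                             alpha = alpha,
                             test = config$test %||% "genotypic",
                             categories = config$categories %||%
                                 c("hom_minor", "het"))
        outputs$perturbation <- .writeTsv(steps,
            file.path(outDir, "perturbation_scan.tsv"))
        rep <- mafDeltaReport(steps)
        outputs$mafDelta <- .writeTsv(rep,
            file.path(outDir, "maf_delta_report.tsv"))
        flip <- attr(rep, "minimal_flip")
        message(if (is.null(flip))
            "perturb: no perturbation crosses the threshold"
        else sprintf(paste0("perturb: minimal flip adds (%d hom_minor, ",
                            "%d het, %d hom_major); MAF %.2f -> %.2f ",
                            "(delta %.2f), P = %.3f"),
                     flip$added_hom_minor, flip$added_het,
                     flip$added_hom_major, round(steps$maf[1], 2),
                     round(flip$maf, 2), flip$maf_delta_2dp, flip$p_value))
    } else if (sub == "simulate") {
        cfg <- config$synthetic %||% list()
        if (!is(cfg, "SyntheticConfig"))
            cfg <- do.call(syntheticConfig, cfg)
        if (!is.null(config$seed)) cfg@seed <- as.integer(config$seed)
        panel <- genPopulationPanel(cfg)
        cohort <- genCaseControl(cfg)
        outputs$panel <- writeGenotypeCounts(panel,
            file.path(outDir, "synthetic_panel.tsv"))
        outputs$cohort <- writeGenotypeCounts(
            list(PopulationTable("case", list(cases(cohort))),
                 PopulationTable("control", list(controls(cohort)))),
            file.path(outDir, "synthetic_cohort.tsv"))
        message(sprintf("simulate: %d population(s) x %d SNP(s), cohort %d/%d",
                        cfg@nPopulations, cfg@nSnps, cfg@nCases,
                        cfg@nControls))
    } else {  # pipeline
        simOut <- runAnalysis(list(subcommand = "simulate",
                                   synthetic = config$synthetic,
                                   seed = config$seed, outDir = outDir))
        cmpOut <- runAnalysis(list(subcommand = "compare-pops",
                                   counts = simOut$panel, alpha = alpha,
                                   outDir = outDir))
        assocOut <- runAnalysis(list(subcommand = "assoc",
                                     counts = simOut$cohort, alpha = alpha,
                                     outDir = outDir))
        drop <- function(x) x[names(x) != "manifest"]
        outputs <- c(drop(simOut), drop(cmpOut), drop(assocOut))
    }
    outputs$manifest <- .writeManifest(outDir, config, outputs)
    invisible(outputs)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
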