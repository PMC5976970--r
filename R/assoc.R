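## Case-control association under the five classical inheritance models:
## grouped unconditional logistic regression with Wald CIs, LRT P values
## and AIC-based model selection.

#' The five inheritance models
#'
#' @return character vector in the package's canonical order (also the
#'   tie-break order of [selectModel()]): additive, dominant, recessive,
#'   overdominant, codominant.
#' @export
inheritanceModels <- function() {
    c("additive", "dominant", "recessive", "overdominant", "codominant")
}

#' Encode a genotype category under an inheritance model
#'
#' Textbook predictor coding with respect to an effect allele: additive is
#' the effect-allele dose 0/1/2; dominant is 1 for carriers of at least one
#' effect allele; recessive is 1 for effect-allele homozygotes;
#' overdominant is 1 for heterozygotes; codominant returns the two
#' indicators (heterozygote, major homozygote) with the minor homozygote as
#' reference.
#'
#' @param model one of [inheritanceModels()].
#' @param category "hom_major", "het" or "hom_minor".
#' @param effectAllele "minor" (default) or "major".
#' @return numeric design value(s) for the category (length 2 for
#'   codominant).
#' @examples
#' encodeGenotype("additive", "het")        # 1
#' encodeGenotype("recessive", "hom_minor") # 1
#' @export
encodeGenotype <- function(model, category,
                           effectAllele = c("minor", "major")) {
    model <- match.arg(model, inheritanceModels())
    effectAllele <- match.arg(effectAllele)
    if (!category %in% c("hom_major", "het", "hom_minor"))
        stop("unknown genotype category '", category, "'", call. = FALSE)
    ## rows: hom_major, het, hom_minor
    enc <- switch(model,
        additive = if (effectAllele == "minor") c(0, 1, 2) else c(2, 1, 0),
        dominant = if (effectAllele == "minor") c(0, 1, 1) else c(1, 1, 0),
        recessive = if (effectAllele == "minor") c(0, 0, 1) else c(1, 0, 0),
        overdominant = c(0, 1, 0),
        codominant = matrix(c(0, 1, 0, 1, 0, 0), nrow = 3,
                            dimnames = list(NULL, c("het", "hom_major"))))
    i <- match(category, c("hom_major", "het", "hom_minor"))
    if (is.matrix(enc)) enc[i, ] else enc[i]
}

## Design matrix rows (hom_major, het, hom_minor) used for FITTING.
## Orientation rule for single-column models: the indicator marks the
## group CONTAINING the major-allele homozygote, so the reference category
## is the group that does not contain it; codominant uses the minor
## homozygote as reference. This is the orientation under which the OR of
## the single-column models coincides with the cross-product ratio of the
## collapsed 2x2 table with the major-homozygote group in the numerator.
.designColumns <- function(model, effectAllele) {
    switch(model,
        additive = matrix(if (effectAllele == "minor") c(0, 1, 2)
                          else c(2, 1, 0), ncol = 1,
                          dimnames = list(NULL, "dose")),
        dominant = matrix(if (effectAllele == "minor") c(1, 0, 0)
                          else c(1, 1, 0), ncol = 1,
                          dimnames = list(NULL, "dominant")),
        recessive = matrix(if (effectAllele == "minor") c(1, 1, 0)
                           else c(1, 0, 0), ncol = 1,
                           dimnames = list(NULL, "recessive")),
        overdominant = matrix(c(1, 0, 1), ncol = 1,
                              dimnames = list(NULL, "overdominant")),
        codominant = matrix(c(0, 1, 0, 1, 0, 0), nrow = 3,
                            dimnames = list(NULL, c("het", "hom_major"))))
}

.contrastLabels <- function(model, effectAllele, gHomMajor, gHet, gHomMinor) {
    grp <- function(idx) paste(c(gHomMajor, gHet, gHomMinor)[idx],
                               collapse = ",")
    switch(model,
        additive = paste0("per ", if (effectAllele == "minor")
            substr(gHomMinor, 1, 1) else substr(gHomMajor, 1, 1), " allele"),
        dominant = if (effectAllele == "minor")
            paste(grp(1), "vs", grp(2:3)) else paste(grp(1:2), "vs", grp(3)),
        recessive = if (effectAllele == "minor")
            paste(grp(1:2), "vs", grp(3)) else paste(grp(1), "vs", grp(2:3)),
        overdominant = paste(grp(c(1, 3)), "vs", grp(2)),
        codominant = c(paste(grp(2), "vs", grp(3)),
                       paste(grp(1), "vs", grp(3))))
}

## Maximum-likelihood grouped logistic regression by IRLS (Newton-Raphson
## on the observed information). y = case counts, n = group totals, X has
## an intercept column. Deterministic: starts at zero coefficients,
## converges when the log-likelihood improves by < 1e-10 (cap 100
## iterations). The log-likelihood is the individual-level Bernoulli one,
## sum(y*log(p) + (n-y)*log(1-p)), so AIC is comparable across models.
.fitGroupedLogit <- function(y, n, X, tol = 1e-10, maxit = 100L) {
    keep <- n > 0
    y <- y[keep]; n <- n[keep]; X <- X[keep, , drop = FALSE]
    loglik <- function(eta) {
        p <- stats::plogis(eta)
        lp <- ifelse(y == 0, 0, y * log(p))
        lq <- ifelse(n - y == 0, 0, (n - y) * log(1 - p))
        sum(lp + lq)
    }
    beta <- rep(0, ncol(X))
    ll <- loglik(drop(X %*% beta))
    converged <- FALSE
    for (it in seq_len(maxit)) {
        eta <- drop(X %*% beta)
        p <- stats::plogis(eta)
        w <- n * p * (1 - p)
        score <- drop(crossprod(X, y - n * p))
        info <- crossprod(X * w, X)
        step <- tryCatch(solve(info, score), error = function(e) NULL)
        if (is.null(step))
            stop("singular information matrix in logistic fit", call. = FALSE)
        ## step-halving keeps Newton monotone on flat likelihoods
        for (h in 0:10) {
            cand <- beta + step / 2^h
            llNew <- loglik(drop(X %*% cand))
            if (llNew >= ll - 1e-12) break
        }
        beta <- cand
        if (abs(llNew - ll) < tol) { ll <- llNew; converged <- TRUE; break }
        ll <- llNew
    }
    if (!converged)
        stop("logistic fit did not converge in ", maxit, " iterations",
             call. = FALSE)
    eta <- drop(X %*% beta)
    p <- stats::plogis(eta)
    info <- crossprod(X * (n * p * (1 - p)), X)
    vcov <- tryCatch(solve(info), error = function(e)
        matrix(NA_real_, ncol(X), ncol(X)))
    list(beta = beta, se = sqrt(diag(vcov)), loglik = ll,
         separated = any(abs(beta[-1]) > 12))
}

.ccFitData <- function(cc) {
    ca <- genotypeCounts(cc@cases)
    co <- genotypeCounts(cc@controls)
    if (sum(ca) < 1L || sum(co) < 1L)
        stop("empty case or control group after excluding missing",
             call. = FALSE)
    list(y = as.numeric(ca), n = as.numeric(ca + co))
}

#' Fit one inheritance model to a case-control SNP
#'
#' Unconditional logistic regression of case status on the encoded
#' genotype, fitted on the grouped counts (missing individuals excluded).
#' Reports exp(coefficient) as the odds ratio with a 95% Wald interval
#' (z = 1.96, SE from the observed information), the likelihood-ratio
#' P value against the intercept-only model, and AIC = 2k - 2*logLik with
#' k the number of coefficients including the intercept.
#'
#' Odds-ratio orientation: for the four single-column models the reference
#' category is the genotype group that does not contain the major-allele
#' homozygote (so e.g. the overdominant OR is homozygotes vs heterozygotes,
#' and the recessive OR with a minor effect allele is
#' \{major-hom, het\} vs minor-hom); the codominant reference is the minor
#' homozygote. The additive OR is per copy of the effect allele. A genotype
#' group empty on one side yields an infinite (or zero) OR with a
#' convergence warning; no continuity correction is applied.
#'
#' @param cc a [CaseControlCounts-class].
#' @param model one of [inheritanceModels()].
#' @param effectAllele "minor" (default), "major", or an explicit allele
#'   symbol matching one of the SNP's alleles.
#' @return data.frame with one row per contrast (two for codominant):
#'   snp_id, model, contrast, effect_allele, or, ci_low, ci_high, log_lik,
#'   lrt, df, p_value, aic, converged, degenerate.
#' @examples
#' cc <- CaseControlCounts(
#'     GenotypeCounts("rs1800629", "G", "A", 96, 54, 3),
#'     GenotypeCounts("rs1800629", "G", "A", 74, 20, 2))
#' fitModel(cc, "overdominant")  # OR 0.48 (0.27-0.87), P 0.014
#' @export
fitModel <- function(cc, model, effectAllele = "minor") {
    stopifnot(is(cc, "CaseControlCounts"))
    model <- match.arg(model, inheritanceModels())
    if (!effectAllele %in% c("minor", "major")) {
        if (identical(effectAllele, alleleMinor(cc))) effectAllele <- "minor"
        else if (identical(effectAllele, alleleMajor(cc))) effectAllele <- "major"
        else stop("effectAllele '", effectAllele,
                  "' is not an allele of SNP '", cc@snpId, "' (",
                  alleleMajor(cc), "/", alleleMinor(cc), ")", call. = FALSE)
    }
    dat <- .ccFitData(cc)
    Xg <- .designColumns(model, effectAllele)
    M <- alleleMajor(cc); m <- alleleMinor(cc)
    labs <- .contrastLabels(model, effectAllele,
                            paste0(M, M), paste0(M, m), paste0(m, m))
    effAllele <- if (model == "overdominant") NA_character_
                 else if (effectAllele == "minor") m else M
    ## degenerate columns: no variation among categories with individuals
    act <- dat$n > 0
    degenerate <- vapply(seq_len(ncol(Xg)), function(j)
        length(unique(Xg[act, j])) < 2L, logical(1))
    base <- data.frame(snp_id = cc@snpId, model = model, contrast = labs,
                       effect_allele = effAllele, or = NA_real_,
                       ci_low = NA_real_, ci_high = NA_real_,
                       log_lik = NA_real_, lrt = NA_real_, df = NA_integer_,
                       p_value = NA_real_, aic = NA_real_,
                       converged = FALSE, degenerate = any(degenerate),
                       stringsAsFactors = FALSE)
    if (any(degenerate)) return(base)
    X <- cbind(`(Intercept)` = 1, Xg)
    fit <- .fitGroupedLogit(dat$y, dat$n, X)
    ## intercept-only log-likelihood for the LRT
    p0 <- sum(dat$y) / sum(dat$n)
    ll0 <- sum(ifelse(dat$y == 0, 0, dat$y * log(p0)) +
               ifelse(dat$n - dat$y == 0, 0, (dat$n - dat$y) * log(1 - p0)))
    lrt <- 2 * (fit$loglik - ll0)
    df <- ncol(Xg)
    coefs <- fit$beta[-1]; ses <- fit$se[-1]
    or <- exp(coefs)
    ciLow <- exp(coefs - 1.96 * ses)
    ciHigh <- exp(coefs + 1.96 * ses)
    if (fit$separated) {
        inf <- abs(coefs) > 12
        or[inf] <- ifelse(coefs[inf] > 0, Inf, 0)
        ciLow[inf] <- NA_real_; ciHigh[inf] <- NA_real_
        warning("SNP '", cc@snpId, "', model '", model,
                "': empty genotype cell gives an unbounded odds ratio",
                call. = FALSE)
    }
    base$or <- or; base$ci_low <- ciLow; base$ci_high <- ciHigh
    base$log_lik <- fit$loglik
    base$lrt <- lrt; base$df <- df
    base$p_value <- stats::pchisq(lrt, df, lower.tail = FALSE)
    base$aic <- 2 * (df + 1L) - 2 * fit$loglik
    base$converged <- TRUE
    base
}

#' Fit all five inheritance models
#'
#' Runs [fitModel()] for every model in [inheritanceModels()] in that
#' fixed order. A model that errors (e.g. a degenerate fit) contributes a
#' non-converged row carrying the error message instead of aborting the
#' remaining fits.
#'
#' @inheritParams fitModel
#' @return data.frame of stacked [fitModel()] rows (6 rows for a
#'   polymorphic SNP: codominant contributes two) plus an `error` column.
#' @export
fitAllModels <- function(cc, effectAllele = "minor") {
    rows <- lapply(inheritanceModels(), function(mod) {
        r <- tryCatch(fitModel(cc, mod, effectAllele = effectAllele),
                      error = function(e) {
            data.frame(snp_id = cc@snpId, model = mod,
                       contrast = NA_character_,
                       effect_allele = NA_character_, or = NA_real_,
                       ci_low = NA_real_, ci_high = NA_real_,
                       log_lik = NA_real_, lrt = NA_real_, df = NA_integer_,
                       p_value = NA_real_, aic = NA_real_, converged = FALSE,
                       degenerate = NA, error = conditionMessage(e),
                       stringsAsFactors = FALSE)
        })
        if (is.null(r$error)) r$error <- NA_character_
        r
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' Select the best-fitting inheritance model by AIC
#'
#' Among the converged, non-degenerate fits of [fitAllModels()], returns
#' the rows of the model with the smallest AIC. Ties (within 1e-8) are
#' broken by fewer fitted parameters, then by the fixed order additive,
#' dominant, recessive, overdominant, codominant.
#'
#' @param results data.frame from [fitAllModels()].
#' @return the selected model's row(s); the model name is in `$model`.
#' @export
selectModel <- function(results) {
    ok <- results[results$converged & !is.na(results$aic) &
                  is.finite(results$aic) &
                  !(results$degenerate %in% TRUE), , drop = FALSE]
    if (!nrow(ok))
        stop("no converged model fit to select from", call. = FALSE)
    perModel <- unique(ok[, c("model", "aic", "df")])
    perModel$rank <- match(perModel$model, inheritanceModels())
    best <- min(perModel$aic)
    cand <- perModel[perModel$aic <= best + 1e-8, , drop = FALSE]
    cand <- cand[order(cand$df, cand$rank), , drop = FALSE]
    sel <- cand$model[1]
    out <- ok[ok$model == sel, , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Per-SNP association table with model selection
#'
#' Convenience wrapper: [fitAllModels()] on each SNP of a case/control pair
#' of [PopulationTable-class] objects, with a `selected` flag on the rows
#' of the AIC-best model.
#'
#' @param caseTable,controlTable [PopulationTable-class] objects sharing
#'   the SNPs to analyse.
#' @param snpIds SNPs to analyse (default: all SNPs of the case table).
#' @param effectAllele passed to [fitModel()].
#' @return data.frame of stacked results with a `selected` column.
#' @export
associationTable <- function(caseTable, controlTable, snpIds = NULL,
                             effectAllele = "minor") {
    if (is.null(snpIds)) snpIds <- snpIds(caseTable)
    out <- do.call(rbind, lapply(snpIds, function(id) {
        cc <- CaseControlCounts(caseTable[[id]], controlTable[[id]])
        res <- fitAllModels(cc, effectAllele = effectAllele)
        sel <- tryCatch(selectModel(res)$model[1], error = function(e) NA)
        res$selected <- !is.na(sel) & res$model == sel
        res
    }))
    rownames(out) <- NULL
    out
}
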