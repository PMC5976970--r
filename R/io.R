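## Native genotype count table: tab-separated, UTF-8, '#' comments, header:
##   population snp_id gene allele_major allele_minor
##   n_hom_major n_het n_hom_minor n_missing

.COUNT_HEADER <- c("population", "snp_id", "gene", "allele_major",
                   "allele_minor", "n_hom_major", "n_het", "n_hom_minor",
                   "n_missing")

#' Read a genotype count table
#'
#' Parses the package's native TSV format into one [PopulationTable-class]
#' per population. Allele labels are harmonized per SNP across populations:
#' all populations must carry the same unordered allele pair, and the
#' major/minor assignment is made on the pooled counts (ties at 0.5 broken
#' by alphabetical order), so the same allele is coded minor everywhere.
#' Parse errors name the offending line.
#'
#' @param path path to a TSV file (header required, '#' comments allowed).
#' @return named list of `PopulationTable`, in order of first appearance.
#' @seealso [writeGenotypeCounts()] for the inverse; the pair round-trips.
#' @export
readGenotypeCounts <- function(path) {
    lines <- readLines(path, encoding = "UTF-8")
    keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
    lineNo <- seq_along(lines)[keep]
    lines <- lines[keep]
    if (!length(lines))
        stop("'", path, "': no content", call. = FALSE)
    header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
    if (!identical(trimws(header), .COUNT_HEADER))
        stop("'", path, "' line ", lineNo[1], ": malformed header; expected: ",
             paste(.COUNT_HEADER, collapse = " "), call. = FALSE)
    if (length(lines) < 2L)
        stop("'", path, "': no data rows", call. = FALSE)
    rows <- vector("list", length(lines) - 1L)
    seen <- character()
    for (k in 2:length(lines)) {
        ln <- lineNo[k]
        f <- strsplit(lines[k], "\t", fixed = TRUE)[[1]]
        if (length(f) != length(.COUNT_HEADER))
            stop("'", path, "' line ", ln, ": expected ",
                 length(.COUNT_HEADER), " fields, found ", length(f),
                 call. = FALSE)
        cnts <- suppressWarnings(as.numeric(f[6:9]))
        if (anyNA(cnts) || any(cnts < 0) || any(cnts != round(cnts)))
            stop("'", path, "' line ", ln,
                 ": counts must be non-negative integers", call. = FALSE)
        key <- paste(f[1], f[2], sep = "\r")
        if (key %in% seen)
            stop("'", path, "' line ", ln, ": duplicate (population, snp_id) (",
                 f[1], ", ", f[2], ")", call. = FALSE)
        seen <- c(seen, key)
        rows[[k - 1L]] <- list(population = f[1], snp_id = f[2],
                               gene = if (identical(f[3], "NA") || !nzchar(f[3]))
                                   NA_character_ else f[3],
                               a1 = f[4], a2 = f[5],
                               n = as.integer(cnts))
    }
    ## harmonize allele orientation per SNP over the pooled sample
    ids <- vapply(rows, `[[`, character(1), "snp_id")
    orientation <- list()
    for (id in unique(ids)) {
        sub <- rows[ids == id]
        pair <- sort(c(sub[[1]]$a1, sub[[1]]$a2))
        pooled <- c(0, 0)  # allele counts of pair[1], pair[2]
        for (r in sub) {
            if (!identical(sort(c(r$a1, r$a2)), pair))
                stop("'", path, "': SNP '", id,
                     "' carries different allele pairs across populations",
                     call. = FALSE)
            cnt <- stats::setNames(
                c(2 * r$n[1] + r$n[2], 2 * r$n[3] + r$n[2]), c(r$a1, r$a2))
            pooled <- pooled + cnt[pair]
        }
        major <- if (pooled[1] > pooled[2]) pair[1]
                 else if (pooled[2] > pooled[1]) pair[2]
                 else pair[1]  # tie: alphabetically earlier allele is major
        orientation[[id]] <- c(major, setdiff(pair, major))
    }
    pops <- unique(vapply(rows, `[[`, character(1), "population"))
    out <- lapply(pops, function(p) {
        entries <- lapply(rows[vapply(rows, `[[`, character(1),
                                      "population") == p], function(r) {
            ornt <- orientation[[r$snp_id]]
            flip <- !identical(r$a1, ornt[1])
            GenotypeCounts(r$snp_id, ornt[1], ornt[2],
                           nHomMajor = if (flip) r$n[3] else r$n[1],
                           nHet = r$n[2],
                           nHomMinor = if (flip) r$n[1] else r$n[3],
                           nMissing = r$n[4], gene = r$gene, relabel = FALSE)
        })
        PopulationTable(p, entries)
    })
    stats::setNames(out, pops)
}

#' Write genotype count tables
#'
#' Writes one or more [PopulationTable-class] objects in the native TSV
#' format; `readGenotypeCounts()` of the result reproduces the input.
#'
#' @param tables a `PopulationTable` or list thereof.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeGenotypeCounts <- function(tables, path) {
    if (is(tables, "PopulationTable")) tables <- list(tables)
    con <- file(path, open = "wt", encoding = "UTF-8")
    on.exit(close(con))
    writeLines(paste(.COUNT_HEADER, collapse = "\t"), con)
    for (tab in tables) {
        for (g in tab@entries) {
            writeLines(paste(tab@populationLabel, g@snpId,
                             ifelse(is.na(g@gene), "NA", g@gene),
                             g@alleleMajor, g@alleleMinor,
                             g@nHomMajor, g@nHet, g@nHomMinor, g@nMissing,
                             sep = "\t"), con)
        }
    }
    invisible(path)
}

#' Read a genotype matrix (individuals x SNPs)
#'
#' Reads a TSV whose first column is an individual identifier and whose
#' remaining columns hold two-letter genotype calls ("AG", "GG", ...; "NA"
#' or "." for missing) and tallies each SNP column with
#' [tallyFromCalls()]. The allele pair of each SNP is inferred from the
#' observed alleles; a SNP with only one observed allele gets "N" as the
#' placeholder second allele unless `alleles` overrides it.
#'
#' @param path TSV path, header required.
#' @param population label for the resulting table.
#' @param alleles optional named list: SNP id -> character(2) allele pair.
#' @return a [PopulationTable-class].
#' @export
readGenotypeMatrix <- function(path, population = "matrix", alleles = list()) {
    m <- utils::read.delim(path, check.names = FALSE,
                           colClasses = "character")
    if (ncol(m) < 2L)
        stop("'", path, "': expected an id column plus one column per SNP",
             call. = FALSE)
    entries <- lapply(names(m)[-1], function(id) {
        calls <- m[[id]]
        pair <- alleles[[id]]
        if (is.null(pair)) {
            norm <- gsub("[/|]", "", calls)
            ok <- !is.na(norm) & !norm %in% c("", "NA", ".", "..") &
                nchar(norm) == 2 & !grepl("\\.", norm)
            obs <- sort(unique(unlist(strsplit(norm[ok], ""))))
            if (length(obs) > 2L)
                stop("SNP '", id, "' in '", path, "' has >2 alleles: ",
                     paste(obs, collapse = ", "), call. = FALSE)
            if (length(obs) == 0L)
                stop("SNP '", id, "' in '", path, "' has no called genotypes",
                     call. = FALSE)
            pair <- if (length(obs) == 1L) c(obs, "N") else obs
        }
        tallyFromCalls(calls, pair, snpId = id)
    })
    PopulationTable(population, entries)
}

#' Tally genotypes from a VCF
#'
#' Reads a VCF (4.x, GT field) with `vcfR` and tallies each biallelic SNP
#' record into a [GenotypeCounts-class]. Multi-allelic or non-SNP records
#' are skipped with a warning. Genotypes are treated as unphased
#' ("0/1" and "1|0" are the same heterozygote); half-missing calls count
#' as missing. The record's ID column provides the SNP id (CHROM:POS when
#' ID is ".").
#'
#' @param path VCF file path (plain or bgzipped).
#' @param population label for the resulting table.
#' @return a [PopulationTable-class].
#' @export
readVcfCounts <- function(path, population = "VCF") {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- vcfR::getFIX(v)
    if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                         dimnames = list(NULL, names(fix)))
    ref <- fix[, "REF"]; alt <- fix[, "ALT"]
    biallelic <- !is.na(alt) & nchar(ref) == 1L & nchar(alt) == 1L &
        ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
    if (any(!biallelic))
        warning(sum(!biallelic),
                " multi-allelic or non-SNP record(s) skipped", call. = FALSE)
    if (!any(biallelic))
        stop("'", path, "': no biallelic SNP records", call. = FALSE)
    gt <- vcfR::extract.gt(v, element = "GT", convertNA = FALSE)
    if (is.null(dim(gt))) gt <- matrix(gt, nrow = nrow(fix))
    entries <- lapply(which(biallelic), function(i) {
        id <- fix[i, "ID"]
        if (is.na(id) || id == ".")
            id <- paste0(fix[i, "CHROM"], ":", fix[i, "POS"])
        codes <- gsub("\\|", "/", gt[i, ])
        calls <- vapply(strsplit(codes, "/", fixed = TRUE), function(a) {
            if (length(a) != 2L || any(is.na(a)) || any(a == "."))
                return(NA_character_)
            paste0(c(ref[i], alt[i])[as.integer(a) + 1L], collapse = "")
        }, character(1))
        tallyFromCalls(calls, c(ref[i], alt[i]), snpId = id)
    })
    PopulationTable(population, entries)
}
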