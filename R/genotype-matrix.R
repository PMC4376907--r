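## GenotypeMatrix: a RangedSummarizedExperiment holding a sites x samples
## dosage matrix for biallelic SNPs, with filter accounting in metadata().

#' Genotype dosage matrix
#'
#' A `GenotypeMatrix` is a `RangedSummarizedExperiment` whose single assay
#' `"dosage"` holds alternate-allele counts (0, 1, 2; `NA` for missing
#' calls) for biallelic SNPs. Rows are sites (width-1 `GRanges` with `ref`
#' and `alt` metadata columns, sorted by sequence then position); columns
#' are samples. Filter functions append per-stage accounting to
#' `metadata()$accounting`, retrievable with [filterAccounting].
#'
#' @export
setClass("GenotypeMatrix",
         contains = "RangedSummarizedExperiment")

setValidity("GenotypeMatrix", function(object) {
    msg <- character()
    if (!"dosage" %in% SummarizedExperiment::assayNames(object))
        return("assay 'dosage' is required")
    d <- SummarizedExperiment::assay(object, "dosage")
    if (!all(d[!is.na(d)] %in% 0:2))
        msg <- c(msg, "dosage values must be 0, 1, 2 or NA")
    rr <- SummarizedExperiment::rowRanges(object)
    if (length(rr)) {
        mc <- S4Vectors::mcols(rr)
        if (!all(c("ref", "alt") %in% names(mc)))
            msg <- c(msg, "rowRanges need 'ref' and 'alt' columns")
        else if (!all(nchar(mc$ref) == 1L & nchar(mc$alt) == 1L))
            msg <- c(msg, "only biallelic SNPs allowed (single-base ref/alt)")
        if (any(BiocGenerics::width(rr) != 1L))
            msg <- c(msg, "sites must be width-1 positions")
        key <- paste(GenomicRanges::seqnames(rr), BiocGenerics::start(rr),
                     mc$ref, mc$alt)
        if (anyDuplicated(key))
            msg <- c(msg, "site keys (seq, pos, ref, alt) must be unique")
    }
    if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
        msg <- c(msg, "sample names must be present and unique")
    if (length(msg)) msg else TRUE
})

#' @describeIn GenotypeMatrix constructor.
#' @param dosage integer matrix, sites x samples, values 0/1/2/NA; column
#'   names are sample ids.
#' @param sites `GRanges` of site positions with `ref`/`alt` metadata
#'   columns, parallel to the rows of `dosage`.
#' @export
GenotypeMatrix <- function(dosage, sites) {
    stopifnot(is.matrix(dosage), length(sites) == nrow(dosage))
    mode(dosage) <- "integer"
    ord <- order(as.character(GenomicRanges::seqnames(sites)),
                 BiocGenerics::start(sites))
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(dosage = dosage[ord, , drop = FALSE]),
        rowRanges = sites[ord])
    new("GenotypeMatrix", se)
}

#' @describeIn GenotypeMatrix the dosage matrix (sites x samples).
#' @param x a `GenotypeMatrix`.
#' @export
dosage <- function(x) SummarizedExperiment::assay(x, "dosage")

#' @describeIn GenotypeMatrix site keys as a data.frame
#'   (`seqnames`, `pos`, `ref`, `alt`).
#' @export
siteKeys <- function(x) {
    rr <- SummarizedExperiment::rowRanges(x)
    data.frame(seqnames = as.character(GenomicRanges::seqnames(rr)),
               pos = BiocGenerics::start(rr),
               ref = S4Vectors::mcols(rr)$ref,
               alt = S4Vectors::mcols(rr)$alt,
               stringsAsFactors = FALSE)
}

#' @describeIn GenotypeMatrix per-stage filter accounting accumulated by
#'   the filter cascade (`NULL` before any filter ran).
#' @export
filterAccounting <- function(x) S4Vectors::metadata(x)$accounting

setMethod("show", "GenotypeMatrix", function(object) {
    d <- dosage(object)
    cat("GenotypeMatrix:", nrow(object), "sites x", ncol(object),
        "samples\n")
    if (length(d))
        cat(sprintf("  missing: %.1f%%  het: %.2f%%\n",
                    100 * mean(is.na(d)),
                    100 * mean(d[!is.na(d)] == 1L)))
    acc <- filterAccounting(object)
    if (!is.null(acc))
        cat("  filters applied:", paste(acc$stage, collapse = " -> "), "\n")
})

.appendAccounting <- function(x, stage, sitesIn, sitesOut,
                              samplesIn, samplesOut) {
    row <- data.frame(stage = stage, sitesIn = sitesIn,
                      sitesRemoved = sitesIn - sitesOut, sitesOut = sitesOut,
                      samplesIn = samplesIn, samplesOut = samplesOut,
                      stringsAsFactors = FALSE)
    S4Vectors::metadata(x)$accounting <-
        rbind(S4Vectors::metadata(x)$accounting, row)
    x
}

.gtToDosage <- function(gt) {
    ## diploid GT string ("0/1", "1|1", "./.") -> dosage or NA
    out <- rep(NA_integer_, length(gt))
    clean <- gsub("\\|", "/", gt)
    out[clean %in% c("0/0")] <- 0L
    out[clean %in% c("0/1", "1/0")] <- 1L
    out[clean %in% c("1/1")] <- 2L
    out
}

#' Merge per-sample VCFs into a genotype matrix
#'
#' Reads one or more VCF files (single- or multi-sample) and merges their
#' biallelic SNP calls over the union of site keys `(seq, pos, ref, alt)`.
#' A sample lacking a record at a site is missing (`NA`) there.
#' Multi-allelic records and indels are dropped, with counts reported in
#' `metadata()$merge`. Two files calling different reference alleles at
#' the same position is an error.
#'
#' @param files character vector of VCF paths.
#' @return a [GenotypeMatrix].
#' @export
mergeVcfs <- function(files) {
    stopifnot(length(files) >= 1L)
    droppedMulti <- 0L; droppedIndel <- 0L
    tabs <- list(); sampleNames <- character()
    for (f in files) {
        v <- tryCatch(
            suppressWarnings(VariantAnnotation::readVcf(f, genome = "unknown")),
            error = function(e)
                stop(sprintf("malformed VCF '%s': %s", f, conditionMessage(e)),
                     call. = FALSE))
        rr <- SummarizedExperiment::rowRanges(v)
        altList <- VariantAnnotation::alt(v)
        nAlt <- S4Vectors::elementNROWS(altList)
        multi <- nAlt != 1L
        droppedMulti <- droppedMulti + sum(multi)
        refs <- as.character(VariantAnnotation::ref(v))
        alts <- rep(NA_character_, length(v))
        alts[!multi] <- as.character(unlist(altList[!multi]))
        snv <- !multi & nchar(refs) == 1L & !is.na(alts) &
            nchar(alts) == 1L & refs %in% c("A", "C", "G", "T") &
            alts %in% c("A", "C", "G", "T")
        droppedIndel <- droppedIndel + sum(!multi & !snv)
        gt <- VariantAnnotation::geno(v)$GT
        if (is.null(gt))
            stop(sprintf("VCF '%s' has no GT field", f))
        keep <- which(snv)
        if (!length(keep)) next
        dos <- apply(gt[keep, , drop = FALSE], 2, .gtToDosage)
        if (!is.matrix(dos)) dos <- matrix(dos, nrow = length(keep))
        tab <- data.frame(
            seqnames = as.character(GenomicRanges::seqnames(rr))[keep],
            pos = BiocGenerics::start(rr)[keep],
            ref = refs[keep], alt = alts[keep], stringsAsFactors = FALSE)
        vcfSamples <- colnames(gt)
        if (any(vcfSamples %in% sampleNames))
            stop("duplicate sample name(s) across VCFs: ",
                 paste(intersect(vcfSamples, sampleNames), collapse = ", "))
        sampleNames <- c(sampleNames, vcfSamples)
        tabs[[length(tabs) + 1L]] <- list(tab = tab, dos = dos,
                                          samples = vcfSamples)
    }
    if (!length(tabs)) stop("no biallelic SNP records found in any VCF")
    allTab <- unique(do.call(rbind, lapply(tabs, `[[`, "tab")))
    posKey <- paste(allTab$seqnames, allTab$pos, sep = ":")
    refByPos <- tapply(allTab$ref, posKey, function(r) length(unique(r)))
    if (any(refByPos > 1L))
        stop("conflicting reference alleles at: ",
             paste(names(refByPos)[refByPos > 1L], collapse = ", "))
    allTab <- allTab[order(allTab$seqnames, allTab$pos, allTab$alt), ,
                     drop = FALSE]
    key <- with(allTab, paste(seqnames, pos, ref, alt))
    dosAll <- matrix(NA_integer_, nrow(allTab), length(sampleNames),
                     dimnames = list(NULL, sampleNames))
    for (t in tabs) {
        idx <- match(with(t$tab, paste(seqnames, pos, ref, alt)), key)
        dosAll[idx, t$samples] <- t$dos
    }
    sites <- GenomicRanges::GRanges(
        allTab$seqnames, IRanges::IRanges(allTab$pos, width = 1L),
        ref = allTab$ref, alt = allTab$alt)
    gm <- GenotypeMatrix(dosAll, sites)
    S4Vectors::metadata(gm)$merge <- list(
        files = length(files), droppedMultiallelic = droppedMulti,
        droppedIndel = droppedIndel)
    gm
}
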