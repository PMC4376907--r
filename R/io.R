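## Plain-text writers/readers for the pipeline's tabular interchange
## formats: fragment TSV, dosage TSV, multi-sample VCF, accounting and
## report JSON.

#' Write digest fragments as TSV
#'
#' Columns: `seq_id`, `start`, `end` (0-based, half-open), `length`,
#' `left_cut`, `right_cut`.
#'
#' @param fragments fragment `GRanges` from [digestSingle]/[digestDouble].
#' @param file output path.
#' @export
writeFragmentsTSV <- function(fragments, file) {
    df <- data.frame(
        seq_id = as.character(GenomicRanges::seqnames(fragments)),
        start = BiocGenerics::start(fragments) - 1L,
        end = BiocGenerics::end(fragments),
        length = BiocGenerics::width(fragments),
        left_cut = as.character(fragments$leftCut),
        right_cut = as.character(fragments$rightCut))
    write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(file)
}

#' Write a genotype matrix as a dosage TSV
#'
#' First four columns are the site key (`seqnames`, `pos`, `ref`, `alt`),
#' followed by one dosage column per sample (`NA` for missing).
#'
#' @param gm a [GenotypeMatrix].
#' @param file output path.
#' @export
writeGenotypeTSV <- function(gm, file) {
    df <- cbind(siteKeys(gm), as.data.frame(dosage(gm)))
    write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(file)
}

#' Read a dosage TSV written by [writeGenotypeTSV]
#'
#' @param file path.
#' @return a [GenotypeMatrix].
#' @export
readGenotypeTSV <- function(file) {
    df <- read.delim(file, stringsAsFactors = FALSE, check.names = FALSE)
    keyCols <- c("seqnames", "pos", "ref", "alt")
    stopifnot(all(keyCols %in% names(df)))
    d <- as.matrix(df[, setdiff(names(df), keyCols), drop = FALSE])
    sites <- GenomicRanges::GRanges(
        df$seqnames, IRanges::IRanges(df$pos, width = 1L),
        ref = df$ref, alt = df$alt)
    GenotypeMatrix(d, sites)
}

#' Write a genotype matrix as a minimal multi-sample VCF
#'
#' Emits VCF 4.2 with GT-only genotypes (`0/0`, `0/1`, `1/1`, `./.`).
#'
#' @param gm a [GenotypeMatrix].
#' @param file output path.
#' @export
writeGenotypeVcf <- function(gm, file) {
    keys <- siteKeys(gm)
    d <- dosage(gm)
    gt <- matrix(c("0/0", "0/1", "1/1")[d + 1L], nrow(d),
                 dimnames = dimnames(d))
    gt[is.na(d)] <- "./."
    con <- file(file, "w")
    on.exit(close(con))
    writeLines(c(
        "##fileformat=VCFv4.2",
        "##source=gbskit",
        "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
        paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                "INFO", "FORMAT", colnames(d)), collapse = "\t")), con)
    body <- cbind(keys$seqnames, keys$pos, ".", keys$ref, keys$alt, ".",
                  ".", ".", "GT", gt)
    writeLines(apply(body, 1, paste, collapse = "\t"), con)
    invisible(file)
}

#' Write the filter accounting table
#'
#' @param gm a filtered [GenotypeMatrix].
#' @param tsv,json optional output paths; one or both.
#' @export
writeAccounting <- function(gm, tsv = NULL, json = NULL) {
    acc <- filterAccounting(gm)
    if (is.null(acc)) stop("no filters have been applied")
    if (!is.null(tsv))
        write.table(acc, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(json))
        jsonlite::write_json(acc, json, dataframe = "rows", pretty = TRUE)
    invisible(acc)
}

#' Write a demultiplexing report
#'
#' @param x a [DemuxResult].
#' @param tsv,json optional output paths; one or both.
#' @export
writeDemuxReport <- function(x, tsv = NULL, json = NULL) {
    rep <- demuxReport(x)
    if (!is.null(tsv)) {
        df <- data.frame(sample_id = names(rep$perSample),
                         pairs = unname(rep$perSample))
        write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
    }
    if (!is.null(json))
        jsonlite::write_json(rep, json, auto_unbox = TRUE, pretty = TRUE)
    invisible(rep)
}
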