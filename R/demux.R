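## Barcode demultiplexing of paired-end GBS reads with restriction-remnant
## validation, and merging of technical replicates.

REJECT_REASONS <- c("no_barcode", "bad_rare_remnant", "bad_common_remnant",
                    "ambiguous")

#' Demultiplexing result
#'
#' Holds the barcode-trimmed assigned read pairs, the per-read assignment,
#' rejected-read bookkeeping and a summary report. Assigned plus rejected
#' reads always account for every input pair.
#'
#' @slot read1,read2 `DNAStringSet` of assigned pairs (read1 barcode-trimmed,
#'   restriction remnant retained; read2 untouched), with per-read qualities
#'   in `mcols(read1)$quality` / `mcols(read2)$quality`.
#' @slot sample character vector parallel to `read1`: the assigned sample id.
#' @slot rejects `data.frame` with columns `id` and `reason`.
#' @slot report list: `total`, `assigned`, `rejected`, `perSample`
#'   (named counts) and `rejectReasons` (named counts).
#' @export
setClass("DemuxResult",
    representation(read1 = "DNAStringSet", read2 = "DNAStringSet",
                   sample = "character", rejects = "data.frame",
                   report = "list"))

setValidity("DemuxResult", function(object) {
    msg <- character()
    if (length(object@read1) != length(object@read2) ||
        length(object@read1) != length(object@sample))
        msg <- c(msg, "read1, read2 and sample must have equal length")
    rep <- object@report
    if (rep$assigned + rep$rejected != rep$total)
        msg <- c(msg, "assigned + rejected must equal total input pairs")
    if (length(msg)) msg else TRUE
})

setMethod("show", "DemuxResult", function(object) {
    rep <- object@report
    cat("DemuxResult:", rep$total, "pairs;", rep$assigned, "assigned to",
        length(rep$perSample), "samples;", rep$rejected, "rejected\n")
    if (rep$rejected > 0) {
        rr <- rep$rejectReasons[rep$rejectReasons > 0]
        cat("  rejects:", paste(names(rr), rr, sep = "=", collapse = ", "),
            "\n")
    }
})

#' @describeIn DemuxResult the summary report list.
#' @param x a `DemuxResult`.
#' @export
demuxReport <- function(x) x@report

#' @describeIn DemuxResult per-pair sample assignments (named by read id).
#' @export
demuxAssignments <- function(x) setNames(x@sample, names(x@read1))

#' Load and validate a barcode table
#'
#' Reads (or validates) a barcode table with columns `sample_id`, `barcode`
#' and optional `replicate_id`, `run_id`. Barcodes must be unique A/C/G/T
#' strings, and no barcode may equal another barcode's prefix extended by
#' the first base of the rare-site remnant: such a pair could not be
#' distinguished from a remnant match at demultiplexing time
#' (prefix-safety).
#'
#' @param x a TSV path or a data.frame.
#' @param rareRemnant remnant used for the prefix-safety check.
#' @return validated data.frame.
#' @export
readBarcodeTable <- function(x, rareRemnant = "TGCAG") {
    bc <- if (is.character(x)) read.delim(x, stringsAsFactors = FALSE) else x
    stopifnot(is.data.frame(bc))
    need <- c("sample_id", "barcode")
    if (!all(need %in% names(bc)))
        stop("barcode table needs columns: ", paste(need, collapse = ", "))
    if (nrow(bc) == 0L) stop("empty barcode table")
    bc$barcode <- toupper(bc$barcode)
    if (any(grepl("[^ACGT]", bc$barcode)))
        stop("barcodes must use only A/C/G/T")
    if (anyDuplicated(bc$barcode))
        stop("duplicate barcode(s): ",
             paste(unique(bc$barcode[duplicated(bc$barcode)]), collapse = ", "))
    ## prefix-safety: barcode B vs longer barcode L with L == paste0(B, r)
    ## where r starts with the rare remnant's first base
    first <- substr(rareRemnant, 1, 1)
    for (b in bc$barcode) {
        longer <- bc$barcode[nchar(bc$barcode) > nchar(b)]
        clash <- longer[startsWith(longer, paste0(b, first))]
        if (length(clash))
            stop(sprintf(
                "barcode '%s' is a prefix of '%s' followed by the remnant base '%s'; reads cannot be assigned unambiguously",
                b, clash[1], first))
    }
    if (!"replicate_id" %in% names(bc)) bc$replicate_id <- "r1"
    if (!"run_id" %in% names(bc)) bc$run_id <- "run1"
    bc
}

.readFastqPair <- function(r1, r2) {
    x1 <- Biostrings::readDNAStringSet(r1, format = "fastq",
                                       with.qualities = TRUE)
    x2 <- Biostrings::readDNAStringSet(r2, format = "fastq",
                                       with.qualities = TRUE)
    if (length(x1) != length(x2))
        stop("read1 and read2 files contain different numbers of reads")
    list(r1 = x1, r2 = x2)
}

.hammingPrefix <- function(seqs, word) {
    ## mismatches between `word` and the first nchar(word) bases of seqs
    n <- nchar(word)
    mm <- integer(length(seqs))
    for (i in seq_len(n))
        mm <- mm + (substr(seqs, i, i) != substr(word, i, i))
    mm[nchar(seqs) < n] <- n + 1L
    mm
}

#' Demultiplex paired-end GBS reads
#'
#' Assigns each read pair to a sample by its inline barcode and validates
#' the restriction remnants the two-enzyme library chemistry leaves at the
#' read starts. A pair is assigned to sample S when read1 begins with S's
#' barcode (up to `maxMismatch` mismatches within the barcode only)
#' immediately followed by the exact rare-cutter remnant, and read2 begins
#' with the exact common-cutter remnant. Longer barcodes are tried first;
#' two equal-length barcode hits reject the pair as `ambiguous`. On
#' assignment the barcode (only) is trimmed from read1; the remnant is
#' genome-adjacent and retained for alignment.
#'
#' @param r1,r2 FASTQ paths, or `DNAStringSet`s with qualities in
#'   `mcols()$qualities` as returned by
#'   `readDNAStringSet(format = "fastq", with.qualities = TRUE)`.
#' @param barcodes barcode table (path or data.frame), see
#'   [readBarcodeTable].
#' @param rareRemnant expected remnant at the start of read1 after the
#'   barcode (PstI leaves `TGCAG`).
#' @param commonRemnant expected remnant at the start of read2 (MspI
#'   leaves `CGG`).
#' @param maxMismatch mismatches tolerated within the barcode.
#' @return a [DemuxResult].
#' @export
demultiplex <- function(r1, r2, barcodes, rareRemnant = "TGCAG",
                        commonRemnant = "CGG", maxMismatch = 0L) {
    stopifnot(grepl("^[ACGT]+$", rareRemnant),
              grepl("^[ACGT]+$", commonRemnant))
    bc <- readBarcodeTable(barcodes, rareRemnant)
    if (is.character(r1)) {
        fq <- .readFastqPair(r1, r2)
        r1 <- fq$r1; r2 <- fq$r2
    }
    stopifnot(is(r1, "DNAStringSet"), is(r2, "DNAStringSet"),
              length(r1) == length(r2))
    n <- length(r1)
    s1 <- as.character(r1)
    s2 <- as.character(r2)
    ids <- names(r1)
    if (is.null(ids)) ids <- paste0("pair", seq_len(n))

    assigned <- rep(NA_character_, n)
    reason <- rep(NA_character_, n)
    trimAt <- integer(n)                # barcode length to trim from read1

    ## candidate barcode hits per read, longest barcode length first
    open <- rep(TRUE, n)                # still undecided
    sawBarcode <- rep(FALSE, n)         # matched some barcode prefix
    for (L in sort(unique(nchar(bc$barcode)), decreasing = TRUE)) {
        idxL <- which(nchar(bc$barcode) == L)
        hits <- matrix(FALSE, n, length(idxL))
        for (j in seq_along(idxL))
            hits[, j] <- .hammingPrefix(s1, bc$barcode[idxL[j]]) <= maxMismatch
        nh <- rowSums(hits)
        sawBarcode <- sawBarcode | nh > 0L
        ## remnant must follow the barcode exactly
        remOK <- substr(s1, L + 1L, L + nchar(rareRemnant)) == rareRemnant
        amb <- open & nh > 1L & remOK
        reason[amb] <- "ambiguous"; open[amb] <- FALSE
        hit1 <- open & nh == 1L & remOK
        if (any(hit1)) {
            j <- max.col(hits[hit1, , drop = FALSE], ties.method = "first")
            assigned[hit1] <- bc$sample_id[idxL[j]]
            trimAt[hit1] <- L
            open[hit1] <- FALSE
        }
    }
    reason[open & !sawBarcode] <- "no_barcode"
    reason[open & sawBarcode] <- "bad_rare_remnant"

    ## mate check on assigned pairs
    ok <- !is.na(assigned)
    badMate <- ok & !startsWith(s2, commonRemnant)
    reason[badMate] <- "bad_common_remnant"
    assigned[badMate] <- NA_character_

    keep <- which(!is.na(assigned))
    q1 <- S4Vectors::mcols(r1)$qualities
    q2 <- S4Vectors::mcols(r2)$qualities
    if (is.null(q1)) q1 <- Biostrings::BStringSet(
        vapply(nchar(s1), function(k) strrep("I", k), ""))
    if (is.null(q2)) q2 <- Biostrings::BStringSet(
        vapply(nchar(s2), function(k) strrep("I", k), ""))

    out1 <- Biostrings::DNAStringSet(substring(s1[keep], trimAt[keep] + 1L))
    out2 <- Biostrings::DNAStringSet(s2[keep])
    names(out1) <- names(out2) <- ids[keep]
    S4Vectors::mcols(out1)$quality <- Biostrings::BStringSet(
        substring(as.character(q1[keep]), trimAt[keep] + 1L))
    S4Vectors::mcols(out2)$quality <- Biostrings::BStringSet(
        as.character(q2[keep]))

    rejects <- data.frame(id = ids[is.na(assigned)],
                          reason = reason[is.na(assigned)],
                          stringsAsFactors = FALSE)
    perSample <- table(factor(assigned[keep], levels = unique(bc$sample_id)))
    report <- list(
        total = n, assigned = length(keep), rejected = nrow(rejects),
        perSample = setNames(as.integer(perSample), names(perSample)),
        rejectReasons = setNames(
            as.integer(table(factor(rejects$reason, levels = REJECT_REASONS))),
            REJECT_REASONS))
    new("DemuxResult", read1 = out1, read2 = out2,
        sample = assigned[keep], rejects = rejects, report = report)
}

#' Merge technical replicates
#'
#' Re-labels assigned reads from replicate-level sample ids to merged
#' sample ids (e.g. `S1_r1` and `S1_r2` both to `S1`), preserving read ids.
#' Uneven read yield between technical replicates makes merging before
#' variant calling the standard practice.
#'
#' @param x a [DemuxResult].
#' @param replicateMap data.frame with columns `replicate_sample`
#'   (ids as used at demultiplexing) and `sample` (merged id); every
#'   replicate must map to exactly one sample.
#' @return a [DemuxResult] with merged sample labels and updated report.
#' @export
mergeReplicates <- function(x, replicateMap) {
    stopifnot(is(x, "DemuxResult"),
              all(c("replicate_sample", "sample") %in% names(replicateMap)))
    if (anyDuplicated(replicateMap$replicate_sample))
        stop("replicate mapped to more than one sample: ",
             paste(unique(replicateMap$replicate_sample[
                 duplicated(replicateMap$replicate_sample)]), collapse = ", "))
    m <- setNames(replicateMap$sample, replicateMap$replicate_sample)
    unknown <- setdiff(unique(x@sample), names(m))
    if (length(unknown))
        stop("no mapping for replicate sample(s): ",
             paste(unknown, collapse = ", "))
    merged <- unname(m[x@sample])
    perSample <- table(factor(merged, levels = unique(replicateMap$sample)))
    if (any(perSample == 0))
        warning("sample(s) with zero merged pairs: ",
                paste(names(perSample)[perSample == 0], collapse = ", "))
    rep <- x@report
    rep$perSample <- setNames(as.integer(perSample), names(perSample))
    new("DemuxResult", read1 = x@read1, read2 = x@read2, sample = merged,
        rejects = x@rejects, report = rep)
}

#' Write demultiplexed reads as per-sample paired FASTQ
#'
#' @param x a [DemuxResult].
#' @param dir output directory (created if needed).
#' @return invisibly, the written file paths.
#' @export
writeDemuxFastq <- function(x, dir) {
    stopifnot(is(x, "DemuxResult"))
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    files <- character()
    for (s in sort(unique(x@sample))) {
        idx <- which(x@sample == s)
        f1 <- file.path(dir, paste0(s, "_R1.fastq"))
        f2 <- file.path(dir, paste0(s, "_R2.fastq"))
        Biostrings::writeXStringSet(
            x@read1[idx], f1, format = "fastq",
            qualities = S4Vectors::mcols(x@read1)$quality[idx])
        Biostrings::writeXStringSet(
            x@read2[idx], f2, format = "fastq",
            qualities = S4Vectors::mcols(x@read2)$quality[idx])
        files <- c(files, f1, f2)
    }
    invisible(files)
}
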