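## In silico restriction digestion: site scanning, fragment tiling and
## one- vs two-enzyme protocol comparison.

CUT_CLASSES <- c("RARE", "COMMON", "SINGLE", "TERMINUS")

.asDNAStringSet <- function(x) {
    if (is(x, "DNAStringSet")) return(x)
    if (is(x, "DNAString")) x <- as.character(x)
    if (is.character(x) && length(x) == 1L && file.exists(x) &&
        grepl("\\.(fa|fasta|fna)(\\.gz)?$", x, ignore.case = TRUE))
        return(Biostrings::readDNAStringSet(x))
    if (is.character(x)) {
        if (is.null(names(x)))
            names(x) <- if (length(x) == 1L) "seq1" else
                paste0("seq", seq_along(x))
        return(Biostrings::DNAStringSet(toupper(x)))
    }
    stop("cannot interpret input as DNA sequences")
}

.checkSequenceAlphabet <- function(seq, what = "sequence") {
    bad <- regexpr("[^ACGTNacgtn]", seq)
    if (bad > 0L)
        stop(sprintf("invalid character '%s' in %s at position %d",
                     substr(seq, bad, bad), what, bad))
    invisible(TRUE)
}

#' Find restriction recognition sites
#'
#' Scans a nucleotide sequence for every occurrence of an enzyme's IUPAC
#' recognition pattern, including overlapping occurrences. `N` in the
#' sequence never matches a non-`N` pattern letter, so assembly gaps cannot
#' create phantom sites. All three built-in GBS enzymes have palindromic
#' sites, so this single-strand scan is complete for them.
#'
#' @param sequence a single character string, `DNAString`, or a
#'   `DNAStringSet` of length 1; letters restricted to A, C, G, T, N
#'   (case-insensitive).
#' @param enzyme an [Enzyme].
#' @return integer vector of 0-based site start positions, strictly
#'   increasing.
#' @examples
#' findSites("CCGG", gbsEnzyme("MspI"))
#' findSites("GCTGCTGC", gbsEnzyme("ApeKI"))
#' @export
findSites <- function(sequence, enzyme) {
    stopifnot(is(enzyme, "Enzyme"))
    if (is(sequence, "DNAStringSet")) {
        stopifnot(length(sequence) == 1L)
        sequence <- as.character(sequence[[1L]])
    }
    if (is(sequence, "DNAString")) sequence <- as.character(sequence)
    stopifnot(is.character(sequence), length(sequence) == 1L)
    .checkSequenceAlphabet(sequence)
    subject <- Biostrings::DNAString(toupper(sequence))
    hits <- Biostrings::matchPattern(enzyme@recognition, subject,
                                     fixed = "subject")
    as.integer(BiocGenerics::start(hits)) - 1L
}

## cuts: 0-based cut coordinates (already deduplicated, sorted, within
## (0, len)); labels: cut class for each cut. Returns a GRanges tiling
## [1, len] in 1-based coordinates.
.fragmentsFromCuts <- function(seqId, len, cuts, labels) {
    stopifnot(length(cuts) == length(labels))
    bounds <- c(0, cuts, len)
    leftLab <- c("TERMINUS", labels)
    rightLab <- c(labels, "TERMINUS")
    gr <- GenomicRanges::GRanges(
        seqnames = seqId,
        ranges = IRanges::IRanges(start = bounds[-length(bounds)] + 1L,
                                  end = bounds[-1L]))
    gr$leftCut <- factor(leftLab, levels = CUT_CLASSES)
    gr$rightCut <- factor(rightLab, levels = CUT_CLASSES)
    gr
}

.cutPositions <- function(seq, enzyme) {
    sites <- findSites(seq, enzyme)
    cuts <- sites + enzyme@cutOffset
    len <- nchar(seq)
    sort(unique(cuts[cuts > 0L & cuts < len]))
}

.digestOne <- function(seqId, seq, enzyme) {
    cuts <- .cutPositions(seq, enzyme)
    .fragmentsFromCuts(seqId, nchar(seq), cuts,
                       rep("SINGLE", length(cuts)))
}

#' Single-enzyme digest
#'
#' Cuts each input sequence at `site + cutOffset` for every recognition-site
#' occurrence and returns the resulting fragments as a `GRanges` that tiles
#' each sequence exactly. Internal fragments are flanked `SINGLE`/`SINGLE`;
#' the first and last fragment of each sequence carry `TERMINUS` on the
#' outer side.
#'
#' @param x sequences: character vector, `DNAString(Set)` or FASTA path.
#' @param enzyme an [Enzyme].
#' @return `GRanges` (1-based, inclusive) with metadata columns `leftCut`
#'   and `rightCut`.
#' @examples
#' digestSingle("GCAGCAAGCTGC", gbsEnzyme("ApeKI"))
#' @export
digestSingle <- function(x, enzyme) {
    dna <- .asDNAStringSet(x)
    frags <- lapply(seq_along(dna), function(i)
        .digestOne(names(dna)[i], as.character(dna[[i]]), enzyme))
    out <- do.call(c, frags)
    GenomeInfoDb::seqlevels(out) <- names(dna)
    out
}

#' Double (rare + common) enzyme digest
#'
#' Simulates a two-enzyme digest: cut positions from both enzymes are pooled
#' and each fragment boundary is labelled by the enzyme that produced it
#' (`RARE` or `COMMON`). A coordinate cut by both enzymes is ambiguous and
#' raised as an error rather than silently attributed.
#'
#' @param x sequences as in [digestSingle].
#' @param rare the rare-cutter [Enzyme] (e.g. PstI).
#' @param common the common-cutter [Enzyme] (e.g. MspI).
#' @return `GRanges` with `leftCut`/`rightCut` in
#'   `{RARE, COMMON, TERMINUS}`.
#' @examples
#' digestDouble("AACTGCAGTTTCCGGAA", gbsEnzyme("PstI"), gbsEnzyme("MspI"))
#' @export
digestDouble <- function(x, rare, common) {
    stopifnot(is(rare, "Enzyme"), is(common, "Enzyme"))
    if (rare@recognition == common@recognition)
        stop("rare and common enzymes must have distinct recognition sites")
    dna <- .asDNAStringSet(x)
    frags <- lapply(seq_along(dna), function(i) {
        seq <- as.character(dna[[i]])
        rc <- .cutPositions(seq, rare)
        cc <- .cutPositions(seq, common)
        clash <- intersect(rc, cc)
        if (length(clash))
            stop(sprintf(
                "coincident rare/common cut position(s) on '%s': %s",
                names(dna)[i], paste(clash, collapse = ", ")))
        cuts <- sort(c(rc, cc))
        labels <- ifelse(cuts %in% rc, "RARE", "COMMON")
        .fragmentsFromCuts(names(dna)[i], nchar(seq), cuts, labels)
    })
    out <- do.call(c, frags)
    GenomeInfoDb::seqlevels(out) <- names(dna)
    out
}

#' Summarise a digest
#'
#' Tabulates fragments by flanking-cut class and checks the tiling
#' invariant (fragment lengths sum to the total sequence length).
#'
#' @param fragments `GRanges` from [digestSingle] or [digestDouble].
#' @return list with `counts` (data.frame: class, n, meanLength,
#'   totalLength), `totalLength`, and `lengths` (per-class length list).
#' @export
digestSummary <- function(fragments) {
    cls <- fragmentClass(fragments)
    w <- BiocGenerics::width(fragments)
    bySeq <- split(w, as.character(GenomicRanges::seqnames(fragments)))
    total <- sum(vapply(bySeq, sum, numeric(1)))
    lens <- split(w, cls)
    counts <- data.frame(
        class = names(lens),
        n = vapply(lens, length, integer(1)),
        meanLength = vapply(lens, mean, numeric(1)),
        totalLength = vapply(lens, sum, numeric(1)),
        row.names = NULL)
    stopifnot(sum(counts$totalLength) == total)
    list(counts = counts, totalLength = total, lengths = lens)
}

#' Canonical fragment class label
#'
#' Combines the two flanking-cut labels into an orientation-independent
#' class such as `"RARE-COMMON"` or `"SINGLE-SINGLE"` (labels sorted so
#' that `COMMON-RARE` and `RARE-COMMON` collapse to one class, except that
#' `TERMINUS` always sorts last).
#'
#' @param fragments a fragment `GRanges`.
#' @return character vector of class labels, one per fragment.
#' @export
fragmentClass <- function(fragments) {
    l <- as.character(fragments$leftCut)
    r <- as.character(fragments$rightCut)
    ord <- match(l, CUT_CLASSES) <= match(r, CUT_CLASSES)
    paste(ifelse(ord, l, r), ifelse(ord, r, l), sep = "-")
}

#' Compare one-enzyme and two-enzyme protocol complexity
#'
#' Digests a genome with a one-enzyme protocol and with a rare+common
#' two-enzyme protocol and reports the relative reduction in fragment count,
#' `1 - two/one`. By default the one-enzyme count is the internal
#' (`SINGLE-SINGLE`) fragments and the two-enzyme count is the sequenced
#' `RARE-COMMON` class; set `countClass` to `"internal"` to count all
#' internal two-enzyme fragments instead, or `"all"` to count every
#' fragment on both sides.
#'
#' @param genome sequences as in [digestSingle]; must be non-empty.
#' @param oneEnzyme [Enzyme] for the single-enzyme protocol.
#' @param rare,common [Enzyme] pair for the two-enzyme protocol.
#' @param countClass which two-enzyme fragment class is counted.
#' @param minLength,maxLength optional fragment-length window applied to
#'   both protocols before counting (no size selection by default).
#' @return list with `oneSummary`, `twoSummary`, `oneCount`, `twoCount`
#'   and `reduction`.
#' @export
compareProtocols <- function(genome, oneEnzyme, rare, common,
                             countClass = c("rare-common", "internal", "all"),
                             minLength = NULL, maxLength = NULL) {
    countClass <- match.arg(countClass)
    dna <- .asDNAStringSet(genome)
    if (length(dna) == 0L || sum(BiocGenerics::width(dna)) == 0L)
        stop("empty genome")
    one <- digestSingle(dna, oneEnzyme)
    two <- digestDouble(dna, rare, common)
    sel <- function(fr) {
        keep <- rep(TRUE, length(fr))
        if (!is.null(minLength)) keep <- keep & BiocGenerics::width(fr) >= minLength
        if (!is.null(maxLength)) keep <- keep & BiocGenerics::width(fr) <= maxLength
        fr[keep]
    }
    oneSel <- sel(one); twoSel <- sel(two)
    oneCount <- sum(fragmentClass(oneSel) == "SINGLE-SINGLE")
    twoCount <- switch(countClass,
        "rare-common" = sum(fragmentClass(twoSel) == "RARE-COMMON"),
        "internal" = sum(!grepl("TERMINUS", fragmentClass(twoSel))),
        "all" = length(twoSel))
    if (countClass == "all") oneCount <- length(oneSel)
    if (oneCount == 0L)
        stop("one-enzyme protocol yields no fragments to compare against")
    list(oneSummary = digestSummary(one), twoSummary = digestSummary(two),
         oneCount = oneCount, twoCount = twoCount,
         reduction = 1 - twoCount / oneCount)
}
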