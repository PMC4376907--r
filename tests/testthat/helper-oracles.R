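## Independent oracles and fixture builders used across the suite.

suppressPackageStartupMessages({
    library(GenomicRanges)
    library(S4Vectors)
})

IUPAC_SETS <- list(
    A = "A", C = "C", G = "G", T = "T",
    R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
    K = c("G", "T"), M = c("A", "C"), B = c("C", "G", "T"),
    D = c("A", "G", "T"), H = c("A", "C", "T"), V = c("A", "C", "G"),
    N = c("A", "C", "G", "T"))

## naive O(n*m) position-by-position IUPAC comparator; N in the sequence
## matches nothing but a literal N in the pattern
iupacScanOracle <- function(seq, pattern) {
    seq <- toupper(seq); pattern <- toupper(pattern)
    n <- nchar(seq); m <- nchar(pattern)
    if (n < m) return(integer(0))
    ok <- rep(TRUE, n - m + 1L)
    pat <- strsplit(pattern, "")[[1]]
    for (k in seq_len(m)) {
        sub <- substring(seq, k, n - m + k)
        chars <- strsplit(sub, "")[[1]]
        allowed <- IUPAC_SETS[[pat[k]]]
        hit <- chars %in% allowed
        if (pat[k] == "N") hit <- hit | chars == "N"
        ok <- ok & hit
    }
    which(ok) - 1L
}

randomDnaString <- function(n, withN = FALSE) {
    alpha <- c("A", "C", "G", "T", if (withN) "N")
    prob <- if (withN) c(rep(0.24, 4), 0.04) else rep(0.25, 4)
    paste(sample(alpha, n, replace = TRUE, prob = prob), collapse = "")
}

randomGenotypeMatrix <- function(nSites = 200L, nSamples = 100L,
                                 missingRate = 0.1, nSeqs = 2L) {
    d <- matrix(sample(0:2, nSites * nSamples, replace = TRUE,
                       prob = c(0.45, 0.1, 0.45)),
                nSites, nSamples,
                dimnames = list(NULL, sprintf("S%03d", seq_len(nSamples))))
    d[matrix(runif(length(d)) < missingRate, nrow(d))] <- NA_integer_
    seqs <- sort(rep_len(paste0("sc", seq_len(nSeqs)), nSites))
    pos <- unlist(lapply(split(seq_len(nSites), seqs), function(i)
        sort(sample.int(nSites * 50L, length(i)))), use.names = FALSE)
    sites <- GenomicRanges::GRanges(seqs, IRanges::IRanges(pos, width = 1L),
                                    ref = "A", alt = "G")
    GenotypeMatrix(d, sites)
}

## brute-force filter re-implementations (loop-based, no shared code with
## the package internals)
bruteMaskKeep <- function(gm, mask) {
    keys <- siteKeys(gm)
    keep <- logical(nrow(keys))
    m <- as.data.frame(mask)
    for (i in seq_len(nrow(keys))) {
        p0 <- keys$pos[i] - 1L   # 0-based
        inMask <- FALSE
        for (j in seq_len(nrow(m))) {
            if (m$seqnames[j] == keys$seqnames[i] &&
                p0 >= m$start[j] - 1L && p0 < m$end[j]) {
                inMask <- TRUE
                break
            }
        }
        keep[i] <- !inMask
    }
    keep
}

bruteMissingKeep <- function(gm, maxSite = 0.2, maxSample = 0.2) {
    d <- dosage(gm)
    siteKeep <- vapply(seq_len(nrow(d)), function(i)
        mean(is.na(d[i, ])) <= maxSite, logical(1))
    d2 <- d[siteKeep, , drop = FALSE]
    sampleKeep <- vapply(seq_len(ncol(d2)), function(j)
        mean(is.na(d2[, j])) <= maxSample, logical(1))
    list(sites = siteKeep, samples = sampleKeep)
}

bruteMafKeep <- function(gm, minMAF = 0.1) {
    d <- dosage(gm)
    vapply(seq_len(nrow(d)), function(i) {
        x <- d[i, ][!is.na(d[i, ])]
        if (!length(x)) return(FALSE)
        p <- sum(x) / (2 * length(x))
        min(p, 1 - p) >= minMAF
    }, logical(1))
}

bruteR2 <- function(x, y) {
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < 3) return(0)
    if (length(unique(x[ok])) < 2 || length(unique(y[ok])) < 2) return(0)
    cor(x[ok], y[ok])^2
}

## exhaustive within-window recheck that no kept pair is in high LD
ldPostHocViolations <- function(gm, r2Cutoff = 0.8, windowSites = 50L) {
    d <- dosage(gm)
    seqs <- siteKeys(gm)$seqnames
    bad <- 0L
    for (sq in unique(seqs)) {
        idx <- which(seqs == sq)
        for (a in seq_along(idx)) {
            for (b in seq_len(a - 1L)) {
                if (a - b > windowSites) next
                if (bruteR2(d[idx[a], ], d[idx[b], ]) > r2Cutoff)
                    bad <- bad + 1L
            }
        }
    }
    bad
}

bruteDistance <- function(d) {
    n <- ncol(d)
    out <- matrix(0, n, n, dimnames = list(colnames(d), colnames(d)))
    for (i in seq_len(n)) for (j in seq_len(n)) {
        ok <- !is.na(d[, i]) & !is.na(d[, j])
        out[i, j] <- mean(abs(d[ok, i] - d[ok, j]) / 2)
    }
    out
}

## paired FASTQ-like read sets constructed directly from barcode + remnant
## + genomic filler
buildReadSet <- function(specs) {
    r1 <- Biostrings::DNAStringSet(vapply(specs, `[[`, "", "r1"))
    r2 <- Biostrings::DNAStringSet(vapply(specs, `[[`, "", "r2"))
    names(r1) <- names(r2) <- vapply(specs, `[[`, "", "id")
    S4Vectors::mcols(r1)$qualities <-
        Biostrings::BStringSet(strrep("I", BiocGenerics::width(r1)))
    S4Vectors::mcols(r2)$qualities <-
        Biostrings::BStringSet(strrep("I", BiocGenerics::width(r2)))
    list(r1 = r1, r2 = r2)
}

writeMinimalVcf <- function(path, samples, rows) {
    writeLines(c(
        "##fileformat=VCFv4.2",
        "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
        paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                "INFO", "FORMAT", samples), collapse = "\t"),
        rows), path)
    path
}

vcfRow <- function(chrom, pos, ref, alt, gts) {
    paste(c(chrom, pos, ".", ref, alt, "50", ".", ".", "GT", gts),
          collapse = "\t")
}
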