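## The SNP filter cascade: repeat masking, missingness, minor allele
## frequency, and LD-redundancy pruning, each with per-stage accounting.

.subsetSites <- function(gm, keep, stage, samplesKeep = NULL) {
    sIn <- nrow(gm); pIn <- ncol(gm)
    out <- gm[keep, , drop = FALSE]
    if (!is.null(samplesKeep)) out <- out[, samplesKeep, drop = FALSE]
    out <- as(out, "GenotypeMatrix")
    .appendAccounting(out, stage, sIn, nrow(out), pIn, ncol(out))
}

#' Remove sites in repeat-masked regions
#'
#' Drops SNPs whose position falls inside a repeat mask (e.g. from
#' RepeatMasker), removing probable mismapping artefacts. The mask uses
#' BED conventions (0-based, half-open), so a VCF position `p` is masked
#' when `p - 1` lies inside an interval on the same sequence.
#'
#' @param gm a [GenotypeMatrix].
#' @param mask a `GRanges` (1-based, as returned by
#'   `rtracklayer::import`) or a BED file path.
#' @return filtered `GenotypeMatrix` with an accounting row appended.
#' @export
maskRepeats <- function(gm, mask) {
    stopifnot(is(gm, "GenotypeMatrix"))
    if (is.character(mask)) mask <- rtracklayer::import(mask)
    stopifnot(is(mask, "GRanges"))
    if (any(BiocGenerics::start(mask) < 1L))
        stop("mask contains negative coordinates")
    hit <- IRanges::overlapsAny(SummarizedExperiment::rowRanges(gm), mask,
                                ignore.strand = TRUE)
    .subsetSites(gm, !hit, "mask_repeats")
}

#' Filter by missing-data fraction
#'
#' First removes sites whose missing fraction exceeds `maxSiteMissing`
#' (strictly greater), then removes samples whose missing fraction over
#' the remaining sites exceeds `maxSampleMissing`. Sites are handled first
#' so that borderline samples are rescued by the removal of bad sites.
#'
#' @param gm a [GenotypeMatrix].
#' @param maxSiteMissing,maxSampleMissing maximum tolerated missing
#'   fraction (default 0.20 each, the usual GBS setting).
#' @return filtered `GenotypeMatrix` with accounting appended.
#' @export
filterMissing <- function(gm, maxSiteMissing = 0.20,
                          maxSampleMissing = 0.20) {
    stopifnot(is(gm, "GenotypeMatrix"),
              maxSiteMissing >= 0, maxSiteMissing <= 1,
              maxSampleMissing >= 0, maxSampleMissing <= 1)
    d <- dosage(gm)
    siteKeep <- rowMeans(is.na(d)) <= maxSiteMissing
    if (!any(siteKeep))
        stop("all sites exceed the missing-data threshold; ",
             "raise 'maxSiteMissing'")
    sampleKeep <- colMeans(is.na(d[siteKeep, , drop = FALSE])) <=
        maxSampleMissing
    .subsetSites(gm, siteKeep, "missing", samplesKeep = sampleKeep)
}

#' Filter by minor allele frequency
#'
#' Per site, the alternate-allele frequency is the dosage sum over called
#' samples divided by twice their number; the MAF is `min(p, 1 - p)`.
#' Sites with `MAF < minMAF` are removed (a site at exactly the threshold
#' is kept), as are sites with no called genotypes.
#'
#' @param gm a [GenotypeMatrix].
#' @param minMAF minimum minor allele frequency (default 0.10).
#' @return filtered `GenotypeMatrix` with accounting appended.
#' @export
filterMAF <- function(gm, minMAF = 0.10) {
    stopifnot(is(gm, "GenotypeMatrix"), minMAF >= 0, minMAF <= 1)
    d <- dosage(gm)
    called <- rowSums(!is.na(d))
    p <- rowSums(d, na.rm = TRUE) / (2 * called)
    maf <- pmin(p, 1 - p)
    keep <- called > 0L & maf >= minMAF
    .subsetSites(gm, keep, "maf")
}

.pairR2 <- function(x, y) {
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < 3L) return(0)
    x <- x[ok]; y <- y[ok]
    if (stats::var(x) == 0 || stats::var(y) == 0) return(0)
    stats::cor(x, y)^2
}

#' LD-redundancy pruning
#'
#' Greedy left-to-right scan within each sequence: a site is kept unless
#' its squared Pearson correlation (r-squared of dosages over
#' pairwise-complete samples) with any of the `windowSites` most recently
#' kept sites exceeds `r2Cutoff`. Pairs sharing fewer than 3 called
#' samples, or with a monomorphic member, contribute r-squared 0. The
#' result is a quasi-independent marker set suitable for tree building and
#' population-structure analysis.
#'
#' @param gm a [GenotypeMatrix] (sites are kept sorted by position).
#' @param r2Cutoff prune threshold on genotype r-squared (default 0.80).
#' @param windowSites number of preceding kept sites compared against
#'   (default 50; bounds the scan to linear time).
#' @return filtered `GenotypeMatrix` with accounting appended.
#' @export
ldPrune <- function(gm, r2Cutoff = 0.80, windowSites = 50L) {
    stopifnot(is(gm, "GenotypeMatrix"), r2Cutoff >= 0, r2Cutoff <= 1,
              windowSites >= 1L)
    d <- dosage(gm)
    seqs <- as.character(GenomicRanges::seqnames(
        SummarizedExperiment::rowRanges(gm)))
    keep <- logical(nrow(d))
    for (sq in unique(seqs)) {
        idx <- which(seqs == sq)
        kept <- integer()
        for (j in idx) {
            recent <- tail(kept, windowSites)
            linked <- FALSE
            for (k in rev(recent)) {
                if (.pairR2(d[j, ], d[k, ]) > r2Cutoff) {
                    linked <- TRUE
                    break
                }
            }
            if (!linked) kept <- c(kept, j)
        }
        keep[kept] <- TRUE
    }
    .subsetSites(gm, keep, "ld_prune")
}

#' Run the full filter cascade
#'
#' Applies, in order: repeat masking (if a mask is given), missing-data
#' filtering, MAF filtering and LD pruning — the standard cascade for
#' building a phylogeny-ready SNP set from raw merged GBS calls.
#'
#' @param gm a [GenotypeMatrix].
#' @param mask optional repeat mask (`GRanges` or BED path).
#' @param maxSiteMissing,maxSampleMissing,minMAF,r2Cutoff,windowSites
#'   stage parameters, see the individual filters.
#' @return filtered `GenotypeMatrix`; `filterAccounting()` lists every
#'   stage.
#' @export
filterCascade <- function(gm, mask = NULL, maxSiteMissing = 0.20,
                          maxSampleMissing = 0.20, minMAF = 0.10,
                          r2Cutoff = 0.80, windowSites = 50L) {
    if (!is.null(mask)) gm <- maskRepeats(gm, mask)
    gm <- filterMissing(gm, maxSiteMissing, maxSampleMissing)
    gm <- filterMAF(gm, minMAF)
    ldPrune(gm, r2Cutoff, windowSites)
}

#' Heterozygosity rate
#'
#' Fraction of called genotypes that are heterozygous (dosage 1), overall
#' and per sample. Selfing species are expected to show sub-percent rates;
#' higher values may point at paralog collapse or contamination.
#'
#' @param gm a [GenotypeMatrix] with at least one called genotype.
#' @return list with `overall` (fraction) and `perSample` (named vector).
#' @export
hetRate <- function(gm) {
    stopifnot(is(gm, "GenotypeMatrix"))
    d <- dosage(gm)
    if (length(d) == 0L || all(is.na(d)))
        stop("empty genotype matrix")
    list(overall = mean(d[!is.na(d)] == 1L),
         perSample = apply(d, 2, function(x) mean(x[!is.na(x)] == 1L)))
}
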