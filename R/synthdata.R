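## Seeded generators for synthetic genomes with implanted restriction
## sites, barcoded GBS read pairs, and structured populations. Each
## generator returns a machine-readable truth table so downstream modules
## can be scored without external data.

.randomBases <- function(n, gc = 0.45) {
    sample(c("A", "C", "G", "T"), n, replace = TRUE,
           prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

.iupacInstantiate <- function(pattern) {
    expand <- c(A = "A", C = "C", G = "G", T = "T", R = "AG", Y = "CT",
                S = "CG", W = "AT", K = "GT", M = "AC", B = "CGT",
                D = "AGT", H = "ACT", V = "ACG", N = "ACGT")
    paste(vapply(strsplit(pattern, "")[[1]], function(ch) {
        opts <- strsplit(expand[[ch]], "")[[1]]
        if (length(opts) == 1L) opts else sample(opts, 1L)
    }, ""), collapse = "")
}

#' Synthetic genome with implanted restriction sites
#'
#' Generates a random background sequence scrubbed of both enzymes'
#' recognition patterns, then implants concrete recognition sites at
#' recorded, well-separated positions — so the digest truth is exactly
#' known. The generated genome is verified: the digest scan must recover
#' precisely the implanted positions.
#'
#' @param length genome length in bp.
#' @param gc background GC content.
#' @param nRareSites,nCommonSites number of implanted sites per enzyme.
#' @param rare,common the [Enzyme] pair (default PstI/MspI).
#' @param seed optional integer seed.
#' @return list with `genome` (`DNAStringSet`, one sequence named
#'   `"synth1"`) and `truth` (data.frame: `enzyme`, `position` 0-based
#'   site start, `cut` 0-based cut coordinate).
#' @export
makeGenome <- function(length = 10000L, gc = 0.45, nRareSites = 5L,
                       nCommonSites = 40L, rare = gbsEnzyme("PstI"),
                       common = gbsEnzyme("MspI"), seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    stopifnot(length >= 100L, nRareSites >= 0L, nCommonSites >= 0L)
    maxSite <- max(nchar(rare@recognition), nchar(common@recognition))
    gap <- maxSite + 8L
    slots <- seq(gap, length - gap, by = gap)
    nSites <- nRareSites + nCommonSites
    if (length(slots) < nSites)
        stop("site density infeasible for genome length")

    for (attempt in 1:25) {
        chars <- .randomBases(length, gc)
        seqStr <- paste(chars, collapse = "")
        ## scrub background of both patterns
        for (pass in 1:50) {
            hits <- c(findSites(seqStr, rare), findSites(seqStr, common))
            if (!length(hits)) break
            for (h in hits) {
                at <- h + sample.int(min(nchar(rare@recognition),
                                         nchar(common@recognition)), 1L)
                substr(seqStr, at, at) <- .randomBases(1L, gc)
            }
        }
        if (length(c(findSites(seqStr, rare), findSites(seqStr, common))))
            next
        pos <- sort(sample(slots, nSites))
        which_rare <- sort(sample(seq_len(nSites), nRareSites))
        enz <- rep("common", nSites); enz[which_rare] <- "rare"
        for (k in seq_len(nSites)) {
            e <- if (enz[k] == "rare") rare else common
            site <- .iupacInstantiate(e@recognition)
            substr(seqStr, pos[k] + 1L, pos[k] + nchar(site)) <- site
        }
        truth <- data.frame(
            enzyme = ifelse(enz == "rare", rare@name, common@name),
            position = pos,
            cut = pos + ifelse(enz == "rare", rare@cutOffset,
                               common@cutOffset),
            stringsAsFactors = FALSE)
        ## verify: scans must recover exactly the implanted sites
        okRare <- identical(findSites(seqStr, rare),
                            as.integer(truth$position[enz == "rare"]))
        okCommon <- identical(findSites(seqStr, common),
                              as.integer(truth$position[enz == "common"]))
        if (okRare && okCommon) {
            genome <- Biostrings::DNAStringSet(seqStr)
            names(genome) <- "synth1"
            return(list(genome = genome, truth = truth))
        }
    }
    stop("failed to construct a clean genome; lower the site density")
}

#' Synthetic barcoded GBS read pairs
#'
#' Draws read pairs from the rare-common fragments of a genome, emulating
#' a two-enzyme GBS library: read1 is barcode + rare-cutter remnant +
#' fragment prefix, read2 is common-cutter remnant + reverse-complemented
#' fragment suffix. Per-sample read counts follow the supplied depth
#' multipliers, emulating DNA-quality-driven yield bias between samples.
#' The truth table records each pair's generating sample, so
#' demultiplexing can be scored exactly.
#'
#' @param genome `DNAStringSet` (e.g. from [makeGenome]).
#' @param barcodes barcode table (data.frame with `sample_id`,
#'   `barcode`, ...; see [readBarcodeTable]).
#' @param nPairs total number of read pairs.
#' @param readLength read length in bp (reads are shorter when the
#'   fragment is exhausted).
#' @param depthMultipliers positive per-sample weights (recycled named by
#'   `sample_id` order; default all equal).
#' @param errorRate per-base substitution probability applied to the
#'   whole read (default 0; any error inside barcode or remnant makes the
#'   pair undemultiplexable by design).
#' @param rare,common the [Enzyme] pair.
#' @param seed optional integer seed.
#' @return list with `read1`, `read2` (`DNAStringSet` with qualities in
#'   `mcols()$qualities`), `truth` (data.frame `id`, `sample_id`,
#'   `fragmentStart`), and `skippedFragments` (count too short to carry
#'   both remnants).
#' @export
makeReads <- function(genome, barcodes, nPairs = 10000L, readLength = 100L,
                      depthMultipliers = NULL, errorRate = 0,
                      rare = gbsEnzyme("PstI"), common = gbsEnzyme("MspI"),
                      seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    bc <- readBarcodeTable(barcodes)
    frags <- digestDouble(genome, rare, common)
    cls <- fragmentClass(frags)
    rc <- frags[cls == "RARE-COMMON"]
    if (length(rc) == 0L)
        stop("genome contains no rare-common fragments")
    rareRem <- enzymeRemnant(rare)
    commonRem <- enzymeRemnant(common)
    seqStrs <- setNames(as.character(genome), names(genome))
    fragSeq <- substring(seqStrs[as.character(GenomicRanges::seqnames(rc))],
                         BiocGenerics::start(rc), BiocGenerics::end(rc))
    names(fragSeq) <- NULL
    ## orient every fragment rare-end first
    flip <- as.character(rc$leftCut) == "COMMON"
    fragSeq[flip] <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(fragSeq[flip])))
    longEnough <- nchar(fragSeq) >= nchar(rareRem) + nchar(commonRem)
    skipped <- sum(!longEnough)
    fragSeq <- fragSeq[longEnough]
    fragStart <- BiocGenerics::start(rc)[longEnough]
    if (!length(fragSeq))
        stop("all rare-common fragments shorter than the remnants")

    nS <- nrow(bc)
    w <- depthMultipliers
    if (is.null(w)) w <- rep(1, nS)
    stopifnot(all(w > 0), length(w) == nS)
    perSample <- as.integer(stats::rmultinom(1, nPairs, w / sum(w)))
    sampleOf <- rep(bc$sample_id, perSample)
    bcOf <- rep(bc$barcode, perSample)
    fi <- sample.int(length(fragSeq), nPairs, replace = TRUE)

    p1 <- paste0(bcOf, rareRem,
                 substr(fragSeq[fi], 1L,
                        pmax(0L, readLength - nchar(bcOf) - nchar(rareRem))))
    suffixLen <- pmin(nchar(fragSeq[fi]), readLength - nchar(commonRem))
    suffix <- substr(fragSeq[fi], nchar(fragSeq[fi]) - suffixLen + 1L,
                     nchar(fragSeq[fi]))
    p2 <- paste0(commonRem, as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(suffix))))

    if (errorRate > 0) {
        mutate <- function(s) {
            vapply(s, function(x) {
                n <- nchar(x)
                hit <- which(stats::runif(n) < errorRate)
                for (i in hit)
                    substr(x, i, i) <- sample(setdiff(c("A", "C", "G", "T"),
                                                      substr(x, i, i)), 1L)
                x
            }, "", USE.NAMES = FALSE)
        }
        p1 <- mutate(p1); p2 <- mutate(p2)
    }
    ids <- sprintf("pair%06d", seq_len(nPairs))
    r1 <- Biostrings::DNAStringSet(p1); names(r1) <- ids
    r2 <- Biostrings::DNAStringSet(p2); names(r2) <- ids
    S4Vectors::mcols(r1)$qualities <- Biostrings::BStringSet(
        strrep("I", nchar(p1)))
    S4Vectors::mcols(r2)$qualities <- Biostrings::BStringSet(
        strrep("I", nchar(p2)))
    list(read1 = r1, read2 = r2,
         truth = data.frame(id = ids, sample_id = sampleOf,
                            fragmentStart = fragStart[fi],
                            stringsAsFactors = FALSE),
         skippedFragments = skipped)
}

#' Synthetic structured population genotypes
#'
#' Draws a samples-by-sites genotype matrix from `nPools` diverged gene
#' pools under the Balding-Nichols model: per pool and site the allele
#' frequency is Beta-distributed around a shared ancestral frequency
#' (uniform on `[0.05, 0.95]`) with divergence controlled by `fst`.
#' Genotypes are drawn nearly fully homozygous (`inbreeding` close to 1),
#' as appropriate for a selfing species. Missing data combine a
#' per-sample random rate with per-run site dropout: each sequencing run
#' loses a random subset of sites for all its samples, emulating
#' run-to-run variation in covered loci under low-coverage sequencing.
#' Optionally a fraction of accessions receive a second replicate sample:
#' the same underlying genotype re-observed with independent missingness,
#' assigned to the other run.
#'
#' @param nPools number of gene pools.
#' @param samplesPerPool accessions per pool.
#' @param nSites number of SNP sites.
#' @param fst Balding-Nichols divergence parameter in (0, 1).
#' @param inbreeding probability a genotype is drawn fully homozygous
#'   (expected heterozygosity is `(1 - inbreeding) * 2p(1-p)`).
#' @param missingRate per-sample random missing-call rate.
#' @param runs number of sequencing runs samples are spread over.
#' @param runDropout fraction of sites dropped (missing) per run.
#' @param replicateFraction fraction of accessions given a second
#'   replicate sample.
#' @param seed optional integer seed.
#' @return list with `genotypes` (a [GenotypeMatrix]; sites placed every
#'   100 bp on one synthetic scaffold), `meta` (data.frame `sample_id`,
#'   `accession`, `taxon`, `replicate`, `run`), and `truth` (list:
#'   `pool` per-sample labels, `ancestralFreq`, `poolFreq` pools x sites).
#' @export
makePopulation <- function(nPools = 4L, samplesPerPool = 10L,
                           nSites = 2000L, fst = 0.3, inbreeding = 0.98,
                           missingRate = 0.05, runs = 2L, runDropout = 0.05,
                           replicateFraction = 0, seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    stopifnot(fst > 0, fst < 1, inbreeding >= 0, inbreeding <= 1,
              missingRate >= 0, missingRate < 1, runDropout >= 0,
              runDropout < 1, replicateFraction >= 0,
              replicateFraction <= 1)
    p0 <- runif(nSites, 0.05, 0.95)
    shape <- (1 - fst) / fst
    poolFreq <- t(vapply(seq_len(nPools), function(k)
        rbeta(nSites, shape * p0, shape * (1 - p0)), numeric(nSites)))
    rownames(poolFreq) <- paste0("pool", seq_len(nPools))

    acc <- expand.grid(a = seq_len(samplesPerPool), k = seq_len(nPools))
    accession <- sprintf("p%d_a%02d", acc$k, acc$a)
    pool <- acc$k
    nRep <- round(replicateFraction * length(accession))
    repAcc <- if (nRep > 0) sort(sample(seq_along(accession), nRep)) else
        integer()

    drawGenotype <- function(k) {
        p <- poolFreq[k, ]
        full <- runif(nSites) < inbreeding
        g <- integer(nSites)
        g[full] <- 2L * rbinom(sum(full), 1L, p[full])
        g[!full] <- rbinom(sum(!full), 2L, p[!full])
        g
    }
    genoAcc <- lapply(pool, drawGenotype)

    sampleId <- character(); accOf <- character(); poolOf <- integer()
    repOf <- character(); rows <- integer()
    for (i in seq_along(accession)) {
        sampleId <- c(sampleId, paste0(accession[i], "_r1"))
        accOf <- c(accOf, accession[i]); poolOf <- c(poolOf, pool[i])
        repOf <- c(repOf, "r1"); rows <- c(rows, i)
        if (i %in% repAcc) {
            sampleId <- c(sampleId, paste0(accession[i], "_r2"))
            accOf <- c(accOf, accession[i]); poolOf <- c(poolOf, pool[i])
            repOf <- c(repOf, "r2"); rows <- c(rows, i)
        }
    }
    n <- length(sampleId)
    runOf <- paste0("run", ((seq_len(n) - 1L) %% runs) + 1L)
    runOf[repOf == "r2"] <- paste0("run", runs)  # replicates on the later run

    dos <- matrix(NA_integer_, nSites, n,
                  dimnames = list(NULL, sampleId))
    runDrop <- lapply(seq_len(runs), function(r)
        which(runif(nSites) < runDropout))
    for (j in seq_len(n)) {
        g <- genoAcc[[rows[j]]]
        miss <- runif(nSites) < missingRate
        miss[runDrop[[as.integer(sub("run", "", runOf[j]))]]] <- TRUE
        g[miss] <- NA_integer_
        dos[, j] <- g
    }
    sites <- GenomicRanges::GRanges(
        "scaffold1", IRanges::IRanges(start = 100L * seq_len(nSites),
                                      width = 1L),
        ref = "A", alt = "G")
    gm <- GenotypeMatrix(dos, sites)
    meta <- data.frame(sample_id = sampleId, accession = accOf,
                       taxon = paste0("pool", poolOf), replicate = repOf,
                       run = runOf, stringsAsFactors = FALSE)
    list(genotypes = gm, meta = meta,
         truth = list(pool = setNames(paste0("pool", poolOf), sampleId),
                      ancestralFreq = p0, poolFreq = poolFreq))
}

#' Default 48-barcode set
#'
#' A deterministic set of 4-8 bp barcodes satisfying the demultiplexer's
#' uniqueness and prefix-safety constraints, for simulations and
#' examples.
#'
#' @param n number of barcodes (<= 48).
#' @return data.frame with `sample_id`, `barcode`, `replicate_id`,
#'   `run_id`.
#' @export
defaultBarcodes <- function(n = 48L) {
    stopifnot(n >= 1L, n <= 48L)
    bases <- c("A", "C", "G", "T")
    ## enumerate fixed-length 5-mers not starting with T (rare remnant
    ## TGCAG starts with T, keeping prefixes safe) and not containing
    ## the remnant prefix
    words <- character()
    for (i in 1:3) for (j in 1:4) for (k in 1:4) for (l in 1:4) {
        w <- paste0(bases[i], bases[j], bases[k], bases[l],
                    bases[(i + j + k + l) %% 4 + 1])
        if (!grepl("TGCAG", w)) words <- c(words, w)
        if (length(words) >= n) break
    }
    words <- unique(words)[seq_len(n)]
    data.frame(sample_id = sprintf("S%02d", seq_len(n)), barcode = words,
               replicate_id = rep(c("r1", "r2"), length.out = n),
               run_id = "run1", stringsAsFactors = FALSE)
}
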