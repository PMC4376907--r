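test_that("enzyme definitions are validated and built-ins are palindromic", {
    expect_error(Enzyme("bad", "GCXGC", 1L), "non-IUPAC")
    expect_error(Enzyme("bad", "GCGC", 9L), "cutOffset")
    for (nm in c("ApeKI", "PstI", "MspI")) {
        e <- gbsEnzyme(nm)
        rc <- as.character(Biostrings::reverseComplement(
            Biostrings::DNAString(recognitionSite(e))))
        expect_identical(rc, recognitionSite(e))
    }
    expect_identical(enzymeRemnant(gbsEnzyme("PstI")), "TGCAG")
    expect_identical(enzymeRemnant(gbsEnzyme("MspI")), "CGG")
})

test_that("findSites matches hand-derived and oracle positions", {
    expect_identical(findSites("CCGG", gbsEnzyme("MspI")), 0L)
    expect_identical(findSites("GCTGCTGC", gbsEnzyme("ApeKI")),
                     iupacScanOracle("GCTGCTGC", "GCWGC"))
    expect_identical(findSites("GCTGCTGC", gbsEnzyme("ApeKI")), c(0L, 3L))
    expect_identical(findSites("AACTGCAGTTTCCGGAA", gbsEnzyme("PstI")), 2L)
    ## overlapping matches are all reported
    expect_identical(findSites("GCAGCAGC", gbsEnzyme("ApeKI")), c(0L, 3L))
})

test_that("N in the genome never matches and bad characters are rejected", {
    expect_identical(findSites("CCNG", gbsEnzyme("MspI")), integer(0))
    expect_identical(findSites("NNNNNN", gbsEnzyme("PstI")), integer(0))
    expect_error(findSites("ACGXACGT", gbsEnzyme("MspI")), "position 4")
})

test_that("scanner equals the naive IUPAC comparator on random sequences", {
    set.seed(101)
    enzymes <- lapply(c("ApeKI", "PstI", "MspI"), gbsEnzyme)
    for (r in 1:25) {
        seq <- randomDnaString(2000, withN = TRUE)
        for (e in enzymes)
            expect_identical(findSites(seq, e),
                             iupacScanOracle(seq, recognitionSite(e)))
    }
})

test_that("single digest cuts at site + offset and tiles the sequence", {
    fr <- digestSingle("AAAA", gbsEnzyme("ApeKI"))
    expect_equal(length(fr), 1L)
    expect_equal(as.character(fr$leftCut), "TERMINUS")
    expect_equal(as.character(fr$rightCut), "TERMINUS")

    fr <- digestSingle("GCAGCAAGCTGC", gbsEnzyme("ApeKI"))
    expect_equal(BiocGenerics::start(fr) - 1L, c(0L, 1L, 8L))
    expect_equal(BiocGenerics::end(fr), c(1L, 8L, 12L))
    expect_equal(sum(BiocGenerics::width(fr)), 12L)
    expect_equal(as.character(fr$leftCut[2]), "SINGLE")
})

test_that("double digest labels cuts by enzyme and flags coincidences", {
    fr <- digestDouble("AACTGCAGTTTCCGGAA", gbsEnzyme("PstI"),
                       gbsEnzyme("MspI"))
    expect_equal(BiocGenerics::start(fr) - 1L, c(0L, 7L, 12L))
    expect_equal(as.character(fr$leftCut), c("TERMINUS", "RARE", "COMMON"))
    expect_equal(as.character(fr$rightCut), c("RARE", "COMMON", "TERMINUS"))

    fr2 <- digestDouble("CCGGCCGG", gbsEnzyme("PstI"), gbsEnzyme("MspI"))
    expect_equal(BiocGenerics::start(fr2) - 1L, c(0L, 1L, 5L))
    expect_equal(fragmentClass(fr2)[2], "COMMON-COMMON")

    ## no common sites: degenerates to the rare single digest
    seq <- "AACTGCAGTTAACTGCAGTT"
    fr3 <- digestDouble(seq, gbsEnzyme("PstI"), gbsEnzyme("MspI"))
    fr4 <- digestSingle(seq, gbsEnzyme("PstI"))
    expect_equal(BiocGenerics::start(fr3), BiocGenerics::start(fr4))
    expect_true(all(fr3$leftCut != "COMMON"))

    ## same-coordinate cuts from the two enzymes are an error:
    ## AC^GT at position 2 and C^GTA at position 3 both cut coordinate 4
    e1 <- Enzyme("E1", "ACGT", 2L)
    e2 <- Enzyme("E2", "CGTA", 1L)
    expect_error(digestDouble("AAACGTAAA", e1, e2), "coincident")
})

test_that("fragments tile random sequences exactly", {
    set.seed(202)
    for (r in 1:20) {
        seq <- randomDnaString(sample(500:3000, 1))
        for (fr in list(digestSingle(seq, gbsEnzyme("ApeKI")),
                        digestDouble(seq, gbsEnzyme("PstI"),
                                     gbsEnzyme("MspI")))) {
            expect_equal(sum(BiocGenerics::width(fr)), nchar(seq))
            st <- BiocGenerics::start(fr); en <- BiocGenerics::end(fr)
            expect_true(all(st[-1] == en[-length(en)] + 1L))
            expect_equal(st[1], 1L)
            expect_equal(en[length(en)], nchar(seq))
        }
    }
})

test_that("palindromic scans are strand-complete", {
    set.seed(303)
    for (r in 1:10) {
        seq <- randomDnaString(1500)
        rcSeq <- as.character(Biostrings::reverseComplement(
            Biostrings::DNAString(seq)))
        for (nm in c("ApeKI", "PstI", "MspI")) {
            e <- gbsEnzyme(nm)
            fwd <- findSites(seq, e)
            rev <- findSites(rcSeq, e)
            m <- nchar(recognitionSite(e))
            expect_identical(sort(nchar(seq) - m - rev), sort(fwd))
        }
    }
})

test_that("adding a recognition site never decreases the fragment count", {
    set.seed(404)
    for (r in 1:10) {
        seq <- randomDnaString(800)
        n0 <- length(digestSingle(seq, gbsEnzyme("MspI")))
        at <- sample(100:700, 1)
        seq2 <- paste0(substr(seq, 1, at), "CCGG",
                       substr(seq, at + 1, nchar(seq)))
        n1 <- length(digestSingle(seq2, gbsEnzyme("MspI")))
        expect_gte(n1, n0)
    }
})

test_that("protocol comparison reports the relative fragment reduction", {
    set.seed(505)
    g <- makeGenome(length = 50000, nRareSites = 20, nCommonSites = 120,
                    seed = 42)
    cmp <- compareProtocols(g$genome, gbsEnzyme("ApeKI"),
                            gbsEnzyme("PstI"), gbsEnzyme("MspI"))
    expect_equal(cmp$reduction, 1 - cmp$twoCount / cmp$oneCount)
    expect_equal(cmp$twoSummary$totalLength, 50000)
    ## counts equal an independent naive re-scan
    seq <- as.character(g$genome[[1]])
    apeSites <- iupacScanOracle(seq, "GCWGC")
    apeCuts <- apeSites + 1L
    apeCuts <- sort(unique(apeCuts[apeCuts > 0 & apeCuts < nchar(seq)]))
    expect_equal(cmp$oneCount, max(0L, length(apeCuts) - 1L))
    rareCuts <- iupacScanOracle(seq, "CTGCAG") + 5L
    commonCuts <- iupacScanOracle(seq, "CCGG") + 1L
    cuts <- sort(c(rareCuts, commonCuts))
    lab <- cuts %in% rareCuts
    expect_equal(cmp$twoCount, sum(lab[-length(lab)] != lab[-1]))

    expect_error(compareProtocols(Biostrings::DNAStringSet(character()),
                                  gbsEnzyme("ApeKI"), gbsEnzyme("PstI"),
                                  gbsEnzyme("MspI")), "empty")
    ## no one-enzyme internal fragments -> division guard
    expect_error(compareProtocols("AACTGCAGTTTCCGGAA", gbsEnzyme("ApeKI"),
                                  gbsEnzyme("PstI"), gbsEnzyme("MspI")),
                 "no fragments")
})

test_that("fragment TSV output uses 0-based half-open coordinates", {
    fr <- digestDouble("AACTGCAGTTTCCGGAA", gbsEnzyme("PstI"),
                       gbsEnzyme("MspI"))
    f <- tempfile(fileext = ".tsv")
    writeFragmentsTSV(fr, f)
    tab <- read.delim(f)
    expect_equal(tab$start, c(0L, 7L, 12L))
    expect_equal(tab$end, c(7L, 12L, 17L))
    expect_equal(sum(tab$length), 17L)
})
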