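test_that("per-sample VCFs merge over the union of site keys", {
    f1 <- writeMinimalVcf(tempfile(fileext = ".vcf"), "A",
                          vcfRow("s1", 100, "A", "G", "0/1"))
    f2 <- writeMinimalVcf(tempfile(fileext = ".vcf"), "B",
                          vcfRow("s1", 200, "C", "T", "1/1"))
    gm <- mergeVcfs(c(f1, f2))
    expect_equal(dim(gm), c(2L, 2L))
    d <- dosage(gm)
    expect_equal(d[, "A"], c(1L, NA))
    expect_equal(d[, "B"], c(NA, 2L))
})

test_that("GT strings encode to dosages; same site aligns across samples", {
    f1 <- writeMinimalVcf(tempfile(fileext = ".vcf"), "A",
                          vcfRow("s1", 100, "A", "G", "0/1"))
    f2 <- writeMinimalVcf(tempfile(fileext = ".vcf"), "B",
                          vcfRow("s1", 100, "A", "G", "1/1"))
    gm <- mergeVcfs(c(f1, f2))
    expect_equal(dim(gm), c(1L, 2L))
    expect_equal(unname(dosage(gm)[1, ]), c(1L, 2L))
})

test_that("a five-sample engineered fixture merges to its truth table", {
    ## 20 sites across 2 scaffolds; each sample observes an overlapping
    ## subset, with planted dosages
    set.seed(55)
    sites <- data.frame(
        chrom = rep(c("sc1", "sc2"), each = 10),
        pos = rep(seq(100, 1000, by = 100), 2),
        ref = rep(c("A", "C", "G", "T"), 5),
        alt = rep(c("G", "T", "A", "C"), 5))
    truth <- matrix(NA_integer_, 20, 5,
                    dimnames = list(NULL, paste0("S", 1:5)))
    files <- character(5)
    gtOf <- c("0/0", "0/1", "1/1")
    for (j in 1:5) {
        idx <- sort(sample(20, 12))
        dos <- sample(0:2, 12, replace = TRUE)
        truth[idx, j] <- dos
        rows <- vapply(seq_along(idx), function(k)
            vcfRow(sites$chrom[idx[k]], sites$pos[idx[k]],
                   sites$ref[idx[k]], sites$alt[idx[k]],
                   gtOf[dos[k] + 1L]), "")
        files[j] <- writeMinimalVcf(tempfile(fileext = ".vcf"),
                                    paste0("S", j), rows)
    }
    gm <- mergeVcfs(files)
    ## union semantics: only sites observed by at least one sample appear
    seen <- rowSums(!is.na(truth)) > 0L
    ord <- order(sites$chrom, sites$pos)
    ordSeen <- ord[seen[ord]]
    expect_equal(siteKeys(gm)$pos, sites$pos[ordSeen])
    expect_equal(siteKeys(gm)$seqnames, sites$chrom[ordSeen])
    expect_equal(unname(dosage(gm)), unname(truth[ordSeen, ]))
})

test_that("multi-allelic records are dropped with counts; ref conflicts error", {
    f1 <- writeMinimalVcf(tempfile(fileext = ".vcf"), "A",
        c(vcfRow("s1", 100, "A", "G,T", "1/2"),
          vcfRow("s1", 200, "C", "T", "0/1"),
          vcfRow("s1", 300, "CA", "C", "1/1")))
    gm <- mergeVcfs(f1)
    expect_equal(nrow(gm), 1L)
    m <- S4Vectors::metadata(gm)$merge
    expect_equal(m$droppedMultiallelic, 1L)
    expect_equal(m$droppedIndel, 1L)

    f2 <- writeMinimalVcf(tempfile(fileext = ".vcf"), "B",
                          vcfRow("s1", 200, "G", "A", "0/1"))
    expect_error(mergeVcfs(c(f1, f2)), "conflicting reference")

    bad <- tempfile(fileext = ".vcf")
    writeLines("not a vcf at all", bad)
    expect_error(mergeVcfs(bad), "malformed VCF")
})

test_that("repeat masking uses BED half-open boundary semantics", {
    d <- matrix(0L, 3, 2, dimnames = list(NULL, c("A", "B")))
    sites <- GRanges("s1", IRanges::IRanges(c(100L, 150L, 300L), width = 1L),
                     ref = "A", alt = "G")
    gm <- GenotypeMatrix(d, sites)
    ## BED [99,100) covers 0-based 99 = VCF pos 100; BED [100,200) does not
    bedA <- GRanges("s1", IRanges::IRanges(100L, 100L))   # bed 99..100
    gmA <- maskRepeats(gm, bedA)
    expect_equal(siteKeys(gmA)$pos, c(150L, 300L))
    bed <- tempfile(fileext = ".bed")
    writeLines("s1\t100\t200", bed)                        # pos 101..200
    gmB <- maskRepeats(gm, bed)
    expect_equal(siteKeys(gmB)$pos, c(100L, 300L))
    acc <- filterAccounting(gmB)
    expect_equal(acc$sitesIn - acc$sitesRemoved, acc$sitesOut)
})

test_that("random masks match a naive per-site interval scan", {
    set.seed(66)
    for (r in 1:5) {
        gm <- randomGenotypeMatrix(80, 10)
        m <- GRanges(sample(c("sc1", "sc2"), 15, TRUE),
                     IRanges::IRanges(sample.int(5000, 15),
                                      width = sample(50:500, 15, TRUE)))
        gmM <- maskRepeats(gm, m)
        keep <- bruteMaskKeep(gm, m)
        expect_equal(siteKeys(gmM), siteKeys(gm)[keep, ],
                     ignore_attr = TRUE)
    }
})

test_that("missingness thresholds are strictly greater-than", {
    d <- matrix(0L, 10, 10, dimnames = list(NULL, paste0("S", 1:10)))
    d[1, 1:2] <- NA   # 0.20 missing: retained (not > 0.20)
    d[2, 1:3] <- NA   # 0.30 missing: removed
    gm <- GenotypeMatrix(d, GRanges("s1",
        IRanges::IRanges(seq(10L, 100L, by = 10L), width = 1L),
        ref = "A", alt = "G"))
    out <- filterMissing(gm)
    expect_equal(nrow(out), 9L)
    expect_false(20L %in% siteKeys(out)$pos)
    ## samples 1-2 carry 1 NA over the 9 remaining sites (0.11): kept
    expect_equal(ncol(out), 10L)
    allNA <- GenotypeMatrix(
        matrix(NA_integer_, 2, 3, dimnames = list(NULL, c("A", "B", "C"))),
        GRanges("s1", IRanges::IRanges(c(1L, 2L), width = 1L),
                ref = "A", alt = "G"))
    expect_error(filterMissing(allNA), "maxSiteMissing")
})

test_that("MAF uses called samples only and keeps the exact boundary", {
    ## 8 called samples, dosage sum 3 -> p = 0.1875
    d <- matrix(c(1L, 1L, 1L, 0L, 0L, 0L, 0L, 0L, NA, NA), 1)
    colnames(d) <- paste0("S", 1:10)
    gm <- GenotypeMatrix(d, GRanges("s1", IRanges::IRanges(5L, width = 1L),
                                    ref = "A", alt = "G"))
    expect_equal(nrow(filterMAF(gm, 0.10)), 1L)
    expect_equal(nrow(filterMAF(gm, 0.19)), 0L)
    ## boundary: maf exactly 0.10 is retained
    d2 <- matrix(c(1L, 1L, rep(0L, 8L)), 1,
                 dimnames = list(NULL, paste0("S", 1:10)))
    gm2 <- GenotypeMatrix(d2, GRanges("s1", IRanges::IRanges(5L, width = 1L),
                                      ref = "A", alt = "G"))
    expect_equal(nrow(filterMAF(gm2, 0.10)), 1L)
    ## monomorphic site removed
    d3 <- matrix(0L, 1, 10, dimnames = list(NULL, paste0("S", 1:10)))
    gm3 <- GenotypeMatrix(d3, GRanges("s1", IRanges::IRanges(5L, width = 1L),
                                      ref = "A", alt = "G"))
    expect_equal(nrow(filterMAF(gm3, 0.10)), 0L)
})

test_that("LD pruning removes duplicated columns and keeps orthogonal ones", {
    set.seed(88)
    base <- sample(0:2, 30, replace = TRUE)
    orth <- rep(c(0L, 2L), 15)
    d <- rbind(base, base, orth)
    colnames(d) <- paste0("S", 1:30)
    gm <- GenotypeMatrix(d, GRanges("s1",
        IRanges::IRanges(c(10L, 20L, 30L), width = 1L),
        ref = "A", alt = "G"))
    out <- ldPrune(gm)
    expect_equal(siteKeys(out)$pos, c(10L, 30L))
})

test_that("all filters equal brute-force recomputation on random matrices", {
    set.seed(99)
    for (r in 1:3) {
        gm <- randomGenotypeMatrix(200, 100)
        mm <- bruteMissingKeep(gm)
        out <- filterMissing(gm)
        expect_equal(nrow(out), sum(mm$sites))
        expect_equal(colnames(out), colnames(gm)[mm$samples])
        out2 <- filterMAF(gm)
        expect_equal(nrow(out2), sum(bruteMafKeep(gm)))
        out3 <- ldPrune(gm, windowSites = 10L)
        expect_equal(ldPostHocViolations(out3, windowSites = 10L), 0L)
    }
})

test_that("accounting identity holds and every filter is idempotent", {
    set.seed(111)
    gm <- randomGenotypeMatrix(150, 60, missingRate = 0.12)
    out <- filterCascade(gm)
    acc <- filterAccounting(out)
    expect_equal(acc$stage, c("missing", "maf", "ld_prune"))
    expect_true(all(acc$sitesIn - acc$sitesRemoved == acc$sitesOut))
    expect_equal(acc$sitesIn[-1], acc$sitesOut[-nrow(acc)])
    expect_equal(acc$sitesIn[1], 150L)
    ## idempotence on each filter's own output
    expect_equal(nrow(filterMissing(out)), nrow(out))
    expect_equal(ncol(filterMissing(out)), ncol(out))
    expect_equal(nrow(filterMAF(out)), nrow(out))
    expect_equal(nrow(ldPrune(out)), nrow(out))
})

test_that("heterozygosity accounting matches hand arithmetic", {
    set.seed(123)
    d <- matrix(rep(c(0L, 2L), length.out = 9 * 20), 9, 20)
    d[1, 1] <- 1L           # one het
    d[2, 1:5] <- NA         # 175 called cells
    colnames(d) <- paste0("S", 1:20)
    gm <- GenotypeMatrix(d, GRanges("s1",
        IRanges::IRanges(seq(10L, 90L, by = 10L), width = 1L),
        ref = "A", alt = "G"))
    hr <- hetRate(gm)
    expect_equal(hr$overall, 1 / 175)
    called <- colSums(!is.na(d))
    expect_equal(unname(sum(hr$perSample * called) / sum(called)),
                 hr$overall)
    allHom <- GenotypeMatrix(
        matrix(0L, 2, 3, dimnames = list(NULL, c("A", "B", "C"))),
        GRanges("s1", IRanges::IRanges(c(1L, 2L), width = 1L),
                ref = "A", alt = "G"))
    expect_equal(hetRate(allHom)$overall, 0)
})
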