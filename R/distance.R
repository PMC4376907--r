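## Allele-sharing genetic distances from dosage matrices.

#' Pairwise genetic distance matrix
#'
#' Symmetric allele-sharing distances between samples, with the number of
#' shared (pairwise-complete) sites each estimate is based on.
#'
#' @slot distance symmetric numeric matrix in `[0, 1]`, zero diagonal,
#'   dimnames = sample ids.
#' @slot sharedSites integer matrix of pairwise-complete site counts.
#' @export
setClass("GenotypeDistance",
    representation(distance = "matrix", sharedSites = "matrix"))

setValidity("GenotypeDistance", function(object) {
    d <- object@distance
    msg <- character()
    if (!isSymmetric(unname(d), tol = 1e-12))
        msg <- c(msg, "distance matrix must be symmetric")
    if (any(abs(diag(d)) > 1e-12))
        msg <- c(msg, "diagonal must be zero")
    if (any(d < -1e-12 | d > 1 + 1e-12, na.rm = TRUE))
        msg <- c(msg, "allele-sharing distances must lie in [0, 1]")
    if (is.null(rownames(d)))
        msg <- c(msg, "sample ids required as dimnames")
    if (length(msg)) msg else TRUE
})

setMethod("show", "GenotypeDistance", function(object) {
    cat("GenotypeDistance:", nrow(object@distance), "samples; mean distance",
        sprintf("%.4f", mean(object@distance[upper.tri(object@distance)])),
        "\n")
})

#' @describeIn GenotypeDistance distance matrix as a base matrix.
#' @param x a `GenotypeDistance`.
#' @export
distanceMatrix <- function(x) x@distance

#' @describeIn GenotypeDistance pairwise shared-site counts.
#' @export
sharedSites <- function(x) x@sharedSites

setOldClass("dist")
setAs("GenotypeDistance", "dist", function(from) stats::as.dist(from@distance))

## Fast allele-sharing distance on a sites x samples dosage matrix.
## d(i,j) = mean over pairwise-complete sites of |d_i - d_j| / 2.
## Dosages take values in {0,1,2}, so the L1 numerator decomposes into
## cross-tabulations of dosage-level indicator matrices.
.dosageDist <- function(d, zeroSharedAs = NA_real_) {
    i0 <- !is.na(d) & d == 0L; i1 <- !is.na(d) & d == 1L
    i2 <- !is.na(d) & d == 2L
    mode(i0) <- "numeric"; mode(i1) <- "numeric"; mode(i2) <- "numeric"
    shared <- crossprod(!is.na(d) + 0)
    n01 <- crossprod(i0, i1); n02 <- crossprod(i0, i2)
    n12 <- crossprod(i1, i2)
    num <- (n01 + t(n01)) + 2 * (n02 + t(n02)) + (n12 + t(n12))
    dist <- num / (2 * shared)
    dist[shared == 0] <- zeroSharedAs
    diag(dist) <- 0
    dimnames(dist) <- list(colnames(d), colnames(d))
    list(distance = dist, shared = matrix(as.integer(shared), nrow(shared),
                                          dimnames = dimnames(dist)))
}

#' Allele-sharing distance between samples
#'
#' For each sample pair the distance is the mean, over sites called in
#' both, of `|dosage_i - dosage_j| / 2` — 0 for identical genotypes, 1
#' for opposite homozygotes at every shared site. Computed on
#' pairwise-complete sites so unfiltered matrices with missing data can
#' be used directly.
#'
#' @param gm a [GenotypeMatrix] (or a sites x samples dosage matrix) with
#'   at least two samples.
#' @param minSharedSites minimum pairwise-complete sites per pair; pairs
#'   below this raise an error naming them.
#' @return a [GenotypeDistance].
#' @export
pairwiseDistance <- function(gm, minSharedSites = 1L) {
    d <- if (is(gm, "GenotypeMatrix")) dosage(gm) else gm
    stopifnot(is.matrix(d), ncol(d) >= 2L)
    if (is.null(colnames(d))) colnames(d) <- paste0("S", seq_len(ncol(d)))
    noCalls <- colSums(!is.na(d)) == 0L
    if (any(noCalls))
        stop("sample(s) with zero called sites: ",
             paste(colnames(d)[noCalls], collapse = ", "))
    res <- .dosageDist(d)
    low <- which(res$shared < minSharedSites & upper.tri(res$shared),
                 arr.ind = TRUE)
    if (nrow(low))
        stop("pair(s) with fewer than ", minSharedSites, " shared sites: ",
             paste(sprintf("%s-%s", rownames(res$shared)[low[, 1]],
                           colnames(res$shared)[low[, 2]]), collapse = ", "))
    new("GenotypeDistance", distance = res$distance,
        sharedSites = res$shared)
}

#' Write a PHYLIP square distance matrix
#'
#' @param x a [GenotypeDistance] or square matrix with dimnames.
#' @param file output path.
#' @export
writePhylipDist <- function(x, file) {
    d <- if (is(x, "GenotypeDistance")) x@distance else x
    con <- file(file, "w")
    on.exit(close(con))
    writeLines(sprintf("%5d", nrow(d)), con)
    for (i in seq_len(nrow(d)))
        writeLines(paste(formatC(rownames(d)[i], width = -10),
                         paste(sprintf("%.6f", d[i, ]), collapse = " ")),
                   con)
    invisible(file)
}

#' Read a PHYLIP square distance matrix
#'
#' @param file path to a square-format PHYLIP distance matrix.
#' @return a [GenotypeDistance] (shared-site counts unknown, set to 0).
#' @export
readPhylipDist <- function(file) {
    lines <- readLines(file)
    n <- as.integer(trimws(lines[1]))
    parts <- strsplit(trimws(lines[1 + seq_len(n)]), "[[:space:]]+")
    ids <- vapply(parts, `[[`, "", 1L)
    d <- t(vapply(parts, function(p) as.numeric(p[-1]), numeric(n)))
    dimnames(d) <- list(ids, ids)
    new("GenotypeDistance", distance = d,
        sharedSites = matrix(0L, n, n, dimnames = dimnames(d)))
}
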