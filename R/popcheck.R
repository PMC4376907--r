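## Downstream population checks: Evanno delta-K over external clustering
## log-likelihoods, and the replicate/taxon authenticity audit.

#' Evanno delta-K
#'
#' Given replicate log-likelihoods `L(K)` from an external clustering
#' program run over a contiguous range of K, computes the Evanno
#' statistics: the first-order rate of change
#' `L'(K) = mean L(K) - mean L(K-1)`, the absolute second-order rate
#' `|L''(K)| = |L'(K+1) - L'(K)|`, and
#' `deltaK = |L''(K)| / sd(L(K))`. The best K is the interior K
#' maximising deltaK. A zero standard deviation yields an infinite
#' deltaK with a warning.
#'
#' @param x data.frame with columns `K` (integer) and `logL` (one row per
#'   replicate run; a `replicate` column is allowed and ignored). At least
#'   4 consecutive K values and 2 replicates per K are required.
#' @return list with `bestK` and `table` (K, nReplicates, meanL, sdL,
#'   dL, absD2L, deltaK).
#' @examples
#' ll <- expand.grid(K = 1:4, replicate = 1:2)
#' ll$logL <- c(-500, -300, -290, -288)[ll$K] + c(-1, 1)[ll$replicate]
#' deltaK(ll)$bestK
#' @export
deltaK <- function(x) {
    stopifnot(is.data.frame(x), all(c("K", "logL") %in% names(x)))
    ks <- sort(unique(x$K))
    if (length(ks) < 4L)
        stop("need at least 4 K values")
    if (!all(diff(ks) == 1L))
        stop("K values must be contiguous: got ",
             paste(ks, collapse = ", "))
    grp <- split(x$logL, factor(x$K, levels = ks))
    nRep <- vapply(grp, length, integer(1))
    if (any(nRep < 2L))
        stop("at least 2 replicates per K required for sd(L(K))")
    meanL <- vapply(grp, mean, numeric(1))
    sdL <- vapply(grp, sd, numeric(1))
    nk <- length(ks)
    dL <- c(NA, diff(meanL))                      # L'(K), defined for K >= 2
    absD2L <- rep(NA_real_, nk)
    absD2L[2:(nk - 1)] <- abs(dL[3:nk] - dL[2:(nk - 1)])
    dk <- absD2L / sdL
    if (any(sdL == 0 & !is.na(absD2L))) {
        warning("sd(L(K)) is zero for some K; deltaK reported as Inf")
        dk[sdL == 0 & !is.na(absD2L) & absD2L > 0] <- Inf
        dk[sdL == 0 & !is.na(absD2L) & absD2L == 0] <- NaN
    }
    tab <- data.frame(K = ks, nReplicates = nRep, meanL = meanL, sdL = sdL,
                      dL = dL, absD2L = absD2L, deltaK = dk,
                      row.names = NULL)
    best <- tab$K[which.max(ifelse(is.na(tab$deltaK), -Inf, tab$deltaK))]
    list(bestK = best, table = tab)
}

#' Simulate clustering log-likelihood curves with a knee
#'
#' Generates replicate `L(K)` values that increase steeply up to a planted
#' number of clusters `trueK` and nearly plateau beyond it — the shape a
#' model-based clustering program produces when the data contain `trueK`
#' populations. Used to exercise [deltaK].
#'
#' @param kRange integer range of K (contiguous).
#' @param trueK the planted knee; must be interior to `kRange`.
#' @param replicates replicate runs per K.
#' @param rise mean log-likelihood gain per K below the knee.
#' @param plateau mean gain per K above the knee.
#' @param noiseSd replicate-to-replicate standard deviation.
#' @param seed optional integer seed.
#' @return data.frame with columns `K`, `replicate`, `logL`.
#' @export
simulateLogLikelihoods <- function(kRange = 1:10, trueK = 3L,
                                   replicates = 5L, rise = 300,
                                   plateau = 10, noiseSd = 5,
                                   seed = NULL) {
    stopifnot(trueK > min(kRange), trueK < max(kRange))
    if (!is.null(seed)) set.seed(seed)
    base <- -5000 + rise * pmin(kRange, trueK) +
        plateau * pmax(0, kRange - trueK)
    out <- expand.grid(K = kRange, replicate = seq_len(replicates))
    out$logL <- base[match(out$K, kRange)] +
        stats::rnorm(nrow(out), sd = noiseSd)
    out
}

#' Replicate and taxon authenticity audit
#'
#' Operationalises the clade-membership check used to vet germplasm
#' collections: each sample's `kNeighbors` nearest neighbours (by genetic
#' distance, excluding itself) vote a taxon by majority; a sample whose
#' voted taxon differs from its recorded taxon is flagged
#' `MISCLASSIFIED`. Independently, a sample with another replicate of the
#' same accession in the data is flagged `REPLICATE_DISCORDANT` when its
#' nearest neighbour of its own recorded taxon is not one of its
#' replicates. Neighbour-distance ties are broken by sample id and noted.
#'
#' @param dist a [GenotypeDistance] (or symmetric matrix with sample
#'   dimnames).
#' @param meta data.frame with columns `sample_id`, `accession`, `taxon`
#'   (optional `replicate`, `run`), covering exactly the samples in
#'   `dist`.
#' @param kNeighbors how many nearest neighbours vote (default 1; use a
#'   value close to the expected group size for robustness to multiple
#'   mislabels).
#' @return list with `audit` (per-sample data.frame), `nMisclassified`,
#'   `fractionMisclassified` and `fractionFlagged` (either flag).
#' @export
checkReplicates <- function(dist, meta, kNeighbors = 1L) {
    d <- .asDistanceMatrix(dist)
    stopifnot(is.data.frame(meta),
              all(c("sample_id", "accession", "taxon") %in% names(meta)))
    ids <- rownames(d)
    if (!setequal(ids, meta$sample_id) ||
        anyDuplicated(meta$sample_id))
        stop("metadata must cover the distance matrix sample set exactly")
    n <- length(ids)
    if (kNeighbors >= n)
        stop("kNeighbors must be smaller than the number of samples")
    meta <- meta[match(ids, meta$sample_id), , drop = FALSE]

    voted <- character(n); nn <- character(n); nnDist <- numeric(n)
    misc <- logical(n); discord <- logical(n); ties <- 0L
    for (i in seq_len(n)) {
        others <- setdiff(seq_len(n), i)
        ord <- others[order(d[i, others], ids[others])]
        kd <- d[i, ord[seq_len(kNeighbors)]]
        if (kNeighbors < length(ord) &&
            d[i, ord[kNeighbors + 1L]] == kd[kNeighbors]) ties <- ties + 1L
        nn[i] <- ids[ord[1L]]
        nnDist[i] <- d[i, ord[1L]]
        kTaxa <- meta$taxon[ord[seq_len(kNeighbors)]]
        counts <- table(kTaxa)
        top <- names(counts)[counts == max(counts)]
        voted[i] <- if (length(top) == 1L) top else
            kTaxa[which(kTaxa %in% top)[1L]]   # nearest among tied taxa
        misc[i] <- voted[i] != meta$taxon[i]
        sameAcc <- meta$accession == meta$accession[i] & seq_len(n) != i
        if (any(sameAcc)) {
            sameTaxon <- ord[meta$taxon[ord] == meta$taxon[i]]
            if (length(sameTaxon))
                discord[i] <- !sameAcc[sameTaxon[1L]]
        }
    }
    if (ties > 0L)
        message(ties, " sample(s) had neighbour-distance ties broken by id")
    audit <- data.frame(
        sample_id = ids, accession = meta$accession, taxon = meta$taxon,
        votedTaxon = voted, nearestNeighbor = nn, nnDistance = nnDist,
        misclassified = misc, replicateDiscordant = discord,
        stringsAsFactors = FALSE)
    list(audit = audit, nMisclassified = sum(misc),
         fractionMisclassified = mean(misc),
         fractionFlagged = mean(misc | discord))
}
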