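## Column-resampling bootstrap support for neighbour-joining trees.

#' Bootstrap support for the NJ tree of a genotype matrix
#'
#' Builds the neighbour-joining tree from all sites, then resamples site
#' columns with replacement `replicates` times, recomputing the
#' allele-sharing distance and NJ tree for each replicate, and maps
#' bipartition frequencies (as percentages) onto the internal edges of
#' the full-data tree. Replicate pairs that happen to share no called
#' sites are assigned the maximum distance 1 (counted in
#' `attr(tree, "zeroSharedPairs")`).
#'
#' @param gm a [GenotypeMatrix] (or sites x samples dosage matrix) with
#'   at least 2 sites and 3 samples.
#' @param replicates number of bootstrap replicates (>= 1); 1000 is the
#'   conventional choice.
#' @param seed optional integer; set for reproducible resampling.
#' @return the full-data `phylo` tree with `node.label` holding support
#'   percentages in `[0, 100]` (`NA` for the root of the unrooted tree).
#' @export
bootstrapSupport <- function(gm, replicates = 1000L, seed = NULL) {
    d <- if (is(gm, "GenotypeMatrix")) dosage(gm) else gm
    stopifnot(is.matrix(d), replicates >= 1L)
    if (nrow(d) < 2L)
        stop("bootstrap needs at least 2 sites")
    if (is.null(colnames(d))) colnames(d) <- paste0("S", seq_len(ncol(d)))
    if (!is.null(seed)) set.seed(seed)

    full <- njTree(pairwiseDistance(d))
    nSites <- nrow(d)
    zeroShared <- 0L
    reps <- vector("list", replicates)
    for (b in seq_len(replicates)) {
        idx <- sample.int(nSites, nSites, replace = TRUE)
        res <- .dosageDist(d[idx, , drop = FALSE], zeroSharedAs = 1)
        zeroShared <- zeroShared + sum(res$shared == 0 &
                                       upper.tri(res$shared))
        reps[[b]] <- njTree(res$distance)
    }
    counts <- ape::prop.clades(full, reps, rooted = FALSE)
    support <- 100 * counts / replicates
    support[is.na(counts)] <- 0
    ## the basal node of the stored unrooted tree is not a bipartition
    support[1] <- NA
    full$node.label <- support
    attr(full, "zeroSharedPairs") <- zeroShared
    full
}

#' Write a tree in Newick format
#'
#' Branch lengths are written in full precision; bootstrap support values
#' (if present) appear as internal node labels.
#'
#' @param tree an `ape::phylo` tree.
#' @param file output path.
#' @export
writeNewick <- function(tree, file) {
    if (!is.null(tree$node.label))
        tree$node.label <- ifelse(is.na(tree$node.label), "",
                                  format(tree$node.label, trim = TRUE))
    ape::write.tree(tree, file = file)
    invisible(file)
}
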