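## Neighbour-joining (Saitou & Nei, Studier-Keppler Q-criterion) with
## deterministic tie-breaking, emitting ape "phylo" trees.

.asDistanceMatrix <- function(x) {
    if (is(x, "GenotypeDistance")) return(x@distance)
    if (inherits(x, "dist")) return(as.matrix(x))
    if (is.matrix(x)) return(x)
    stop("cannot interpret input as a distance matrix")
}

#' Neighbour-joining tree
#'
#' Classic agglomerative neighbour joining on a pairwise distance matrix:
#' at each step the pair minimising the Studier-Keppler criterion
#' `Q(i,j) = (n-2) d(i,j) - r_i - r_j` is joined, with ties broken
#' deterministically in favour of the lowest index pair (in current input
#' order). On an additive distance matrix the generating topology and
#' branch lengths are recovered exactly. Negative branch-length estimates
#' are clamped to zero for output, with the originals kept in
#' `attr(tree, "clampedEdges")`.
#'
#' @param x a [GenotypeDistance], `dist`, or symmetric numeric matrix with
#'   dimnames; at least 3 samples.
#' @return an unrooted `ape::phylo` tree.
#' @examples
#' d <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
#'             dimnames = list(LETTERS[1:3], LETTERS[1:3]))
#' njTree(d)$edge.length  # 1, 2, 3
#' @export
njTree <- function(x) {
    d <- .asDistanceMatrix(x)
    n <- nrow(d)
    if (n < 3L) stop("neighbour joining needs at least 3 samples")
    if (!isSymmetric(unname(d), tol = 1e-8))
        stop("distance matrix must be symmetric")
    if (any(d < 0)) stop("distance matrix must be non-negative")
    labels <- rownames(d)
    if (is.null(labels)) labels <- paste0("S", seq_len(n))

    clamped <- list()
    fmt <- function(len, from, to) {
        if (len < 0) {
            clamped[[length(clamped) + 1L]] <<- c(from = from, to = to,
                                                  length = len)
            len <- 0
        }
        sprintf("%.17g", len)
    }
    nodes <- labels          # newick fragment per active node
    nodeIds <- labels        # provenance for clamp logging
    active <- d

    while (nrow(active) > 3L) {
        m <- nrow(active)
        r <- rowSums(active)
        q <- (m - 2) * active - outer(r, r, `+`)
        diag(q) <- Inf
        q[lower.tri(q)] <- Inf
        best <- which(q == min(q), arr.ind = TRUE)
        best <- best[order(best[, 1], best[, 2]), , drop = FALSE][1, ]
        i <- best[1]; j <- best[2]
        li <- active[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
        lj <- active[i, j] - li
        newick <- sprintf("(%s:%s,%s:%s)",
                          nodes[i], fmt(li, nodeIds[i], "joined"),
                          nodes[j], fmt(lj, nodeIds[j], "joined"))
        dNew <- (active[i, ] + active[j, ] - active[i, j]) / 2
        keep <- setdiff(seq_len(m), c(i, j))
        active <- rbind(cbind(active[keep, keep, drop = FALSE],
                              dNew[keep]),
                        c(dNew[keep], 0))
        nodes <- c(nodes[keep], newick)
        nodeIds <- c(nodeIds[keep], "internal")
        dimnames(active) <- NULL
    }
    ## final three active nodes join at an unrooted central trifurcation
    a <- (active[1, 2] + active[1, 3] - active[2, 3]) / 2
    b <- (active[1, 2] + active[2, 3] - active[1, 3]) / 2
    c3 <- (active[1, 3] + active[2, 3] - active[1, 2]) / 2
    newick <- sprintf("(%s:%s,%s:%s,%s:%s);",
                      nodes[1], fmt(a, nodeIds[1], "center"),
                      nodes[2], fmt(b, nodeIds[2], "center"),
                      nodes[3], fmt(c3, nodeIds[3], "center"))
    tree <- ape::read.tree(text = newick)
    attr(tree, "clampedEdges") <- clamped
    tree
}
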