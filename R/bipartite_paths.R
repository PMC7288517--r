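# Graph helpers: adjacency list (sorted neighbour names) and the unweighted
# distance matrix. Vertices are ordered by name so lexicographic tie-breaks
# reduce to taking the alphabetically smallest candidate.
graphIndex <- function(network) {
    g <- if (inherits(network, "DifferentialNetwork")) asIgraph(network)
         else network
    nodes <- sort(igraph::V(g)$name)
    adj <- lapply(igraph::adjacent_vertices(g, nodes), function(v)
        sort(v$name))
    names(adj) <- nodes
    D <- igraph::distances(g, v = nodes, to = nodes)
    list(nodes = nodes, adj = adj, D = D)
}

# Deterministic shortest path from `a` to `p` over a graphIndex: among all
# equal-length shortest paths, the lexicographically smallest node sequence.
# NULL when unconnected.
lexShortestPath <- function(gi, a, p) {
    d <- gi$D[a, p]
    if (!is.finite(d)) return(NULL)
    path <- character(d + 1)
    path[1] <- a
    cur <- a
    i <- 1L
    while (d > 0) {
        nb <- gi$adj[[cur]]
        cand <- nb[gi$D[nb, p] == d - 1]
        cur <- cand[1L]          # neighbours pre-sorted: lexicographic min
        i <- i + 1L
        path[i] <- cur
        d <- d - 1
    }
    path
}

#' Shortest paths from every aging marker to every PD marker
#'
#' Enumerates all (aging marker, PD marker) candidate pairs and computes,
#' for each connected pair, one deterministic shortest path on the
#' (unweighted) network: among all equal-length shortest paths the
#' lexicographically smallest node sequence is chosen, so results are
#' reproducible. Unconnected pairs keep an absent path. Markers missing
#' from the network are reported in a warning and skipped.
#'
#' @param network a [DifferentialNetwork] or named [igraph::igraph].
#' @param agingMarkers,pdMarkers character marker sets (disjoint).
#' @return data.frame with columns `aging`, `pd`, `length` (NA when
#'   unconnected) and a list column `path` (character node sequences).
#' @export
shortestMarkerPaths <- function(network, agingMarkers, pdMarkers) {
    agingMarkers <- unique(as.character(agingMarkers))
    pdMarkers <- unique(as.character(pdMarkers))
    clash <- intersect(agingMarkers, pdMarkers)
    if (length(clash))
        stop("gene(s) in both marker sets: ", paste(clash, collapse = ", "))
    gi <- graphIndex(network)
    dropA <- setdiff(agingMarkers, gi$nodes)
    dropP <- setdiff(pdMarkers, gi$nodes)
    if (length(dropA) || length(dropP))
        warning("marker(s) absent from the network skipped: ",
                paste(c(dropA, dropP), collapse = ", "))
    agingMarkers <- sort(intersect(agingMarkers, gi$nodes))
    pdMarkers <- sort(intersect(pdMarkers, gi$nodes))
    pairs <- expand.grid(aging = agingMarkers, pd = pdMarkers,
                         stringsAsFactors = FALSE,
                         KEEP.OUT.ATTRS = FALSE)
    paths <- vector("list", nrow(pairs))
    len <- rep(NA_real_, nrow(pairs))
    for (i in seq_len(nrow(pairs))) {
        pt <- lexShortestPath(gi, pairs$aging[i], pairs$pd[i])
        if (!is.null(pt)) {
            paths[[i]] <- pt
            len[i] <- length(pt) - 1
        }
    }
    out <- data.frame(aging = pairs$aging, pd = pairs$pd, length = len,
                      stringsAsFactors = FALSE)
    out$path <- paths
    out
}

#' Retain marker pairs whose correlations flip sign between groups
#'
#' A pair is kept when `r_control * r_pd < 0` (strictly opposite signs; a
#' zero coefficient never qualifies). The signed difference
#' `diff = r_control - r_pd` and its absolute value are recorded, and the
#' retained pair with the maximum `|diff|` is flagged.
#'
#' @param pairs data.frame with columns `aging`, `pd` (from
#'   [shortestMarkerPaths()] or constructed directly).
#' @param rControl,rPd square correlation matrices (gene x gene) from which
#'   the per-pair coefficients are looked up.
#' @return The input rows annotated with `r_control`, `r_pd`, `diff`,
#'   `abs_diff`, `opposite_sign`, restricted to retained pairs, with a
#'   logical `is_max_abs_diff` column.
#' @export
retainOppositeSignPairs <- function(pairs, rControl, rPd) {
    ij <- cbind(pairs$aging, pairs$pd)
    pairs$r_control <- rControl[ij]
    pairs$r_pd <- rPd[ij]
    pairs$diff <- pairs$r_control - pairs$r_pd
    pairs$abs_diff <- abs(pairs$diff)
    pairs$opposite_sign <- pairs$r_control * pairs$r_pd < 0
    out <- pairs[pairs$opposite_sign, , drop = FALSE]
    out$is_max_abs_diff <- if (nrow(out))
        out$abs_diff >= max(out$abs_diff) - 1e-15 else logical()
    rownames(out) <- NULL
    out
}

#' Linkage scores between marker families
#'
#' For every aging marker, the sum of `|diff|` over the retained pairs it
#' appears in (and symmetrically for every PD marker). The marker(s) with
#' the largest sum on each side are reported; ties are all reported, sorted
#' lexicographically.
#'
#' @param retained retained pair table from [retainOppositeSignPairs()].
#' @return list with data.frames `aging` and `pd` (`marker`,
#'   `linkage`, sorted by decreasing linkage then marker id) and character
#'   vectors `top_aging`, `top_pd`.
#' @export
markerLinkageScores <- function(retained) {
    sumBy <- function(key) {
        if (!nrow(retained))
            return(data.frame(marker = character(), linkage = numeric()))
        s <- tapply(retained$abs_diff, retained[[key]], sum)
        df <- data.frame(marker = names(s), linkage = as.numeric(s),
                         stringsAsFactors = FALSE)
        df[order(-df$linkage, df$marker), , drop = FALSE]
    }
    ag <- sumBy("aging")
    pd <- sumBy("pd")
    rownames(ag) <- rownames(pd) <- NULL
    pick <- function(df) if (nrow(df))
        sort(df$marker[df$linkage >= max(df$linkage) - 1e-15]) else character()
    list(aging = ag, pd = pd, top_aging = pick(ag), top_pd = pick(pd))
}

# Interior-node counts over a list of paths, tabulated for `nodes`.
interiorCounts <- function(paths, nodes) {
    counts <- setNames(integer(length(nodes)), nodes)
    for (pt in paths) {
        if (is.null(pt) || length(pt) < 3) next
        inner <- pt[-c(1L, length(pt))]
        counts[inner] <- counts[inner] + 1L
    }
    counts
}

#' Path betweenness of network genes
#'
#' For each gene, the number of marker-pair shortest paths in which it
#' appears as an interior node (path endpoints never count). Sorted by
#' decreasing betweenness, ties broken lexicographically.
#'
#' @param pairs path table from [shortestMarkerPaths()] (rows with absent
#'   paths contribute nothing).
#' @param nodes optional gene universe; defaults to all genes seen on paths.
#' @return data.frame with columns `gene`, `betweenness`.
#' @export
pathBetweenness <- function(pairs, nodes = NULL) {
    if (is.null(nodes))
        nodes <- sort(unique(unlist(pairs$path)))
    counts <- interiorCounts(pairs$path, nodes)
    df <- data.frame(gene = names(counts),
                     betweenness = as.integer(counts),
                     stringsAsFactors = FALSE)
    df <- df[order(-df$betweenness, df$gene), , drop = FALSE]
    rownames(df) <- NULL
    df
}

#' Permutation null for path betweenness
#'
#' Repeatedly draws disjoint random aging/PD marker sets of the observed
#' sizes from the network's nodes, recomputes the deterministic shortest
#' paths and the betweenness of each observed top gene, and reports
#' `p = (# reps with permuted betweenness >= observed) / reps`.
#'
#' Two alternative estimators are available. `"smoothed"` reports
#' `(count + 1) / (reps + 1)`, which can never be exactly 0. `"randomized"`
#' reports the randomized tie-broken p-value
#' `(#\{perm > obs\} + U * (#\{perm = obs\} + 1)) / (reps + 1)` with
#' `U ~ Uniform(0, 1)`: because path betweenness is a discrete statistic
#' with heavy ties (many genes sit on no path at all), the plain proportion
#' is super-uniform under the null; the randomized estimator is exactly
#' uniform under exchangeability and is the appropriate choice for
#' calibration checks of the permutation machinery.
#'
#' @param network a [DifferentialNetwork] or named [igraph::igraph].
#' @param nAging,nPd sizes of the random marker sets.
#' @param observed data.frame with columns `gene`, `betweenness` (e.g. the
#'   head of [pathBetweenness()]'s output). Genes absent from the network
#'   have permuted betweenness 0 and hence p = 1 unless their observed
#'   betweenness is positive, in which case p = 0 smoothing aside.
#' @param reps permutation replicates (default 1000).
#' @param seed RNG seed.
#' @param estimator `"proportion"` (default), `"smoothed"` or
#'   `"randomized"`.
#' @return `observed` with an added `perm_p` column; attributes `reps` and
#'   `seed`.
#' @export
betweennessPermutationTest <- function(network, nAging, nPd, observed,
                                       reps = 1000L, seed = 1L,
                                       estimator = c("proportion",
                                                     "smoothed",
                                                     "randomized")) {
    estimator <- match.arg(estimator)
    gi <- graphIndex(network)
    nAging <- as.integer(nAging)
    nPd <- as.integer(nPd)
    if (nAging + nPd > length(gi$nodes))
        stop("network has fewer nodes than nAging + nPd")
    genes <- observed$gene
    ge <- gt <- eq <- integer(length(genes))
    perm_p <- withSeed(seed, {
        for (rep in seq_len(reps)) {
            pickIdx <- sample.int(length(gi$nodes), nAging + nPd)
            aging <- gi$nodes[pickIdx[seq_len(nAging)]]
            pd <- gi$nodes[pickIdx[nAging + seq_len(nPd)]]
            counts <- setNames(integer(length(genes)), genes)
            for (a in aging) {
                dd <- gi$D[a, pd]
                for (j in which(is.finite(dd) & dd >= 2)) {
                    pt <- lexShortestPath(gi, a, pd[j])
                    inner <- pt[-c(1L, length(pt))]
                    hit <- inner[inner %in% genes]
                    counts[hit] <- counts[hit] + 1L
                }
            }
            ge <- ge + as.integer(counts >= observed$betweenness)
            gt <- gt + as.integer(counts > observed$betweenness)
            eq <- eq + as.integer(counts == observed$betweenness)
        }
        switch(estimator,
               proportion = ge / reps,
               smoothed = (ge + 1) / (reps + 1),
               randomized = (gt + runif(length(genes)) * (eq + 1)) /
                   (reps + 1))
    })
    observed$perm_p <- perm_p
    attr(observed, "reps") <- reps
    attr(observed, "seed") <- seed
    observed
}
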