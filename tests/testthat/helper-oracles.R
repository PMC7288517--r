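# Independent brute-force oracles used to check the implementation.

# Breadth-first single-source distances on an edge list (independent of the
# package's igraph-based machinery).
bfsDistOracle <- function(nodes, edgeA, edgeB, source) {
    adj <- setNames(vector("list", length(nodes)), nodes)
    for (i in seq_along(edgeA)) {
        adj[[edgeA[i]]] <- c(adj[[edgeA[i]]], edgeB[i])
        adj[[edgeB[i]]] <- c(adj[[edgeB[i]]], edgeA[i])
    }
    dist <- setNames(rep(Inf, length(nodes)), nodes)
    dist[source] <- 0
    queue <- source
    while (length(queue)) {
        cur <- queue[1L]
        queue <- queue[-1L]
        for (nb in adj[[cur]]) {
            if (!is.finite(dist[nb])) {
                dist[nb] <- dist[cur] + 1
                queue <- c(queue, nb)
            }
        }
    }
    dist
}

# Partial correlation via the residual-regression route: correlate the
# residuals of x ~ z and y ~ z.
partialCorOracle <- function(x, y, z) {
    rx <- residuals(lm(x ~ z))
    ry <- residuals(lm(y ~ z))
    cor(rx, ry)
}

# AUC as the fraction of concordant positive-negative score pairs (ties 1/2).
aucOracle <- function(scores, labels) {
    pos <- scores[labels == 1]
    neg <- scores[labels == 0]
    tot <- 0
    for (p in pos) for (n in neg)
        tot <- tot + if (p > n) 1 else if (p == n) 0.5 else 0
    tot / (length(pos) * length(neg))
}

# Hypergeometric upper tail by full enumeration of all size-n draws.
hyperTailOracle <- function(N, M, n, k) {
    draws <- combn(N, n)
    inSet <- seq_len(M)      # WLOG the set is genes 1..M
    mean(apply(draws, 2, function(d) sum(d %in% inSet) >= k))
}

# Two-sided Fisher exact p by enumeration of all tables with fixed margins.
fisherOracle <- function(tab) {
    r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); N <- sum(tab)
    lo <- max(0, r1 + c1 - N); hi <- min(r1, c1)
    probs <- vapply(lo:hi, function(a) dhyper(a, c1, N - c1, r1), 0)
    pObs <- dhyper(tab[1, 1], c1, N - c1, r1)
    sum(probs[probs <= pObs * (1 + 1e-7)])
}

# Random connected graph with named vertices.
randomConnectedGraph <- function(n, p, seed, prefix = "N") {
    set.seed(seed)
    repeat {
        g <- igraph::sample_gnp(n, p)
        igraph::V(g)$name <- sprintf("%s%03d", prefix, seq_len(n))
        if (igraph::is_connected(g)) return(g)
    }
}

# Small deterministic expression fixture: genes x samples of N(0,1) noise.
noiseMatrix <- function(nGenes, nSamples, seed = 1,
                        genes = sprintf("G%03d", seq_len(nGenes)),
                        samples = sprintf("S%03d", seq_len(nSamples))) {
    set.seed(seed)
    matrix(rnorm(nGenes * nSamples), nGenes, nSamples,
           dimnames = list(genes, samples))
}

# Residual-space masking construction for the improved-vs-traditional PD
# comparison: young samples vary strongly along one gene-space direction v1
# (so v1 is their leading PC); old/PD samples carry the same
# disease-irrelevant v1 variation as a nuisance, while the true PD shift
# sits on a small block of genes along a direction orthogonal to v1.
# Residualizing on the young PCs removes the v1 nuisance and exposes the
# shift.
maskedPdCohort <- function(nGenes = 60, nYoung = 60, nOld = 60, nPd = 60,
                           nDisease = 10, nuisanceSd = 10, shift = 1,
                           seed = 1) {
    set.seed(seed)
    v1 <- rep(1 / sqrt(nGenes), nGenes)                # nuisance direction
    u <- c(rep(c(1, -1), nDisease / 2), rep(0, nGenes - nDisease))
    stopifnot(abs(sum(u * v1)) < 1e-12)                # orthogonal to v1
    genes <- sprintf("G%03d", seq_len(nGenes))
    nTot <- nYoung + nOld + nPd
    samples <- sprintf("S%03d", seq_len(nTot))
    grp <- c(rep("normal", nYoung + nOld), rep("PD", nPd))
    age <- c(sample(20:49, nYoung, TRUE), sample(50:95, nOld + nPd, TRUE))
    m <- matrix(rnorm(nGenes * nTot), nGenes, nTot,
                dimnames = list(genes, samples))
    m <- m + v1 %o% rnorm(nTot, 0, nuisanceSd)
    pdIdx <- which(grp == "PD")
    m[, pdIdx] <- m[, pdIdx] + shift * u
    AgingCohort(m, data.frame(sample_id = samples, age = age, group = grp,
                              platform = "P1"))
}
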