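#' All-pairs Pearson correlations with p-values
#'
#' Correlation of every gene pair across samples; the two-sided p-value
#' comes from `t = r * sqrt((n - 2) / (1 - r^2))` with `n - 2` degrees of
#' freedom. Zero-variance genes get r = 0, p = 1 against every other
#' gene (diagonal kept at r = 1).
#'
#' @param matrix numeric matrix, genes x samples (n >= 4).
#' @return list of square matrices `r` and `p`.
#' @export
pairwiseCorrelation <- function(matrix) {
    n <- ncol(matrix)
    if (n < 4) stop("need at least 4 samples")
    sdv <- apply(matrix, 1, sd)
    r <- suppressWarnings(cor(t(matrix)))
    r[!is.finite(r)] <- 0
    r <- pmin(pmax(r, -1), 1)
    p <- corPvalue(r, n - 2)
    dimnames(p) <- dimnames(r)
    zero <- sdv == 0
    r[zero, ] <- 0
    r[, zero] <- 0
    p[zero, ] <- 1
    p[, zero] <- 1
    diag(r) <- 1
    diag(p) <- 0
    list(r = r, p = p)
}

#' First-order partial correlation given one covariate
#'
#' `rp = (r_xy - r_xz * r_yz) / sqrt((1 - r_xz^2) (1 - r_yz^2))`, with the
#' two-sided p-value from a t statistic on `n - 3` degrees of freedom.
#' When either variable is perfectly correlated with the covariate the
#' coefficient is undefined; the convention `rp = 0`, `p = 1` is returned
#' with a warning.
#'
#' @param x,y numeric vectors of equal length (>= 5).
#' @param z covariate vector (the aging score) of the same length.
#' @return list with `rp` and `p`.
#' @export
partialCorrelation <- function(x, y, z) {
    n <- length(x)
    if (length(y) != n || length(z) != n) stop("x, y, z must share length")
    if (n < 5) stop("need at least 5 observations")
    rxy <- cor(x, y)
    rxz <- cor(x, z)
    ryz <- cor(y, z)
    if (anyNA(c(rxy, rxz, ryz))) {
        warning("zero-variance input; partial correlation set to 0")
        return(list(rp = 0, p = 1))
    }
    if (abs(rxz) >= 1 - 1e-12 || abs(ryz) >= 1 - 1e-12) {
        warning("degenerate covariate (|r| = 1); partial correlation set to 0")
        return(list(rp = 0, p = 1))
    }
    rp <- (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
    rp <- min(1, max(-1, rp))
    list(rp = rp, p = corPvalue(rp, n - 3)[1L])
}

# All-pairs first-order partial correlations given covariate z:
# matrices rp and p. Genes with |cor(gene, z)| ~ 1 or zero variance get
# rp = 0, p = 1 rows/columns.
pairwisePartialCorrelation <- function(matrix, z) {
    n <- ncol(matrix)
    if (n < 5) stop("need at least 5 samples")
    pc <- pairwiseCorrelation(matrix)
    rz <- suppressWarnings(as.vector(cor(t(matrix), z)))
    bad <- !is.finite(rz) | abs(rz) >= 1 - 1e-12
    rz[bad] <- 0
    den <- sqrt(1 - rz^2)
    rp <- (pc$r - outer(rz, rz)) / outer(den, den)
    rp <- pmin(pmax(rp, -1), 1)
    rp[bad, ] <- 0
    rp[, bad] <- 0
    p <- corPvalue(rp, n - 3)
    p[bad, ] <- 1
    p[, bad] <- 1
    diag(rp) <- 1
    diag(p) <- 0
    list(rp = rp, p = p)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up BH q-values (monotone, clipped at 1), as in
#' `p.adjust(method = "BH")`.
#'
#' @param pvalues numeric vector of p-values in `[0, 1]`.
#' @return q-values of the same length.
#' @export
bhFdr <- function(pvalues) {
    if (!length(pvalues)) return(numeric())
    if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE))
        stop("p-values must lie in [0, 1]")
    p.adjust(pvalues, method = "BH")
}

#' Build the aging-acceleration network
#'
#' For every gene pair computes the Pearson correlation and the first-order
#' partial correlation given the aging score, separately in control and PD
#' samples, and retains the pair as an edge when
#' `|r_control - r_pd| > deltaThreshold` AND
#' `|rp_control - rp_pd| > deltaThreshold` (strict), under a BH-FDR
#' significance gate. BH adjustment runs within each of the four coefficient
#' families (r and rp in each group); `significanceMode` controls the gate:
#' `"any"` (default) requires the minimum of the four q-values to fall below
#' `fdrThreshold`, `"all"` requires all four, `"off"` disables the gate.
#'
#' @param controlMatrix,pdMatrix genes x samples matrices (shared gene ids;
#'   the intersection is used, and disjoint universes are an error).
#' @param controlScores,pdScores aging scores aligned to the columns.
#' @param deltaThreshold minimum absolute difference (default 0.5).
#' @param fdrThreshold BH-FDR gate level (default 0.05).
#' @param significanceMode `"any"`, `"all"` or `"off"`.
#' @param provenance free-text tag stored on the network.
#' @return A [DifferentialNetwork].
#' @export
buildNetwork <- function(controlMatrix, pdMatrix, controlScores, pdScores,
                         deltaThreshold = 0.5, fdrThreshold = 0.05,
                         significanceMode = c("any", "all", "off"),
                         provenance = "network") {
    significanceMode <- match.arg(significanceMode)
    genes <- intersect(rownames(controlMatrix), rownames(pdMatrix))
    if (!length(genes)) stop("gene universes are disjoint")
    genes <- sort(genes)
    cm <- controlMatrix[genes, , drop = FALSE]
    pm <- pdMatrix[genes, , drop = FALSE]
    if (length(controlScores) != ncol(cm) || length(pdScores) != ncol(pm))
        stop("scores must align with the sample columns")
    cc <- pairwiseCorrelation(cm)
    cp <- pairwiseCorrelation(pm)
    rc <- pairwisePartialCorrelation(cm, controlScores)
    rp <- pairwisePartialCorrelation(pm, pdScores)

    ut <- upper.tri(cc$r)
    idx <- which(ut, arr.ind = TRUE)
    q1 <- bhFdr(cc$p[ut])
    q2 <- bhFdr(cp$p[ut])
    q3 <- bhFdr(rc$p[ut])
    q4 <- bhFdr(rp$p[ut])
    qmin <- pmin(q1, q2, q3, q4)
    qmax <- pmax(q1, q2, q3, q4)
    deltaR <- abs(cc$r[ut] - cp$r[ut])
    deltaRp <- abs(rc$rp[ut] - rp$rp[ut])
    gate <- switch(significanceMode,
                   any = qmin < fdrThreshold,
                   all = qmax < fdrThreshold,
                   off = rep(TRUE, length(qmin)))
    keep <- gate & deltaR > deltaThreshold & deltaRp > deltaThreshold
    edges <- data.frame(
        gene_a = genes[idx[keep, 1L]], gene_b = genes[idx[keep, 2L]],
        r_control = cc$r[ut][keep], r_pd = cp$r[ut][keep],
        rp_control = rc$rp[ut][keep], rp_pd = rp$rp[ut][keep],
        delta_r = deltaR[keep], delta_rp = deltaRp[keep],
        q_min = qmin[keep], stringsAsFactors = FALSE)
    edges <- edges[order(edges$gene_a, edges$gene_b), , drop = FALSE]
    rownames(edges) <- NULL
    methods::new("DifferentialNetwork", nodes = genes, edges = edges,
                 thresholds = list(delta = deltaThreshold,
                                   fdr = fdrThreshold,
                                   significance_mode = significanceMode),
                 provenance = provenance)
}

#' Fisher's exact test of edge overlap between two networks
#'
#' Classifies every unordered gene pair of the common universe by membership
#' in each network's edge set and applies the two-sided Fisher exact test to
#' the resulting 2x2 table.
#'
#' @param netA,netB [DifferentialNetwork] objects.
#' @return list with `odds_ratio` (conditional MLE), `p`, and the `table`.
#' @export
networkSimilarityFisher <- function(netA, netB) {
    universe <- intersect(networkNodes(netA), networkNodes(netB))
    if (length(universe) < 2) stop("common gene universe is empty")
    pairKey <- function(net) {
        ed <- networkEdges(net)
        ed <- ed[ed$gene_a %in% universe & ed$gene_b %in% universe, ,
                 drop = FALSE]
        paste(pmin(ed$gene_a, ed$gene_b), pmax(ed$gene_a, ed$gene_b),
              sep = "\r")
    }
    a <- pairKey(netA)
    b <- pairKey(netB)
    total <- choose(length(universe), 2)
    both <- length(intersect(a, b))
    onlyA <- length(setdiff(a, b))
    onlyB <- length(setdiff(b, a))
    tab <- matrix(c(both, onlyA, onlyB, total - both - onlyA - onlyB), 2, 2,
                  dimnames = list(inA = c("yes", "no"),
                                  inB = c("yes", "no")))
    ft <- fisher.test(tab)
    list(odds_ratio = unname(ft$estimate), p = ft$p.value, table = tab)
}

#' Scale-free diagnostic of the degree distribution
#'
#' Correlates `log10(degree)` with `log10(frequency)` over the observed
#' degrees of nodes with `degree >= minDegree`. A strongly negative
#' correlation is the expected signature of a scale-free (power-law-like)
#' degree distribution. With fewer than 3 distinct degrees the statistic is
#' undefined and `NA` is returned.
#'
#' @param network a [DifferentialNetwork] or [igraph::igraph].
#' @param minDegree smallest degree entering the fit (default 1, excluding
#'   isolated nodes).
#' @return list with `r`, `p`, `n_degrees` and the degree-frequency table.
#' @export
scaleFreeCheck <- function(network, minDegree = 1L) {
    g <- if (inherits(network, "DifferentialNetwork")) asIgraph(network)
         else network
    deg <- igraph::degree(g)
    deg <- deg[deg >= minDegree]
    tab <- table(deg)
    d <- as.numeric(names(tab))
    f <- as.numeric(tab)
    if (length(d) < 3)
        return(list(r = NA_real_, p = NA_real_, n_degrees = length(d),
                    degrees = d, frequencies = f))
    ct <- cor.test(log10(d), log10(f))
    list(r = unname(ct$estimate), p = ct$p.value, n_degrees = length(d),
         degrees = d, frequencies = f)
}
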