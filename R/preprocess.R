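#' Collapse probe-level rows to gene symbols
#'
#' Rows sharing a gene symbol are averaged (arithmetic mean per sample);
#' probes absent from the map are dropped.
#'
#' @param probeMatrix numeric matrix, probes x samples, probe ids as
#'   rownames.
#' @param probeMap data.frame with columns `probe_id`, `gene_symbol`
#'   (many-to-one allowed; empty symbols rejected).
#' @return Numeric matrix keyed by gene symbol (rows sorted by symbol).
#' @export
collapseProbes <- function(probeMatrix, probeMap) {
    if (!all(c("probe_id", "gene_symbol") %in% colnames(probeMap)))
        stop("'probeMap' needs columns probe_id and gene_symbol")
    probeMap <- probeMap[probeMap$probe_id %in% rownames(probeMatrix), ,
                         drop = FALSE]
    if (!nrow(probeMap))
        stop("probe map is empty (no probe matches the matrix)")
    if (any(!nzchar(probeMap$gene_symbol)) || anyNA(probeMap$gene_symbol))
        stop("probe map contains empty gene symbols")
    sym <- probeMap$gene_symbol
    sub <- probeMatrix[probeMap$probe_id, , drop = FALSE]
    out <- rowsum(sub, group = sym) / as.vector(table(sym)[sort(unique(sym))])
    out[order(rownames(out)), , drop = FALSE]
}

#' Zero-fill missing values and drop mostly-zero genes
#'
#' Missing values are set to 0; genes whose fraction of exactly-zero values
#' is at least `zeroFraction` are then removed.
#'
#' @param matrix numeric matrix, genes x samples (may contain NA).
#' @param zeroFraction removal threshold on the zero fraction (default 0.30;
#'   the boundary itself is removed).
#' @return The filtered matrix.
#' @export
fillAndFilterGenes <- function(matrix, zeroFraction = 0.30) {
    matrix[is.na(matrix)] <- 0
    if (!ncol(matrix)) return(matrix)
    frac <- rowMeans(matrix == 0)
    keep <- frac < zeroFraction
    if (!any(keep)) stop("empty matrix after filtering")
    matrix[keep, , drop = FALSE]
}

#' Remove early-onset PD samples
#'
#' Drops PD samples younger than `ageCut` from both the matrix and the
#' sample table; normal samples are never touched.
#'
#' @param matrix numeric matrix, genes x samples.
#' @param table data.frame with `sample_id`, `age`, `group`.
#' @param ageCut onset threshold in years (default 50; `age >= ageCut` kept).
#' @return list with elements `matrix` and `table`.
#' @export
filterSamples <- function(matrix, table, ageCut = 50) {
    keep <- !(table$group == "PD" & table$age < ageCut)
    tab <- table[keep, , drop = FALSE]
    list(matrix = matrix[, tab$sample_id, drop = FALSE], table = tab)
}

# Rank-3 truncated SVD reconstruction of a block (genes x samples).
rankKReconstruction <- function(block, k = 3L) {
    k <- min(k, nrow(block), ncol(block))
    if (k == 0L) return(block * 0)
    sv <- svd(block, nu = k, nv = k)
    d <- sv$d[seq_len(k)]
    sv$u %*% (d * t(sv$v))
}

# z-score rows of `block` using per-gene mean/sd taken from `ref`.
# Reference genes with (numerically) zero variance give 0 with a warning.
zscoreByReference <- function(block, ref, what = "reference") {
    mu <- rowMeans(ref)
    sdv <- apply(ref, 1, sd)
    bad <- !is.finite(sdv) | sdv < 1e-10 * pmax(1, abs(mu))
    if (any(bad)) {
        warning(sum(bad), " gene(s) with zero variance in the ", what,
                " group; their z-scores are set to 0")
        sdv[bad] <- 1
    }
    out <- (block - mu) / sdv
    out[bad, ] <- 0
    out
}

#' Per-platform three-step normalization
#'
#' Applied independently within each platform:
#' 1. every sample is z-scored per gene using the mean and SD of the
#'    platform's normal samples, putting all groups (young samples
#'    included) on the platform's normal-referenced z scale;
#' 2. the rank-3 truncated-SVD reconstruction is subtracted from the
#'    old-normal block and the PD block separately, removing the three
#'    dominant inter-sample variation components of each block;
#' 3. all samples (young included) are z-scored per gene using the
#'    old-normal mean and SD computed after step 2.
#'
#' After step 3 every gene has mean 0 and SD 1 across the platform's
#' old-normal samples, so platform-level location/scale differences are
#' gone. Zero-variance reference genes yield 0 z-scores with a warning.
#'
#' @param matrix numeric matrix, genes x samples.
#' @param table sample table (`sample_id`, `age`, `group`, `platform`).
#' @param ageCut young/old threshold in years.
#' @param nComponents number of SVD components removed (default 3).
#' @return Normalized matrix with the same dimensions (z-units).
#' @export
normalizePlatform <- function(matrix, table, ageCut = 50, nComponents = 3L) {
    table <- table[match(colnames(matrix), table$sample_id), , drop = FALSE]
    out <- matrix
    for (pf in unique(table$platform)) {
        sel <- table$platform == pf
        tb <- table[sel, , drop = FALSE]
        m <- matrix[, tb$sample_id, drop = FALSE]
        normal <- tb$group == "normal"
        old <- tb$age >= ageCut
        oldNormal <- normal & old
        pd <- tb$group == "PD"
        if (sum(normal) >= 2)
            m <- zscoreByReference(m, m[, normal, drop = FALSE],
                                   what = "normal")
        if (sum(oldNormal) >= 4)
            m[, oldNormal] <- m[, oldNormal, drop = FALSE] -
                rankKReconstruction(m[, oldNormal, drop = FALSE], nComponents)
        if (sum(pd) >= 4)
            m[, pd] <- m[, pd, drop = FALSE] -
                rankKReconstruction(m[, pd, drop = FALSE], nComponents)
        if (sum(oldNormal) >= 2)
            m <- zscoreByReference(m, m[, oldNormal, drop = FALSE],
                                   what = "old-normal")
        out[, tb$sample_id] <- m
    }
    out
}

#' Residualize old/PD samples on the young principal components
#'
#' Computes the leading principal-component directions of the healthy young
#' samples in gene space (samples are observations, genes variables; the
#' young block is centered on its per-gene means), then replaces every
#' old/PD sample by the residual of the ordinary least-squares regression of
#' its young-mean-centered gene vector on those direction vectors. Because
#' the directions are orthonormal this is the projection onto their
#' orthogonal complement, so the operation is idempotent.
#'
#' @param matrixOldPd numeric matrix, genes x (old and PD) samples.
#' @param matrixYoung numeric matrix, genes x young samples (>= 4 samples).
#' @param nComponents number of young PCs to remove (default 3).
#' @return Matrix of residual expression, dimensions matching `matrixOldPd`
#'   (restricted to the genes shared with `matrixYoung`).
#' @export
residualizeOnYoung <- function(matrixOldPd, matrixYoung, nComponents = 3L) {
    shared <- intersect(rownames(matrixOldPd), rownames(matrixYoung))
    if (!length(shared)) stop("no shared genes between the two matrices")
    if (ncol(matrixYoung) < 4)
        stop("need at least 4 young samples")
    x <- matrixOldPd[shared, , drop = FALSE]
    y <- matrixYoung[shared, , drop = FALSE]
    mu <- rowMeans(y)
    yc <- y - mu
    sv <- svd(yc, nu = nComponents, nv = 0)
    pos <- sv$d[seq_len(min(nComponents, length(sv$d)))] > 1e-10 * max(sv$d, 1)
    k <- sum(pos)
    if (k < nComponents)
        warning("young block has only ", k,
                " non-degenerate principal components; using those")
    xc <- x - mu
    if (k == 0L) return(xc)
    v <- sv$u[, seq_len(k), drop = FALSE]     # orthonormal gene-space dirs
    xc - v %*% crossprod(v, xc)
}
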