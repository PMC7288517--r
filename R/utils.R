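# Internal helpers shared across modules.

# Derive a stage seed from a global seed by a fixed offset, kept inside the
# 32-bit integer range so set.seed() always accepts it.
stageSeed <- function(seed, offset) {
    as.integer((as.numeric(seed) + 1013L * offset) %% 2147483629)
}

# Evaluate an expression with a locally-set RNG state, restoring the caller's.
withSeed <- function(seed, expr) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
        on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
    }
    set.seed(seed)
    expr
}

# 0/1 integer labels from a logical or two-level vector.
asBinaryLabels <- function(labels) {
    if (is.logical(labels)) return(as.integer(labels))
    labels <- as.integer(labels)
    if (!all(labels %in% c(0L, 1L))) stop("labels must be coded 0/1")
    labels
}

stopifnotScalarCount <- function(x, name, min = 0L) {
    if (length(x) != 1L || is.na(x) || x != floor(x) || x < min)
        stop(sprintf("'%s' must be a single integer >= %d", name, min))
}

# Two-sided p-value for a Pearson correlation with the given residual df.
corPvalue <- function(r, df) {
    dd <- dim(r)
    r <- pmin(pmax(r, -1), 1)
    p <- rep(1, length(r))
    ok <- is.finite(r) & abs(r) < 1 & df > 0
    tt <- abs(r[ok]) * sqrt(df / (1 - r[ok]^2))
    p[ok] <- 2 * pt(tt, df, lower.tail = FALSE)
    p[abs(r) >= 1 & df > 0] <- 0
    dim(p) <- dd
    p
}
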