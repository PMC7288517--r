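#' Read / write gene sets in GMT format
#'
#' GMT is the tab-delimited gene-set format used by MSigDB/GSEA: one set per
#' line as `name<TAB>description<TAB>member1<TAB>member2...`. Members are
#' deduplicated on read. Unless an explicit `universe` is supplied, the
#' universe is the union of all members.
#'
#' @param file path to a GMT file.
#' @param universe optional character vector overriding the universe.
#' @return `readGmt()`: a [GeneSetCollection]; `writeGmt()`: the file path,
#'   invisibly.
#' @export
readGmt <- function(file, universe = NULL) {
    lines <- readLines(file)
    lines <- lines[nzchar(lines)]
    if (!length(lines)) stop("empty GMT file: ", file)
    sets <- list()
    for (i in seq_along(lines)) {
        parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
        if (length(parts) < 3 || !nzchar(parts[1]))
            stop("malformed GMT line ", i,
                 ": need name, description and at least one member")
        sets[[parts[1]]] <- unique(parts[-(1:2)])
    }
    if (is.null(universe)) universe <- sort(unique(unlist(sets)))
    methods::new("GeneSetCollection", sets = sets,
                 universe = as.character(universe), source = file)
}

#' @rdname readGmt
#' @param collection a [GeneSetCollection].
#' @param descriptions optional named character descriptions per set.
#' @export
writeGmt <- function(collection, file, descriptions = NULL) {
    nm <- names(geneSets(collection))
    desc <- if (is.null(descriptions)) setNames(rep("na", length(nm)), nm)
            else descriptions
    lines <- vapply(nm, function(s)
        paste(c(s, desc[[s]], geneSets(collection)[[s]]), collapse = "\t"),
        character(1))
    writeLines(lines, file)
    invisible(file)
}

#' Hypergeometric upper-tail probability
#'
#' `P(X >= k)` where X counts the overlap between a random draw of `n`
#' genes from a universe of `N` and a set of `M` genes:
#' `1 - sum_{j=0}^{k-1} C(M,j) C(N-M, n-j) / C(N,n)`, evaluated stably via
#' [stats::phyper()].
#'
#' @param N universe size.
#' @param M set size within the universe.
#' @param n draw size (genes on the path).
#' @param k observed overlap.
#' @return The upper-tail p-value (1 when `k = 0`).
#' @export
hypergeomUpperTail <- function(N, M, n, k) {
    for (v in c(N, M, n, k))
        if (length(v) != 1 || is.na(v) || v < 0 || v != floor(v))
            stop("N, M, n, k must be single non-negative integers")
    if (M > N || n > N || k > min(n, M))
        stop(sprintf("inconsistent counts: N=%d, M=%d, n=%d, k=%d",
                     N, M, n, k))
    if (k == 0) return(1)
    phyper(k - 1, M, N - M, n, lower.tail = FALSE)
}

#' Per-path hypergeometric enrichment with BH control
#'
#' Each path's gene list is tested against every set of the collection with
#' the hypergeometric upper tail; BH adjustment runs across sets within each
#' path (optionally globally across all path-set tests). A row passes at
#' `p < pThreshold` and `q < qThreshold` (defaults 0.05 and 0.1).
#'
#' @param paths named list of character vectors (genes per path).
#' @param collection a [GeneSetCollection].
#' @param pThreshold,qThreshold pass thresholds on p and BH q.
#' @param bhScope `"within-path"` (default) or `"global"`.
#' @return data.frame with one row per (path, set): `path_id`, `set`, `N`,
#'   `M`, `n`, `k`, `p`, `q`, `pass`; a summary data.frame of sets ranked
#'   by the number of enriched paths is attached as attribute `"summary"`.
#' @export
enrichPaths <- function(paths, collection, pThreshold = 0.05,
                        qThreshold = 0.1,
                        bhScope = c("within-path", "global")) {
    bhScope <- match.arg(bhScope)
    if (!length(paths)) stop("no paths supplied")
    if (is.null(names(paths)))
        names(paths) <- sprintf("path_%03d", seq_along(paths))
    universe <- geneUniverse(collection)
    N <- length(universe)
    sets <- lapply(geneSets(collection), intersect, universe)
    rows <- lapply(names(paths), function(pid) {
        genes <- intersect(unique(paths[[pid]]), universe)
        n <- length(genes)
        k <- vapply(sets, function(s) length(intersect(genes, s)), 0L)
        M <- vapply(sets, length, 0L)
        p <- mapply(function(M, k) hypergeomUpperTail(N, M, n, k), M, k)
        data.frame(path_id = pid, set = names(sets), N = N, M = M, n = n,
                   k = k, p = as.numeric(p), stringsAsFactors = FALSE,
                   row.names = NULL)
    })
    out <- do.call(rbind, rows)
    out$q <- if (bhScope == "global") bhFdr(out$p)
             else unsplit(lapply(split(out$p, out$path_id), bhFdr),
                          out$path_id)
    out$pass <- out$p < pThreshold & out$q < qThreshold
    hits <- out[out$pass, , drop = FALSE]
    summary <- if (nrow(hits)) {
        s <- tapply(hits$path_id, hits$set, function(x) length(unique(x)))
        df <- data.frame(set = names(s), n_enriched_paths = as.integer(s),
                         min_p = as.numeric(tapply(hits$p, hits$set, min)),
                         stringsAsFactors = FALSE)
        df <- df[order(-df$n_enriched_paths, df$min_p, df$set), ,
                 drop = FALSE]
        rownames(df) <- NULL
        df
    } else data.frame(set = character(), n_enriched_paths = integer(),
                      min_p = numeric())
    attr(out, "summary") <- summary
    out
}
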