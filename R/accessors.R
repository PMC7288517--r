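#' Construct an AgingCohort
#'
#' @param exprs numeric matrix, genes x samples, with gene symbols as
#'   rownames and sample ids as colnames.
#' @param sampleTable data.frame with columns `sample_id`, `age`, `group`
#'   (`"normal"`/`"PD"`) and `platform`, one row per column of `exprs`.
#' @param groundTruth optional [GroundTruth] for simulated cohorts.
#' @return An [AgingCohort].
#' @examples
#' m <- matrix(rnorm(20), 4, 5,
#'             dimnames = list(paste0("G", 1:4), paste0("S", 1:5)))
#' tab <- data.frame(sample_id = colnames(m), age = c(30, 40, 55, 60, 70),
#'                   group = c("normal", "normal", "normal", "PD", "PD"),
#'                   platform = "P1")
#' AgingCohort(m, tab)
#' @export
AgingCohort <- function(exprs, sampleTable, groundTruth = NULL) {
    exprs <- as.matrix(exprs)
    if (nrow(exprs) > 0 && is.null(rownames(exprs)))
        stop("'exprs' must have gene rownames")
    if (ncol(exprs) > 0 && is.null(colnames(exprs)))
        stop("'exprs' must have sample colnames")
    need <- c("sample_id", "age", "group", "platform")
    miss <- setdiff(need, colnames(sampleTable))
    if (length(miss))
        stop("sample table is missing column(s): ", paste(miss, collapse = ", "))
    extraM <- setdiff(colnames(exprs), sampleTable$sample_id)
    extraT <- setdiff(sampleTable$sample_id, colnames(exprs))
    if (length(extraM) || length(extraT))
        stop("matrix/table sample mismatch; only in matrix: [",
             paste(extraM, collapse = ", "), "]; only in table: [",
             paste(extraT, collapse = ", "), "]")
    sampleTable <- sampleTable[match(colnames(exprs), sampleTable$sample_id), ,
                               drop = FALSE]
    cd <- S4Vectors::DataFrame(age = as.numeric(sampleTable$age),
                               group = as.character(sampleTable$group),
                               platform = as.character(sampleTable$platform),
                               row.names = colnames(exprs))
    md <- if (is.null(groundTruth)) list() else list(groundTruth = groundTruth)
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(exprs = exprs), colData = cd, metadata = md)
    methods::new("AgingCohort", se)
}

#' @describeIn AgingCohort the genes x samples expression matrix.
#' @param x an AgingCohort.
#' @export
exprsMatrix <- function(x) SummarizedExperiment::assay(x, "exprs")

#' @describeIn AgingCohort sample ages in years.
#' @export
sampleAges <- function(x) {
    setNames(SummarizedExperiment::colData(x)$age, colnames(x))
}

#' @describeIn AgingCohort sample groups ("normal"/"PD").
#' @export
sampleGroups <- function(x) {
    setNames(SummarizedExperiment::colData(x)$group, colnames(x))
}

#' @describeIn AgingCohort sample platform ids.
#' @export
samplePlatforms <- function(x) {
    setNames(SummarizedExperiment::colData(x)$platform, colnames(x))
}

#' @describeIn AgingCohort derived age class: "young" (< ageCut) or "old".
#' @param ageCut age threshold in years separating young from old.
#' @export
ageClasses <- function(x, ageCut = 50) {
    setNames(ifelse(SummarizedExperiment::colData(x)$age < ageCut,
                    "young", "old"), colnames(x))
}

#' @describeIn AgingCohort the planted [GroundTruth], or NULL.
#' @export
groundTruth <- function(x) S4Vectors::metadata(x)$groundTruth

#' @describeIn AgingCohort the per-sample metadata as a plain data.frame
#'   (`sample_id`, `age`, `group`, `platform`).
#' @export
sampleTable <- function(x) {
    cd <- SummarizedExperiment::colData(x)
    data.frame(sample_id = colnames(x), age = cd$age, group = cd$group,
               platform = cd$platform, stringsAsFactors = FALSE)
}

setMethod("show", "AgingCohort", function(object) {
    cd <- SummarizedExperiment::colData(object)
    cat(sprintf("AgingCohort: %d genes x %d samples\n",
                nrow(object), ncol(object)))
    if (ncol(object)) {
        ac <- ifelse(cd$age < 50, "young", "old")
        cat(sprintf("  normal: %d (young %d / old %d), PD: %d; platforms: %s\n",
                    sum(cd$group == "normal"),
                    sum(cd$group == "normal" & ac == "young"),
                    sum(cd$group == "normal" & ac == "old"),
                    sum(cd$group == "PD"),
                    paste(sort(unique(cd$platform)), collapse = ", ")))
    }
    if (!is.null(groundTruth(object)))
        cat("  carries planted ground truth\n")
    invisible(NULL)
})

#' @describeIn RankedGeneList-class the ranking table (gene, r, rank).
#' @param x a RankedGeneList.
#' @export
rankTable <- function(x) x@table

#' @describeIn RankedGeneList-class the top-n gene ids in rank order.
#' @param n number of genes.
#' @export
topGenes <- function(x, n) head(x@table$gene, n)

setMethod("show", "RankedGeneList", function(object) {
    cat(sprintf("RankedGeneList (%s): %d genes\n", object@label,
                nrow(object@table)))
    if (nrow(object@table))
        print(head(object@table, 5L), row.names = FALSE)
    invisible(NULL)
})

setMethod("show", "KnnModel", function(object) {
    cat(sprintf("KnnModel (%s): k = %d, %d features, %d training samples\n",
                object@label, object@k, length(object@featureGenes),
                ncol(object@trainX)))
    invisible(NULL)
})

#' @describeIn CvCurve-class accuracy by candidate feature count.
#' @param x a CvCurve.
#' @export
cvAccuracy <- function(x) x@accuracy

#' @describeIn CvCurve-class the selected (smallest argmax) feature count.
#' @export
selectedN <- function(x) x@selectedN

setMethod("show", "CvCurve", function(object) {
    cat(sprintf(
        "CvCurve: %d candidate feature counts, %d folds; selected n = %d (accuracy %.4f)\n",
        length(object@accuracy), object@folds, object@selectedN,
        object@accuracy[object@selectedN]))
    invisible(NULL)
})

#' @describeIn RocResult-class area under the ROC curve (NA if undefined).
#' @param x a RocResult.
#' @export
auc <- function(x) x@auc

#' @describeIn RocResult-class majority-vote accuracy.
#' @export
accuracy <- function(x) x@accuracy

setMethod("show", "RocResult", function(object) {
    cat(sprintf("RocResult: accuracy %.4f, AUC %s over %d test samples\n",
                object@accuracy,
                ifelse(is.na(object@auc), "NA", sprintf("%.4f", object@auc)),
                length(object@labels)))
    invisible(NULL)
})

setMethod("show", "AgingScoreModel", function(object) {
    cat(sprintf(
        "AgingScoreModel: %d markers, sigmoid center %g y / scale %g y%s\n",
        length(object@markers), object@center, object@scale,
        if (object@intercept != 0) sprintf(", intercept %.4g", object@intercept)
        else ""))
    invisible(NULL)
})

#' @describeIn DifferentialNetwork-class the retained edge table.
#' @param x a DifferentialNetwork.
#' @export
networkEdges <- function(x) x@edges

#' @describeIn DifferentialNetwork-class the gene universe.
#' @export
networkNodes <- function(x) x@nodes

#' @describeIn DifferentialNetwork-class the network as an [igraph::igraph]
#'   (all universe genes as vertices, retained pairs as edges).
#' @export
asIgraph <- function(x) {
    g <- igraph::make_empty_graph(n = 0, directed = FALSE)
    g <- igraph::add_vertices(g, length(x@nodes), name = x@nodes)
    if (nrow(x@edges))
        g <- igraph::add_edges(g, rbind(x@edges$gene_a, x@edges$gene_b))
    g
}

setMethod("show", "DifferentialNetwork", function(object) {
    cat(sprintf(
        "DifferentialNetwork (%s): %d nodes, %d edges (delta > %g, FDR %g, mode '%s')\n",
        object@provenance, length(object@nodes), nrow(object@edges),
        object@thresholds$delta, object@thresholds$fdr,
        object@thresholds$significance_mode))
    invisible(NULL)
})

#' @describeIn GeneSetCollection-class the named list of member vectors.
#' @param x a GeneSetCollection.
#' @export
geneSets <- function(x) x@sets

#' @describeIn GeneSetCollection-class the gene universe.
#' @export
geneUniverse <- function(x) x@universe

setMethod("show", "GeneSetCollection", function(object) {
    cat(sprintf("GeneSetCollection: %d sets over a universe of %d genes\n",
                length(object@sets), length(object@universe)))
    invisible(NULL)
})

setMethod("show", "GroundTruth", function(object) {
    cat(sprintf(
        "GroundTruth: %d aging genes, %d PD genes, %d differential pairs, %d samples\n",
        length(object@agingGenes), length(object@pdGenes),
        nrow(object@diffEdges), length(object@trueAges)))
    invisible(NULL)
})

#' @describeIn GroundTruth-class planted aging genes.
#' @param x a GroundTruth.
#' @export
agingGenes <- function(x) x@agingGenes

#' @describeIn GroundTruth-class planted PD genes.
#' @export
pdGenes <- function(x) x@pdGenes

#' @describeIn GroundTruth-class planted differential-correlation pairs.
#' @export
diffEdges <- function(x) x@diffEdges
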