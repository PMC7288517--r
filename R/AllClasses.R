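#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment assay assayNames colData
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom stats cor cor.test coef fisher.test kruskal.test median p.adjust
#'   phyper pt quantile rnorm runif sd setNames var
#' @importFrom utils read.delim write.table head
#' @importFrom graphics plot.new
NULL

#' AgingCohort: expression cohort with age, group and platform annotation
#'
#' A thin extension of [SummarizedExperiment::SummarizedExperiment] holding a
#' genes x samples expression matrix in the `"exprs"` assay and per-sample
#' metadata in `colData`: `age` (years), `group` (`"normal"` or `"PD"`),
#' `platform` (platform identifier). The age class used throughout the
#' package (young `< 50`, old `>= 50`) is derived, never stored. When the
#' cohort was simulated, the planted [GroundTruth] is kept in
#' `metadata(x)$groundTruth`.
#'
#' @slot .data inherited SummarizedExperiment slots.
#' @seealso [AgingCohort()], [generateCohort()]
#' @export
setClass("AgingCohort", contains = "SummarizedExperiment")

setValidity("AgingCohort", function(object) {
    msg <- character()
    if (!"exprs" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'exprs' is missing")
    cd <- SummarizedExperiment::colData(object)
    for (col in c("age", "group", "platform"))
        if (!col %in% colnames(cd))
            msg <- c(msg, sprintf("colData column '%s' is missing", col))
    if ("age" %in% colnames(cd)) {
        if (!is.numeric(cd$age) || anyNA(cd$age) || any(cd$age < 0))
            msg <- c(msg, "'age' must be non-negative and non-missing")
    }
    if ("group" %in% colnames(cd) &&
        !all(cd$group %in% c("normal", "PD")))
        msg <- c(msg, "'group' must be 'normal' or 'PD'")
    if (anyDuplicated(rownames(object)))
        msg <- c(msg, "duplicate gene ids")
    if (anyDuplicated(colnames(object)))
        msg <- c(msg, "duplicate sample ids")
    if (length(msg)) msg else TRUE
})

#' Ground truth of a simulated cohort
#'
#' Records what was planted by [generateCohort()]: which genes carry an
#' age-dependent mean, which carry a disease shift, which gene pairs flip
#' their co-expression sign between control and PD samples (with the target
#' correlation in each group), and the true age of every sample.
#'
#' @slot agingGenes character, genes with age-dependent mean.
#' @slot pdGenes character, genes shifted in PD samples.
#' @slot diffEdges data.frame with columns `gene_a`, `gene_b`, `r_control`,
#'   `r_pd`: planted differential-correlation pairs and their target
#'   correlations.
#' @slot trueAges named numeric, age in years per sample id.
#' @export
setClass("GroundTruth",
    representation(agingGenes = "character", pdGenes = "character",
                   diffEdges = "data.frame", trueAges = "numeric"))

setValidity("GroundTruth", function(object) {
    msg <- character()
    de <- object@diffEdges
    need <- c("gene_a", "gene_b", "r_control", "r_pd")
    if (!all(need %in% colnames(de)))
        msg <- c(msg, paste("diffEdges needs columns",
                            paste(need, collapse = ", ")))
    else if (nrow(de) && any(de$gene_a == de$gene_b))
        msg <- c(msg, "diffEdges contains self-pairs")
    if (length(object@trueAges) && is.null(names(object@trueAges)))
        msg <- c(msg, "trueAges must be named by sample id")
    if (length(msg)) msg else TRUE
})

#' Genes ranked by absolute correlation with a binary phenotype
#'
#' @slot table data.frame with columns `gene`, `r` (Pearson correlation with
#'   the 0/1 phenotype), `rank` (1-based, ordered by decreasing `|r|`, ties
#'   broken lexicographically by gene id).
#' @slot label character, how the phenotype was coded (e.g. "young=0/old=1").
#' @export
setClass("RankedGeneList",
    representation(table = "data.frame", label = "character"))

setValidity("RankedGeneList", function(object) {
    tb <- object@table
    msg <- character()
    if (!all(c("gene", "r", "rank") %in% colnames(tb)))
        msg <- c(msg, "table needs columns gene, r, rank")
    else {
        if (nrow(tb) && !identical(tb$rank, seq_len(nrow(tb))))
            msg <- c(msg, "ranks must be consecutive from 1")
        if (nrow(tb) > 1 && any(diff(abs(tb$r)) > 1e-12))
            msg <- c(msg, "table must be sorted by decreasing |r|")
        if (nrow(tb) && any(abs(tb$r) > 1 + 1e-12))
            msg <- c(msg, "correlations must lie in [-1, 1]")
    }
    if (length(msg)) msg else TRUE
})

#' Cosine k-nearest-neighbour classifier
#'
#' @slot featureGenes ordered character vector of feature genes (a prefix of
#'   a [RankedGeneList]).
#' @slot k integer neighbour count.
#' @slot trainX numeric matrix, featureGenes x training samples.
#' @slot trainLabels integer vector of 0/1 labels, one per training sample.
#' @slot label character, label coding description.
#' @export
setClass("KnnModel",
    representation(featureGenes = "character", k = "integer",
                   trainX = "matrix", trainLabels = "integer",
                   label = "character"))

setValidity("KnnModel", function(object) {
    msg <- character()
    if (object@k < 1L || object@k > ncol(object@trainX))
        msg <- c(msg, "k must satisfy 1 <= k <= number of training samples")
    if (length(object@trainLabels) != ncol(object@trainX))
        msg <- c(msg, "one label per training sample required")
    if (!all(object@trainLabels %in% c(0L, 1L)))
        msg <- c(msg, "labels must be 0/1")
    if (!identical(object@featureGenes, rownames(object@trainX)))
        msg <- c(msg, "trainX rows must equal featureGenes in order")
    if (length(msg)) msg else TRUE
})

#' Cross-validation learning curve over feature counts
#'
#' @slot accuracy numeric vector; element n is the mean k-fold CV accuracy of
#'   the kNN model built on the top-n ranked genes.
#' @slot selectedN integer; smallest n attaining the maximum accuracy.
#' @slot folds integer; number of CV folds.
#' @export
setClass("CvCurve",
    representation(accuracy = "numeric", selectedN = "integer",
                   folds = "integer"))

setValidity("CvCurve", function(object) {
    msg <- character()
    acc <- object@accuracy
    if (length(acc)) {
        best <- max(acc)
        if (object@selectedN != which(acc >= best - 1e-12)[1L])
            msg <- c(msg, "selectedN must be the smallest argmax of accuracy")
        if (any(acc < 0 | acc > 1)) msg <- c(msg, "accuracies must be in [0,1]")
    }
    if (length(msg)) msg else TRUE
})

#' Classifier test-set evaluation: accuracy, ROC curve and AUC
#'
#' Scores are class-1 vote fractions of the kNN model; the ROC curve is the
#' step curve over score thresholds and the AUC its trapezoidal area. When
#' the test labels contain one class only, `auc` is `NA`.
#'
#' @slot scores numeric, per-sample class-1 vote fraction.
#' @slot labels integer 0/1 truth.
#' @slot predicted integer 0/1 majority-vote predictions.
#' @slot fpr,tpr numeric, ROC curve points (monotone, from (0,0) to (1,1)).
#' @slot auc numeric(1), trapezoid area (NA when undefined).
#' @slot accuracy numeric(1), fraction correct under the majority vote.
#' @export
setClass("RocResult",
    representation(scores = "numeric", labels = "integer",
                   predicted = "integer", fpr = "numeric", tpr = "numeric",
                   auc = "numeric", accuracy = "numeric"))

#' Aging-score model: no-intercept regression on aging markers
#'
#' Linear model `sigmoidAge(age) = sum_i b_i * marker_i` fitted by (minimum
#' norm) least squares without an intercept.
#'
#' @slot markers character, aging marker genes.
#' @slot coefficients numeric, one b per marker.
#' @slot center,scale numeric(1), parameters of the age sigmoid.
#' @slot intercept numeric(1), 0 unless fitted with `intercept = TRUE`.
#' @export
setClass("AgingScoreModel",
    representation(markers = "character", coefficients = "numeric",
                   center = "numeric", scale = "numeric",
                   intercept = "numeric"))

setValidity("AgingScoreModel", function(object) {
    msg <- character()
    if (length(object@markers) != length(object@coefficients))
        msg <- c(msg, "one coefficient per marker required")
    if (!all(is.finite(object@coefficients)))
        msg <- c(msg, "coefficients must be finite")
    if (length(msg)) msg else TRUE
})

#' Aging-acceleration network of differential (partial) correlations
#'
#' An undirected gene graph. An edge between two genes is retained when the
#' absolute difference of their Pearson correlations between control and PD
#' samples and the absolute difference of their first-order partial
#' correlations given the aging score both exceed the delta threshold, under
#' a BH-FDR significance gate (see [buildNetwork()]).
#'
#' @slot nodes character, the gene universe the network was computed over.
#' @slot edges data.frame of retained pairs with per-edge statistics
#'   (`gene_a`, `gene_b`, `r_control`, `r_pd`, `rp_control`, `rp_pd`,
#'   `delta_r`, `delta_rp`, `q_min`).
#' @slot thresholds list with `delta`, `fdr`, `significance_mode`.
#' @slot provenance character free-text tag (e.g. "training").
#' @export
setClass("DifferentialNetwork",
    representation(nodes = "character", edges = "data.frame",
                   thresholds = "list", provenance = "character"))

setValidity("DifferentialNetwork", function(object) {
    msg <- character()
    ed <- object@edges
    need <- c("gene_a", "gene_b", "delta_r", "delta_rp")
    if (!all(need %in% colnames(ed)))
        msg <- c(msg, paste("edges needs columns",
                            paste(need, collapse = ", ")))
    else if (nrow(ed)) {
        if (any(ed$gene_a == ed$gene_b)) msg <- c(msg, "self-loop edge found")
        if (!all(c(ed$gene_a, ed$gene_b) %in% object@nodes))
            msg <- c(msg, "edge endpoint outside node universe")
    }
    if (length(msg)) msg else TRUE
})

#' Named gene sets over a universe
#'
#' @slot sets named list of character vectors (members, deduplicated).
#' @slot universe character, gene universe used for testing.
#' @slot source character free-text provenance.
#' @export
setClass("GeneSetCollection",
    representation(sets = "list", universe = "character",
                   source = "character"))

setValidity("GeneSetCollection", function(object) {
    msg <- character()
    if (length(object@sets)) {
        nm <- names(object@sets)
        if (is.null(nm) || any(!nzchar(nm)))
            msg <- c(msg, "every gene set must have a non-empty name")
        if (anyDuplicated(nm)) msg <- c(msg, "duplicate set names")
    }
    if (length(msg)) msg else TRUE
})
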