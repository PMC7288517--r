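#' Rank genes by absolute Pearson correlation with a binary phenotype
#'
#' Computes the Pearson correlation of each gene's expression with the 0/1
#' phenotype labels and orders genes by decreasing `|r|`, ties broken
#' lexicographically by gene id. Zero-variance genes get r = 0 and sort
#' after every gene with nonzero `|r|`.
#'
#' @param matrix numeric matrix, genes x samples.
#' @param labels 0/1 (or logical) phenotype, one per sample; both classes
#'   must be present.
#' @param label description of the coding, stored on the result.
#' @return A [RankedGeneList].
#' @export
rankGenesByCorrelation <- function(matrix, labels,
                                   label = "class0=0/class1=1") {
    labels <- asBinaryLabels(labels)
    if (length(labels) != ncol(matrix))
        stop("one label per sample required")
    if (ncol(matrix) < 3) stop("need at least 3 samples")
    if (length(unique(labels)) < 2)
        stop("both label values must be present")
    y <- labels - mean(labels)
    xc <- matrix - rowMeans(matrix)
    num <- as.vector(xc %*% y)
    den <- sqrt(rowSums(xc^2)) * sqrt(sum(y^2))
    r <- ifelse(den > 0, num / den, 0)
    r <- pmin(1, pmax(-1, r))
    ord <- order(-abs(r), rownames(matrix))
    tb <- data.frame(gene = rownames(matrix)[ord], r = r[ord],
                     rank = seq_len(nrow(matrix)), stringsAsFactors = FALSE)
    methods::new("RankedGeneList", table = tb, label = label)
}

#' Build a cosine k-nearest-neighbour model
#'
#' @param matrix numeric training matrix, genes x samples (must contain all
#'   `featureGenes`).
#' @param labels 0/1 training labels.
#' @param featureGenes ordered feature genes (typically the top-n of a
#'   [RankedGeneList]).
#' @param k neighbour count (default 5).
#' @param label description of the label coding.
#' @return A [KnnModel].
#' @export
knnModel <- function(matrix, labels, featureGenes, k = 5L,
                     label = "class0=0/class1=1") {
    labels <- asBinaryLabels(labels)
    miss <- setdiff(featureGenes, rownames(matrix))
    if (length(miss))
        stop("feature gene(s) absent from the matrix: ",
             paste(miss, collapse = ", "))
    methods::new("KnnModel", featureGenes = as.character(featureGenes),
                 k = as.integer(k),
                 trainX = matrix[featureGenes, , drop = FALSE],
                 trainLabels = labels, label = label)
}

# Cosine distances between columns of q and columns of t; zero-norm vectors
# are assigned distance 1 to everything (orthogonal convention).
cosineDistances <- function(q, tr) {
    nq <- sqrt(colSums(q^2))
    nt <- sqrt(colSums(tr^2))
    zq <- nq == 0
    zt <- nt == 0
    if (any(zq) || any(zt))
        warning("zero-norm feature vector(s); cosine distance set to 1")
    nq[zq] <- 1
    nt[zt] <- 1
    d <- 1 - crossprod(q / rep(nq, each = nrow(q)),
                       tr / rep(nt, each = nrow(tr)))
    d[zq, ] <- 1
    d[, zt] <- 1
    d
}

#' Predict with a cosine kNN model
#'
#' Distance is `1 - cos(query, training sample)` over the model's feature
#' genes; the k smallest distances (ties broken by training-sample index)
#' vote by majority, with even-vote ties resolved to class 0. The class-1
#' vote fraction is returned as a score.
#'
#' @param model a [KnnModel].
#' @param queries numeric matrix, genes x query samples (must contain all
#'   feature genes).
#' @return data.frame with columns `sample`, `score` (class-1 vote
#'   fraction) and `predicted` (0/1).
#' @export
knnPredict <- function(model, queries) {
    miss <- setdiff(model@featureGenes, rownames(queries))
    if (length(miss))
        stop("query matrix lacks feature gene(s): ",
             paste(miss, collapse = ", "))
    q <- queries[model@featureGenes, , drop = FALSE]
    d <- cosineDistances(q, model@trainX)
    k <- model@k
    score <- apply(d, 1, function(di) {
        nb <- order(di, seq_along(di))[seq_len(k)]
        mean(model@trainLabels[nb] == 1L)
    })
    data.frame(sample = colnames(queries), score = as.numeric(score),
               predicted = as.integer(score > 0.5), stringsAsFactors = FALSE,
               row.names = NULL)
}

# Stratified fold ids (1..folds) for 0/1 labels, deterministic under seed.
stratifiedFolds <- function(labels, folds, seed) {
    withSeed(seed, {
        fold <- integer(length(labels))
        for (cl in c(0L, 1L)) {
            idx <- sample(which(labels == cl))
            fold[idx] <- rep_len(seq_len(folds), length(idx))
        }
        fold
    })
}

#' Cross-validated learning curve over candidate feature counts
#'
#' For every candidate feature count n in `1..maxFeatures`, estimates the
#' mean stratified k-fold CV accuracy of the cosine kNN classifier on the
#' top-n correlation-ranked genes, and selects the smallest n attaining the
#' maximum. By default genes are re-ranked inside each training fold so
#' feature selection never sees the held-out fold; `rankOnce = TRUE`
#' instead ranks once on the full training data before splitting
#' (the single-ranking variant of the original procedure).
#'
#' @param matrix numeric matrix, genes x samples.
#' @param labels 0/1 labels.
#' @param maxFeatures largest candidate feature count (default 100; capped
#'   at the number of genes with a warning).
#' @param folds number of CV folds (default 10).
#' @param k kNN neighbour count (default 5).
#' @param seed RNG seed for the fold assignment.
#' @param rankOnce logical; rank features once on the full data instead of
#'   per fold.
#' @return A [CvCurve].
#' @export
crossValidateFeatureCounts <- function(matrix, labels, maxFeatures = 100L,
                                       folds = 10L, k = 5L, seed = 1L,
                                       rankOnce = FALSE) {
    labels <- asBinaryLabels(labels)
    if (min(table(factor(labels, levels = c(0, 1)))) < folds)
        stop("need at least 'folds' samples in each class")
    if (maxFeatures > nrow(matrix)) {
        warning("maxFeatures capped at the number of genes (", nrow(matrix),
                ")")
        maxFeatures <- nrow(matrix)
    }
    fold <- stratifiedFolds(labels, folds, seed)
    globalRank <- if (rankOnce) rankGenesByCorrelation(matrix, labels)
    accMat <- matrix(NA_real_, nrow = maxFeatures, ncol = folds)
    for (f in seq_len(folds)) {
        testIdx <- which(fold == f)
        trainIdx <- which(fold != f)
        ranking <- if (rankOnce) globalRank else
            rankGenesByCorrelation(matrix[, trainIdx, drop = FALSE],
                                   labels[trainIdx])
        ordGenes <- head(rankTable(ranking)$gene, maxFeatures)
        trX <- matrix[ordGenes, trainIdx, drop = FALSE]
        teX <- matrix[ordGenes, testIdx, drop = FALSE]
        trY <- labels[trainIdx]
        teY <- labels[testIdx]
        # cumulative cosine distances over growing feature prefixes;
        # conventions identical to knnPredict (zero norm -> distance 1)
        dots <- matrix(0, length(testIdx), length(trainIdx))
        sqQ <- rep(0, length(testIdx))
        sqT <- rep(0, length(trainIdx))
        for (n in seq_len(maxFeatures)) {
            dots <- dots + outer(teX[n, ], trX[n, ])
            sqQ <- sqQ + teX[n, ]^2
            sqT <- sqT + trX[n, ]^2
            den <- outer(sqrt(sqQ), sqrt(sqT))
            d <- 1 - dots / den
            d[sqQ == 0, ] <- 1
            d[, sqT == 0] <- 1
            predN <- vapply(seq_len(nrow(d)), function(i) {
                nb <- order(d[i, ], seq_len(ncol(d)))[seq_len(k)]
                as.integer(mean(trY[nb] == 1L) > 0.5)
            }, integer(1))
            accMat[n, f] <- mean(predN == teY)
        }
    }
    acc <- rowMeans(accMat)
    methods::new("CvCurve", accuracy = acc,
                 selectedN = which(acc >= max(acc) - 1e-12)[1L],
                 folds = as.integer(folds))
}

#' Stratified train/test split
#'
#' Splits samples into training and test partitions at the given ratio,
#' stratified by class so class proportions match across partitions within
#' one sample; deterministic under the seed.
#'
#' @param labels 0/1 labels, one per sample.
#' @param testFraction fraction held out (default 1/3, a 2:1 split).
#' @param seed RNG seed.
#' @return list with integer index vectors `train` and `test`.
#' @export
splitTrainTest <- function(labels, testFraction = 1 / 3, seed = 1L) {
    labels <- asBinaryLabels(labels)
    if (length(unique(labels)) < 2) stop("both classes must be present")
    if (min(table(labels)) < 3) stop("each class needs at least 3 samples")
    withSeed(seed, {
        test <- integer()
        for (cl in c(0L, 1L)) {
            idx <- which(labels == cl)
            test <- c(test, sample(idx, round(length(idx) * testFraction)))
        }
        test <- sort(test)
        list(train = setdiff(seq_along(labels), test), test = test)
    })
}

#' Evaluate a kNN model on a test set
#'
#' Computes majority-vote accuracy and, when both classes are present, the
#' ROC step curve over the class-1 vote-fraction scores and its trapezoidal
#' AUC.
#'
#' @param model a [KnnModel].
#' @param testMatrix genes x test samples.
#' @param testLabels 0/1 truth.
#' @return A [RocResult] (with `auc = NA` for one-class test labels).
#' @export
evaluateModel <- function(model, testMatrix, testLabels) {
    testLabels <- asBinaryLabels(testLabels)
    if (!length(testLabels)) stop("test set is empty")
    pred <- knnPredict(model, testMatrix)
    roc <- rocCurve(pred$score, testLabels)
    methods::new("RocResult", scores = pred$score, labels = testLabels,
                 predicted = pred$predicted, fpr = roc$fpr, tpr = roc$tpr,
                 auc = roc$auc,
                 accuracy = mean(pred$predicted == testLabels))
}

# ROC step curve and trapezoid AUC from scores and 0/1 labels.
rocCurve <- function(scores, labels) {
    pos <- sum(labels == 1L)
    neg <- sum(labels == 0L)
    if (pos == 0L || neg == 0L)
        return(list(fpr = numeric(), tpr = numeric(), auc = NA_real_))
    thr <- sort(unique(scores), decreasing = TRUE)
    tpr <- vapply(thr, function(t) sum(labels == 1L & scores >= t) / pos,
                  0)
    fpr <- vapply(thr, function(t) sum(labels == 0L & scores >= t) / neg,
                  0)
    fpr <- c(0, fpr, 1)
    tpr <- c(0, tpr, 1)
    auc <- sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
    list(fpr = fpr, tpr = tpr, auc = auc)
}

#' Train a predictor end to end on a cohort
#'
#' Runs the full modelling pipeline for one of three tasks:
#' * `"aging"` — young (0) vs old (1) on normal samples;
#' * `"pd-traditional"` — normal old (0) vs PD (1) on the expression matrix
#'   as given;
#' * `"pd-improved"` — as above, after replacing every old/PD sample by its
#'   residual from the top principal components of the healthy young
#'   samples ([residualizeOnYoung()]), so covariation already present in
#'   young samples cannot drive the classifier.
#'
#' The pipeline is: stratified 2:1 train/test split, correlation ranking,
#' CV selection of the feature count ([crossValidateFeatureCounts()]),
#' final model fit on the training partition, and test-set evaluation.
#'
#' @param cohort an [AgingCohort] (typically normalized).
#' @param task one of `"aging"`, `"pd-improved"`, `"pd-traditional"`.
#' @param maxFeatures,folds,k,rankOnce passed to
#'   [crossValidateFeatureCounts()].
#' @param ageCut young/old threshold in years.
#' @param testFraction held-out fraction for the outer split.
#' @param seed RNG seed (split and folds are derived from it).
#' @return list with `model` ([KnnModel]), `ranking` ([RankedGeneList]),
#'   `cv` ([CvCurve]), `evaluation` ([RocResult]), `markers` (the selected
#'   top genes) and the index split.
#' @export
trainPredictor <- function(cohort, task = c("aging", "pd-improved",
                                            "pd-traditional"),
                           maxFeatures = 100L, folds = 10L, k = 5L,
                           rankOnce = FALSE, ageCut = 50,
                           testFraction = 1 / 3, seed = 1L) {
    task <- match.arg(task)
    m <- exprsMatrix(cohort)
    grp <- sampleGroups(cohort)
    acl <- ageClasses(cohort, ageCut)
    if (task == "aging") {
        keep <- grp == "normal"
        labels <- as.integer(acl[keep] == "old")
        label <- "young=0/old=1"
        x <- m[, keep, drop = FALSE]
    } else {
        keep <- (grp == "normal" & acl == "old") | grp == "PD"
        labels <- as.integer(grp[keep] == "PD")
        label <- "normal=0/PD=1"
        x <- m[, keep, drop = FALSE]
        if (task == "pd-improved") {
            young <- m[, grp == "normal" & acl == "young", drop = FALSE]
            if (!ncol(young)) stop("no healthy young samples available")
            x <- residualizeOnYoung(x, young)
        }
    }
    split <- splitTrainTest(labels, testFraction, seed = stageSeed(seed, 1L))
    trX <- x[, split$train, drop = FALSE]
    trY <- labels[split$train]
    ranking <- rankGenesByCorrelation(trX, trY, label = label)
    cv <- crossValidateFeatureCounts(trX, trY, maxFeatures = maxFeatures,
                                     folds = folds, k = k,
                                     seed = stageSeed(seed, 2L),
                                     rankOnce = rankOnce)
    markers <- topGenes(ranking, selectedN(cv))
    model <- knnModel(trX, trY, markers, k = k, label = label)
    evaluation <- evaluateModel(model, x[, split$test, drop = FALSE],
                                labels[split$test])
    list(task = task, model = model, ranking = ranking, cv = cv,
         evaluation = evaluation, markers = markers, split = split,
         labels = labels, samples = colnames(x))
}
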