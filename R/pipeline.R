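#' Pipeline configuration
#'
#' Collects and validates every tunable of the end-to-end run. Defaults are
#' the study's parameter values (kNN k = 5, 10-fold CV, up to 100 candidate
#' features, age cut 50 y, sigmoid 50/50, delta threshold 0.5, BH-FDR 0.05,
#' 1000 permutation replicates, enrichment thresholds p < 0.05 and
#' FDR < 0.1). Input is either a [syntheticConfig()] (default) or a cohort
#' directory written by [writeCohort()].
#'
#' @param synthetic a [syntheticConfig()], or NULL when reading from disk.
#' @param input_dir cohort directory for [readCohort()] (used when
#'   `synthetic` is NULL).
#' @param age_cut young/old and early-onset threshold, years.
#' @param zero_fraction gene-removal threshold on the zero fraction.
#' @param n_components SVD / young-PC components removed.
#' @param max_features,folds,k,rank_once,test_fraction predictor settings.
#' @param sigmoid_center,sigmoid_scale age-sigmoid parameters, years.
#' @param score_fit_group `"normal"` (default) fits the aging score on
#'   normal samples only; `"all"` uses every sample.
#' @param score_intercept logical; fit the aging score with an intercept
#'   (default TRUE: normalized markers are mean-zero, so the no-intercept
#'   model cannot represent the mean transformed age).
#' @param delta_threshold,fdr_threshold,significance_mode network settings.
#' @param network_max_genes cap on the number of genes entering the
#'   all-pairs network stage.
#' @param perm_reps,top_betweenness permutation-test settings.
#' @param enrich_p,enrich_fdr enrichment pass thresholds.
#' @param gene_sets_gmt optional GMT file; when NULL, gene sets are
#'   generated around the planted ground truth (synthetic runs only).
#' @param n_decoy_sets,set_size generated gene-set settings.
#' @param seed global seed; stage seeds are derived by fixed offsets.
#' @param out_dir output directory.
#' @return A validated list of class `"PipelineConfig"`.
#' @export
pipelineConfig <- function(synthetic = syntheticConfig(), input_dir = NULL,
                           age_cut = 50, zero_fraction = 0.30,
                           n_components = 3L, max_features = 100L,
                           folds = 10L, k = 5L, rank_once = FALSE,
                           test_fraction = 1 / 3, sigmoid_center = 50,
                           sigmoid_scale = 50, score_fit_group = "normal",
                           score_intercept = TRUE,
                           delta_threshold = 0.5, fdr_threshold = 0.05,
                           significance_mode = "any",
                           network_max_genes = 2000L, perm_reps = 1000L,
                           top_betweenness = 10L, enrich_p = 0.05,
                           enrich_fdr = 0.1, gene_sets_gmt = NULL,
                           n_decoy_sets = 20L, set_size = 15L, seed = 1L,
                           out_dir = tempfile("agingaccel_run_")) {
    cfg <- as.list(environment())
    if (is.null(cfg$synthetic) && is.null(cfg$input_dir))
        stop("either 'synthetic' or 'input_dir' must be given")
    if (!is.null(cfg$synthetic) && !inherits(cfg$synthetic,
                                             "SyntheticConfig"))
        cfg$synthetic <- do.call(syntheticConfig, as.list(cfg$synthetic))
    inRange <- function(x, lo, hi, name) {
        if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < lo || x > hi)
            stop(sprintf("'%s' must lie in [%g, %g]", name, lo, hi))
    }
    inRange(cfg$delta_threshold, 0, 2, "delta_threshold")
    inRange(cfg$fdr_threshold, 0, 1, "fdr_threshold")
    inRange(cfg$zero_fraction, 0, 1, "zero_fraction")
    inRange(cfg$test_fraction, 0.05, 0.95, "test_fraction")
    inRange(cfg$enrich_p, 0, 1, "enrich_p")
    inRange(cfg$enrich_fdr, 0, 1, "enrich_fdr")
    if (!cfg$score_fit_group %in% c("normal", "all"))
        stop("'score_fit_group' must be 'normal' or 'all'")
    if (!cfg$significance_mode %in% c("any", "all", "off"))
        stop("'significance_mode' must be 'any', 'all' or 'off'")
    for (f in c("n_components", "max_features", "folds", "k", "perm_reps",
                "top_betweenness", "n_decoy_sets", "set_size",
                "network_max_genes"))
        stopifnotScalarCount(cfg[[f]], f, min = if (f %in%
            c("n_decoy_sets", "perm_reps")) 0L else 1L)
    class(cfg) <- "PipelineConfig"
    cfg
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the arguments of [pipelineConfig()]; a `synthetic`
#' mapping mirrors [syntheticConfig()]. Unknown keys are rejected.
#'
#' @param path YAML file path.
#' @return A `"PipelineConfig"`.
#' @export
readPipelineConfig <- function(path) {
    y <- yaml::read_yaml(path)
    known <- names(formals(pipelineConfig))
    unknown <- setdiff(names(y), known)
    if (length(unknown))
        stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
    if (!is.null(y$synthetic)) {
        sk <- setdiff(names(y$synthetic), names(formals(syntheticConfig)))
        if (length(sk))
            stop("unknown synthetic key(s): ", paste(sk, collapse = ", "))
        y$synthetic <- do.call(syntheticConfig, y$synthetic)
    }
    do.call(pipelineConfig, y)
}

writeTsv <- function(df, path) {
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    basename(path)
}

predictorOutputs <- function(fit, prefix, dir) {
    files <- c(
        writeTsv(rankTable(fit$ranking),
                 file.path(dir, paste0(prefix, "_ranked_genes.tsv"))),
        writeTsv(data.frame(n_features = seq_along(cvAccuracy(fit$cv)),
                            cv_accuracy = cvAccuracy(fit$cv)),
                 file.path(dir, paste0(prefix, "_learning_curve.tsv"))),
        writeTsv(data.frame(fpr = fit$evaluation@fpr,
                            tpr = fit$evaluation@tpr),
                 file.path(dir, paste0(prefix, "_roc.tsv"))))
    list(files = files,
         metrics = list(selected_n = selectedN(fit$cv),
                        cv_accuracy = cvAccuracy(fit$cv)[selectedN(fit$cv)],
                        test_accuracy = accuracy(fit$evaluation),
                        auc = auc(fit$evaluation)))
}

#' Run the full analysis pipeline
#'
#' Chains every stage on a synthetic or user cohort: preprocessing
#' (early-onset filtering and per-platform normalization), the aging
#' predictor, the improved and traditional PD predictors, aging scores with
#' the PD-vs-control comparison, the aging-acceleration networks on a
#' training and a replication partition with their Fisher similarity and
#' scale-free diagnostic, aging-PD shortest paths with opposite-sign pair
#' retention, linkage sums, path betweenness and its permutation null, and
#' per-path enrichment. All tabular outputs are written to
#' `config$out_dir` together with `manifest.json` recording every parameter
#' actually used. The run is deterministic under `config$seed`.
#'
#' @param config a [pipelineConfig()].
#' @return Invisibly, a list with all stage objects and the manifest.
#' @export
runPipeline <- function(config) {
    if (!inherits(config, "PipelineConfig"))
        stop("'config' must come from pipelineConfig()")
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    manifest <- list(package = "AgingAccel",
                     version = as.character(utils::packageVersion("AgingAccel")),
                     seed = config$seed,
                     parameters = config[setdiff(names(config),
                                                 c("synthetic", "out_dir"))],
                     synthetic = if (!is.null(config$synthetic))
                         unclass(config$synthetic),
                     stages = list())
    stage <- function(name, expr) {
        tryCatch(expr, error = function(e)
            stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
                 call. = FALSE))
    }

    ## stage 1: cohort
    cohort <- stage("cohort", {
        if (!is.null(config$synthetic)) generateCohort(config$synthetic)
        else readCohort(config$input_dir)
    })
    writeCohort(cohort, file.path(config$out_dir, "cohort"))
    manifest$stages$cohort <- list(
        n_genes = nrow(cohort), n_samples = ncol(cohort),
        files = "cohort/expression.tsv")

    ## stage 2: preprocess
    norm <- stage("preprocess", {
        m <- fillAndFilterGenes(exprsMatrix(cohort), config$zero_fraction)
        fs <- filterSamples(m, sampleTable(cohort), config$age_cut)
        nm <- suppressWarnings(
            normalizePlatform(fs$matrix, fs$table, config$age_cut,
                              config$n_components))
        AgingCohort(nm, fs$table, groundTruth = groundTruth(cohort))
    })
    manifest$stages$preprocess <- list(
        n_genes = nrow(norm), n_samples = ncol(norm),
        files = writeTsv(data.frame(GENE_SYMBOL = rownames(exprsMatrix(norm)),
                                    exprsMatrix(norm), check.names = FALSE),
                         file.path(config$out_dir,
                                   "expression_normalized.tsv")))

    ## stage 3: predictors
    fits <- list()
    for (task in c("aging", "pd-improved", "pd-traditional")) {
        fits[[task]] <- stage(task, trainPredictor(
            norm, task, maxFeatures = config$max_features,
            folds = config$folds, k = config$k,
            rankOnce = config$rank_once, ageCut = config$age_cut,
            testFraction = config$test_fraction,
            seed = stageSeed(config$seed, match(task, c(
                "aging", "pd-improved", "pd-traditional")))))
        po <- predictorOutputs(fits[[task]], gsub("-", "_", task),
                               config$out_dir)
        manifest$stages[[task]] <- c(po$metrics, list(files = po$files))
    }
    agingMarkers <- fits$aging$markers
    pdMarkers <- fits$`pd-improved`$markers

    ## stage 4: aging scores
    scoresOut <- stage("aging_score", {
        m <- exprsMatrix(norm)
        grp <- sampleGroups(norm)
        fitOn <- if (config$score_fit_group == "normal") grp == "normal"
                 else rep(TRUE, ncol(m))
        model <- suppressWarnings(fitAgingScore(
            m[, fitOn, drop = FALSE], sampleAges(norm)[fitOn], agingMarkers,
            config$sigmoid_center, config$sigmoid_scale,
            intercept = config$score_intercept))
        scores <- scoreSamples(model, m)
        comparison <- compareAgingByGroup(scores, sampleTable(norm))
        list(model = model, scores = scores, comparison = comparison)
    })
    manifest$stages$aging_score <- list(
        n_markers = length(agingMarkers),
        files = c(writeTsv(data.frame(sample_id = names(scoresOut$scores),
                                      age = sampleAges(norm),
                                      group = sampleGroups(norm),
                                      aging_score = scoresOut$scores),
                           file.path(config$out_dir, "aging_scores.tsv")),
                  writeTsv(scoresOut$comparison,
                           file.path(config$out_dir,
                                     "aging_score_comparison.tsv"))))

    ## stage 5: aging-acceleration networks (training + replication)
    nets <- stage("network", {
        m <- exprsMatrix(norm)
        grp <- sampleGroups(norm)
        acl <- ageClasses(norm, config$age_cut)
        ctrlIds <- names(grp)[grp == "normal" & acl == "old"]
        pdIds <- names(grp)[grp == "PD"]
        genes <- rownames(m)
        if (length(genes) > config$network_max_genes)
            genes <- sort(genes[seq_len(config$network_max_genes)])
        lab <- c(rep(0L, length(ctrlIds)), rep(1L, length(pdIds)))
        sp <- splitTrainTest(lab, config$test_fraction,
                             seed = stageSeed(config$seed, 5L))
        ids <- c(ctrlIds, pdIds)
        buildOne <- function(sel, tag) {
            cIds <- intersect(ids[sel], ctrlIds)
            pIds <- intersect(ids[sel], pdIds)
            buildNetwork(m[genes, cIds, drop = FALSE],
                         m[genes, pIds, drop = FALSE],
                         scoresOut$scores[cIds], scoresOut$scores[pIds],
                         config$delta_threshold, config$fdr_threshold,
                         config$significance_mode, provenance = tag)
        }
        train <- buildOne(sp$train, "training")
        test <- buildOne(sp$test, "replication")
        list(train = train, test = test,
             similarity = networkSimilarityFisher(train, test),
             scale_free = scaleFreeCheck(train))
    })
    manifest$stages$network <- list(
        n_edges_train = nrow(networkEdges(nets$train)),
        n_edges_test = nrow(networkEdges(nets$test)),
        fisher_p = nets$similarity$p,
        fisher_odds_ratio = nets$similarity$odds_ratio,
        scale_free_r = nets$scale_free$r,
        files = c(writeTsv(networkEdges(nets$train),
                           file.path(config$out_dir, "network_train_edges.tsv")),
                  writeTsv(networkEdges(nets$test),
                           file.path(config$out_dir,
                                     "network_test_edges.tsv"))))

    ## stage 6: bipartite aging-PD paths
    paths <- stage("bipartite_paths", {
        net <- nets$train
        pdM <- setdiff(pdMarkers, agingMarkers)
        agM <- intersect(agingMarkers, networkNodes(net))
        pdM <- intersect(pdM, networkNodes(net))
        pairs <- shortestMarkerPaths(net, agM, pdM)
        m <- exprsMatrix(norm)
        grp <- sampleGroups(norm)
        acl <- ageClasses(norm, config$age_cut)
        mk <- unique(c(agM, pdM))
        rC <- suppressWarnings(
            cor(t(m[mk, grp == "normal" & acl == "old", drop = FALSE])))
        rP <- suppressWarnings(cor(t(m[mk, grp == "PD", drop = FALSE])))
        rC[!is.finite(rC)] <- 0
        rP[!is.finite(rP)] <- 0
        retained <- retainOppositeSignPairs(pairs, rC, rP)
        linkage <- markerLinkageScores(retained)
        btw <- pathBetweenness(pairs, nodes = networkNodes(net))
        top <- head(btw, config$top_betweenness)
        perm <- if (config$perm_reps > 0 &&
                    length(agM) + length(pdM) <= length(networkNodes(net)))
            betweennessPermutationTest(net, length(agM), length(pdM), top,
                                       reps = config$perm_reps,
                                       seed = stageSeed(config$seed, 6L))
        else cbind(top, perm_p = NA_real_)
        list(pairs = pairs, retained = retained, linkage = linkage,
             betweenness = btw, permutation = perm)
    })
    pairsFlat <- paths$pairs
    pairsFlat$path <- vapply(pairsFlat$path, function(p)
        if (is.null(p)) NA_character_ else paste(p, collapse = "|"), "")
    manifest$stages$bipartite_paths <- list(
        n_candidate_pairs = nrow(paths$pairs),
        n_retained_pairs = nrow(paths$retained),
        top_betweenness = if (nrow(paths$betweenness))
            paths$betweenness$betweenness[1L] else 0L,
        files = c(writeTsv(pairsFlat,
                           file.path(config$out_dir, "aging_pd_pairs.tsv")),
                  writeTsv(paths$permutation,
                           file.path(config$out_dir, "betweenness.tsv")),
                  writeTsv(paths$linkage$aging,
                           file.path(config$out_dir, "linkage_aging.tsv")),
                  writeTsv(paths$linkage$pd,
                           file.path(config$out_dir, "linkage_pd.tsv"))))

    ## stage 7: enrichment
    enrich <- stage("enrichment", {
        collection <- if (!is.null(config$gene_sets_gmt))
            readGmt(config$gene_sets_gmt)
        else if (!is.null(groundTruth(cohort)))
            generateGeneSets(groundTruth(cohort), rownames(norm),
                             config$n_decoy_sets, config$set_size,
                             seed = stageSeed(config$seed, 7L))
        else stop("no gene sets: supply 'gene_sets_gmt'")
        src <- if (nrow(paths$retained)) paths$retained else paths$pairs
        withPath <- !vapply(src$path, is.null, TRUE)
        pl <- src$path[withPath]
        if (length(pl)) {
            names(pl) <- sprintf("%s__%s", src$aging[withPath],
                                 src$pd[withPath])
            table <- enrichPaths(pl, collection, config$enrich_p,
                                 config$enrich_fdr)
        } else {
            table <- data.frame(path_id = character(), set = character(),
                                p = numeric(), q = numeric(),
                                pass = logical())
            attr(table, "summary") <- data.frame(set = character(),
                                                 n_enriched_paths = integer())
        }
        list(collection = collection, table = table,
             summary = attr(table, "summary"))
    })
    writeGmt(enrich$collection, file.path(config$out_dir, "gene_sets.gmt"))
    manifest$stages$enrichment <- list(
        n_sets = length(geneSets(enrich$collection)),
        n_paths_tested = length(unique(enrich$table$path_id)),
        n_passing_rows = sum(enrich$table$pass),
        files = c("gene_sets.gmt",
                  writeTsv(enrich$table,
                           file.path(config$out_dir, "enrichment.tsv")),
                  writeTsv(enrich$summary,
                           file.path(config$out_dir,
                                     "enrichment_summary.tsv"))))

    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         pretty = TRUE)
    invisible(list(config = config, cohort = cohort, normalized = norm,
                   predictors = fits, aging_score = scoresOut,
                   networks = nets, paths = paths, enrichment = enrich,
                   manifest = manifest))
}

#' Draw the standard run figures
#'
#' Reads the tabular outputs of a completed [runPipeline()] directory and
#' writes four PNG figures: the aging-predictor learning curve, its ROC
#' curve, aging-score boxplots by age threshold and group, and the log-log
#' degree distribution of the training network. Figures whose inputs are
#' missing are skipped with a warning; an empty ROC table yields a labelled
#' placeholder.
#'
#' @param runDir output directory of a pipeline run.
#' @return Character vector of the files written, invisibly.
#' @export
makeFigures <- function(runDir) {
    written <- character()
    plotTo <- function(file, expr) {
        grDevices::png(file.path(runDir, file), width = 900, height = 700,
                       res = 120)
        on.exit(grDevices::dev.off(), add = TRUE)
        expr
        written <<- c(written, file)
    }
    lc <- file.path(runDir, "aging_learning_curve.tsv")
    if (file.exists(lc)) {
        d <- read.delim(lc)
        plotTo("learning_curve.png", {
            plot(d$n_features, d$cv_accuracy, type = "l",
                 xlab = "number of top-ranked genes",
                 ylab = "mean CV accuracy", main = "Aging predictor")
            best <- which.max(d$cv_accuracy)
            graphics::abline(v = d$n_features[best], lty = 2)
        })
    } else warning("learning-curve table missing; figure skipped")
    rocf <- file.path(runDir, "aging_roc.tsv")
    if (file.exists(rocf)) {
        d <- read.delim(rocf)
        plotTo("roc.png", {
            if (!nrow(d)) {
                warning("ROC table empty; placeholder written")
                plot.new()
                graphics::title("ROC unavailable")
            } else {
                plot(d$fpr, d$tpr, type = "l", xlab = "false positive rate",
                     ylab = "true positive rate", main = "Aging predictor ROC")
                graphics::abline(0, 1, lty = 3)
            }
        })
    } else warning("ROC table missing; figure skipped")
    sc <- file.path(runDir, "aging_scores.tsv")
    if (file.exists(sc)) {
        d <- read.delim(sc)
        plotTo("scores_by_threshold.png", {
            thr <- seq(50, 85, by = 5)
            groupsAt <- lapply(thr, function(t) {
                list(ctrl = d$aging_score[d$age >= t & d$group == "normal"],
                     pd = d$aging_score[d$age >= t & d$group == "PD"])
            })
            boxes <- unlist(groupsAt, recursive = FALSE)
            graphics::boxplot(boxes, col = rep(c("grey80", "tomato"),
                                               length(thr)),
                              names = rep(thr, each = 2), las = 2,
                              ylab = "aging score",
                              main = "Aging score by age threshold (grey = control, red = PD)")
        })
    } else warning("aging-score table missing; figure skipped")
    ed <- file.path(runDir, "network_train_edges.tsv")
    if (file.exists(ed)) {
        d <- read.delim(ed)
        plotTo("degree_distribution.png", {
            if (!nrow(d)) {
                plot.new()
                graphics::title("network empty")
            } else {
                deg <- table(c(d$gene_a, d$gene_b))
                tab <- table(as.integer(deg))
                plot(log10(as.numeric(names(tab))), log10(as.numeric(tab)),
                     xlab = "log10 degree", ylab = "log10 frequency",
                     main = "Degree distribution (training network)")
            }
        })
    } else warning("edge table missing; degree figure skipped")
    invisible(written)
}
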