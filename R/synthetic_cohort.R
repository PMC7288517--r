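#' Configuration for the synthetic cohort generator
#'
#' Assembles and validates the parameters of [generateCohort()]. The defaults
#' emulate the structure of the multi-platform LOPD study design the package
#' targets: three sample groups (healthy young < 50 y, healthy old >= 50 y,
#' PD patients all >= 50 y) at the study's sample sizes, five platforms with
#' additive per-(gene, platform) shifts, a block of genes whose mean follows
#' the sigmoid-transformed age, a block of genes shifted in PD, and planted
#' gene pairs whose co-expression flips sign between control and PD samples.
#'
#' @param n_genes number of genes.
#' @param n_young,n_old_normal,n_pd samples per group (young/old normal, PD).
#' @param n_aging_genes genes with an age-dependent mean.
#' @param aging_effect slope of the age-dependent mean: expression units per
#'   standard deviation of the cohort's sigmoid-transformed age (so
#'   `aging_effect = 2` with `noise_sd = 1` plants a two-noise-SD swing per
#'   transformed-age SD). The mean is linear in the sigmoid-transformed age.
#' @param n_pd_genes genes mean-shifted in PD samples.
#' @param pd_effect size of that shift (expression units).
#' @param n_diff_edges planted differential-correlation gene pairs.
#' @param latent_corr_strength within-pair correlation magnitude in `[0, 1)`;
#'   `+latent_corr_strength` in controls, `-latent_corr_strength` in PD.
#' @param n_latent_factors global co-expression factors loading on every
#'   gene in every sample (default 3). These emulate the dominant
#'   transcriptome-wide covariation modules of real expression data: they
#'   are what the rank-3 SVD step of the normalization and the young-PC
#'   residualization remove, and they are why a disease mean shift only
#'   becomes cleanly visible after that removal.
#' @param latent_factor_sd SD of the per-gene factor loadings.
#' @param platform_ids character vector of platform labels.
#' @param platform_shift_sd SD of the additive per-(gene, platform) offset.
#' @param noise_sd SD of the i.i.d. Gaussian noise (> 0).
#' @param seed integer RNG seed.
#' @return A validated list of class `"SyntheticConfig"`.
#' @export
syntheticConfig <- function(n_genes = 300L, n_young = 425L,
                            n_old_normal = 447L, n_pd = 392L,
                            n_aging_genes = 30L, aging_effect = 2,
                            n_pd_genes = 20L, pd_effect = 2,
                            n_diff_edges = 20L, latent_corr_strength = 0.8,
                            n_latent_factors = 3L, latent_factor_sd = 1,
                            platform_ids = c("GPL96", "GPL97", "GPL570",
                                             "GPL6104", "GPL6947"),
                            platform_shift_sd = 0.5, noise_sd = 1,
                            seed = 1L) {
    cfg <- list(n_genes = as.integer(n_genes), n_young = as.integer(n_young),
                n_old_normal = as.integer(n_old_normal),
                n_pd = as.integer(n_pd),
                n_aging_genes = as.integer(n_aging_genes),
                aging_effect = as.numeric(aging_effect),
                n_pd_genes = as.integer(n_pd_genes),
                pd_effect = as.numeric(pd_effect),
                n_diff_edges = as.integer(n_diff_edges),
                latent_corr_strength = as.numeric(latent_corr_strength),
                n_latent_factors = as.integer(n_latent_factors),
                latent_factor_sd = as.numeric(latent_factor_sd),
                platform_ids = as.character(platform_ids),
                platform_shift_sd = as.numeric(platform_shift_sd),
                noise_sd = as.numeric(noise_sd), seed = as.integer(seed))
    for (f in c("n_genes", "n_young", "n_old_normal", "n_pd",
                "n_aging_genes", "n_pd_genes", "n_diff_edges",
                "n_latent_factors"))
        stopifnotScalarCount(cfg[[f]], f)
    if (cfg$latent_factor_sd < 0)
        stop("'latent_factor_sd' must be >= 0")
    if (cfg$n_aging_genes + cfg$n_pd_genes > cfg$n_genes)
        stop("'n_aging_genes' + 'n_pd_genes' exceeds 'n_genes'")
    if (cfg$latent_corr_strength < 0 || cfg$latent_corr_strength >= 1)
        stop("'latent_corr_strength' must lie in [0, 1)")
    if (!is.finite(cfg$noise_sd) || cfg$noise_sd <= 0)
        stop("'noise_sd' must be > 0")
    if (cfg$platform_shift_sd < 0)
        stop("'platform_shift_sd' must be >= 0")
    if (!length(cfg$platform_ids))
        stop("'platform_ids' must name at least one platform")
    if (2L * cfg$n_diff_edges >
        cfg$n_genes - cfg$n_aging_genes - cfg$n_pd_genes)
        stop("'n_diff_edges' too large: each pair needs two genes outside ",
             "the aging and PD gene blocks")
    class(cfg) <- "SyntheticConfig"
    cfg
}

#' Simulate a multi-platform aging/PD expression cohort
#'
#' Draws ages uniformly (young in 20..49 years, old-normal and PD in
#' 50..95), assigns samples to platforms uniformly, and builds expression as
#' the sum of i.i.d. Gaussian noise, a per-(gene, platform) offset, global
#' co-expression latent factors loading on every gene (the dominant
#' components that the SVD normalization and young-PC residualization are
#' designed to remove), an age-dependent mean for the aging genes
#' (`aging_effect` times the standardized sigmoid-transformed age), a
#' `pd_effect` mean shift for the PD genes in PD samples, and for each
#' planted differential pair a shared pair-level latent `z`: both genes
#' load `+a*z` in control samples while the second gene loads `-a*z` in PD
#' samples, with `a` scaled against the total background variance so the
#' within-pair correlation is about `+rho` in controls and `-rho` in PD
#' (`rho = latent_corr_strength`).
#'
#' @param config a [syntheticConfig()].
#' @return An [AgingCohort] carrying its [GroundTruth] in the metadata.
#' @examples
#' cohort <- generateCohort(syntheticConfig(n_genes = 50, n_young = 20,
#'                                          n_old_normal = 20, n_pd = 20,
#'                                          n_diff_edges = 3))
#' cohort
#' @export
generateCohort <- function(config) {
    if (!inherits(config, "SyntheticConfig"))
        config <- do.call(syntheticConfig, as.list(config))
    withSeed(config$seed, {
        ng <- config$n_genes
        genes <- sprintf("GENE%04d", seq_len(ng))
        groups <- c(rep("normal", config$n_young + config$n_old_normal),
                    rep("PD", config$n_pd))
        ns <- length(groups)
        samples <- sprintf("%s%03d",
                           c(rep("YNG", config$n_young),
                             rep("NRM", config$n_old_normal),
                             rep("PDS", config$n_pd)),
                           c(seq_len(config$n_young),
                             seq_len(config$n_old_normal),
                             seq_len(config$n_pd)))
        ages <- c(sample(20:49, config$n_young, replace = TRUE),
                  sample(50:95, config$n_old_normal + config$n_pd,
                         replace = TRUE))
        platforms <- sample(config$platform_ids, ns, replace = TRUE)

        mat <- matrix(rnorm(ng * ns, 0, config$noise_sd), nrow = ng,
                      dimnames = list(genes, samples))
        shift <- matrix(rnorm(ng * length(config$platform_ids), 0,
                              config$platform_shift_sd), nrow = ng)
        colnames(shift) <- config$platform_ids
        mat <- mat + shift[, platforms, drop = FALSE]
        if (config$n_latent_factors > 0 && config$latent_factor_sd > 0) {
            loadings <- matrix(rnorm(ng * config$n_latent_factors, 0,
                                     config$latent_factor_sd), nrow = ng)
            factorScores <- matrix(rnorm(config$n_latent_factors * ns),
                                   nrow = config$n_latent_factors)
            mat <- mat + loadings %*% factorScores
        }

        pool <- genes
        aging <- sort(sample(pool, config$n_aging_genes))
        pool <- setdiff(pool, aging)
        pd <- sort(sample(pool, config$n_pd_genes))
        pool <- setdiff(pool, pd)

        if (config$n_aging_genes > 0) {
            tage <- sigmoidAge(ages)
            tage <- if (sd(tage) > 0) (tage - mean(tage)) / sd(tage)
                    else tage - mean(tage)
            mat[aging, ] <- mat[aging, , drop = FALSE] +
                config$aging_effect * matrix(tage, nrow = length(aging),
                                             ncol = ns, byrow = TRUE)
        }
        isPd <- groups == "PD"
        if (config$n_pd_genes > 0 && any(isPd))
            mat[pd, isPd] <- mat[pd, isPd, drop = FALSE] + config$pd_effect

        de <- data.frame(gene_a = character(), gene_b = character(),
                         r_control = numeric(), r_pd = numeric(),
                         stringsAsFactors = FALSE)
        if (config$n_diff_edges > 0) {
            rho <- config$latent_corr_strength
            picked <- sample(pool, 2L * config$n_diff_edges)
            # total background variance per gene (noise + expected factor
            # and platform components), so the realized within-pair
            # correlation is ~ +/- rho on average
            bg <- sqrt(config$noise_sd^2 +
                       config$n_latent_factors * config$latent_factor_sd^2 +
                       config$platform_shift_sd^2)
            a <- bg * sqrt(rho / (1 - rho))
            sgn <- ifelse(isPd, -1, 1)
            for (i in seq_len(config$n_diff_edges)) {
                g1 <- picked[2L * i - 1L]
                g2 <- picked[2L * i]
                z <- rnorm(ns)
                mat[g1, ] <- mat[g1, ] + a * z
                mat[g2, ] <- mat[g2, ] + a * sgn * z
            }
            pairs <- t(vapply(seq_len(config$n_diff_edges), function(i)
                sort(c(picked[2L * i - 1L], picked[2L * i])), character(2)))
            de <- data.frame(gene_a = pairs[, 1], gene_b = pairs[, 2],
                             r_control = rho, r_pd = -rho,
                             stringsAsFactors = FALSE)
        }

        truth <- methods::new("GroundTruth", agingGenes = aging,
                              pdGenes = pd, diffEdges = de,
                              trueAges = setNames(as.numeric(ages), samples))
        tab <- data.frame(sample_id = samples, age = ages, group = groups,
                          platform = platforms, stringsAsFactors = FALSE)
        AgingCohort(mat, tab, groundTruth = truth)
    })
}

#' Write / read a cohort as tab-delimited text
#'
#' `writeCohort()` writes `expression.tsv` (first column `GENE_SYMBOL`, one
#' column per sample), `samples.tsv` (`sample_id`, `age`, `group`,
#' `platform`) and, when ground truth is attached, `ground_truth.json`.
#' Values are serialized with 17 significant digits so the round trip
#' reproduces the matrix exactly. `readCohort()` inverts it.
#'
#' @param cohort an [AgingCohort].
#' @param dir directory to write into (created if needed).
#' @return `writeCohort()`: the directory, invisibly. `readCohort()`: an
#'   [AgingCohort].
#' @export
writeCohort <- function(cohort, dir) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    m <- exprsMatrix(cohort)
    fm <- matrix(sprintf("%.17g", m), nrow = nrow(m), ncol = ncol(m))
    df <- data.frame(GENE_SYMBOL = if (nrow(m)) rownames(m) else character(),
                     fm, stringsAsFactors = FALSE, check.names = FALSE)
    colnames(df) <- c("GENE_SYMBOL", colnames(m))
    write.table(df, file.path(dir, "expression.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(sampleTable(cohort), file.path(dir, "samples.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    gt <- groundTruth(cohort)
    if (!is.null(gt)) {
        jsonlite::write_json(
            list(aging_genes = gt@agingGenes, pd_genes = gt@pdGenes,
                 diff_edges = gt@diffEdges,
                 true_ages = as.list(gt@trueAges)),
            file.path(dir, "ground_truth.json"), digits = NA,
            auto_unbox = TRUE)
    }
    invisible(dir)
}

#' @rdname writeCohort
#' @export
readCohort <- function(dir) {
    ef <- file.path(dir, "expression.tsv")
    sf <- file.path(dir, "samples.tsv")
    for (f in c(ef, sf)) if (!file.exists(f)) stop("missing file: ", f)
    edf <- read.delim(ef, check.names = FALSE, colClasses = "character")
    if (!ncol(edf) || colnames(edf)[1] != "GENE_SYMBOL")
        stop("expression table must start with a GENE_SYMBOL column")
    m <- as.matrix(edf[, -1, drop = FALSE])
    storage.mode(m) <- "double"
    rownames(m) <- edf$GENE_SYMBOL
    tab <- read.delim(sf, check.names = FALSE, stringsAsFactors = FALSE)
    gt <- NULL
    gf <- file.path(dir, "ground_truth.json")
    if (file.exists(gf)) {
        j <- jsonlite::read_json(gf, simplifyVector = TRUE)
        de <- as.data.frame(j$diff_edges, stringsAsFactors = FALSE)
        if (!nrow(de))
            de <- data.frame(gene_a = character(), gene_b = character(),
                             r_control = numeric(), r_pd = numeric())
        gt <- methods::new("GroundTruth",
                           agingGenes = as.character(j$aging_genes),
                           pdGenes = as.character(j$pd_genes),
                           diffEdges = de,
                           trueAges = unlist(j$true_ages))
    }
    AgingCohort(m, tab, groundTruth = gt)
}

#' Build gene sets around the planted differential-edge genes
#'
#' Produces one "planted" set holding every gene involved in a planted
#' differential-correlation pair, padded up to `setSize` with genes drawn
#' from the rest of the universe, plus `nDecoySets` decoy sets drawn
#' uniformly from genes outside the planted set. Supports power checks of
#' the enrichment stage.
#'
#' @param truth a [GroundTruth].
#' @param universe character vector of all gene ids (the cohort's genes).
#' @param nDecoySets number of decoy sets.
#' @param setSize members per set.
#' @param seed RNG seed.
#' @return A [GeneSetCollection] whose universe is `universe`.
#' @export
generateGeneSets <- function(truth, universe, nDecoySets = 20L,
                             setSize = 15L, seed = 1L) {
    stopifnotScalarCount(nDecoySets, "nDecoySets")
    stopifnotScalarCount(setSize, "setSize", min = 1L)
    if (setSize > length(universe))
        stop("'setSize' exceeds the size of the gene universe")
    withSeed(seed, {
        core <- sort(unique(c(truth@diffEdges$gene_a, truth@diffEdges$gene_b)))
        core <- intersect(core, universe)
        pad <- setdiff(universe, core)
        planted <- sort(c(core,
                          if (length(core) < setSize)
                              sample(pad, setSize - length(core))))
        rest <- setdiff(universe, planted)
        sets <- list(PLANTED_DIFF_EDGE_SET = planted)
        if (nDecoySets > 0) {
            if (setSize > length(rest))
                stop("not enough genes outside the planted set for decoys of ",
                     "size ", setSize)
            for (i in seq_len(nDecoySets))
                sets[[sprintf("DECOY_SET_%03d", i)]] <- sort(sample(rest,
                                                                    setSize))
        }
        methods::new("GeneSetCollection", sets = sets,
                     universe = as.character(universe), source = "synthetic")
    })
}
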