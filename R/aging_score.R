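#' Sigmoid transform of chronological age
#'
#' `1 / (1 + exp(-(age - center) / scale))`, mapping age in years to a
#' dimensionless value in (0, 1) with value 0.5 at `center` (default 50 y).
#'
#' @param age numeric vector of ages in years.
#' @param center,scale sigmoid midpoint and width in years (defaults 50/50).
#' @return Transformed ages in (0, 1).
#' @examples
#' sigmoidAge(c(0, 50, 100))
#' @export
sigmoidAge <- function(age, center = 50, scale = 50) {
    1 / (1 + exp(-(age - center) / scale))
}

#' Fit the aging-score model
#'
#' No-intercept least-squares regression of the sigmoid-transformed age on
#' the aging-marker expressions: `transformed_age = sum_i b_i * marker_i`.
#' When the system is under-determined (more markers than samples, or rank
#' deficiency) the minimum-norm solution is returned with a warning.
#'
#' @param matrix numeric matrix, genes x samples, containing every marker.
#' @param ages numeric ages in years, one per sample.
#' @param markers character, aging-marker gene ids.
#' @param center,scale sigmoid parameters (see [sigmoidAge()]).
#' @param intercept logical; add an intercept term (default FALSE, the
#'   literal no-intercept model).
#' @return An [AgingScoreModel].
#' @export
fitAgingScore <- function(matrix, ages, markers, center = 50, scale = 50,
                          intercept = FALSE) {
    miss <- setdiff(markers, rownames(matrix))
    if (length(miss))
        stop("marker(s) missing from the matrix: ",
             paste(miss, collapse = ", "))
    if (length(ages) != ncol(matrix))
        stop("one age per sample required")
    y <- sigmoidAge(ages, center, scale)
    x <- t(matrix[markers, , drop = FALSE])    # samples x markers
    if (intercept) x <- cbind(`(Intercept)` = 1, x)
    if (nrow(x) <= ncol(x) - as.integer(intercept))
        warning("fewer samples than markers; returning the minimum-norm ",
                "least-squares solution")
    sv <- svd(x)
    tol <- max(dim(x)) * .Machine$double.eps * max(sv$d, 0)
    pos <- sv$d > tol
    if (sum(pos) < ncol(x) && nrow(x) > ncol(x))
        warning("rank-deficient marker matrix; returning the minimum-norm ",
                "least-squares solution")
    b <- sv$v[, pos, drop = FALSE] %*%
        ((1 / sv$d[pos]) * crossprod(sv$u[, pos, drop = FALSE], y))
    b <- as.vector(b)
    if (intercept) {
        icpt <- b[1L]
        b <- b[-1L]
    } else icpt <- 0
    methods::new("AgingScoreModel", markers = as.character(markers),
                 coefficients = b, center = center, scale = scale,
                 intercept = icpt)
}

#' Compute aging scores
#'
#' The aging score of a sample is the model's predicted transformed age,
#' `sum_i b_i * expression_i` (plus the intercept when one was fitted). It
#' is dimensionless and deliberately not clipped to (0, 1): scores above the
#' value expected for a sample's chronological age indicate accelerated
#' aging.
#'
#' @param model an [AgingScoreModel].
#' @param matrix genes x samples matrix containing every marker.
#' @return Named numeric vector of scores, one per sample.
#' @export
scoreSamples <- function(model, matrix) {
    miss <- setdiff(model@markers, rownames(matrix))
    if (length(miss))
        stop("marker(s) missing from the matrix: ",
             paste(miss, collapse = ", "))
    x <- matrix[model@markers, , drop = FALSE]
    setNames(as.vector(crossprod(x, model@coefficients)) + model@intercept,
             colnames(matrix))
}

#' Compare aging scores between PD and control across age thresholds
#'
#' For each age threshold t, takes every sample with `age >= t` and reports
#' group medians/means of chronological age and aging score together with a
#' Kruskal-Wallis test (tie-corrected, chi-square with 1 df for the
#' two-group comparison) of PD vs control scores. Thresholds at which one
#' group is empty yield an `NA` row.
#'
#' @param scores named numeric aging scores (names = sample ids).
#' @param table sample table (`sample_id`, `age`, `group`).
#' @param thresholds age thresholds in years (default 50 to 85 by 5).
#' @return data.frame, one row per threshold, with per-group summary
#'   statistics, `H` and `p`.
#' @export
compareAgingByGroup <- function(scores, table,
                                thresholds = seq(50, 85, by = 5)) {
    table <- table[match(names(scores), table$sample_id), , drop = FALSE]
    rows <- lapply(thresholds, function(t) {
        sel <- table$age >= t
        pd <- sel & table$group == "PD"
        ct <- sel & table$group == "normal"
        row <- data.frame(threshold = t, n_pd = sum(pd), n_control = sum(ct),
                          median_age_pd = NA_real_,
                          median_age_control = NA_real_,
                          mean_age_pd = NA_real_, mean_age_control = NA_real_,
                          median_score_pd = NA_real_,
                          median_score_control = NA_real_,
                          mean_score_pd = NA_real_,
                          mean_score_control = NA_real_,
                          H = NA_real_, p = NA_real_)
        if (!any(pd) || !any(ct)) return(row)
        row$median_age_pd <- median(table$age[pd])
        row$median_age_control <- median(table$age[ct])
        row$mean_age_pd <- mean(table$age[pd])
        row$mean_age_control <- mean(table$age[ct])
        row$median_score_pd <- median(scores[pd])
        row$median_score_control <- median(scores[ct])
        row$mean_score_pd <- mean(scores[pd])
        row$mean_score_control <- mean(scores[ct])
        if (stats::var(c(scores[pd], scores[ct])) == 0) {
            row$H <- 0
            row$p <- 1
        } else {
            kw <- kruskal.test(list(scores[ct], scores[pd]))
            row$H <- unname(kw$statistic)
            row$p <- kw$p.value
        }
        row
    })
    do.call(rbind, rows)
}
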